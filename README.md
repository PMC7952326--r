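# eamtools

Electroanatomic mapping (EAM) systems guide catheter ablation procedures
and, along the way, record everything an electrophysiology researcher
wants: chamber geometry, spatially localised intracardiac electrograms,
activation and voltage annotations, and ablation delivery parameters.
Exported study trees are proprietary, awkward to parse and enormous.
`eamtools` is an R toolkit for that data: a compact single-file exchange
container, a parser for a documented clinical-export-style dialect, and
the analysis layer researchers actually run on such studies — chamber
geometry, activation mapping, conduction velocity, voltage mapping,
electrogram access and ablation quantification — plus a seeded synthetic
study generator with known ground truth so every stage is testable
without clinical data.

## What it computes

For a chamber surface (vertices $X$, triangles $T$) with per-vertex LAT
$t_i$ (ms) and bipolar voltage $v_i$ (mV), and mapping points with
positions $x_i$ and annotations:

* **Geometry** — free-boundary loops (valve/vein rims), open (`nofill`)
  and hole-filled (`fill`) surface area, divergence-theorem chamber
  volume with automatic winding repair, and in/out point status by ray
  casting.
* **Interpolation** — $s(x) = \sum_i c_i e^{-\|x-x_i\|^2/2\sigma_k^2} +
  d_0 + d \cdot x$ fitted with ridge $\lambda$ and evaluated at the
  vertices, masked by a 10 mm colour-fill distance (also IDW / nearest).
* **Activation** — total activation time as $\max t - \min t$ or the
  central percentile range $P_{100-q} - P_q$ ($q = 2.5$), over point,
  clinical-map or re-interpolated-map populations; earliest-activation
  site, including a percentile-cohort variant.
* **Conduction velocity** — the RBF-gradient method: speed
  $= 1/\|\nabla s\|$ (m/s), tangent-plane direction field, and an
  area-weighted CV histogram.
* **Voltage** — area-weighted mean voltage, low-voltage area below
  0.5 mV by exact per-triangle isoline clipping, and area-weighted
  voltage histograms.
* **Ablation** — visitag import (index value, force, power, temperature,
  impedance, duration), lesion plots and union-semantics ablated area
  within a 5 mm influence radius.

## Worked example

```r
library(eamtools)

study <- make_study_fixture(
  n_points = 150, seed = 7, n_visitags = 15,
  patches = list(list(center_vertex = 40L, radius = 8, level = 0.3)))

get_area(study, "nofill"); get_area(study, "fill"); get_volume(study)
total_activation_time(study, "ptbased")
cv <- compute_conduction_velocity(study)
cv_histogram(cv, study)$median_speed
low_voltage_area(study, "map")
get_ablation_area(study)$area_cm2
```

prints (seed 7):

```
area (open):   102.24 cm2
area (closed): 113.00 cm2
volume:        105.04 cm3
TAT (point-based):      60.00 ms
TAT (2.5% percentile):  57.61 ms
median CV: 1.000 m/s over 102.2 cm2
low-voltage area (<0.5 mV): 0.61 cm2 (0.6% of 102.2 cm2)
ablated area (r = 5 mm): 9.56 cm2
```

Reading the numbers: the fixture is a 30 mm chamber with five anatomical
cut-outs, so the closed area (113 cm^2) exceeds the open one by exactly
the fan area of the five rims. The planar wave crosses the ~60 mm chamber
at 1 m/s, hence a 60 ms point-based TAT, and the CV method recovers the
1.000 m/s wave speed. The 0.3 mV patch of ~0.6 cm^2 shows up as the
low-voltage area below the conventional 0.5 mV threshold, and the 15
lesions mark 9.6 cm^2 at the default 5 mm radius.

Round-tripping a study is one call each way:

```r
emit_clinical_export(study, "export_tree")      # dialect tree (XML + CSV)
st   <- parse_clinical_export("export_tree")    # back to an eam_study
write_container(st, "study.openep.zip")         # single-file container
back <- read_container("study.openep.zip")      # bit-exact arrays
```

A command-line front end covers the same workflows
(`inst/cli/eamtool synth | import | batch-import | info | map | metrics |
visitag`); see `eamtool --help`.

## Scope notes

Activation times are taken as annotated by the source platform (no LAT
re-detection); only the RBF-gradient CV method is implemented; the
clinical dialect is a documented stand-in for proprietary export formats,
which are out of scope. See the methods vignette
(`vignettes/eamtools-methods.Rmd`) for the models, defaults and design
decisions in full.
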