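---
title: "Methods: electroanatomic mapping analysis in eamtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electroanatomic mapping analysis in eamtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamtools)
```

## The data model

An electroanatomic mapping (EAM) study couples two kinds of data acquired
during an electrophysiology procedure: a triangulated chamber surface with
per-vertex clinical map fields (local activation time `act` in ms, bipolar
voltage `bip` in mV), and a set of mapping points, each carrying a raw and a
surface-projected catheter position, electrogram traces (bipolar, a paired
unipolar pair, and a reference channel), a reference annotation, an
activation annotation, a window of interest, and scalar point voltages.
`eam_study()` is the root container; the two halves may be present
independently, and when both are present the surface-projected point
positions must lie on the mesh (within twice the mean edge length).

Conventions worth stating once:

* **Units.** Positions mm, times ms, voltages mV, conduction speed m/s
  (numerically identical to mm/ms). Areas and volumes are reported in
  cm^2 / cm^3.
* **Missing values** are `NaN`, and every derived surface field carries an
  explicit validity mask; clinical exports routinely contain unannotated
  points, so missingness is a first-class state, not an error.
* **Annotations** are absolute times on the trace clock; the window of
  interest is stored relative to the reference annotation, matching
  clinical convention. For every annotated point the activation annotation
  lies inside the absolute window.
* **Location-only points** (e.g. ablation tags) carry positions but no
  usable electrical data; they are excluded from every map computation.
* Internal indices are 1-based in R; clinical point ids are opaque labels,
  and all file formats store triangle and trace indices 0-based.

## The exchange container and the clinical dialect

The exchange container (`write_container()` / `read_container()`) is a
single ZIP archive holding `manifest.json` plus one CSV per array. Three
design choices carry the storage argument for this format: identical
traces referenced by several points (typically the shared reference
electrogram) are stored once and referenced by index; the whole study is
one file rather than tens of thousands; and numeric text is written with
17 significant digits, so read-back is bit-exact for 64-bit floats while
the extracted arrays stay diff-able. The archive is written by a small
deterministic store-only ZIP writer (fixed timestamps; same study, same
bytes) and read back with R's built-in extractor, which also verifies the
CRCs. The manifest declares every array's shape and is validated before
reconstruction: a truncated file is an integrity error naming the array,
never silent corruption, while unknown extra arrays are accepted with a
warning for forward compatibility.

The clinical-export-style dialect (`emit_clinical_export()` /
`parse_clinical_export()`) is a *documented simplification* of the file
trees clinical systems export (a study descriptor XML, a geometry file,
and per-point files). The proprietary schemas are not public, so the
dialect is a stand-in with the same structure: `study.xml` (name, sampling
frequency, map list), `mesh.xml`, one `P<id>_point.xml` and one
`P<id>_egm.csv` per point (the trace file is absent for location-only
points), and `visitags/sites.csv` (+ `grid.csv`) for ablation records.
Parsing is order-insensitive in the point list, selects the only map when
just one exists, and otherwise requires an explicit map name.

## Chamber geometry

Free-boundary detection walks all edges incident to exactly one triangle
and traces them into closed loops — on a clinical chamber these rims are
the anatomical structures (mitral valve, pulmonary veins). Hole filling
triangulates each loop by a fan to a new centroid vertex: deterministic,
linear-time, and adequate because clinical rims are near-planar. One
documented special case: on a planar sheet (a toy, not a chamber) the
outermost boundary is the sheet's rim, not a hole, and is left open —
filling it would double-cover the plane.

Surface area is the plain triangle-area sum, `"nofill"` on the open mesh
and `"fill"` after closing the cut-outs, so `fill >= nofill` and the
difference is exactly the summed fan areas. Volume closes the mesh,
repairs triangle winding by breadth-first propagation across shared edges
(clinical meshes are not guaranteed consistently wound), and applies the
divergence theorem `|sum det(a,b,c)/6|`; the signed sum makes the result
translation-invariant to floating-point cancellation (~1e-9 relative for
realistic coordinate offsets). Whether a clinical system's own "volume"
uses the filled or unfilled rim surface is unknowable from outside, so the
package documents its definition precisely instead of trying to match.
`point_status()` classifies points interior/exterior by crossing-parity
ray casting with a majority vote over three seeded ray directions, against
the closed surface.

## Surface interpolation

`generate_interp_data()` builds a scattered-data interpolant from point
positions and per-point values (relative LAT for `'lat-map'`, point
voltages for `'bip-map'`/`'uni-map'`) and evaluates it at every vertex.
The default scheme is a Gaussian radial basis function with a linear
polynomial tail,

$$s(x) = \sum_i c_i\,\varphi(\lVert x - x_i\rVert) + d_0 + d\cdot x,
\qquad \varphi(r) = e^{-r^2/2\sigma_k^2},$$

with coefficients from the augmented ridge system
$(\Phi + \lambda I)c + Pd = y$, $P^\top c = 0$. Defaults: kernel width
$\sigma_k$ = 2x the mean nearest-neighbour spacing of the sample points,
$\lambda = 10^{-8}\,\mathrm{tr}(\Phi)/p$; at $\lambda = 0$ the interpolant
passes through every sample. The polynomial tail reproduces constant and
linear fields exactly; this matters for conduction velocity (below) and
costs four extra unknowns. Degenerate layouts are handled rather than
assumed away: redundant polynomial columns are dropped for
collinear/coplanar samples, and a singular system at $\lambda = 0$
(duplicate positions) falls back to the default ridge with a warning.
Inverse-distance weighting and nearest-neighbour schemes are provided for
comparison; they obey the maximum principle, while the RBF may overshoot
the data range slightly (regression-tested under 10% on the fixtures).

Validity is distance-based colour fill: a vertex is valid iff it lies
within `fill_threshold` (default 10 mm, the conventional clinical value)
of a contributing point, using Euclidean (3D chord) distance — that is
what a clinical fill threshold means in practice; geodesic masking would
be an extension. Enlarging the threshold never invalidates a vertex.

## Activation metrics

Total activation time (TAT) comes in a six-method family: the population
is either the point annotations (`ptbased*`), the clinical vertex field
(`clinmap*`), or the re-interpolated field (`openepmap*`), and the
statistic is either the full range or the central percentile range
$P_{100-q} - P_q$ with default $q = 2.5$ (a central 95% range, robust to
single-point annotation errors in high-density maps). The exact
definitions of the map- and percentile-based variants are not published in
full anywhere we can cite, so this reconstruction — documented here and
flagged in the function help — is the package's own. Percentiles use
linear interpolation between closest order statistics, stated so that
ports to other languages agree to the last bit.

The earliest-activation site is the argmin location for the range-based
methods (ties to the lowest index). For the percentile method the site is
the centroid of all points with LAT at or below $P_q$, projected to the
nearest surface point; the published description names the method but not
its geometry, and the centroid-of-cohort rule is our documented choice.

## Conduction velocity

CV mapping fits the augmented RBF to (position, LAT) samples, evaluates
the *analytic* gradient at each vertex, and inverts the slowness:
speed $= 1/\lVert\nabla s\rVert$ in m/s. The direction field is the
gradient projected onto the local tangent plane (area-weighted vertex
normals) and normalised — a surface wave has no meaningful normal
direction, and the projection keeps directions tangent to within 1e-3.

The speed deliberately uses the full, unprojected gradient. Projecting
before inversion looks natural but inflates speeds on curved chambers:
for a planar wavefront crossing a sphere the tangential slowness is
$\sin\theta / v$ ($\theta$ the angle between wavefront normal and surface
normal), so apparent speeds are $v/\sin\theta \ge v$ with a median of
about $1.15v$ over a sphere — an artifact of the projection, not of the
data. With the linear tail the full gradient reproduces planar waves
exactly (the planar fixture recovers 1.000 m/s), which is the calibration
that justifies both this choice and the kernel-width default. Plateau
vertices ($\lVert\nabla s\rVert < 10^{-6}$ ms/mm) are marked invalid
rather than infinite; speeds outside the analysis clamp (default 0–10
m/s, physiologically impossible values flagged) are set to the clamp
bound; display convention is 0–2 m/s. The CV histogram assigns each
all-valid triangle's area to the bin of its mean vertex speed
(out-of-range speeds into the end bins, so bin areas conserve the valid
area exactly) and reports area-weighted mean and median speeds.

## Voltage metrics

All three voltage metrics run on either the clinical vertex field
(`method = "map"`) or a field re-interpolated from the exported point
voltages (`method = "egm"`), and all share one kernel: triangles whose
three vertices are valid, with the vertex values defining a linear field
per triangle. Mean voltage is the area-weighted mean of per-triangle
vertex means. Low-voltage area clips each triangle against the threshold
isoline exactly (the sub-threshold region is a triangle or quadrilateral
whose corners are vertices and edge crossings), so the area is continuous
and monotone in the threshold and independent of mesh resolution to first
order; whole-triangle thresholding would make the 0.5 mV convention
jumpy. The voltage histogram takes differences of the same cumulative
clipped area between consecutive edges; values below the first (above the
last) edge count into the first (last) bin so the bins always sum to the
total considered area. Invalid triangles are excluded from numerator and
denominator alike — whether clinical systems count uncoloured regions in
the denominator is not documented, so we state our choice. The default
threshold is 0.5 mV, the conventional bipolar low-voltage cut-off.

## Ablation

Visitag-style records store per-site position, a platform lesion-quality
index (Ablation Index / Lesion Size Index; these vary per platform, so
the value lives in one slot with a name attribute), contact force, power,
temperature, impedance and duration, plus an optional raw grid.
`get_ablation_area()` marks every triangle whose centroid lies within
`r_abl` of any projected site and sums marked areas: union semantics, so
overlapping lesions count once and duplicating a site changes nothing.
The published description does not state the radius its area function
uses; the default of 5 mm approximates a typical radiofrequency lesion
diameter and is an explicit argument everywhere it appears.

## The synthetic fixture generator

`make_study_fixture()` builds complete studies with known ground truth;
it is first-class, tested code, and its defaults are the package's study
conditions: a 30 mm chamber from an icosphere at subdivision level 3
(~1280 triangles before cut-outs), five cut-outs (one valve-sized, four
vein-sized, non-overlapping by construction), a planar wave at 1.0 m/s,
1 kHz electrograms, and seeded vertex sampling. These sizes keep every
suite at seconds scale while leaving the geometry non-trivial.

Activation: planar mode is the closed form
$t(x) = t_0 + n\cdot(x - x_{\min})/v$ — an exact linear field, the
fixture for CV recovery. Focal mode propagates by Dijkstra shortest paths
over the edge graph, which overestimates true geodesic distance slightly
and direction-dependently; focal fixtures therefore test earliest-site
recovery, not speed recovery. Voltage: geodesic discs of a given level in
a uniform background; the truth record carries both the area of triangles
fully inside the patch and the exact linear-field sub-threshold area from
an independent closed-form order-statistic formula
(`tri_area_below_oracle()`), deliberately a different algorithm from the
polygon clipping used by the metrics. Electrograms: a Gaussian-derivative
unipolar template $u(t) = -A\,\frac{t-t^*}{\tau} e^{-(t-t^*)^2/2\tau^2}$,
whose steepest negative slope — the conventional LAT marker — is exactly
at $t^*$; the proximal electrode is delayed by $\Delta$ (default 2 ms),
the bipole is their difference plus seeded Gaussian noise, and point
amplitudes are rescaled in a second pass so the bipolar peak-to-peak
voltage equals the voltage field at the point exactly. The reference
annotation is placed at 30% of the trace and the window of interest is
chosen to contain every annotation.

What the generator does *not* emulate — fibrosis texture, anisotropy,
re-entry, far-field components, fractionated electrograms, catheter
noise — bounds what green tests mean: they demonstrate correct geometry,
interpolation, metric and I/O behaviour on controlled inputs, not
clinical equivalence. The published validation of this class of platform
against clinical systems used proprietary exports that are not public,
so those correlation figures are not reproducible here and are not
claimed.

## Numerical choices, in one place

* Percentiles: linear interpolation between closest order statistics.
* RBF defaults: Gaussian kernel, $\sigma_k$ = 2x mean nearest-neighbour
  spacing, $\lambda = 10^{-8}\mathrm{tr}(\Phi)/p$; singular fallback to
  the same ridge with a warning.
* Ties in argmin (earliest site): lowest index wins.
* Plateau rule: gradient norm under $10^{-6}$ ms/mm marks a vertex
  invalid rather than producing infinite speed.
* Degenerate meshes: zero-area triangles and edges shared by three or
  more triangles are construction-time errors.
* Containers: `%.17g` numeric text, fixed ZIP timestamps, store-only
  compression; bit-exact round trips are asserted, not hoped for.
* Problem sizes in the shipped suites: chambers at subdivision 3 (~600
  vertices) for metric tests, subdivision 4 (5120 triangles) for analytic
  area/volume checks, 50–200 points for interpolation/CV/activation, 500
  points for the I/O identity run.

## Known limitations

Only one CV method is implemented (the RBF gradient method); triangulation,
omnipole, cosine-fit and polynomial-fit estimators are out of scope here.
LAT re-annotation from electrograms is out of scope: activation times are
taken as annotated by the source system. The dialect parser targets this
package's documented dialect, not the proprietary exports themselves.
Rendering uses orthographic ggplot2 projections (AP/PA views, painter's
algorithm), adequate for single-chamber figures but not an interactive 3D
viewer.
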