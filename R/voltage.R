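## Voltage metrics: area-weighted mean chamber voltage, low-voltage area by
## exact sub-triangle isoline clipping, and area-weighted voltage
## histograms. Each metric can use the clinical per-vertex field
## ("map") or a field re-interpolated from the point voltages ("egm").

## Resolve the voltage surface field for a method.
voltage_field <- function(study, method = c("map", "egm"), fill_threshold = 10) {
  method <- match.arg(method)
  if (method == "map") clinical_field(require_surface(study), "bip")
  else generate_interp_data(study, "bip-map", fill_threshold = fill_threshold)
}

## Triangles with all three vertices valid, their areas (mm^2) and vertex
## values; the shared kernel of all three voltage metrics.
valid_triangle_values <- function(mesh, field) {
  tri <- mesh$triangles
  ok <- field$valid[tri[, 1]] & field$valid[tri[, 2]] & field$valid[tri[, 3]]
  if (!any(ok))
    stop_eam("no triangle has all vertices valid", "eam_insufficient_data_error")
  list(tri = tri[ok, , drop = FALSE], areas = triangle_areas(mesh)[ok],
       v = cbind(field$values[tri[ok, 1]], field$values[tri[ok, 2]],
                 field$values[tri[ok, 3]]))
}

#' Mean chamber voltage
#'
#' Area-weighted mean over all triangles whose three vertices carry a valid
#' voltage: `sum(area_t * mean vertex voltage) / sum(area_t)`.
#'
#' @param study an [eam_study()].
#' @param method `"map"` (clinical per-vertex bipolar field) or `"egm"`
#'   (re-interpolated from the exported point voltages).
#' @param fill_threshold colour-fill threshold (mm) for the `"egm"` method.
#' @return Mean voltage in mV.
#' @export
mean_voltage <- function(study, method = c("map", "egm"), fill_threshold = 10) {
  mesh <- require_surface(study)
  f <- voltage_field(study, method, fill_threshold)
  vt <- valid_triangle_values(mesh, f)
  sum(vt$areas * rowMeans(vt$v)) / sum(vt$areas)
}

## Exact area (mm^2) of the sub-region below thr within one triangle,
## by isoline clipping: the linear field crosses the threshold along a
## straight segment, so the sub-region is a triangle or quadrilateral whose
## corners are vertices and edge crossings (Sutherland-Hodgman against the
## half-plane v < thr). Independent of tri_area_below_oracle(), which uses
## the closed-form order-statistic formula.
clip_triangle_below <- function(p, v, thr) {
  below <- v < thr
  if (!any(below)) return(0)
  if (all(below)) return(0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2)))
  poly <- matrix(numeric(0), 0, 3)
  for (i in 1:3) {
    j <- if (i == 3) 1L else i + 1L
    if (below[i]) poly <- rbind(poly, p[i, ])
    if (xor(below[i], below[j])) {
      t_ <- (thr - v[i]) / (v[j] - v[i])
      poly <- rbind(poly, p[i, ] + t_ * (p[j, ] - p[i, ]))
    }
  }
  area <- 0
  for (k in 2:(nrow(poly) - 1L)) {
    area <- area + 0.5 * sqrt(sum(cross3(poly[k, ] - poly[1, ],
                                         poly[k + 1L, ] - poly[1, ])^2))
  }
  area
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

## vectorised driver: exact below-threshold area (mm^2) over a set of
## triangles; only mixed triangles need clipping.
area_below_threshold <- function(mesh, vt, thr) {
  vmin <- pmin(vt$v[, 1], vt$v[, 2], vt$v[, 3])
  vmax <- pmax(vt$v[, 1], vt$v[, 2], vt$v[, 3])
  full <- vmax < thr
  none <- vmin >= thr
  mixed <- !full & !none
  total <- sum(vt$areas[full])
  if (any(mixed)) {
    verts <- mesh$vertices
    for (i in which(mixed)) {
      p <- verts[vt$tri[i, ], , drop = FALSE]
      total <- total + clip_triangle_below(p, vt$v[i, ], thr)
    }
  }
  total
}

#' Low-voltage area
#'
#' Surface area where the (linearly interpolated) bipolar voltage lies
#' below `v_thr`, computed exactly by per-triangle isoline clipping; the
#' result is continuous and monotone in the threshold and counts partial
#' triangles exactly. Triangles with any invalid vertex are excluded from
#' both the low-voltage and the total area.
#'
#' @param study an [eam_study()].
#' @param method `"map"` or `"egm"` (see [mean_voltage()]).
#' @param v_thr threshold in mV; the conventional low-voltage cut-off is
#'   0.5 mV.
#' @param fill_threshold colour-fill threshold (mm) for `"egm"`.
#' @return tibble with `method`, `threshold_mv`, `low_area_cm2`,
#'   `total_area_cm2`, `fraction_low_pct`.
#' @export
low_voltage_area <- function(study, method = c("map", "egm"), v_thr = 0.5,
                             fill_threshold = 10) {
  method <- match.arg(method)
  mesh <- require_surface(study)
  f <- voltage_field(study, method, fill_threshold)
  vt <- valid_triangle_values(mesh, f)
  low <- area_below_threshold(mesh, vt, v_thr) / 100
  tot <- sum(vt$areas) / 100
  tibble::tibble(method = method, threshold_mv = v_thr,
                 low_area_cm2 = low, total_area_cm2 = tot,
                 fraction_low_pct = 100 * low / tot)
}

#' Area-weighted voltage histogram
#'
#' Per-bin surface areas computed with the same exact isoline clipping as
#' [low_voltage_area()]: the area in bin `[e_k, e_{k+1})` is
#' `A(<e_{k+1}) - A(<e_k)`. Field values below the first (above the last)
#' edge are counted in the first (last) bin so bin areas always sum to the
#' total valid area.
#'
#' @param study an [eam_study()].
#' @param method `"map"` or `"egm"`.
#' @param bin_edges strictly increasing bin edges in mV.
#' @param fill_threshold colour-fill threshold (mm) for `"egm"`.
#' @return list with `histogram` (tibble: `bin_lo`, `bin_hi`, `area_cm2`),
#'   `total_area_cm2` and `method`.
#' @export
voltage_histogram <- function(study, method = c("map", "egm"),
                              bin_edges = seq(0, 5, by = 0.5),
                              fill_threshold = 10) {
  method <- match.arg(method)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_eam("bin edges must be strictly increasing", "eam_argument_error")
  mesh <- require_surface(study)
  f <- voltage_field(study, method, fill_threshold)
  vt <- valid_triangle_values(mesh, f)
  tot <- sum(vt$areas)
  k <- length(bin_edges) - 1L
  cum <- vapply(bin_edges, function(e) area_below_threshold(mesh, vt, e), 1)
  cum[1] <- 0           # below-first-edge counted in the first bin
  cum[k + 1L] <- tot    # above-last-edge counted in the last bin
  areas <- diff(cum) / 100
  structure(list(histogram = tibble::tibble(bin_lo = bin_edges[-(k + 1L)],
                                            bin_hi = bin_edges[-1L],
                                            area_cm2 = areas),
                 total_area_cm2 = tot / 100, method = method),
            class = "eam_histogram")
}
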