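## Total activation time (six methods) and earliest-activation-site
## identification.
##
## The six-method family is {point, clinical-map, interpolated-map} x
## {full range, percentile range}: ptbased, ptbasedprct, clinmap,
## clinmapprct, openepmap, openepmapprct. Percentiles use linear
## interpolation between closest order statistics; the default q = 2.5
## gives a central 95% range.

tat_methods <- c("ptbased", "ptbasedprct", "clinmap", "clinmapprct",
                 "openepmap", "openepmapprct")

## LAT population backing a TAT/earliest-site method
tat_population <- function(study, method, interp = NULL, fill_threshold = 10) {
  base <- sub("prct$", "", method)
  if (base == "ptbased") {
    el <- require_electric(study)
    src <- point_lat_values(el)
    list(values = src$values, positions = src$positions, kind = "point")
  } else if (base == "clinmap") {
    f <- clinical_field(require_surface(study), "act")
    list(values = f$values[f$valid],
         positions = require_surface(study)$vertices[f$valid, , drop = FALSE],
         kind = "vertex")
  } else if (base == "openepmap") {
    f <- interp %||% generate_interp_data(study, "lat-map",
                                          fill_threshold = fill_threshold)
    list(values = f$values[f$valid],
         positions = require_surface(study)$vertices[f$valid, , drop = FALSE],
         kind = "vertex")
  } else {
    stop_eam(sprintf("unknown TAT method '%s' (one of: %s)", method,
                     paste(tat_methods, collapse = ", ")), "eam_argument_error")
  }
}

#' Total activation time
#'
#' Range of local activation times over a chamber. Methods: `ptbased`
#' (max - min over mapping-point LATs, the clinical definition),
#' `clinmap` / `openepmap` (max - min over valid vertex LATs of the
#' clinical or re-interpolated activation map) and their `*prct`
#' percentile variants (P(100-q) - P(q) of the same population, robust to
#' annotation outliers in high-density maps).
#'
#' @param study an [eam_study()].
#' @param method one of `"ptbased"`, `"ptbasedprct"`, `"clinmap"`,
#'   `"clinmapprct"`, `"openepmap"`, `"openepmapprct"`.
#' @param q percentile in (0, 50); default 2.5.
#' @param interp optional precomputed `eam_field` for the `openepmap*`
#'   methods.
#' @return Total activation time in ms.
#' @export
total_activation_time <- function(study, method = "ptbased", q = 2.5,
                                  interp = NULL) {
  method <- match.arg(method, tat_methods)
  if (q <= 0 || q >= 50) stop_eam("q must be in (0, 50)", "eam_argument_error")
  pop <- tat_population(study, method, interp)
  vals <- pop$values[is.finite(pop$values)]
  if (length(vals) < 2L)
    stop_eam("fewer than 2 usable activation times", "eam_insufficient_data_error")
  if (grepl("prct$", method)) {
    eam_percentile(vals, 100 - q) - eam_percentile(vals, q)
  } else {
    max(vals) - min(vals)
  }
}

#' Earliest activation site
#'
#' `ptbased`, `clinmap` and `openepmap` return the location of the minimum
#' LAT over the corresponding population (ties broken by lowest index).
#' `ptbasedprct` returns the centroid of all mapping points with
#' LAT <= P(q), projected to the nearest point on the surface — a
#' percentile-cohort site robust to single-point annotation errors.
#'
#' @param study an [eam_study()].
#' @param method one of `"ptbased"`, `"ptbasedprct"`, `"clinmap"`,
#'   `"openepmap"`.
#' @param q cohort percentile for `"ptbasedprct"`.
#' @param interp optional precomputed `eam_field` for `"openepmap"`.
#' @return list with `position` (mm, on the surface), `vertex` (nearest
#'   1-based mesh vertex, NA without a surface), `lat` (ms) and `method`.
#' @export
earliest_activation_site <- function(study, method = "ptbased", q = 2.5,
                                     interp = NULL) {
  method <- match.arg(method, c("ptbased", "ptbasedprct", "clinmap", "openepmap"))
  pop <- tat_population(study, method, interp)
  ok <- is.finite(pop$values)
  vals <- pop$values[ok]; posn <- pop$positions[ok, , drop = FALSE]
  if (length(vals) < 1L)
    stop_eam("no usable activation times", "eam_insufficient_data_error")
  if (method == "ptbasedprct") {
    cut <- eam_percentile(vals, q)
    cohort <- vals <= cut
    cen <- colMeans(posn[cohort, , drop = FALSE])
    mesh <- require_surface(study)
    proj <- point_surface_distance(mesh, matrix(cen, 1, 3))
    position <- proj$closest[1, ]
    lat <- mean(vals[cohort])
  } else {
    i <- which.min(vals)  # which.min takes the lowest index on ties
    position <- posn[i, ]
    lat <- vals[i]
  }
  vertex <- NA_integer_
  if (!is.null(study$surface)) {
    d <- pairwise_dist(matrix(position, 1, 3), study$surface$vertices)
    vertex <- which.min(d)
  }
  list(position = position, vertex = vertex, lat = lat, method = method)
}
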