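## Conduction-velocity mapping by the radial-basis-function method: fit a
## linear-augmented RBF interpolant to (position, LAT) samples, take its
## analytic gradient at each vertex, and invert the slowness:
## speed = 1 / |grad t| in mm/ms = m/s. The direction field is the
## gradient projected onto the local tangent plane (a surface wave has no
## meaningful normal direction); the speed uses the full gradient, which
## the linear tail makes exact for planar wavefronts on curved chambers.

#' Conduction velocity field
#'
#' Fits an RBF interpolant (with linear polynomial tail) to the
#' mapping-point LATs, evaluates the analytic spatial gradient at every
#' vertex, and computes speed = 1/|grad s| (m/s). The direction is the
#' gradient projected onto the tangent plane (area-weighted vertex
#' normals) and normalised. Vertices whose speed falls outside `clamp`
#' are set to the clamp bound and flagged; plateau vertices
#' (|grad s| < 1e-6 ms/mm) and vertices failing the colour-fill mask are
#' invalid.
#'
#' @param study an [eam_study()] with surface and electric data.
#' @param spec an [interp_spec()]; must be a differentiable RBF scheme.
#' @param clamp analysis clamp range in m/s (default `c(0, 10)`;
#'   physiologically impossible speeds are flagged, the conventional
#'   display range is 0-2 m/s).
#' @param fill_threshold colour-fill distance threshold in mm.
#' @return An object of class `eam_cv_field`: list with per-vertex `speed`
#'   (m/s), `direction` (unit tangent vectors), `valid`, `clamped`, and the
#'   fitted model.
#' @export
compute_conduction_velocity <- function(study, spec = interp_spec(),
                                        clamp = c(0, 10), fill_threshold = 10) {
  if (!spec$scheme %in% c("rbf-gaussian", "rbf-multiquadric"))
    stop_eam("conduction velocity requires a differentiable RBF scheme",
             "eam_argument_error")
  mesh <- require_surface(study)
  el <- require_electric(study)
  src <- point_lat_values(el)
  if (length(src$values) < 10L)
    stop_eam(sprintf("insufficient data: %d annotated points (need >= 10)",
                     length(src$values)), "eam_insufficient_data_error")
  model <- rbf_fit(src$positions, src$values, spec)
  g <- rbf_grad(model, mesh$vertices)            # ms/mm
  vn <- vertex_normals(mesh)
  g_t <- g - vn * rowSums(g * vn)                # tangential part: direction
  gn <- row_norms(g)
  n <- nrow(mesh$vertices)
  speed <- rep(NaN, n); clamped <- rep(FALSE, n)
  plateau <- gn < 1e-6
  speed[!plateau] <- 1 / gn[!plateau]
  lo_hit <- !plateau & speed < clamp[1]; hi_hit <- !plateau & speed > clamp[2]
  speed[lo_hit] <- clamp[1]; speed[hi_hit] <- clamp[2]
  clamped <- lo_hit | hi_hit
  dirs <- g_t / pmax(row_norms(g_t), .Machine$double.xmin)
  valid <- color_fill_mask(mesh, src$positions, fill_threshold) & !plateau
  speed[!valid] <- NaN
  structure(list(speed = speed, direction = dirs, valid = valid,
                 clamped = clamped, clamp = clamp, model = model,
                 n_points = length(src$values)),
            class = "eam_cv_field")
}

#' @export
print.eam_cv_field <- function(x, ...) {
  cat(sprintf("<eam_cv_field> %d/%d valid vertices; median %.3f m/s\n",
              sum(x$valid), length(x$speed),
              stats::median(x$speed[x$valid])))
  invisible(x)
}

#' Tidy a conduction-velocity field
#' @param x an `eam_cv_field`.
#' @param ... unused.
#' @return tibble with `vertex`, `speed`, `valid`, `clamped` and direction
#'   components.
#' @export
tidy.eam_cv_field <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$speed), speed = x$speed,
                 valid = x$valid, clamped = x$clamped,
                 dir_x = x$direction[, 1], dir_y = x$direction[, 2],
                 dir_z = x$direction[, 3])
}

#' Conduction-velocity histogram
#'
#' Each triangle whose three vertices are all valid contributes its area to
#' the bin of its mean vertex speed; speeds outside the bin range are
#' counted in the nearest end bin so the bin areas always sum to the total
#' all-valid triangle area.
#'
#' @param cv an `eam_cv_field` from [compute_conduction_velocity()].
#' @param mesh the [eam_mesh()] (or [eam_study()]) the field was computed
#'   on.
#' @param bin_edges bin edges in m/s; default `seq(0, 2, 0.1)`, the
#'   conventional display range.
#' @return list with `histogram` (tibble: `bin_lo`, `bin_hi`, `area_cm2`),
#'   `total_area_cm2`, and area-weighted `mean_speed` / `median_speed`.
#' @export
cv_histogram <- function(cv, mesh, bin_edges = seq(0, 2, by = 0.1)) {
  if (inherits(mesh, "eam_study")) mesh <- require_surface(mesh)
  if (length(cv$speed) != nrow(mesh$vertices))
    stop_eam("conduction-velocity field does not match this mesh", "eam_consistency_error")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_eam("bin edges must be strictly increasing", "eam_argument_error")
  tri <- mesh$triangles
  ok <- cv$valid[tri[, 1]] & cv$valid[tri[, 2]] & cv$valid[tri[, 3]]
  areas <- triangle_areas(mesh)[ok]
  sp <- rowMeans(cbind(cv$speed[tri[ok, 1]], cv$speed[tri[ok, 2]],
                       cv$speed[tri[ok, 3]]))
  k <- length(bin_edges) - 1L
  bin <- findInterval(sp, bin_edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), k)            # out-of-range into end bins
  area_bin <- tabulate2(bin, areas, k) / 100
  wt <- areas / sum(areas)
  ord <- order(sp)
  cw <- cumsum(wt[ord])
  med <- sp[ord][which(cw >= 0.5)[1]]
  structure(list(histogram = tibble::tibble(bin_lo = bin_edges[-(k + 1L)],
                                            bin_hi = bin_edges[-1L],
                                            area_cm2 = area_bin),
                 total_area_cm2 = sum(areas) / 100,
                 mean_speed = sum(sp * wt), median_speed = med),
            class = "eam_histogram")
}
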