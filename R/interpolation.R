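## Scattered interpolation of point measurements onto mesh vertices, and
## distance-based colour-fill masking.

#' Interpolator specification
#'
#' @param scheme `"rbf-gaussian"` (default), `"rbf-multiquadric"`, `"idw"`
#'   (inverse-distance weighting) or `"nearest"`.
#' @param sigma RBF kernel width in mm; `NULL` means 2x the mean
#'   nearest-neighbour spacing of the sample points, chosen at fit time.
#' @param lambda ridge regularisation (>= 0); `NULL` means
#'   `1e-8 * trace(Phi) / p`.
#' @param power inverse-distance power for `"idw"`.
#' @return An object of class `interp_spec`.
#' @export
interp_spec <- function(scheme = c("rbf-gaussian", "rbf-multiquadric", "idw", "nearest"),
                        sigma = NULL, lambda = NULL, power = 2) {
  scheme <- match.arg(scheme)
  if (!is.null(sigma) && sigma <= 0)
    stop_eam("kernel width sigma must be > 0", "eam_argument_error")
  if (!is.null(lambda) && lambda < 0)
    stop_eam("lambda must be >= 0", "eam_argument_error")
  structure(list(scheme = scheme, sigma = sigma, lambda = lambda, power = power),
            class = "interp_spec")
}

rbf_kernel <- function(r, scheme, sigma) {
  switch(scheme,
         "rbf-gaussian" = exp(-r^2 / (2 * sigma^2)),
         "rbf-multiquadric" = sqrt(1 + (r / sigma)^2),
         stop_eam("not an RBF scheme", "eam_argument_error"))
}

## Fit an RBF interpolant with a linear polynomial tail:
##   s(x) = sum_i c_i phi(|x - x_i|) + d0 + d . x
## subject to the usual moment conditions P' c = 0. The tail gives exact
## reproduction of constant and linear fields (planar wavefronts), the
## standard augmentation in scattered-data RBF interpolation.
rbf_fit <- function(positions, values, spec) {
  p <- nrow(positions)
  sigma <- spec$sigma %||% (2 * mean_nn_spacing(positions))
  r <- pairwise_dist(positions, positions)
  phi <- rbf_kernel(r, spec$scheme, sigma)
  lambda <- spec$lambda %||% (1e-8 * sum(diag(phi)) / p)
  P_full <- cbind(1, positions)
  ## degenerate sample layouts (collinear/coplanar points) make some
  ## polynomial columns redundant; keep an independent subset
  qrP <- qr(P_full)
  keep <- sort(qrP$pivot[seq_len(qrP$rank)])
  P <- P_full[, keep, drop = FALSE]
  q <- ncol(P)
  solve_aug <- function(lam) {
    A <- rbind(cbind(phi + diag(lam, p), P),
               cbind(t(P), matrix(0, q, q)))
    solve(A, c(values, numeric(q)))
  }
  sol <- tryCatch(solve_aug(lambda), error = function(e) {
    lam2 <- max(1e-8 * sum(diag(phi)) / p, 1e-10)
    warning(sprintf("interpolation system singular at lambda=%g; falling back to lambda=%g",
                    lambda, lam2), call. = FALSE)
    solve_aug(lam2)
  })
  poly <- numeric(4)
  poly[keep] <- sol[p + seq_len(q)]
  list(positions = positions, coef = sol[seq_len(p)], poly = poly,
       sigma = sigma, lambda = lambda, scheme = spec$scheme)
}

rbf_eval <- function(model, x) {
  r <- pairwise_dist(x, model$positions)
  as.numeric(rbf_kernel(r, model$scheme, model$sigma) %*% model$coef) +
    model$poly[1] + as.numeric(x %*% model$poly[2:4])
}

## Analytic gradient of the RBF interpolant at rows of x (ms/mm when the
## data are LATs). Gaussian: grad phi = -phi(r) (x - xi) / sigma^2.
## Multiquadric: grad phi = (x - xi) / (sigma^2 sqrt(1 + (r/sigma)^2)).
rbf_grad <- function(model, x) {
  nx <- nrow(x)
  g <- matrix(model$poly[2:4], nx, 3, byrow = TRUE)
  r <- pairwise_dist(x, model$positions)
  w <- switch(model$scheme,
              "rbf-gaussian" = -rbf_kernel(r, model$scheme, model$sigma) / model$sigma^2,
              "rbf-multiquadric" = 1 / (model$sigma^2 * sqrt(1 + (r / model$sigma)^2)))
  wc <- sweep(w, 2, model$coef, "*")
  for (j in 1:3) {
    dj <- outer(x[, j], model$positions[, j], "-")
    g[, j] <- g[, j] + rowSums(wc * dj)
  }
  g
}

idw_eval <- function(positions, values, x, power) {
  d <- pairwise_dist(x, positions)
  out <- numeric(nrow(x))
  exact <- d < 1e-12
  w <- 1 / pmax(d, 1e-12)^power
  out <- as.numeric((w %*% values) / rowSums(w))
  hit <- which(rowSums(exact) > 0)
  for (i in hit) out[i] <- values[which(exact[i, ])[1]]
  out
}

#' Colour-fill validity mask
#'
#' A vertex is valid iff its Euclidean distance to the nearest contributing
#' mapping point is at most `threshold` (the clinical colour-fill
#' threshold; default 10 mm). Enlarging the threshold never invalidates a
#' vertex.
#'
#' @param mesh an [eam_mesh()].
#' @param point_positions q x 3 matrix of contributing point positions.
#' @param threshold distance threshold in mm.
#' @return logical vector of length `nrow(mesh$vertices)`.
#' @export
color_fill_mask <- function(mesh, point_positions, threshold = 10) {
  if (threshold <= 0) stop_eam("threshold must be > 0", "eam_argument_error")
  point_positions <- as_matrix3(point_positions, "point_positions")
  if (nrow(point_positions) == 0L) return(rep(FALSE, nrow(mesh$vertices)))
  d <- pairwise_dist(mesh$vertices, point_positions)
  apply(d, 1, min) <= threshold
}

#' Interpolate point data onto the chamber surface
#'
#' Builds a scattered-data interpolant from the mapping-point positions
#' (`egm_surf_x`) and the chosen per-point quantity, evaluates it at every
#' mesh vertex and masks vertices further than `fill_threshold` from any
#' contributing point. Location-only and unannotated points never
#' contribute.
#'
#' @param study an [eam_study()] with surface and electric data.
#' @param datatype `"lat-map"` (map_annot - ref_annot, ms), `"bip-map"`
#'   (bipolar point voltage, mV) or `"uni-map"` (unipolar point voltage).
#' @param spec an [interp_spec()].
#' @param fill_threshold colour-fill distance threshold in mm.
#' @return An object of class `eam_field`: list with `values` (per-vertex),
#'   `valid` (mask), `source = "interpolated"`, `quantity` and the fitted
#'   `model`.
#' @export
generate_interp_data <- function(study, datatype = c("lat-map", "bip-map", "uni-map"),
                                 spec = interp_spec(), fill_threshold = 10) {
  datatype <- match.arg(datatype)
  mesh <- require_surface(study)
  el <- require_electric(study)
  src <- switch(datatype,
                "lat-map" = point_lat_values(el),
                "bip-map" = point_voltage_values(el, "bip"),
                "uni-map" = point_voltage_values(el, "uni"))
  if (length(src$values) < 4L)
    stop_eam(sprintf("insufficient data: %d usable points (need >= 4)",
                     length(src$values)), "eam_insufficient_data_error")
  vals <- interp_eval_at(mesh$vertices, src$positions, src$values, spec)
  valid <- color_fill_mask(mesh, src$positions, fill_threshold)
  values <- vals$values
  values[!valid] <- NaN
  structure(list(values = values, valid = valid, source = "interpolated",
                 quantity = switch(datatype, "lat-map" = "lat",
                                   "bip-map" = "bip", "uni-map" = "uni"),
                 model = vals$model, n_points = length(src$values)),
            class = "eam_field")
}

interp_eval_at <- function(x, positions, values, spec) {
  if (spec$scheme %in% c("rbf-gaussian", "rbf-multiquadric")) {
    model <- rbf_fit(positions, values, spec)
    list(values = rbf_eval(model, x), model = model)
  } else if (spec$scheme == "idw") {
    list(values = idw_eval(positions, values, x, spec$power), model = NULL)
  } else {
    d <- pairwise_dist(x, positions)
    list(values = values[apply(d, 1, which.min)], model = NULL)
  }
}

#' Wrap a clinical per-vertex field as an `eam_field`
#'
#' @param mesh an [eam_mesh()] with the requested field.
#' @param quantity `"act"` or `"bip"`.
#' @return An `eam_field` with `source = "clinical"`; vertices with a
#'   missing (`NaN`) clinical value are invalid.
#' @export
clinical_field <- function(mesh, quantity = c("act", "bip")) {
  quantity <- match.arg(quantity)
  if (inherits(mesh, "eam_study")) mesh <- require_surface(mesh)
  v <- mesh$fields[[quantity]]
  if (is.null(v))
    stop_eam(sprintf("mesh has no clinical '%s' field; use generate_interp_data()", quantity),
             "eam_missing_data_error")
  structure(list(values = v, valid = is.finite(v), source = "clinical",
                 quantity = if (quantity == "act") "lat" else quantity,
                 model = NULL, n_points = NA_integer_),
            class = "eam_field")
}

#' @export
print.eam_field <- function(x, ...) {
  cat(sprintf("<eam_field> %s (%s): %d/%d valid vertices\n",
              x$quantity, x$source, sum(x$valid), length(x$values)))
  invisible(x)
}

#' Tidy a surface field
#' @param x an `eam_field`.
#' @param ... unused.
#' @return tibble with `vertex`, `value`, `valid`.
#' @export
tidy.eam_field <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$values), value = x$values, valid = x$valid)
}
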