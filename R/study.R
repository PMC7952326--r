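#' Per-point electrical data of an EAM study
#'
#' Holds the mapping-point records: clinical identifiers, tags, raw and
#' surface-projected catheter positions, electrogram traces (bipolar, paired
#' unipolar, reference), annotations and windows of interest, and the point
#' voltages. All times are in ms on the trace clock; the window of interest
#' is stored relative to the reference annotation, matching clinical
#' convention. Points tagged "Location only" carry positions but no usable
#' electrical data and are excluded from every map computation.
#'
#' @param point_id vector of p unique clinical point identifiers.
#' @param egm_x,egm_surf_x p x 3 raw and surface-projected positions (mm).
#' @param tags list of p character vectors of point labels.
#' @param name optional p point names.
#' @param bip,uni1,uni2,ref p x T trace matrices (mV); may be NULL when the
#'   study carries no electrogram traces.
#' @param fs sampling frequency in Hz.
#' @param trace_t0 time (ms) of the first trace sample on the trace clock.
#' @param ref_annot,map_annot absolute annotation times (ms); `NaN` marks an
#'   unannotated point.
#' @param woi p x 2 window of interest (ms, relative to `ref_annot`).
#' @param voltage_bip,voltage_uni per-point voltages (mV).
#' @param impedance optional per-point impedance (Ohm).
#' @return An object of class `eam_electric`.
#' @export
eam_electric <- function(point_id, egm_x, egm_surf_x, tags = NULL, name = NULL,
                         bip = NULL, uni1 = NULL, uni2 = NULL, ref = NULL,
                         fs = 1000, trace_t0 = 0,
                         ref_annot = NULL, map_annot = NULL, woi = NULL,
                         voltage_bip = NULL, voltage_uni = NULL,
                         impedance = NULL) {
  p <- length(point_id)
  if (anyDuplicated(point_id))
    stop_eam("clinical point ids must be unique", "eam_argument_error")
  if (!is.null(fs) && fs <= 0) stop_eam("sample_frequency must be > 0", "eam_argument_error")
  egm_x <- as_matrix3(egm_x, "egm_x"); egm_surf_x <- as_matrix3(egm_surf_x, "egm_surf_x")
  if (nrow(egm_x) != p || nrow(egm_surf_x) != p)
    stop_eam("positions must have one row per point", "eam_argument_error")
  tags <- tags %||% rep(list(character(0)), p)
  lens <- vapply(list(bip, uni1, uni2, ref), function(m) if (is.null(m)) NA_integer_ else ncol(m), 1L)
  if (length(unique(stats::na.omit(lens))) > 1L)
    stop_eam("trace length T must be consistent across channels", "eam_argument_error")
  woi <- if (is.null(woi)) matrix(NaN, p, 2) else {
    woi <- as.matrix(woi); storage.mode(woi) <- "double"; dimnames(woi) <- NULL; woi
  }
  bad <- is.finite(woi[, 1]) & is.finite(woi[, 2]) & woi[, 1] >= woi[, 2]
  if (any(bad)) stop_eam("window of interest must satisfy woi[,1] < woi[,2]", "eam_argument_error")
  structure(list(
    point_id = point_id,
    name = name %||% paste0("P", point_id),
    tags = tags,
    egm_x = egm_x, egm_surf_x = egm_surf_x,
    traces = list(bip = bip, uni1 = uni1, uni2 = uni2, ref = ref),
    fs = as.double(fs), trace_t0 = as.double(trace_t0),
    ref_annot = as.double(ref_annot %||% rep(NaN, p)),
    map_annot = as.double(map_annot %||% rep(NaN, p)),
    woi = woi,
    voltage_bip = as.double(voltage_bip %||% rep(NaN, p)),
    voltage_uni = as.double(voltage_uni %||% rep(NaN, p)),
    impedance = if (is.null(impedance)) NULL else as.double(impedance)
  ), class = "eam_electric")
}

#' @export
print.eam_electric <- function(x, ...) {
  cat(sprintf("<eam_electric> %d points, fs = %g Hz\n", length(x$point_id), x$fs))
  nloc <- sum(is_location_only(x))
  if (nloc) cat("  location-only points:", nloc, "\n")
  invisible(x)
}

is_location_only <- function(electric) {
  vapply(electric$tags, function(tg) any(grepl("location only", tg, ignore.case = TRUE)),
         logical(1))
}

#' Radiofrequency ablation (visitag) record set
#'
#' @param sites tibble/data frame with one row per lesion site; expected
#'   columns `x,y,z` (catheter position, mm), `surf_x,surf_y,surf_z`
#'   (surface-projected position, mm), `index_name`, `index_value`
#'   (platform lesion-quality index, e.g. Ablation Index), `force` (g),
#'   `power` (W), `temperature` (degC), `impedance` (Ohm), `duration` (s).
#' @param grid optional tibble of raw ablation grid positions with
#'   per-position parameter samples.
#' @return An object of class `eam_visitags`.
#' @export
eam_visitags <- function(sites, grid = NULL) {
  sites <- tibble::as_tibble(sites)
  need <- c("x", "y", "z", "surf_x", "surf_y", "surf_z", "index_value",
            "force", "power", "temperature", "impedance", "duration")
  miss <- setdiff(need, names(sites))
  if (nrow(sites) > 0L && length(miss))
    stop_eam(paste0("visitag sites missing column(s): ", paste(miss, collapse = ", ")),
             "eam_format_error")
  if (nrow(sites) > 0L && any(sites$duration < 0, na.rm = TRUE))
    stop_eam("ablation durations must be >= 0", "eam_argument_error")
  if (!"index_name" %in% names(sites) && nrow(sites) > 0L)
    sites$index_name <- "ablation_index"
  structure(list(sites = sites,
                 grid = if (is.null(grid)) tibble::tibble() else tibble::as_tibble(grid)),
            class = "eam_visitags")
}

#' @export
print.eam_visitags <- function(x, ...) {
  cat(sprintf("<eam_visitags> %d sites, %d grid positions\n",
              nrow(x$sites), nrow(x$grid)))
  invisible(x)
}

#' Assemble an EAM study
#'
#' The root record of the package: a chamber surface, the per-point
#' electrical data, optional ablation records and provenance notes. Surface
#' and electric data may each be present independently; when both are
#' present the surface-projected point positions must lie on (within 2x the
#' mean edge length of) the mesh.
#'
#' @param surface an [eam_mesh()] or NULL.
#' @param electric an [eam_electric()] or NULL.
#' @param rfindex an [eam_visitags()] or NULL.
#' @param system_name label of the source platform.
#' @param notes character vector of provenance notes.
#' @param validate check cross-component invariants.
#' @return An object of class `eam_study`.
#' @export
eam_study <- function(surface = NULL, electric = NULL, rfindex = NULL,
                      system_name = "synthetic", notes = character(0),
                      validate = TRUE) {
  std <- structure(list(system_name = system_name, notes = notes,
                        surface = surface, electric = electric,
                        rfindex = rfindex), class = "eam_study")
  if (validate && !is.null(surface) && !is.null(electric) &&
      nrow(electric$egm_surf_x) > 0L && nrow(surface$triangles) > 0L) {
    d <- point_surface_distance(surface, electric$egm_surf_x)$distance
    lim <- 2 * mean_edge_length(surface)
    if (any(d > lim))
      stop_eam(sprintf("egm_surf_x points lie off the mesh (max %.2f mm > %.2f mm)",
                       max(d), lim), "eam_consistency_error")
  }
  std
}

#' @export
print.eam_study <- function(x, ...) {
  cat(sprintf("<eam_study> system: %s\n", x$system_name))
  if (!is.null(x$surface)) print(x$surface)
  if (!is.null(x$electric)) print(x$electric)
  if (!is.null(x$rfindex)) print(x$rfindex)
  invisible(x)
}

require_electric <- function(study) {
  if (is.null(study$electric))
    stop_eam("study contains no electrical data", "eam_missing_data_error")
  study$electric
}

require_surface <- function(study) {
  if (is.null(study$surface))
    stop_eam("study contains no surface data", "eam_missing_data_error")
  study$surface
}

## --- core accessors -------------------------------------------------------

#' Number of mapping points
#'
#' Counts the mapping points of a study. Location-only points (ablation
#' tags and other stored positions without electrical data) are excluded
#' unless `include_location_only = TRUE`.
#'
#' @param study an [eam_study()].
#' @param include_location_only also count location-only points.
#' @return integer count.
#' @export
get_num_points <- function(study, include_location_only = FALSE) {
  el <- require_electric(study)
  if (include_location_only) length(el$point_id)
  else sum(!is_location_only(el))
}

#' Electrode positions of all points
#'
#' @param study an [eam_study()].
#' @param kind `"raw"` for catheter positions (`egm_x`) or `"surface"` for
#'   surface-projected positions (`egm_surf_x`).
#' @return p x 3 matrix (mm), rows in point order.
#' @export
get_electrogram_positions <- function(study, kind = c("raw", "surface")) {
  kind <- match.arg(kind)
  el <- require_electric(study)
  if (kind == "raw") el$egm_x else el$egm_surf_x
}

#' Internal index of a clinical point id
#'
#' Maps a clinical point identifier (an opaque label assigned by the
#' mapping platform) to the point's 0-based internal index.
#'
#' @param study an [eam_study()].
#' @param point_id a clinical point identifier.
#' @return 0-based integer index.
#' @export
index_from_clinical_point_id <- function(study, point_id) {
  el <- require_electric(study)
  idx <- match(point_id, el$point_id)
  if (is.na(idx))
    stop_eam(sprintf("point id '%s' not found (study has %d points, internal indices 0..%d)",
                     point_id, length(el$point_id), length(el$point_id) - 1L),
             "eam_point_not_found_error")
  idx - 1L
}

#' Electrograms at selected points
#'
#' Returns the untruncated traces of the selected points together with
#' their annotations. The annotation sample index is
#' `round((map_annot - trace_start) * fs / 1000)`.
#'
#' @param study an [eam_study()].
#' @param indices 0-based internal point indices.
#' @return list with elements `bip`, `uni1`, `uni2`, `ref` (matrices,
#'   one row per requested point), `t_ms` (sample times), `map_annot`,
#'   `ref_annot`, `woi`, `annot_sample` and `point_id`.
#' @export
get_egms_at_points <- function(study, indices) {
  el <- require_electric(study)
  i1 <- check_indices(el, indices)
  loco <- is_location_only(el)[i1]
  if (any(loco))
    stop_eam(sprintf("no electrogram at location-only point(s): %s",
                     paste(el$point_id[i1][loco], collapse = ", ")),
             "eam_location_only_error")
  if (is.null(el$traces$bip))
    stop_eam("study carries no electrogram traces", "eam_missing_data_error")
  T_ <- ncol(el$traces$bip)
  t_ms <- el$trace_t0 + (seq_len(T_) - 1L) * 1000 / el$fs
  list(bip = el$traces$bip[i1, , drop = FALSE],
       uni1 = el$traces$uni1[i1, , drop = FALSE],
       uni2 = el$traces$uni2[i1, , drop = FALSE],
       ref = el$traces$ref[i1, , drop = FALSE],
       t_ms = t_ms,
       map_annot = el$map_annot[i1],
       ref_annot = el$ref_annot[i1],
       woi = el$woi[i1, , drop = FALSE],
       annot_sample = as.integer(round((el$map_annot[i1] - el$trace_t0) * el$fs / 1000)),
       point_id = el$point_id[i1])
}

#' Absolute window of interest
#'
#' The window of interest is stored relative to each point's reference
#' annotation; this returns the absolute bounds
#' `ref_annot + [woi_low, woi_high]` on the trace clock.
#'
#' @param study an [eam_study()].
#' @param indices 0-based internal point indices; default all points.
#' @return p' x 2 matrix of absolute window bounds (ms).
#' @export
get_window_of_interest <- function(study, indices = NULL) {
  el <- require_electric(study)
  if (is.null(indices)) indices <- seq_along(el$point_id) - 1L
  i1 <- check_indices(el, indices)
  cbind(el$ref_annot[i1] + el$woi[i1, 1], el$ref_annot[i1] + el$woi[i1, 2])
}

check_indices <- function(el, indices) {
  p <- length(el$point_id)
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 0L || max(indices) >= p))
    stop_eam(sprintf("point index out of range [0, %d]", p - 1L), "eam_argument_error")
  indices + 1L
}

## LAT values of mapping points, relative to the reference annotation.
## Location-only and unannotated points are excluded (returned with index).
point_lat_values <- function(el) {
  keep <- !is_location_only(el) & is.finite(el$map_annot) & is.finite(el$ref_annot)
  list(values = el$map_annot[keep] - el$ref_annot[keep],
       index = which(keep),
       positions = el$egm_surf_x[keep, , drop = FALSE])
}

point_voltage_values <- function(el, which_v = c("bip", "uni")) {
  which_v <- match.arg(which_v)
  v <- if (which_v == "bip") el$voltage_bip else el$voltage_uni
  keep <- !is_location_only(el) & is.finite(v)
  list(values = v[keep], index = which(keep),
       positions = el$egm_surf_x[keep, , drop = FALSE])
}
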