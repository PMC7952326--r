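## Figure builders. Every plot function first assembles a plain data
## structure (inspectable in tests without rendering), builds a ggplot from
## it, and only touches a graphics device when out_path is given.
## Rendering uses a simple orthographic projection with painter's-algorithm
## depth ordering, which is adequate for single-chamber views.

## orientation -> camera azimuth (degrees about the z axis); 'ap'
## (antero-posterior) and 'pa' are 180 degrees apart by contract.
camera_azimuth <- function(orientation = c("ap", "pa")) {
  orientation <- match.arg(orientation)
  if (orientation == "ap") 0 else 180
}

## project vertices for a camera azimuth: screen x/y plus depth
project_vertices <- function(v, azimuth) {
  th <- azimuth * pi / 180
  ## view direction rotates about z; screen up is +z
  view <- c(-sin(th), -cos(th), 0)
  right <- c(cos(th), -sin(th), 0)
  cbind(px = as.numeric(v %*% right), py = v[, 3],
        depth = as.numeric(v %*% view))
}

mesh_polygons <- function(mesh, values, azimuth) {
  pr <- project_vertices(mesh$vertices, azimuth)
  tri <- mesh$triangles
  depth <- (pr[tri[, 1], "depth"] + pr[tri[, 2], "depth"] + pr[tri[, 3], "depth"]) / 3
  ord <- order(depth)
  idx <- as.vector(t(tri[ord, ]))
  vals <- if (is.null(values)) rep(NA_real_, length(ord)) else
    (values[tri[ord, 1]] + values[tri[ord, 2]] + values[tri[ord, 3]]) / 3
  tibble::tibble(
    triangle = rep(seq_along(ord), each = 3L),
    px = pr[idx, "px"], py = pr[idx, "py"],
    value = rep(vals, each = 3L))
}

save_plot <- function(gg, out_path, width = 7, height = 5.5) {
  ext <- tolower(tools::file_ext(out_path))
  dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                stop_eam(sprintf("unsupported image extension '.%s' (png or svg)", ext),
                         "eam_argument_error"))
  tryCatch(
    suppressMessages(ggplot2::ggsave(out_path, gg, device = dev,
                                     width = width, height = height, dpi = 100)),
    error = function(e) stop_eam(sprintf("cannot write figure '%s': %s",
                                         out_path, conditionMessage(e)),
                                 "eam_file_error"))
  invisible(out_path)
}

## sequential isoluminant-safe default, plus the rainbow option kept for
## clinical familiarity
map_palette <- function(style = c("viridis", "rainbow")) {
  style <- match.arg(style)
  if (style == "viridis")
    ggplot2::scale_fill_viridis_c(na.value = "grey70")
  else
    ggplot2::scale_fill_gradientn(colours = grDevices::rainbow(64, end = 0.7),
                                  na.value = "grey70")
}

#' Render an electroanatomic map
#'
#' Colours the chamber surface by an activation, voltage, or conduction
#' velocity field; masked vertices render neutral grey. Activation maps
#' default to an isoluminant-safe sequential palette, with a rainbow
#' option for clinical familiarity.
#'
#' @param study an [eam_study()].
#' @param map_type `"act"`, `"bip"` or `"cv"`.
#' @param data optional `eam_field` or `eam_cv_field` (e.g. from
#'   [generate_interp_data()] or [compute_conduction_velocity()]); by
#'   default the clinical vertex field is used (`"cv"` always requires
#'   `data`).
#' @param orientation `"ap"` or `"pa"` (camera azimuths 180 degrees apart).
#' @param color_axis optional `c(lo, hi)` colour limits (ms, mV or m/s);
#'   conventional choices are `c(0, 2)` m/s for CV and `c(0.4, 0.6)` mV
#'   for bipolar voltage.
#' @param fill_threshold colour-fill threshold (mm) when a field has to be
#'   interpolated on demand.
#' @param palette `"viridis"` or `"rainbow"`.
#' @param out_path optional output image (`.png`/`.svg`).
#' @return An `eam_map_plot`: list with the polygon tibble, azimuth,
#'   colour axis and the ggplot (`$gg`). Written to `out_path` if given.
#' @export
draw_map <- function(study, map_type = c("act", "bip", "cv"), data = NULL,
                     orientation = c("ap", "pa"), color_axis = NULL,
                     fill_threshold = 10, palette = c("viridis", "rainbow"),
                     out_path = NULL) {
  map_type <- match.arg(map_type)
  orientation <- match.arg(orientation)
  mesh <- require_surface(study)
  if (is.null(data)) {
    if (map_type == "cv")
      stop_eam("no conduction-velocity data supplied; run compute_conduction_velocity()",
               "eam_missing_data_error")
    data <- tryCatch(clinical_field(mesh, map_type), error = function(e)
      stop_eam(sprintf("no clinical '%s' field on the mesh; supply data from generate_interp_data()",
                       map_type), "eam_missing_data_error"))
  }
  values <- if (inherits(data, "eam_cv_field")) data$speed else data$values
  azimuth <- camera_azimuth(orientation)
  polys <- mesh_polygons(mesh, values, azimuth)
  gg <- ggplot2::ggplot(polys, ggplot2::aes(.data$px, .data$py,
                                            group = .data$triangle,
                                            fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    (if (is.null(color_axis)) map_palette(match.arg(palette)) else
      ggplot2::scale_fill_viridis_c(limits = color_axis, oob = scales_squish,
                                    na.value = "grey70")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = switch(map_type, act = "LAT (ms)", bip = "Bi (mV)",
                                cv = "CV (m/s)"),
                  title = sprintf("%s map (%s)", toupper(map_type), orientation))
  out <- structure(list(polygons = polys, azimuth = azimuth,
                        color_axis = color_axis, map_type = map_type, gg = gg),
                   class = "eam_map_plot")
  if (!is.null(out_path)) save_plot(gg, out_path)
  invisible(out)
}

## squish out-of-range values to the limits (local copy to avoid a scales
## dependency in NAMESPACE)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  finite <- if (only.finite) is.finite(x) else TRUE
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}

#' Plot electrograms at selected points
#'
#' Stacked-trace display per point: reference, bipolar and the paired
#' unipolar electrograms, vertically offset, with the activation-time
#' annotation marked on the bipolar trace.
#'
#' @param study an [eam_study()].
#' @param indices 0-based internal point indices (see
#'   [index_from_clinical_point_id()]).
#' @param separation vertical offset between traces (mV).
#' @param out_path optional output image.
#' @return An `eam_egm_plot`: list with the trace tibble (`$traces`), the
#'   annotation tibble (`$annotations`, x positions equal to `map_annot`)
#'   and the ggplot. Written to `out_path` if given.
#' @export
plot_egms <- function(study, indices, separation = 3, out_path = NULL) {
  eg <- get_egms_at_points(study, indices)
  p <- length(indices)
  chans <- c("ref", "bip", "uni1", "uni2")
  rows <- list()
  offset <- 0
  offsets <- numeric(0)
  for (i in seq_len(p)) {
    for (ch in chans) {
      y <- eg[[ch]][i, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        point_id = eg$point_id[i], channel = ch, t_ms = eg$t_ms,
        mV = y, y_display = y + offset)
      offsets <- c(offsets, offset)
      offset <- offset + separation
    }
  }
  traces <- dplyr::bind_rows(rows)
  bip_off <- offsets[seq(2, by = length(chans), length.out = p)]
  ann_y <- vapply(seq_len(p), function(i) {
    s <- eg$annot_sample[i] + 1L
    if (is.finite(s) && s >= 1 && s <= length(eg$t_ms)) eg$bip[i, s] else NA_real_
  }, 1)
  annotations <- tibble::tibble(point_id = eg$point_id,
                                t_ms = eg$map_annot,
                                y_display = ann_y + bip_off)
  gg <- ggplot2::ggplot(traces, ggplot2::aes(.data$t_ms, .data$y_display,
                                             group = interaction(.data$point_id, .data$channel),
                                             colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = annotations,
                        ggplot2::aes(.data$t_ms, .data$y_display),
                        inherit.aes = FALSE, colour = "red", size = 1.5) +
    ggplot2::scale_colour_manual(values = c(ref = "red3", bip = "blue3",
                                            uni1 = "green4", uni2 = "green3")) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
  out <- structure(list(traces = traces, annotations = annotations, gg = gg),
                   class = "eam_egm_plot")
  if (!is.null(out_path)) save_plot(gg, out_path)
  invisible(out)
}

#' Plot ablation lesions
#'
#' Renders the chamber with the lesion sites (`mode = "tags"`) or the raw
#' ablation grid (`mode = "grid"`), coloured by any available ablation
#' parameter; the data values are never rescaled, only the colour mapping.
#' The default colouring is the lesion-quality index, white (low) to red
#' (high).
#'
#' @param study an [eam_study()] with ablation records.
#' @param color_by site parameter name (e.g. `"index_value"`, `"force"`,
#'   `"power"`, `"temperature"`, `"impedance"`, `"duration"`) or a numeric
#'   vector with one value per site.
#' @param mode `"tags"` (lesion sites) or `"grid"` (raw grid positions).
#' @param orientation `"ap"` or `"pa"`.
#' @param out_path optional output image.
#' @return An `eam_visitag_plot`: list with the glyph tibble (`$glyphs`,
#'   column `value` holding the unscaled parameter values) and the ggplot.
#' @export
plot_visitags <- function(study, color_by = "index_value",
                          mode = c("tags", "grid"),
                          orientation = c("ap", "pa"), out_path = NULL) {
  mode <- match.arg(mode)
  if (is.null(study$rfindex))
    stop_eam("study has no ablation data", "eam_missing_data_error")
  rf <- study$rfindex
  if (mode == "grid" && nrow(rf$grid) == 0L)
    stop_eam("study has no ablation grid data", "eam_missing_data_error")
  src <- if (mode == "tags") rf$sites else rf$grid
  if (is.character(color_by)) {
    numcols <- names(src)[vapply(src, is.numeric, TRUE)]
    if (!color_by %in% names(src))
      stop_eam(sprintf("unknown ablation parameter '%s'; available: %s",
                       color_by, paste(numcols, collapse = ", ")),
               "eam_argument_error")
    vals <- src[[color_by]]
    lab <- color_by
  } else {
    if (length(color_by) != nrow(src))
      stop_eam("color values must have one entry per site", "eam_argument_error")
    vals <- as.numeric(color_by)
    lab <- "value"
  }
  azimuth <- camera_azimuth(match.arg(orientation))
  pos <- if (mode == "tags") cbind(src$surf_x, src$surf_y, src$surf_z)
         else cbind(src$x, src$y, src$z)
  pr <- project_vertices(pos, azimuth)
  glyphs <- tibble::tibble(px = pr[, "px"], py = pr[, "py"], value = vals)
  base <- NULL
  gg <- ggplot2::ggplot()
  if (!is.null(study$surface)) {
    base <- mesh_polygons(study$surface, NULL, azimuth)
    gg <- gg + ggplot2::geom_polygon(
      data = base, ggplot2::aes(.data$px, .data$py, group = .data$triangle),
      fill = "grey85", colour = NA)
  }
  gg <- gg +
    ggplot2::geom_point(data = glyphs,
                        ggplot2::aes(.data$px, .data$py, colour = .data$value),
                        size = if (mode == "tags") 3 else 1) +
    ggplot2::scale_colour_gradient(low = "white", high = "red3", name = lab) +
    ggplot2::coord_equal() + ggplot2::theme_void()
  out <- structure(list(glyphs = glyphs, mode = mode, azimuth = azimuth, gg = gg),
                   class = "eam_visitag_plot")
  if (!is.null(out_path)) save_plot(gg, out_path)
  invisible(out)
}

#' Overlay an ablation-area result on the chamber
#'
#' @param study the [eam_study()] the result was computed on.
#' @param result result of [get_ablation_area()].
#' @param orientation `"ap"` or `"pa"`.
#' @param out_path optional output image.
#' @return An `eam_ablation_plot`: list with the base polygons, the marked
#'   overlay triangle indices (`$overlay_triangles`) and the ggplot.
#' @export
plot_ablation_area <- function(study, result, orientation = c("ap", "pa"),
                               out_path = NULL) {
  mesh <- require_surface(study)
  if (length(result$marked) && max(result$marked) > nrow(mesh$triangles))
    stop_eam("ablation-area result does not match this mesh", "eam_consistency_error")
  azimuth <- camera_azimuth(match.arg(orientation))
  base <- mesh_polygons(mesh, NULL, azimuth)
  marked_flag <- rep(FALSE, nrow(mesh$triangles))
  marked_flag[result$marked] <- TRUE
  ## mesh_polygons reorders triangles by depth; recover the marked rows
  pr <- project_vertices(mesh$vertices, azimuth)
  tri <- mesh$triangles
  depth <- (pr[tri[, 1], "depth"] + pr[tri[, 2], "depth"] + pr[tri[, 3], "depth"]) / 3
  ord <- order(depth)
  overlay <- base[rep(marked_flag[ord], each = 3L), , drop = FALSE]
  gg <- ggplot2::ggplot(base, ggplot2::aes(.data$px, .data$py, group = .data$triangle)) +
    ggplot2::geom_polygon(fill = "grey85", colour = NA) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("ablated area %.2f cm2 (r = %g mm)",
                                  result$area_cm2, result$r_abl))
  if (nrow(overlay))
    gg <- gg + ggplot2::geom_polygon(data = overlay, fill = "red3",
                                     colour = NA, alpha = 0.9)
  out <- structure(list(base = base, overlay_triangles = result$marked,
                        gg = gg), class = "eam_ablation_plot")
  if (!is.null(out_path)) save_plot(gg, out_path)
  invisible(out)
}

#' Autoplot a conduction-velocity or voltage histogram
#'
#' @param object result of [cv_histogram()] or [voltage_histogram()].
#' @param ... unused.
#' @return A ggplot bar chart of per-bin surface area.
#' @export
autoplot.eam_histogram <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$area_cm2)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo) * 0.95, fill = "steelblue") +
    ggplot2::labs(x = "bin", y = "area (cm2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
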