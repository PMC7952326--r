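## Ablation-lesion quantification.

#' Ablated surface area
#'
#' Marks every triangle whose centroid lies within Euclidean distance
#' `r_abl` of any surface-projected ablation site and sums the marked
#' areas. Overlapping lesions are counted once (union semantics), so
#' duplicating a site never changes the result and the area is
#' non-decreasing in both the radius and the site count.
#'
#' @param study an [eam_study()] with surface data and ablation records.
#' @param r_abl lesion influence radius in mm (default 5, approximating a
#'   typical radiofrequency lesion diameter).
#' @return list with `area_cm2`, `r_abl`, and `marked` (1-based indices of
#'   marked triangles).
#' @export
get_ablation_area <- function(study, r_abl = 5) {
  mesh <- require_surface(study)
  if (is.null(study$rfindex))
    stop_eam("study has no ablation data; import it with import_visitags()",
             "eam_missing_data_error")
  sites <- study$rfindex$sites
  if (nrow(sites) == 0L)
    return(list(area_cm2 = 0, r_abl = r_abl, marked = integer(0)))
  cen <- triangle_centroids(mesh)
  pos <- cbind(sites$surf_x, sites$surf_y, sites$surf_z)
  d <- pairwise_dist(cen, pos)
  marked <- which(apply(d, 1, min) <= r_abl)
  list(area_cm2 = sum(triangle_areas(mesh)[marked]) / 100,
       r_abl = r_abl, marked = marked)
}

#' Tidy visitag sites
#' @param x an `eam_visitags`.
#' @param ... unused.
#' @return the sites tibble.
#' @export
tidy.eam_visitags <- function(x, ...) x$sites
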