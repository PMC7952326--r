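## The exchange container: `<study>.openep.zip`, a ZIP archive holding
## manifest.json plus one CSV per array. Numeric text uses 17 significant
## digits so read-back is bit-exact for 64-bit doubles; traces shared by
## several points (e.g. a common reference electrogram) are stored once in
## traces.csv and referenced by 0-based row index.

CONTAINER_SCHEMA <- "eamtools-container-1.0"

#' Write a study to an exchange container
#'
#' @param study an [eam_study()].
#' @param path output path (conventionally `<study>.openep.zip`).
#' @return `path`, invisibly.
#' @export
write_container <- function(study, path) {
  arrays <- list()      # name -> list(df, dtype)
  add <- function(name, df, dtype = "f64") arrays[[name]] <<- list(df = df, dtype = dtype)
  if (!is.null(study$surface)) {
    s <- study$surface
    add("surface_vertices", data.frame(x = s$vertices[, 1], y = s$vertices[, 2],
                                       z = s$vertices[, 3]))
    add("surface_triangles", data.frame(v0 = s$triangles[, 1] - 1L,
                                        v1 = s$triangles[, 2] - 1L,
                                        v2 = s$triangles[, 3] - 1L), "i32")
    n <- nrow(s$vertices)
    add("surface_fields", data.frame(act = s$fields$act %||% rep(NaN, n),
                                     bip = s$fields$bip %||% rep(NaN, n)))
  }
  if (!is.null(study$electric)) {
    el <- study$electric
    p <- length(el$point_id)
    tr <- dedup_traces(el$traces, p)
    pts <- data.frame(
      id = as.character(el$point_id), name = as.character(el$name),
      tags = vapply(el$tags, paste, "", collapse = ";"),
      egm_x_x = el$egm_x[, 1], egm_x_y = el$egm_x[, 2], egm_x_z = el$egm_x[, 3],
      egm_surf_x_x = el$egm_surf_x[, 1], egm_surf_x_y = el$egm_surf_x[, 2],
      egm_surf_x_z = el$egm_surf_x[, 3],
      ref_annot = el$ref_annot, map_annot = el$map_annot,
      woi_low = el$woi[, 1], woi_high = el$woi[, 2],
      voltage_bip = el$voltage_bip, voltage_uni = el$voltage_uni,
      impedance = el$impedance %||% rep(NaN, p),
      trace_ref_index = tr$index$ref, trace_bip_index = tr$index$bip,
      trace_uni1_index = tr$index$uni1, trace_uni2_index = tr$index$uni2,
      stringsAsFactors = FALSE)
    add("electric_points", pts, "mixed")
    if (!is.null(tr$traces)) {
      tdf <- as.data.frame(tr$traces)
      names(tdf) <- paste0("s", seq_len(ncol(tdf)) - 1L)
      add("traces", tdf)
    }
  }
  if (!is.null(study$rfindex)) {
    add("visitag_sites", as.data.frame(study$rfindex$sites), "mixed")
    if (nrow(study$rfindex$grid) > 0L)
      add("visitag_grid", as.data.frame(study$rfindex$grid), "mixed")
  }
  manifest <- list(
    schema_version = CONTAINER_SCHEMA,
    system_name = study$system_name,
    notes = as.list(study$notes),
    units = eam_units()[1:6],
    sample_frequency = if (!is.null(study$electric)) study$electric$fs else NULL,
    trace_t0 = if (!is.null(study$electric)) study$electric$trace_t0 else NULL,
    arrays = lapply(arrays, function(a)
      list(file = NULL, rows = nrow(a$df), cols = ncol(a$df), dtype = a$dtype)))
  files <- list()
  for (nm in names(arrays)) {
    manifest$arrays[[nm]]$file <- paste0(nm, ".csv")
    tmp <- tempfile(fileext = ".csv")
    write_csv17(arrays[[nm]]$df, tmp)
    files[[paste0(nm, ".csv")]] <- file_as_raw(tmp)
    unlink(tmp)
  }
  files <- c(list("manifest.json" = charToRaw(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA))),
    files)
  ok <- tryCatch({ write_zip(files, path); TRUE },
                 error = function(e) stop_eam(
                   sprintf("cannot write container '%s': %s", path, conditionMessage(e)),
                   "eam_file_error"))
  invisible(path)
}

## replace each trace matrix by 0-based indices into a deduplicated matrix
dedup_traces <- function(traces, p) {
  chans <- c("ref", "bip", "uni1", "uni2")
  if (is.null(traces$bip))
    return(list(traces = NULL,
                index = setNames(rep(list(rep(NaN, p)), 4), chans)))
  all_tr <- do.call(rbind, traces[chans])
  key <- apply(all_tr, 1, function(row) paste(fmt17(row), collapse = ","))
  uniq <- !duplicated(key)
  idx_of <- match(key, key[uniq]) - 1L
  index <- list()
  for (i in seq_along(chans))
    index[[chans[i]]] <- idx_of[(i - 1L) * p + seq_len(p)]
  list(traces = all_tr[uniq, , drop = FALSE], index = index)
}

#' Read an exchange container
#'
#' Validates the manifest (schema version, array presence and shapes)
#' before reconstructing the study; shape mismatches raise an integrity
#' error naming the array, and unknown extra arrays are accepted with a
#' warning for forward compatibility.
#'
#' @param path a container written by [write_container()].
#' @return An [eam_study()].
#' @export
read_container <- function(path) {
  if (!file.exists(path))
    stop_eam(sprintf("container '%s' does not exist", path), "eam_file_error")
  exdir <- tempfile("container")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir)
  mpath <- file.path(exdir, "manifest.json")
  if (!file.exists(mpath))
    stop_eam("container has no manifest.json", "eam_integrity_error")
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, CONTAINER_SCHEMA))
    stop_eam(sprintf("unsupported container schema '%s' (this build reads '%s')",
                     manifest$schema_version %||% "<missing>", CONTAINER_SCHEMA),
             "eam_schema_error")
  known <- c("surface_vertices", "surface_triangles", "surface_fields",
             "electric_points", "traces", "visitag_sites", "visitag_grid")
  extra <- setdiff(names(manifest$arrays), known)
  if (length(extra))
    warning("ignoring unknown container array(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  arr <- list()
  for (nm in intersect(names(manifest$arrays), known)) {
    decl <- manifest$arrays[[nm]]
    f <- file.path(exdir, decl$file)
    if (!file.exists(f))
      stop_eam(sprintf("container integrity error: array '%s' missing", nm),
               "eam_integrity_error")
    df <- read_csv_plain(f)
    if (nrow(df) != decl$rows || ncol(df) != decl$cols)
      stop_eam(sprintf("container integrity error: array '%s' is %dx%d, manifest declares %dx%d",
                       nm, nrow(df), ncol(df), decl$rows, decl$cols),
               "eam_integrity_error")
    arr[[nm]] <- df
  }
  surface <- NULL
  if (!is.null(arr$surface_vertices)) {
    sf <- arr$surface_fields
    surface <- eam_mesh(as.matrix(arr$surface_vertices),
                        as.matrix(arr$surface_triangles) + 1L,
                        act = sf$act, bip = sf$bip, validate = FALSE)
  }
  electric <- NULL
  if (!is.null(arr$electric_points)) {
    pts <- arr$electric_points
    traces <- list(bip = NULL, uni1 = NULL, uni2 = NULL, ref = NULL)
    if (!is.null(arr$traces)) {
      tm <- as.matrix(arr$traces)
      dimnames(tm) <- NULL
      pick <- function(col) {
        idx <- pts[[col]]
        out <- tm[idx + 1L, , drop = FALSE]
        out
      }
      traces <- list(bip = pick("trace_bip_index"), uni1 = pick("trace_uni1_index"),
                     uni2 = pick("trace_uni2_index"), ref = pick("trace_ref_index"))
    }
    ids <- pts$id
    if (!anyNA(suppressWarnings(as.numeric(ids)))) ids <- as.numeric(ids)
    electric <- eam_electric(
      point_id = ids, name = as.character(pts$name),
      tags = lapply(strsplit(as.character(pts$tags), ";", fixed = TRUE),
                    function(x) x[nzchar(x)]),
      egm_x = cbind(pts$egm_x_x, pts$egm_x_y, pts$egm_x_z),
      egm_surf_x = cbind(pts$egm_surf_x_x, pts$egm_surf_x_y, pts$egm_surf_x_z),
      bip = traces$bip, uni1 = traces$uni1, uni2 = traces$uni2, ref = traces$ref,
      fs = manifest$sample_frequency %||% 1000,
      trace_t0 = manifest$trace_t0 %||% 0,
      ref_annot = pts$ref_annot, map_annot = pts$map_annot,
      woi = cbind(pts$woi_low, pts$woi_high),
      voltage_bip = pts$voltage_bip, voltage_uni = pts$voltage_uni,
      impedance = pts$impedance)
  }
  rfindex <- NULL
  if (!is.null(arr$visitag_sites)) {
    rfindex <- eam_visitags(tibble::as_tibble(arr$visitag_sites),
                            grid = if (!is.null(arr$visitag_grid))
                              tibble::as_tibble(arr$visitag_grid) else NULL)
  }
  eam_study(surface = surface, electric = electric, rfindex = rfindex,
            system_name = manifest$system_name %||% "unknown",
            notes = unlist(manifest$notes) %||% character(0),
            validate = FALSE)
}
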