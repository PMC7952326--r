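## The clinical-export-style dialect: a documented simplification modelled
## on the structure of clinical system exports (a study descriptor XML, a
## geometry file, and per-point files), emitted by the synthetic module and
## parsed back by parse_clinical_export(). It is a stand-in dialect: the
## proprietary export schemas are not public and bit-exact compatibility
## with them is out of scope.
##
## Tree layout:
##   study.xml                study name, system, fs, map list with point ids
##   mesh.xml                 vertex/triangle blocks + per-vertex act/bip
##   P<id>_point.xml          position, surfX, woi, annotations, voltages, tags
##   P<id>_egm.csv            columns t_ms, ref, bip, uni1, uni2
##   visitags/sites.csv       ablation sites (+ visitags/grid.csv)

num_text <- function(x) paste(fmt17(x), collapse = " ")
parse_nums <- function(s) {
  v <- strsplit(trimws(s), "[ \t\r\n]+")[[1]]
  as.numeric(v[nzchar(v)])
}

#' Emit a clinical-dialect export tree
#'
#' Writes a study as the package's documented clinical-export-style
#' dialect, such that [parse_clinical_export()] recovers it exactly
#' (numeric text uses 17 significant digits).
#'
#' @param study an [eam_study()].
#' @param out_dir directory to create/populate.
#' @param map_name name of the (single) map written.
#' @return `out_dir`, invisibly.
#' @export
emit_clinical_export <- function(study, out_dir, map_name = "map1") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_eam(sprintf("cannot create directory '%s'", out_dir), "eam_file_error")
  el <- study$electric
  ## study.xml
  root <- xml2::xml_new_root("study")
  xml2::xml_set_attrs(root, c(name = basename(out_dir),
                              system = study$system_name,
                              sample_frequency = fmt17(el$fs %||% 1000),
                              trace_t0 = fmt17(el$trace_t0 %||% 0)))
  notes <- xml2::xml_add_child(root, "notes")
  for (nt in study$notes) xml2::xml_add_child(notes, "note", nt)
  map <- xml2::xml_add_child(root, "map")
  xml2::xml_set_attr(map, "name", map_name)
  if (!is.null(el))
    for (id in el$point_id) {
      pt <- xml2::xml_add_child(map, "point")
      xml2::xml_set_attr(pt, "id", as.character(id))
    }
  xml2::write_xml(root, file.path(out_dir, "study.xml"))
  ## mesh.xml
  if (!is.null(study$surface)) {
    s <- study$surface
    mroot <- xml2::xml_new_root("mesh")
    xml2::xml_set_attr(mroot, "index_base", "0")
    vx <- xml2::xml_add_child(mroot, "vertices")
    xml2::xml_set_attr(vx, "count", as.character(nrow(s$vertices)))
    xml2::xml_set_text(vx, paste(apply(s$vertices, 1, num_text), collapse = "\n"))
    tx <- xml2::xml_add_child(mroot, "triangles")
    xml2::xml_set_attr(tx, "count", as.character(nrow(s$triangles)))
    xml2::xml_set_text(tx, paste(apply(s$triangles - 1L, 1, paste, collapse = " "),
                                 collapse = "\n"))
    for (nm in names(s$fields)) {
      fx <- xml2::xml_add_child(mroot, "field")
      xml2::xml_set_attr(fx, "name", nm)
      xml2::xml_set_text(fx, num_text(s$fields[[nm]]))
    }
    xml2::write_xml(mroot, file.path(out_dir, "mesh.xml"))
  }
  ## per-point files
  if (!is.null(el)) {
    loco <- is_location_only(el)
    for (i in seq_along(el$point_id)) {
      id <- el$point_id[i]
      proot <- xml2::xml_new_root("point")
      xml2::xml_set_attrs(proot, c(id = as.character(id), name = el$name[i]))
      tg <- xml2::xml_add_child(proot, "tags")
      for (t_ in el$tags[[i]]) xml2::xml_add_child(tg, "tag", t_)
      xml2::xml_add_child(proot, "position", num_text(el$egm_x[i, ]))
      xml2::xml_add_child(proot, "surface_position", num_text(el$egm_surf_x[i, ]))
      w <- xml2::xml_add_child(proot, "woi")
      xml2::xml_set_attrs(w, c(low = fmt17(el$woi[i, 1]), high = fmt17(el$woi[i, 2])))
      xml2::xml_add_child(proot, "ref_annot",
                          if (is.finite(el$ref_annot[i])) fmt17(el$ref_annot[i]) else "")
      xml2::xml_add_child(proot, "map_annot",
                          if (is.finite(el$map_annot[i])) fmt17(el$map_annot[i]) else "")
      v <- xml2::xml_add_child(proot, "voltages")
      xml2::xml_set_attrs(v, c(bip = fmt17(el$voltage_bip[i]),
                               uni = fmt17(el$voltage_uni[i])))
      xml2::xml_add_child(proot, "impedance",
                          if (!is.null(el$impedance) && is.finite(el$impedance[i]))
                            fmt17(el$impedance[i]) else "")
      xml2::write_xml(proot, file.path(out_dir, sprintf("P%s_point.xml", id)))
      if (!loco[i] && !is.null(el$traces$bip)) {
        T_ <- ncol(el$traces$bip)
        t_ms <- el$trace_t0 + (seq_len(T_) - 1L) * 1000 / el$fs
        write_csv17(data.frame(t_ms = t_ms, ref = el$traces$ref[i, ],
                               bip = el$traces$bip[i, ], uni1 = el$traces$uni1[i, ],
                               uni2 = el$traces$uni2[i, ]),
                    file.path(out_dir, sprintf("P%s_egm.csv", id)))
      }
    }
  }
  ## visitags
  if (!is.null(study$rfindex)) {
    vd <- file.path(out_dir, "visitags")
    dir.create(vd, showWarnings = FALSE)
    write_csv17(as.data.frame(study$rfindex$sites), file.path(vd, "sites.csv"))
    if (nrow(study$rfindex$grid) > 0L)
      write_csv17(as.data.frame(study$rfindex$grid), file.path(vd, "grid.csv"))
  }
  invisible(out_dir)
}

read_xml_checked <- function(path) {
  tryCatch(xml2::read_xml(path), error = function(e)
    stop_eam(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)),
             "eam_parse_error"))
}

xml_num <- function(node) {
  s <- trimws(xml2::xml_text(node))
  if (!nzchar(s)) NaN else as.numeric(s)
}

#' Parse a clinical-dialect export tree
#'
#' Reads a dialect tree (see [emit_clinical_export()]) into an
#' [eam_study()]. When `map_name` is omitted and the study descriptor
#' lists exactly one map it is selected; with several maps an error lists
#' the choices. Points whose activation annotation is empty are loaded
#' with an invalid (`NaN`) annotation and are excluded from all map
#' computations.
#'
#' @param tree_root export directory containing `study.xml`.
#' @param map_name optional map to load.
#' @param ref_channel,ecg_channel accepted for call compatibility with
#'   clinical import workflows; the dialect stores a single reference
#'   channel, so these are informational.
#' @return An [eam_study()].
#' @export
parse_clinical_export <- function(tree_root, map_name = NULL,
                                  ref_channel = NULL, ecg_channel = NULL) {
  spath <- file.path(tree_root, "study.xml")
  if (!file.exists(spath))
    stop_eam(sprintf("no study.xml in '%s'", tree_root), "eam_file_error")
  sdoc <- read_xml_checked(spath)
  maps <- xml2::xml_find_all(sdoc, "./map")
  map_names <- xml2::xml_attr(maps, "name")
  if (is.null(map_name)) {
    if (length(maps) != 1L)
      stop_eam(sprintf("study has %d maps; choose one of: %s", length(maps),
                       paste(map_names, collapse = ", ")), "eam_argument_error")
    map <- maps[[1]]
  } else {
    k <- match(map_name, map_names)
    if (is.na(k))
      stop_eam(sprintf("map '%s' not found; available: %s", map_name,
                       paste(map_names, collapse = ", ")), "eam_argument_error")
    map <- maps[[k]]
  }
  fs <- as.numeric(xml2::xml_attr(sdoc, "sample_frequency"))
  t0 <- as.numeric(xml2::xml_attr(sdoc, "trace_t0") %||% "0")
  notes <- xml2::xml_text(xml2::xml_find_all(sdoc, "./notes/note"))
  ## mesh
  surface <- NULL
  mpath <- file.path(tree_root, "mesh.xml")
  if (file.exists(mpath)) {
    mdoc <- read_xml_checked(mpath)
    base <- as.integer(xml2::xml_attr(mdoc, "index_base") %||% "0")
    v <- matrix(parse_nums(xml2::xml_text(xml2::xml_find_first(mdoc, "./vertices"))),
                ncol = 3, byrow = TRUE)
    tri <- matrix(as.integer(parse_nums(
      xml2::xml_text(xml2::xml_find_first(mdoc, "./triangles")))),
      ncol = 3, byrow = TRUE) + (1L - base)
    fields <- list()
    for (fx in xml2::xml_find_all(mdoc, "./field"))
      fields[[xml2::xml_attr(fx, "name")]] <- parse_nums(xml2::xml_text(fx))
    surface <- eam_mesh(v, tri, act = fields$act, bip = fields$bip,
                        validate = FALSE)
  }
  ## points
  ids <- xml2::xml_attr(xml2::xml_find_all(map, "./point"), "id")
  electric <- NULL
  if (length(ids)) {
    p <- length(ids)
    name <- character(p); tags <- vector("list", p)
    egm_x <- egm_surf_x <- matrix(NaN, p, 3)
    woi <- matrix(NaN, p, 2)
    ref_annot <- map_annot <- vbip <- vuni <- imp <- rep(NaN, p)
    trace_rows <- vector("list", p)
    for (i in seq_len(p)) {
      ppath <- file.path(tree_root, sprintf("P%s_point.xml", ids[i]))
      if (!file.exists(ppath))
        stop_eam(sprintf("point file missing for point id %s", ids[i]),
                 "eam_file_error")
      pdoc <- read_xml_checked(ppath)
      name[i] <- xml2::xml_attr(pdoc, "name")
      tags[[i]] <- xml2::xml_text(xml2::xml_find_all(pdoc, "./tags/tag"))
      egm_x[i, ] <- parse_nums(xml2::xml_text(xml2::xml_find_first(pdoc, "./position")))
      egm_surf_x[i, ] <- parse_nums(xml2::xml_text(
        xml2::xml_find_first(pdoc, "./surface_position")))
      w <- xml2::xml_find_first(pdoc, "./woi")
      woi[i, ] <- as.numeric(c(xml2::xml_attr(w, "low"), xml2::xml_attr(w, "high")))
      ref_annot[i] <- xml_num(xml2::xml_find_first(pdoc, "./ref_annot"))
      map_annot[i] <- xml_num(xml2::xml_find_first(pdoc, "./map_annot"))
      v <- xml2::xml_find_first(pdoc, "./voltages")
      vbip[i] <- as.numeric(xml2::xml_attr(v, "bip"))
      vuni[i] <- as.numeric(xml2::xml_attr(v, "uni"))
      imp[i] <- xml_num(xml2::xml_find_first(pdoc, "./impedance"))
      epath <- file.path(tree_root, sprintf("P%s_egm.csv", ids[i]))
      if (file.exists(epath)) trace_rows[[i]] <- read_csv_plain(epath)
    }
    loco <- vapply(tags, function(tg) any(grepl("location only", tg, ignore.case = TRUE)),
                   TRUE)
    has_tr <- !vapply(trace_rows, is.null, TRUE)
    missing_tr <- !has_tr & !loco
    if (any(missing_tr))
      stop_eam(sprintf("electrogram file missing for point id %s",
                       paste(ids[missing_tr], collapse = ", ")), "eam_file_error")
    traces <- list(bip = NULL, uni1 = NULL, uni2 = NULL, ref = NULL)
    if (any(has_tr)) {
      T_ <- nrow(trace_rows[[which(has_tr)[1]]])
      for (ch in c("bip", "uni1", "uni2", "ref")) {
        m <- matrix(NaN, p, T_)
        for (i in which(has_tr)) {
          if (nrow(trace_rows[[i]]) != T_)
            stop_eam(sprintf("trace length mismatch at point id %s", ids[i]),
                     "eam_format_error")
          m[i, ] <- trace_rows[[i]][[ch]]
        }
        traces[[ch]] <- m
      }
    }
    nid <- suppressWarnings(as.numeric(ids))
    electric <- eam_electric(
      point_id = if (!anyNA(nid)) nid else ids, name = name, tags = tags,
      egm_x = egm_x, egm_surf_x = egm_surf_x,
      bip = traces$bip, uni1 = traces$uni1, uni2 = traces$uni2, ref = traces$ref,
      fs = fs, trace_t0 = t0, ref_annot = ref_annot, map_annot = map_annot,
      woi = woi, voltage_bip = vbip, voltage_uni = vuni,
      impedance = if (all(is.nan(imp))) NULL else imp)
  }
  rfindex <- NULL
  if (file.exists(file.path(tree_root, "visitags", "sites.csv")))
    rfindex <- import_visitags(tree_root)
  eam_study(surface = surface, electric = electric, rfindex = rfindex,
            system_name = xml2::xml_attr(sdoc, "system") %||% "unknown",
            notes = notes, validate = FALSE)
}

#' Import ablation (visitag) records
#'
#' Reads the visitag site table (and grid, if present) from an export tree
#' or directly from a sites CSV file. Sites carry position (mm), the
#' platform lesion-quality index, force (g), power (W), temperature
#' (degC), impedance (Ohm) and duration (s).
#'
#' @param path export tree root (containing `visitags/sites.csv`), a
#'   visitag directory, or a sites CSV file.
#' @return An [eam_visitags()].
#' @export
import_visitags <- function(path) {
  sites_file <- if (dir.exists(path)) {
    cand <- c(file.path(path, "visitags", "sites.csv"), file.path(path, "sites.csv"))
    cand[file.exists(cand)][1]
  } else path
  if (is.na(sites_file) || !file.exists(sites_file))
    stop_eam(sprintf("no visitag site file under '%s'", path), "eam_file_error")
  sites <- read_csv_plain(sites_file)
  rf <- eam_visitags(sites)   # validates required columns
  grid_file <- file.path(dirname(sites_file), "grid.csv")
  if (file.exists(grid_file)) rf$grid <- tibble::as_tibble(read_csv_plain(grid_file))
  rf
}

#' Batch import of export trees
#'
#' Converts every dialect export tree found directly under `directory`
#' into an exchange container. Failures are logged and skipped; the run
#' itself always succeeds.
#'
#' @param directory directory whose subdirectories are export trees
#'   (identified by a `study.xml`).
#' @param out_dir where containers are written (default `directory`).
#' @param verbose log progress to stderr.
#' @return Character vector of container paths (successes), in
#'   lexicographic order.
#' @export
batch_import <- function(directory, out_dir = directory, verbose = TRUE) {
  subs <- list.dirs(directory, recursive = FALSE)
  trees <- subs[file.exists(file.path(subs, "study.xml"))]
  if (length(trees) == 0L) {
    warning(sprintf("no export trees found under '%s'", directory), call. = FALSE)
    return(character(0))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- character(0)
  for (tree in sort(trees)) {
    dest <- file.path(out_dir, paste0(basename(tree), ".openep.zip"))
    res <- tryCatch({
      write_container(parse_clinical_export(tree), dest)
      eam_log("imported ", tree, " -> ", dest, verbose = verbose)
      dest
    }, error = function(e) {
      eam_log("FAILED ", tree, ": ", conditionMessage(e), verbose = verbose)
      NA_character_
    })
    if (!is.na(res)) out <- c(out, res)
  }
  sort(out)
}
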