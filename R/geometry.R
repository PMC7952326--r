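## Chamber geometry: free-boundary (anatomical structure) detection, hole
## filling, open/closed surface area, chamber volume, point status.

#' Detect anatomical structures (free-boundary loops)
#'
#' Finds all free edges of the mesh (edges with exactly one incident
#' triangle), traces them into closed loops and summarises each loop. On a
#' clinical chamber each loop is the rim of a valve or vein cut-out.
#'
#' @param mesh an [eam_mesh()] or an [eam_study()] (its surface is used).
#' @return A tibble with one row per loop, sorted by descending perimeter:
#'   `loop` (id), `n_vertices`, `perimeter_mm`, `area_cm2` (fan
#'   triangulation to the loop centroid), `centroid_x/y/z` (mm) and
#'   `vertices` (list column of ordered 1-based vertex index cycles).
#' @export
get_anatomical_structures <- function(mesh) {
  if (inherits(mesh, "eam_study")) mesh <- require_surface(mesh)
  ec <- edge_counts(mesh)
  if (any(ec$count > 2L))
    stop_eam("non-manifold edge shared by more than 2 triangles", "eam_topology_error")
  free <- ec$count == 1L
  loops <- trace_loops(ec$a[free], ec$b[free])
  v <- mesh$vertices
  rows <- lapply(seq_along(loops), function(i) {
    cyc <- loops[[i]]
    pts <- v[cyc, , drop = FALSE]
    nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
    per <- sum(row_norms(nxt - pts))
    cen <- colMeans(pts)
    fan <- 0.5 * row_norms(row_cross(sweep(pts, 2, cen, "-"), sweep(nxt, 2, cen, "-")))
    tibble::tibble(n_vertices = length(cyc), perimeter_mm = per,
                   area_cm2 = sum(fan) / 100,
                   centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
                   vertices = list(cyc))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    return(tibble::tibble(loop = integer(0), n_vertices = integer(0),
                          perimeter_mm = numeric(0), area_cm2 = numeric(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          centroid_z = numeric(0), vertices = list()))
  out <- out[order(-out$perimeter_mm), ]
  out <- tibble::add_column(out, loop = seq_len(nrow(out)), .before = 1)
  out
}

## all vertices coplanar (within a tolerance scaled to the mesh extent)?
is_planar_mesh <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 4L) return(TRUE)
  cen <- colMeans(v)
  sv <- svd(sweep(v, 2, cen), nu = 0, nv = 0)$d
  sv[3] < 1e-9 * max(sv[1], 1)
}

## trace undirected free edges (a[i]-b[i]) into vertex cycles
trace_loops <- function(a, b) {
  if (length(a) == 0L) return(list())
  adj <- split(c(b, a), c(a, b))
  visited_edge <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  loops <- list()
  for (start in as.integer(names(adj))) {
    repeat {
      nxts <- adj[[as.character(start)]]
      nxts <- nxts[vapply(nxts, function(x) is.null(visited_edge[[ekey(start, x)]]), TRUE)]
      if (length(nxts) == 0L) break
      cyc <- start
      prev <- start; cur <- nxts[1]
      visited_edge[[ekey(prev, cur)]] <- TRUE
      while (cur != start) {
        cyc <- c(cyc, cur)
        cand <- adj[[as.character(cur)]]
        cand <- cand[cand != prev]
        cand <- cand[vapply(cand, function(x) is.null(visited_edge[[ekey(cur, x)]]), TRUE)]
        if (length(cand) == 0L) {
          ## should not happen on a manifold-with-boundary mesh
          stop_eam("boundary tracing failed: open free-edge chain", "eam_topology_error")
        }
        prev <- cur; cur <- cand[1]
        visited_edge[[ekey(prev, cur)]] <- TRUE
      }
      loops[[length(loops) + 1L]] <- cyc
    }
  }
  loops
}

#' Close all holes of a mesh
#'
#' Triangulates each free-boundary loop by a fan to a new vertex at the
#' loop centroid. Original triangles are unchanged; on a chamber the
#' result has no free edges. Per-vertex fields are extended with `NaN` at
#' the new centroid vertices. Idempotent on closed meshes.
#'
#' One special case: on a planar sheet (all vertices coplanar) the
#' outermost (largest-perimeter) boundary is the sheet's rim, not a hole,
#' and filling it would double-cover the plane; it is left open. Chamber
#' surfaces are never planar, so all their cut-outs are filled.
#'
#' @param mesh an [eam_mesh()].
#' @return A closed [eam_mesh()] (closed up to the rim of a planar sheet).
#' @export
fill_holes <- function(mesh) {
  if (inherits(mesh, "eam_study")) mesh <- require_surface(mesh)
  loops <- get_anatomical_structures(mesh)
  if (nrow(loops) == 0L) return(mesh)
  if (is_planar_mesh(mesh)) loops <- loops[-1, , drop = FALSE]  # largest = rim
  if (nrow(loops) == 0L) return(mesh)
  v <- mesh$vertices; tri <- mesh$triangles
  fields <- mesh$fields
  for (i in seq_len(nrow(loops))) {
    cyc <- loops$vertices[[i]]
    cen <- c(loops$centroid_x[i], loops$centroid_y[i], loops$centroid_z[i])
    v <- rbind(v, cen)
    ci <- nrow(v)
    nxt <- c(cyc[-1], cyc[1])
    tri <- rbind(tri, cbind(cyc, nxt, ci))
    fields <- lapply(fields, function(f) c(f, NaN))
  }
  out <- eam_mesh(v, tri, validate = FALSE)
  out$fields <- fields
  validate_mesh(out)
  out
}

#' Chamber surface area
#'
#' `"nofill"` sums the triangle areas of the mesh as-is (open surface,
#' anatomical cut-outs excluded); `"fill"` closes the cut-outs with
#' [fill_holes()] first, so `fill >= nofill` always.
#'
#' @param x an [eam_mesh()] or [eam_study()].
#' @param method `"nofill"` or `"fill"`.
#' @return Area in cm^2.
#' @export
get_area <- function(x, method = c("nofill", "fill")) {
  method <- match.arg(method)
  mesh <- if (inherits(x, "eam_study")) require_surface(x) else x
  if (method == "fill") mesh <- fill_holes(mesh)
  sum(triangle_areas(mesh)) / 100
}

## Make triangle winding consistent by breadth-first propagation across
## shared edges, then orient outward (positive signed volume).
orient_consistently <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri)
  ## adjacency via shared undirected edges
  he <- half_edges(tri)
  tri_of <- rep(seq_len(m), 3L)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  grp <- split(seq_along(key), key)
  adj <- vector("list", m)
  for (g in grp) {
    if (length(g) == 2L) {
      t1 <- tri_of[g[1]]; t2 <- tri_of[g[2]]
      adj[[t1]] <- c(adj[[t1]], t2); adj[[t2]] <- c(adj[[t2]], t1)
    } else if (length(g) > 2L) {
      stop_eam("non-manifold edge: cannot orient", "eam_topology_error")
    }
  }
  ## directed edge sets per triangle for flip detection
  dir_edges <- function(t_) {
    rbind(tri[t_, c(1, 2)], tri[t_, c(2, 3)], tri[t_, c(3, 1)])
  }
  visited <- rep(FALSE, m); flipped <- rep(FALSE, m)
  for (seed_t in seq_len(m)) {
    if (visited[seed_t]) next
    queue <- seed_t; visited[seed_t] <- TRUE
    while (length(queue)) {
      t_ <- queue[[1]]; queue <- queue[-1]
      e1 <- dir_edges(t_)
      if (flipped[t_]) e1 <- e1[, 2:1, drop = FALSE]
      for (u in adj[[t_]]) {
        if (visited[u]) next
        e2 <- dir_edges(u)
        ## consistent winding: the shared edge appears in opposite directions
        same_dir <- any(apply(e1, 1, function(ed)
          any(e2[, 1] == ed[1] & e2[, 2] == ed[2])))
        flipped[u] <- xor(flipped[t_], same_dir)
        visited[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  tri[flipped, ] <- tri[flipped, c(1, 3, 2)]
  out <- mesh; out$triangles <- tri
  out
}

signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices; tri <- mesh$triangles
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  sum(rowSums(a * row_cross(b, c_))) / 6
}

#' Chamber volume
#'
#' Closes the mesh with [fill_holes()], repairs triangle orientation by
#' breadth-first propagation, and evaluates the divergence-theorem volume
#' `|sum det(a,b,c)/6|`. Translation-invariant by signed-volume
#' cancellation.
#'
#' @param x an [eam_mesh()] or [eam_study()].
#' @return Volume in cm^3.
#' @export
get_volume <- function(x) {
  mesh <- if (inherits(x, "eam_study")) require_surface(x) else x
  closed <- fill_holes(mesh)
  oriented <- orient_consistently(closed)
  abs(signed_volume_mm3(oriented)) / 1000
}

#' Classify electric points as interior/exterior to the chamber
#'
#' Ray-casts from each point along three seeded directions against the
#' closed chamber surface and takes the majority crossing-parity vote
#' (odd = interior). Also reports the distance from each point to the open
#' surface.
#'
#' @param study an [eam_study()] with surface and electric data.
#' @param surface_tolerance reported alongside the distances (mm); the
#'   classification itself is strict in/out.
#' @param seed seed for the ray directions.
#' @return tibble with `point_id`, `status` ("interior"/"exterior"),
#'   `distance_mm` and `within_tolerance`.
#' @export
point_status <- function(study, surface_tolerance = 3, seed = 42L) {
  mesh <- require_surface(study)
  el <- require_electric(study)
  closed <- orient_consistently(fill_holes(mesh))
  pts <- el$egm_x
  set.seed(seed)
  dirs <- matrix(rnorm(9), 3, 3)
  dirs <- dirs / row_norms(dirs)
  inside <- vapply(seq_len(nrow(pts)), function(i) {
    votes <- vapply(1:3, function(k)
      ray_crossings(closed, pts[i, ], dirs[k, ]) %% 2L == 1L, TRUE)
    sum(votes) >= 2L
  }, TRUE)
  d <- if (nrow(pts)) point_surface_distance(mesh, pts)$distance else numeric(0)
  tibble::tibble(point_id = el$point_id,
                 status = ifelse(inside, "interior", "exterior"),
                 distance_mm = d,
                 within_tolerance = d <= surface_tolerance)
}
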