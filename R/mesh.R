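#' Triangulated chamber surface
#'
#' Constructs the surface half of an EAM study: an n x 3 vertex matrix (mm),
#' an m x 3 triangle index matrix and optional per-vertex clinical map fields
#' `act` (local activation time, ms, relative to the reference annotation)
#' and `bip` (bipolar voltage, mV). Missing field values are encoded as
#' `NaN`. Triangle indices are 1-based in memory (R convention); all file
#' formats store them 0-based.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param act,bip optional length-n per-vertex scalars; `NaN` marks vertices
#'   without a clinical value.
#' @param validate check topology invariants (manifold-with-boundary, no
#'   degenerate triangles, indices in range).
#' @return An object of class `eam_mesh`.
#' @export
eam_mesh <- function(vertices, triangles, act = NULL, bip = NULL, validate = TRUE) {
  vertices <- as_matrix3(vertices, "vertices")
  triangles <- as.matrix(triangles)
  if (length(triangles) == 0L) triangles <- matrix(integer(0), 0L, 3L)
  if (ncol(triangles) != 3L) stop_eam("triangles must have 3 columns", "eam_argument_error")
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  n <- nrow(vertices)
  fields <- list()
  for (nm in c("act", "bip")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n) stop_eam(sprintf("field '%s' must have length %d", nm, n),
                                   "eam_argument_error")
      fields[[nm]] <- as.double(v)
    }
  }
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         fields = fields), class = "eam_mesh")
  if (validate && nrow(triangles) > 0L) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  n <- nrow(mesh$vertices); tri <- mesh$triangles
  if (nrow(tri) > 0L) {
    if (min(tri) < 1L || max(tri) > n)
      stop_eam("triangle indices out of range", "eam_topology_error")
    if (any(tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]))
      stop_eam("degenerate triangle (repeated vertex)", "eam_topology_error")
    if (any(triangle_areas(mesh) <= 0))
      stop_eam("degenerate triangle (zero area)", "eam_topology_error")
    cnt <- edge_counts(mesh)
    if (any(cnt$count > 2L))
      stop_eam("non-manifold edge shared by more than 2 triangles", "eam_topology_error")
  }
  invisible(mesh)
}

#' @export
print.eam_mesh <- function(x, ...) {
  cat(sprintf("<eam_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (length(x$fields))
    cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  loops <- tryCatch(nrow(get_anatomical_structures(x)), error = function(e) NA)
  if (!is.na(loops)) cat("  free-boundary loops:", loops, "\n")
  invisible(x)
}

## --- topology helpers -----------------------------------------------------

## undirected edge table with incidence counts
edge_counts <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  uk <- names(tab)
  parts <- matrix(as.integer(unlist(strsplit(uk, " ", fixed = TRUE))), ncol = 2, byrow = TRUE)
  list(a = parts[, 1], b = parts[, 2], count = as.integer(tab))
}

## directed half-edges per triangle, used for boundary tracing
half_edges <- function(tri) {
  rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
}

#' Per-triangle areas in mm^2
#' @param mesh an `eam_mesh`.
#' @return numeric vector of length `nrow(mesh$triangles)`.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tri <- mesh$triangles
  if (nrow(tri) == 0L) return(numeric(0))
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  0.5 * row_norms(row_cross(b - a, c_ - a))
}

triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tri <- mesh$triangles
  (v[tri[, 1], , drop = FALSE] + v[tri[, 2], , drop = FALSE] +
     v[tri[, 3], , drop = FALSE]) / 3
}

triangle_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; tri <- mesh$triangles
  nrm <- row_cross(v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE],
                   v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE])
  if (normalize) nrm <- nrm / pmax(row_norms(nrm), .Machine$double.xmin)
  nrm
}

## Area-weighted vertex normals (unit). Used for tangential projection in
## conduction-velocity mapping.
vertex_normals <- function(mesh) {
  tri <- mesh$triangles
  fn <- triangle_normals(mesh, normalize = FALSE)  # magnitude = 2 * area
  n <- nrow(mesh$vertices)
  vn <- matrix(0, n, 3)
  for (k in 1:3) {
    for (j in 1:3) {
      vn[, j] <- vn[, j] + tabulate2(tri[, k], fn[, j], n)
    }
  }
  vn / pmax(row_norms(vn), .Machine$double.xmin)
}

## sum of weights w grouped by integer index idx, result length n
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

mean_edge_length <- function(mesh) {
  ec <- edge_counts(mesh)
  mean(row_norms(mesh$vertices[ec$a, , drop = FALSE] -
                 mesh$vertices[ec$b, , drop = FALSE]))
}

## Edge graph (igraph) weighted by Euclidean edge length; geodesic
## approximations use shortest paths over this graph.
mesh_edge_graph <- function(mesh) {
  ec <- edge_counts(mesh)
  w <- row_norms(mesh$vertices[ec$a, , drop = FALSE] -
                 mesh$vertices[ec$b, , drop = FALSE])
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ec$a, ec$b))
  igraph::E(g)$weight <- w
  g
}

geodesic_distances <- function(mesh, from) {
  g <- mesh_edge_graph(mesh)
  d <- igraph::distances(g, v = from, weights = igraph::E(g)$weight)
  if (length(from) == 1L) as.numeric(d) else d
}

## Minimum distance from each row of pts to the mesh surface, plus the
## closest surface point. Exact point-triangle distance, vectorised over
## triangles for each query point.
point_surface_distance <- function(mesh, pts) {
  pts <- as_matrix3(pts, "pts")
  v <- mesh$vertices; tri <- mesh$triangles
  a <- v[tri[, 1], , drop = FALSE]
  ab <- v[tri[, 2], , drop = FALSE] - a
  ac <- v[tri[, 3], , drop = FALSE] - a
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  np <- nrow(pts)
  dist <- numeric(np); closest <- matrix(0, np, 3); tri_id <- integer(np)
  for (i in seq_len(np)) {
    ap <- sweep(a, 2, pts[i, ], "-") * -1
    d20 <- rowSums(ap * ab); d21 <- rowSums(ap * ac)
    denom <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / denom
    w <- (d00 * d21 - d01 * d20) / denom
    u <- pmin(pmax(u, 0), 1); w <- pmin(pmax(w, 0), 1)
    s <- u + w
    scale <- ifelse(s > 1, 1 / s, 1)
    u <- u * scale; w <- w * scale
    ## clamped barycentric projection is not exact on edge regions; refine by
    ## also clamping each edge parameterisation and taking the best
    cand <- a + ab * u + ac * w
    d2 <- rowSums((cand - matrix(pts[i, ], nrow(a), 3, byrow = TRUE))^2)
    ## edge candidates
    for (edge in list(list(p = a, d = ab, l2 = d00),
                      list(p = a, d = ac, l2 = d11),
                      list(p = a + ab, d = ac - ab,
                           l2 = rowSums((ac - ab)^2)))) {
      t_ <- rowSums(sweep(edge$p, 2, pts[i, ], "-") * -1 * edge$d) / pmax(edge$l2, .Machine$double.xmin)
      t_ <- pmin(pmax(t_, 0), 1)
      q <- edge$p + edge$d * t_
      dq <- rowSums((q - matrix(pts[i, ], nrow(a), 3, byrow = TRUE))^2)
      better <- dq < d2
      cand[better, ] <- q[better, , drop = FALSE]
      d2[better] <- dq[better]
    }
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j]); closest[i, ] <- cand[j, ]; tri_id[i] <- j
  }
  list(distance = dist, closest = closest, triangle = tri_id)
}

## Ray-triangle crossing counts (Moller-Trumbore), one ray per call.
ray_crossings <- function(mesh, origin, dir) {
  v <- mesh$vertices; tri <- mesh$triangles
  a <- v[tri[, 1], , drop = FALSE]
  e1 <- v[tri[, 2], , drop = FALSE] - a
  e2 <- v[tri[, 3], , drop = FALSE] - a
  dmat <- matrix(dir, nrow(a), 3, byrow = TRUE)
  p <- row_cross(dmat, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  tvec <- sweep(a, 2, origin, "-") * -1
  u <- rowSums(tvec * p) / det
  q <- row_cross(tvec, e1)
  vv <- rowSums(dmat * q) / det
  t_ <- rowSums(e2 * q) / det
  hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & t_ > 1e-9
  sum(hit, na.rm = TRUE)
}
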