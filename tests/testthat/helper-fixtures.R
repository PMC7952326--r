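## Shared fixtures (built once per test run) and independent oracles.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

## default study: 30 mm chamber, 5 holes, planar wave 1 m/s, 60 points
fx_study <- function() fx("study", function()
  make_study_fixture(n_points = 60, seed = 11, n_location_only = 2,
                     n_visitags = 12))

## denser study for CV / earliest-site work
fx_study200 <- function() fx("study200", function()
  make_study_fixture(n_points = 200, seed = 23))

## closed unjittered sphere, r = 30 mm
fx_sphere <- function(subdiv = 4) fx(paste0("sphere", subdiv), function()
  make_chamber_mesh(chamber_spec(radius = 30, subdiv = subdiv, holes = list())))

## planar toys -----------------------------------------------------------

## unit square in the z = 0 plane as two triangles
square_mesh <- function() {
  eam_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

## unit square with a triangular hole of area 0.125
square_with_hole_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0.25, 0.25, 0), c(0.75, 0.25, 0), c(0.25, 0.75, 0))
  tri <- rbind(c(1, 2, 6), c(1, 6, 5), c(2, 3, 6), c(3, 7, 6),
               c(3, 4, 7), c(4, 1, 7), c(1, 5, 7))
  eam_mesh(v, tri)
}

## unit cube as 12 triangles (inconsistent winding on purpose: volume code
## must repair orientation)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  eam_mesh(v, tri)
}

tetra_mesh <- function() {
  eam_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

## independent oracles ----------------------------------------------------

## brute-force percentile: sort + linear interpolation between closest
## order statistics, written from the definition
oracle_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

## brute-force min distance from point to a triangle by dense barycentric
## sampling (oracle only; coarse but unbiased)
oracle_point_triangle_dist <- function(p, a, b, c, k = 60) {
  s <- seq(0, 1, length.out = k)
  best <- Inf
  for (u in s) for (v in s[s <= 1 - u + 1e-12]) {
    q <- a + u * (b - a) + v * (c - a)
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

## signed parity point-in-mesh oracle: exhaustive triangle crossing count
## along a fixed ray
oracle_inside <- function(mesh, p, dir = c(0.21, 0.47, 0.86)) {
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices; tri <- mesh$triangles
  hits <- 0L
  for (k in seq_len(nrow(tri))) {
    a <- v[tri[k, 1], ]; b <- v[tri[k, 2], ]; c <- v[tri[k, 3], ]
    e1 <- b - a; e2 <- c - a
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2], dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- p - a
    u <- sum(tv * pv) / det
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    w <- sum(dir * qv) / det
    t_ <- sum(e2 * qv) / det
    if (u >= 0 && w >= 0 && u + w <= 1 && t_ > 1e-9) hits <- hits + 1L
  }
  hits %% 2L == 1L
}

## area-weighted mean voltage by an explicit per-triangle loop
oracle_mean_voltage <- function(mesh, values, valid) {
  tot <- 0; wsum <- 0
  for (k in seq_len(nrow(mesh$triangles))) {
    i <- mesh$triangles[k, ]
    if (!all(valid[i])) next
    a <- mesh$vertices[i[1], ]; b <- mesh$vertices[i[2], ]; c <- mesh$vertices[i[3], ]
    ar <- 0.5 * sqrt(sum(pracma_cross(b - a, c - a)^2))
    tot <- tot + ar * mean(values[i])
    wsum <- wsum + ar
  }
  tot / wsum
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

## distances from mesh vertices to their nearest boundary vertex
boundary_clearance <- function(mesh) {
  loops <- get_anatomical_structures(mesh)
  bv <- unique(unlist(loops$vertices))
  if (length(bv) == 0L) return(rep(Inf, nrow(mesh$vertices)))
  b <- mesh$vertices[bv, , drop = FALSE]
  d2 <- outer(rowSums(mesh$vertices^2), rowSums(b^2), "+") -
    2 * tcrossprod(mesh$vertices, b)
  sqrt(pmax(apply(d2, 1, min), 0))
}
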