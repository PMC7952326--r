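test_that("boundary loops capture each cut-out exactly once", {
  expect_equal(nrow(get_anatomical_structures(fx_sphere(3))), 0)
  mesh <- make_chamber_mesh(chamber_spec())
  loops <- get_anatomical_structures(mesh)
  expect_equal(nrow(loops), 5)
  ## sorted by descending perimeter (valve first)
  expect_true(all(diff(loops$perimeter_mm) <= 0))
  ## each free edge appears in exactly one loop: total loop vertices equals
  ## number of free edges
  ec_free <- sum(table(paste(
    pmin(rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3], mesh$triangles[, c(3, 1)])[, 1],
         rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3], mesh$triangles[, c(3, 1)])[, 2]),
    pmax(rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3], mesh$triangles[, c(3, 1)])[, 1],
         rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3], mesh$triangles[, c(3, 1)])[, 2]))) == 1L)
  expect_equal(sum(loops$n_vertices), ec_free)
  expect_equal(anyDuplicated(unlist(loops$vertices)), 0L)
})

test_that("a circular rim's perimeter matches its construction", {
  ## planar annulus whose inner hole is a circular polygon of radius 5 mm
  n <- 64
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  inner <- cbind(5 * cos(th), 5 * sin(th), 0)
  outer <- cbind(10 * cos(th), 10 * sin(th), 0)
  tri <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(c(i, n + i, n + j), c(i, n + j, j))
  }))
  mesh <- eam_mesh(rbind(inner, outer), tri)
  loops <- get_anatomical_structures(mesh)
  expect_equal(nrow(loops), 2)             # outer rim + inner hole
  hole <- loops[2, ]                       # smaller perimeter
  pts <- mesh$vertices[hole$vertices[[1]], ]
  oracle_perimeter <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  expect_equal(hole$perimeter_mm, oracle_perimeter)
  expect_equal(hole$perimeter_mm, 2 * pi * 5, tolerance = 0.05)
  ## the chamber cut-out rims also satisfy the polygon-sum identity
  ch <- make_chamber_mesh(chamber_spec())
  lp <- get_anatomical_structures(ch)
  cyc <- lp$vertices[[1]]
  p2 <- ch$vertices[cyc, ]
  expect_equal(lp$perimeter_mm[1],
               sum(sqrt(rowSums((p2 - p2[c(2:nrow(p2), 1), ])^2))))
})

test_that("hole filling closes the surface and is idempotent", {
  closed <- fx_sphere(3)
  expect_identical(fill_holes(closed)$triangles, closed$triangles)
  mesh <- make_chamber_mesh(chamber_spec())
  filled <- fill_holes(mesh)
  expect_equal(nrow(get_anatomical_structures(filled)), 0)
  expect_equal(nrow(filled$vertices), nrow(mesh$vertices) + 5)
  ## original triangles unchanged
  expect_identical(filled$triangles[seq_len(nrow(mesh$triangles)), ],
                   mesh$triangles)
})

test_that("areas are exact on planar toys and analytic on spheres", {
  expect_equal(get_area(square_mesh(), "nofill") * 100, 1.0)
  expect_equal(get_area(square_mesh(), "fill") * 100, 1.0)
  hole <- square_with_hole_mesh()
  expect_equal(get_area(hole, "nofill") * 100, 0.875)
  expect_equal(get_area(hole, "fill") * 100, 1.0)
  s4 <- fx_sphere(4)
  expect_equal(get_area(s4, "nofill"), 113.10, tolerance = 0.02)
  expect_error(get_area(s4, "both"))
  ## fill >= nofill, and the difference equals the summed fan areas
  mesh <- make_chamber_mesh(chamber_spec())
  loops <- get_anatomical_structures(mesh)
  expect_equal(get_area(mesh, "fill") - get_area(mesh, "nofill"),
               sum(loops$area_cm2), tolerance = 1e-9)
})

test_that("volumes match analytic solids and survive translation", {
  expect_equal(get_volume(cube_mesh()) * 1000, 1.0, tolerance = 1e-12)
  expect_equal(get_volume(tetra_mesh()) * 1000, 1 / 6, tolerance = 1e-12)
  s4 <- fx_sphere(4)
  expect_equal(get_volume(s4), 4 / 3 * pi * 30^3 / 1000, tolerance = 0.02)
  shifted <- s4
  shifted$vertices <- sweep(shifted$vertices, 2, c(1000, -2000, 500), "+")
  expect_equal(get_volume(shifted), get_volume(s4), tolerance = 1e-9)
})

test_that("refinement strictly shrinks sphere area and volume errors", {
  area_err <- vapply(2:4, function(s)
    abs(get_area(fx_sphere(s), "nofill") - 4 * pi * 9), 1)
  vol_err <- vapply(2:4, function(s)
    abs(get_volume(fx_sphere(s)) - 4 / 3 * pi * 27), 1)
  expect_true(all(diff(area_err) < 0))
  expect_true(all(diff(vol_err) < 0))
})

test_that("point status matches an exhaustive parity oracle", {
  mesh <- make_chamber_mesh(chamber_spec(subdiv = 2))
  set.seed(31)
  pts <- matrix(runif(3 * 40, -50, 50), ncol = 3)
  pts <- rbind(pts, c(0, 0, 0), c(60, 0, 0))
  el <- eam_electric(point_id = seq_len(nrow(pts)), egm_x = pts, egm_surf_x = pts)
  st <- eam_study(surface = mesh, electric = el, validate = FALSE)
  ps <- point_status(st)
  closed <- fill_holes(mesh)
  want <- vapply(seq_len(nrow(pts)), function(i) oracle_inside(closed, pts[i, ]), TRUE)
  expect_equal(ps$status, ifelse(want, "interior", "exterior"))
  expect_equal(ps$status[nrow(pts) - 1L], "interior")  # centroid
  expect_equal(ps$status[nrow(pts)], "exterior")       # 2x radius
  expect_true(all(ps$distance_mm >= 0))
})

test_that("non-manifold meshes are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  tri <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(eam_mesh(v, tri), class = "eam_topology_error")
})
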