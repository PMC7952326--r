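test_that("point counting excludes location-only points unless asked", {
  st <- fx_study()
  expect_equal(get_num_points(st), 60)
  expect_equal(get_num_points(st, include_location_only = TRUE), 62)
  empty <- eam_study(surface = NULL, electric = NULL)
  expect_error(get_num_points(empty), class = "eam_missing_data_error")
})

test_that("electrogram positions come back in point order and on the surface", {
  st <- fx_study()
  raw <- get_electrogram_positions(st, "raw")
  surf <- get_electrogram_positions(st, "surface")
  expect_equal(dim(raw), c(62, 3))
  truth <- attr(st, "truth")
  expect_equal(surf[seq_len(60), ],
               st$surface$vertices[truth$sample_vertices, ])
  ## surface positions within 2x mean edge length of the mesh, checked by a
  ## dense point-triangle sampling oracle on a handful of points
  lim <- 2 * mean(sqrt(rowSums((st$surface$vertices[st$surface$triangles[, 1], ] -
                                st$surface$vertices[st$surface$triangles[, 2], ])^2)))
  for (i in c(1, 25, 60)) {
    d <- min(vapply(seq_len(nrow(st$surface$triangles)), function(k) {
      tr <- st$surface$triangles[k, ]
      oracle_point_triangle_dist(surf[i, ], st$surface$vertices[tr[1], ],
                                 st$surface$vertices[tr[2], ],
                                 st$surface$vertices[tr[3], ], k = 15)
    }, 1))
    expect_lt(d, lim)
  }
  expect_error(get_electrogram_positions(st, "bogus"))
})

test_that("clinical point-id lookup returns 0-based indices and errors on misses", {
  mesh <- fx_study()$surface
  el <- eam_electric(point_id = c(7, 1042, 9),
                     egm_x = mesh$vertices[1:3, ], egm_surf_x = mesh$vertices[1:3, ])
  st <- eam_study(surface = NULL, electric = el)
  expect_identical(index_from_clinical_point_id(st, 1042), 1L)
  expect_identical(index_from_clinical_point_id(st, 7), 0L)
  expect_error(index_from_clinical_point_id(st, 9999),
               class = "eam_point_not_found_error")
  expect_error(eam_electric(point_id = c(1, 1), egm_x = mesh$vertices[1:2, ],
                            egm_surf_x = mesh$vertices[1:2, ]),
               class = "eam_argument_error")
})

test_that("electrogram retrieval keeps traces untruncated with annotations", {
  st <- fx_study()
  eg <- get_egms_at_points(st, c(0L, 5L))
  T_ <- ncol(st$electric$traces$bip)
  expect_equal(ncol(eg$bip), T_)
  expect_equal(ncol(eg$ref), T_)
  ## annotation sample index = round((map_annot - start) * fs / 1000)
  expect_equal(eg$annot_sample,
               as.integer(round(eg$map_annot * st$electric$fs / 1000)))
  ## fixture construction: bip = uni1 - uni2 (noise-free fixture)
  expect_equal(eg$bip, eg$uni1 - eg$uni2, tolerance = 1e-12)
  ## location-only points refuse electrogram access
  loco_idx <- which(vapply(st$electric$tags, function(t) length(t) > 0, TRUE))[1] - 1L
  expect_error(get_egms_at_points(st, loco_idx), class = "eam_location_only_error")
  expect_error(get_egms_at_points(st, 999L), class = "eam_argument_error")
})

test_that("window of interest is returned absolute and contains annotations", {
  mesh <- square_mesh()
  el <- eam_electric(point_id = 1, egm_x = rbind(c(0, 0, 0)),
                     egm_surf_x = rbind(c(0, 0, 0)),
                     ref_annot = 500, map_annot = 520,
                     woi = rbind(c(-50, 100)))
  st <- eam_study(electric = el)
  expect_equal(get_window_of_interest(st, 0L), rbind(c(450, 600)))
  ## width preserved
  w <- get_window_of_interest(st, 0L)
  expect_equal(w[, 2] - w[, 1], 150)
  ## on the fixture every annotation lies inside its absolute window
  stf <- fx_study()
  keep <- is.finite(stf$electric$map_annot)
  wall <- get_window_of_interest(stf)
  expect_true(all(stf$electric$map_annot[keep] >= wall[keep, 1] &
                  stf$electric$map_annot[keep] <= wall[keep, 2]))
})

test_that("metric operations ignore added location-only points", {
  a <- make_study_fixture(n_points = 40, seed = 5)
  b <- make_study_fixture(n_points = 40, seed = 5, n_location_only = 6)
  expect_equal(get_num_points(a), get_num_points(b))
  expect_equal(total_activation_time(a, "ptbased"),
               total_activation_time(b, "ptbased"))
  expect_equal(mean_voltage(a, "egm"), mean_voltage(b, "egm"))
})

test_that("study assembly rejects off-surface projected positions", {
  mesh <- fx_sphere(3)
  el <- eam_electric(point_id = 1, egm_x = rbind(c(200, 0, 0)),
                     egm_surf_x = rbind(c(200, 0, 0)))
  expect_error(eam_study(surface = mesh, electric = el),
               class = "eam_consistency_error")
})
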