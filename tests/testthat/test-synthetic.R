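test_that("chamber meshes have the constructed topology and analytic area", {
  closed <- make_chamber_mesh(chamber_spec(radius = 30, subdiv = 3, holes = list()))
  expect_equal(nrow(get_anatomical_structures(closed)), 0)
  five <- make_chamber_mesh(chamber_spec(radius = 30, subdiv = 3))
  expect_equal(nrow(get_anatomical_structures(five)), 5)
  ## r = 30 mm icosphere at s = 4: area within 2% of 4 pi r^2 = 113.10 cm^2
  s4 <- fx_sphere(4)
  expect_equal(get_area(s4, "nofill"), 4 * pi * 30^2 / 100, tolerance = 0.02)
  ## overlapping holes rejected
  expect_error(chamber_spec(holes = list(
    list(direction = c(0, 0, 1), angular_radius = 0.4),
    list(direction = c(0, 0.3, 1), angular_radius = 0.4))),
    class = "eam_argument_error")
})

test_that("seeded chamber generation is deterministic", {
  a <- make_chamber_mesh(chamber_spec(jitter_sd = 0.1, seed = 9))
  b <- make_chamber_mesh(chamber_spec(jitter_sd = 0.1, seed = 9))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
})

test_that("planar activation matches the closed form and its scaling law", {
  mesh <- fx_sphere(3)
  act <- simulate_activation(mesh, wave_spec("planar", speed = 1,
                                             direction = c(1, 0, 0)))
  ## brute-force oracle: extent of the closed-form field along x
  proj <- mesh$vertices[, 1]
  expect_equal(act$truth$tat, max(proj) - min(proj), tolerance = 1e-12)
  expect_equal(max(act$lat) - min(act$lat), 60, tolerance = 0.01 * 60)
  ## doubling speed halves the range exactly
  act2 <- simulate_activation(mesh, wave_spec("planar", speed = 2,
                                              direction = c(1, 0, 0)))
  expect_equal(act2$truth$tat, act$truth$tat / 2)
})

test_that("focal activation starts at the source with LAT t0", {
  mesh <- make_chamber_mesh(chamber_spec())
  act <- simulate_activation(mesh, wave_spec("focal", speed = 1,
                                             source_vertex = 42L, t0 = 7))
  expect_equal(which.min(act$lat), 42L)
  expect_equal(act$lat[42], 7)
  expect_error(simulate_activation(mesh, wave_spec("focal", source_vertex = 10^6)),
               class = "eam_argument_error")
})

test_that("voltage fields place patches with believable areas", {
  mesh <- make_chamber_mesh(chamber_spec())
  flat <- simulate_voltage_field(mesh, patches = list(), background = 1)
  expect_true(all(flat$bip == 1))
  p <- simulate_voltage_field(mesh,
                              patches = list(list(center_vertex = 50L,
                                                  radius = 10, level = 0.2)),
                              background = 1)
  expect_gt(p$truth$area_full_triangles_cm2, 0)
  ## geodesic disc on a positively curved chamber: area <= pi r^2
  expect_lte(p$truth$area_full_triangles_cm2, pi * 10^2 / 100)
})

test_that("electrogram templates put the steepest negative slope at t*", {
  ## dense numeric minimisation of the slope of the unipolar template
  spec <- egm_spec(fs = 1000, n_samples = 1000, amplitude = 1, width = 5,
                   delay = 2, noise_sd = 0)
  mesh <- square_mesh()
  lat <- c(100, 110, 120, 130)
  el <- synthesize_electrograms(mesh, lat, 1:4, spec, ref_annot = 400)
  t_dense <- seq(480, 520, by = 0.001)
  u <- -1 * ((t_dense - 500) / 5) * exp(-(t_dense - 500)^2 / 50)
  slope <- diff(u) / diff(t_dense)
  t_steepest <- t_dense[which.min(slope)]
  expect_equal(t_steepest, 500, tolerance = 1e-2)
  ## and the synthesized annotation sits at ref_annot + lat
  expect_equal(el$map_annot, 400 + lat)
  ## zero inter-electrode delay cancels the bipole exactly
  el0 <- synthesize_electrograms(mesh, lat, 1:4,
                                 egm_spec(delay = 0, noise_sd = 0))
  expect_true(all(abs(el0$traces$bip) < 1e-15))
  ## bipolar point voltage scales linearly with amplitude
  elA <- synthesize_electrograms(mesh, lat, 1:4, egm_spec(amplitude = 3))
  el1 <- synthesize_electrograms(mesh, lat, 1:4, egm_spec(amplitude = 1))
  expect_equal(elA$voltage_bip, 3 * el1$voltage_bip, tolerance = 1e-12)
  expect_error(synthesize_electrograms(mesh, rep(5000, 4), 1:4, spec),
               class = "eam_argument_error")
})

test_that("fixture ground truth is self-consistent and seeded", {
  st1 <- make_study_fixture(n_points = 30, seed = 77)
  st2 <- make_study_fixture(n_points = 30, seed = 77)
  expect_identical(st1$electric$traces$bip, st2$electric$traces$bip)
  expect_identical(st1$surface$vertices, st2$surface$vertices)
  tr <- attr(st1, "truth")
  expect_equal(st1$electric$map_annot - st1$electric$ref_annot, tr$point_lat)
})
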