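## study with point LATs replaced by a fixed vector (keeps geometry valid)
study_with_lats <- function(lats) {
  st <- make_study_fixture(n_points = length(lats), seed = 2)
  el <- st$electric
  el$map_annot <- el$ref_annot + lats
  el$woi <- cbind(rep(min(0, min(lats)) - 1, length(lats)),
                  rep(max(lats) + 1, length(lats)))
  st$electric <- el
  st
}

test_that("point-based TAT is the range of point LATs", {
  st <- study_with_lats(c(10, 50, 80, 20, 30))
  expect_equal(total_activation_time(st, "ptbased"), 70)
  ## equals ground truth exactly on the planar fixture
  stf <- fx_study()
  truth <- attr(stf, "truth")
  expect_equal(total_activation_time(stf, "ptbased"),
               max(truth$point_lat) - min(truth$point_lat))
})

test_that("percentile TAT matches a brute-force order-statistic oracle", {
  set.seed(99)
  lats <- runif(1001, 0, 100)
  st <- study_with_lats(lats)
  got <- total_activation_time(st, "ptbasedprct", q = 2.5)
  want <- oracle_percentile(lats, 97.5) - oracle_percentile(lats, 2.5)
  expect_equal(got, want, tolerance = 1e-12)
  ## percentile range is never wider than the full range
  for (seed in 1:5) {
    set.seed(seed)
    l2 <- rnorm(67, 50, 20)
    s2 <- study_with_lats(l2)
    expect_lte(total_activation_time(s2, "ptbasedprct"),
               total_activation_time(s2, "ptbased"))
  }
  expect_error(total_activation_time(st, "ptbased", q = 60),
               class = "eam_argument_error")
})

test_that("TAT is shift-invariant and scales linearly", {
  lats <- c(5, 12, 40, 33, 25, 18)
  st <- study_with_lats(lats)
  st2 <- study_with_lats(lats + 100)
  st3 <- study_with_lats(lats * 3)
  for (m in c("ptbased", "ptbasedprct")) {
    expect_equal(total_activation_time(st, m), total_activation_time(st2, m))
    expect_equal(total_activation_time(st3, m), 3 * total_activation_time(st, m))
  }
})

test_that("map-based TAT uses the surface fields", {
  st <- fx_study()
  act <- st$surface$fields$act
  expect_equal(total_activation_time(st, "clinmap"), max(act) - min(act))
  expect_equal(total_activation_time(st, "clinmapprct", q = 2.5),
               oracle_percentile(act, 97.5) - oracle_percentile(act, 2.5))
  ## interpolated-map TAT is computed on demand and is a sane range
  tat_om <- total_activation_time(st, "openepmap")
  expect_gt(tat_om, 0)
  expect_lte(total_activation_time(st, "openepmapprct"), tat_om)
})

test_that("earliest site is recovered on focal fixtures", {
  mesh <- make_chamber_mesh(chamber_spec(seed = 4))
  src_v <- 200L
  st <- make_study_fixture(
    n_points = 200, seed = 4,
    wave = wave_spec("focal", speed = 1, source_vertex = src_v))
  truth <- attr(st, "truth")$activation
  ## ptbased: exactly the sampled point nearest (in LAT) to the source
  es <- earliest_activation_site(st, "ptbased")
  samp <- attr(st, "truth")$sample_vertices
  lat_s <- attr(st, "truth")$point_lat
  expect_equal(es$position,
               st$surface$vertices[samp[which.min(lat_s)], ])
  ## percentile-cohort site lands within 2 mean edge lengths of the source
  mel <- mean(sqrt(rowSums((st$surface$vertices[st$surface$triangles[, 1], ] -
                            st$surface$vertices[st$surface$triangles[, 2], ])^2)))
  es2 <- earliest_activation_site(st, "ptbasedprct", q = 2.5)
  d <- sqrt(sum((es2$position - truth$earliest_position)^2))
  expect_lt(d, 2 * mel)
  ## the percentile site sits on the surface
  ps <- eamtools:::point_surface_distance(st$surface,
                                          matrix(es2$position, 1, 3))
  expect_lt(ps$distance, 1e-6)
})

test_that("all-equal LATs break ties by lowest index without error", {
  st <- study_with_lats(rep(25, 8))
  es <- earliest_activation_site(st, "ptbased")
  expect_equal(es$position, st$electric$egm_surf_x[1, ])
  expect_equal(es$lat, 25)
})
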