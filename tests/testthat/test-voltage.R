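## fixture with one 0.2 mV patch in a 3 mV background
fx_patch <- function() fx("patch", function()
  make_study_fixture(
    n_points = 120, seed = 41,
    patches = list(list(center_vertex = 77L, radius = 9, level = 0.2)),
    background = 3))

test_that("mean voltage matches an independent triangle-loop oracle", {
  st <- fx_patch()
  f <- clinical_field(st$surface, "bip")
  want <- oracle_mean_voltage(st$surface, f$values, f$valid)
  expect_equal(mean_voltage(st, "map"), want, tolerance = 1e-9)
  ## uniform field gives exactly the constant
  stu <- make_study_fixture(n_points = 20, seed = 8, background = 1)
  expect_equal(mean_voltage(stu, "map"), 1.0, tolerance = 1e-12)
  expect_equal(mean_voltage(stu, "egm", fill_threshold = Inf), 1.0,
               tolerance = 1e-6)
  ## masking out above-mean vertices strictly lowers the mean
  f2 <- clinical_field(st$surface, "bip")
  mu <- mean_voltage(st, "map")
  st2 <- st
  st2$surface$fields$bip[f2$values > mu] <- NaN
  expect_lt(mean_voltage(st2, "map"), mu)
})

test_that("low-voltage area recovers the constructed patch exactly", {
  st <- fx_patch()
  truth <- attr(st, "truth")$voltage
  r <- low_voltage_area(st, "map", v_thr = 0.5)
  ## implementation (polygon clipping) vs independent closed-form oracle
  expect_equal(r$low_area_cm2, truth$area_below_threshold_cm2,
               tolerance = 1e-6)
  expect_gt(r$low_area_cm2, 0)
  expect_equal(r$total_area_cm2, get_area(st, "nofill"), tolerance = 1e-9)
  expect_equal(r$fraction_low_pct, 100 * r$low_area_cm2 / r$total_area_cm2)
  ## in the limit threshold -> level+ the clipped area equals the area of
  ## triangles fully inside the patch
  r2 <- low_voltage_area(st, "map", v_thr = 0.2 + 1e-9)
  expect_equal(r2$low_area_cm2, truth$area_full_triangles_cm2,
               tolerance = 1e-6)
})

test_that("low-voltage area saturates, and is monotone and continuous in the threshold", {
  stu <- make_study_fixture(n_points = 20, seed = 8, background = 1)
  expect_equal(low_voltage_area(stu, "map", v_thr = 0.5)$low_area_cm2, 0)
  lo <- make_study_fixture(n_points = 20, seed = 8, background = 0.2)
  r <- low_voltage_area(lo, "map", v_thr = 0.5)
  expect_equal(r$low_area_cm2, r$total_area_cm2, tolerance = 1e-12)
  st <- fx_patch()
  thr <- seq(0.1, 3.2, by = 0.1)
  areas <- vapply(thr, function(t)
    low_voltage_area(st, "map", v_thr = t)$low_area_cm2, 1)
  expect_true(all(diff(areas) >= 0))
  ## continuity: small threshold steps move the area only slightly
  a1 <- low_voltage_area(st, "map", v_thr = 0.5)$low_area_cm2
  a2 <- low_voltage_area(st, "map", v_thr = 0.5 + 1e-6)$low_area_cm2
  expect_lt(abs(a2 - a1), 1e-3)
  ## extremes
  expect_equal(areas[length(areas)],
               low_voltage_area(st, "map", v_thr = 10)$low_area_cm2)
})

test_that("voltage histogram bins sum to the total area and split a two-valued field", {
  st <- fx_patch()
  h <- voltage_histogram(st, "map", bin_edges = seq(0, 5, by = 0.5))
  expect_equal(sum(h$histogram$area_cm2), h$total_area_cm2, tolerance = 1e-9)
  ## a two-valued field (0.2 / 3.0) has mass only in bins touching those
  ## values or the transition between them
  nz <- h$histogram[h$histogram$area_cm2 > 1e-9, ]
  expect_true(all(nz$bin_hi > 0.2 & nz$bin_lo <= 3.0))
  ## the bins strictly between the levels carry only rim-transition area
  mid <- h$histogram$bin_lo >= 1 & h$histogram$bin_hi <= 2
  expect_lt(sum(h$histogram$area_cm2[mid]), 0.2 * h$total_area_cm2)
  ## consistency with low_voltage_area through the shared threshold
  r05 <- low_voltage_area(st, "map", v_thr = 0.5)
  h05 <- voltage_histogram(st, "map", bin_edges = c(0, 0.5, 6))
  expect_equal(h05$histogram$area_cm2[1], r05$low_area_cm2, tolerance = 1e-9)
  expect_error(voltage_histogram(st, "map", bin_edges = c(1, 0.5)),
               class = "eam_argument_error")
})

test_that("map and egm methods agree exactly on constant fields", {
  stu <- make_study_fixture(n_points = 40, seed = 14, background = 1.5)
  expect_equal(mean_voltage(stu, "map"),
               mean_voltage(stu, "egm", fill_threshold = Inf),
               tolerance = 1e-6)
})
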