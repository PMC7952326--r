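test_that("a planar wave at 1 m/s is recovered in speed and direction", {
  st <- fx_study200()
  cv <- compute_conduction_velocity(st)
  mesh <- st$surface
  clearance <- boundary_clearance(mesh)
  interior <- clearance >= 10 & cv$valid
  expect_gt(sum(interior), 100)
  expect_equal(median(cv$speed[interior]), 1.0, tolerance = 0.05)
  tdir <- attr(st, "truth")$activation$wave$direction
  m <- colMeans(cv$direction[interior, , drop = FALSE])
  m <- m / sqrt(sum(m^2))
  expect_lt(acos(sum(m * tdir)) * 180 / pi, 10)
  ## directions are tangent to the surface
  vn <- eamtools:::vertex_normals(mesh)
  dots <- abs(rowSums(cv$direction[interior, ] * vn[interior, ]))
  expect_lt(max(dots), 1e-3)
  ## valid speeds respect the clamp
  expect_true(all(cv$speed[cv$valid] >= cv$clamp[1] &
                  cv$speed[cv$valid] <= cv$clamp[2]))
})

test_that("doubling all LATs halves every speed exactly", {
  st <- fx_study200()
  cv <- compute_conduction_velocity(st)
  el <- st$electric
  el$map_annot <- el$ref_annot + 2 * (el$map_annot - el$ref_annot)
  el$woi <- el$woi * 2
  st2 <- st; st2$electric <- el
  cv2 <- compute_conduction_velocity(st2)
  i <- cv$valid & !cv$clamped & cv2$valid & !cv2$clamped
  expect_equal(cv2$speed[i], cv$speed[i] / 2, tolerance = 1e-9)
})

test_that("speed is invariant to a constant LAT shift", {
  st <- fx_study200()
  cv <- compute_conduction_velocity(st)
  el <- st$electric
  el$map_annot <- el$map_annot + 40
  el$woi[, 2] <- el$woi[, 2] + 41
  st2 <- st; st2$electric <- el
  cv2 <- compute_conduction_velocity(st2)
  expect_equal(cv2$speed[cv$valid], cv$speed[cv$valid], tolerance = 1e-9)
})

test_that("constant LAT gives an all-invalid plateau, not infinities", {
  st <- fx_study200()
  el <- st$electric
  el$map_annot <- el$ref_annot + 10
  st2 <- st; st2$electric <- el
  cv <- compute_conduction_velocity(st2)
  expect_equal(sum(cv$valid), 0)
  expect_true(all(!is.finite(cv$speed) | cv$speed <= cv$clamp[2]))
})

test_that("rigid rotation rotates directions and preserves speeds", {
  st <- fx_study200()
  cv <- compute_conduction_velocity(st)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st2 <- st
  st2$surface$vertices <- st$surface$vertices %*% t(R)
  el <- st$electric
  el$egm_x <- el$egm_x %*% t(R)
  el$egm_surf_x <- el$egm_surf_x %*% t(R)
  st2$electric <- el
  cv2 <- compute_conduction_velocity(st2)
  i <- cv$valid & cv2$valid & !cv$clamped & !cv2$clamped
  expect_lt(max(abs(cv2$speed[i] - cv$speed[i]) / cv$speed[i]), 0.01)
  ## direction comparison restricted to vertices where the wave actually
  ## runs along the surface: where the gradient is near-normal the
  ## tangential direction is undefined and numerically unstable
  g <- eamtools:::rbf_grad(cv$model, st$surface$vertices)
  vn <- eamtools:::vertex_normals(st$surface)
  gt <- g - vn * rowSums(g * vn)
  frac <- sqrt(rowSums(gt^2)) / sqrt(rowSums(g^2))
  j <- i & frac > 0.3
  dots <- rowSums((cv$direction[j, , drop = FALSE] %*% t(R)) *
                  cv2$direction[j, , drop = FALSE])
  expect_gt(min(dots), 0.999)
})

test_that("planar-wave speed error shrinks with sample count", {
  err <- vapply(c(50, 200), function(n) {
    st <- make_study_fixture(n_points = n, seed = 61)
    cv <- compute_conduction_velocity(st)
    interior <- boundary_clearance(st$surface) >= 10 & cv$valid
    abs(median(cv$speed[interior]) - 1)
  }, 1)
  expect_lte(err[2], err[1])
})

test_that("cv histogram conserves valid area and brackets the truth", {
  st <- fx_study200()
  cv <- compute_conduction_velocity(st)
  h <- cv_histogram(cv, st)
  expect_s3_class(h$histogram, "tbl_df")
  ## default display range 0-2 m/s
  expect_equal(range(c(h$histogram$bin_lo, h$histogram$bin_hi)), c(0, 2))
  expect_equal(sum(h$histogram$area_cm2), h$total_area_cm2, tolerance = 1e-9)
  ## the area-weighted median bin contains the true speed 1.0
  med_bin <- h$histogram[h$histogram$bin_lo <= h$median_speed &
                         h$histogram$bin_hi >= h$median_speed, ]
  expect_true(any(med_bin$bin_lo <= 1 & med_bin$bin_hi >= 1))
  ## guards
  expect_error(cv_histogram(cv, fx_sphere(3)), class = "eam_consistency_error")
  expect_error(compute_conduction_velocity(st, interp_spec("idw")),
               class = "eam_argument_error")
})
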