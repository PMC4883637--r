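test_that("gamma variate limits, zeros and closed-form integral", {
  # alpha = 0: pure exponential from t0
  t <- seq(0, 30, by = 0.5)
  g0 <- gamma_variate(t, t0 = 5, alpha = 0, beta = 4, scale = 7)
  expect_equal(g0[t > 5], 7 * exp(-(t[t > 5] - 5) / 4))
  expect_equal(g0[t <= 5], rep(0, sum(t <= 5)))
  # value at t0 is 0 for alpha > 0
  expect_equal(gamma_variate(5, 5, 3, 2.5), 0)
  expect_error(gamma_variate(1, 0, 3, -1), "beta")

  # integral against numeric quadrature
  f <- function(t) gamma_variate(t, 2, 3.2, 2.1, scale = 11)
  num <- stats::integrate(f, 2, Inf, rel.tol = 1e-10)$value
  expect_equal(gamma_variate_auc(3.2, 2.1, 11), num, tolerance = 1e-8)
})

test_that("gamma variate peaks at t0 + alpha*beta", {
  tg <- seq(0, 60, by = 1e-3)
  for (p in list(c(3, 2.5), c(2, 4), c(5, 1.5))) {
    v <- gamma_variate(tg, 8, p[1], p[2])
    expect_equal(tg[which.max(v)], 8 + p[1] * p[2], tolerance = 2e-3)
  }
})

test_that("blood TACs integrate to the indicator-dilution target", {
  cfg <- phantom_config(fsv_true = 80, heart_rate = 60, dose = 4e8,
                        recirculation_fraction = 0)
  bt <- make_blood_tacs(cfg)
  target <- 4e8 / (80 * 60 / 60)
  expect_equal(bt$first_pass_auc, target)
  # closed-form identity: Eq on the ideal continuous curve returns truth
  expect_equal(compute_fsv(cfg$dose, bt$first_pass_auc, cfg$heart_rate), 80,
               tolerance = 1e-12)
  # numeric quadrature of the recirculation-free arterial curve
  num <- stats::integrate(bt$arterial, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(num, target, tolerance = 1e-8)

  # venous and arterial first passes share the integral (mass conservation)
  nv <- stats::integrate(bt$venous_first_pass, 0, Inf, rel.tol = 1e-10)$value
  na <- stats::integrate(bt$arterial_first_pass, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(nv, na, tolerance = 1e-10)
})

test_that("recirculation multiplies the total integral by sum(frac^k)", {
  cfg <- phantom_config(recirculation_fraction = 0.3, n_recirculation_passes = 3)
  bt <- make_blood_tacs(cfg)
  num <- stats::integrate(bt$arterial, 0, Inf, rel.tol = 1e-10,
                          subdivisions = 400L)$value
  expect_equal(num / bt$first_pass_auc, sum(0.3^(0:3)), tolerance = 1e-6)
  expect_equal(bt$total_auc_factor, sum(0.3^(0:3)))
})

test_that("frame truncation of the first-pass TAC is below 2% for the acetate scheme", {
  cfg <- phantom_config(recirculation_fraction = 0)
  bt <- make_blood_tacs(cfg)
  tc <- frame_average_tac(bt$arterial, cfg$schedule)
  frame_sum <- sum(cfg$schedule$frame_duration * tc$value)
  expect_lt(abs(frame_sum - bt$first_pass_auc) / bt$first_pass_auc, 0.02)
})

test_that("compartment voxels carry the frame-averaged ideal TACs", {
  sim <- simulate_dynamic_series(small_phantom_config())
  tr <- sim$truth
  art <- extract_cluster_tac(sim$series, tr$arterial_mask)
  expect_equal(art$value, tr$arterial_tac$value, tolerance = 1e-9)
  ven <- extract_cluster_tac(sim$series, tr$venous_mask)
  expect_equal(ven$value, tr$venous_tac$value, tolerance = 1e-9)
  expect_equal(tr$first_pass_auc_true,
               tr$config$dose / (tr$fsv_true * tr$config$heart_rate / 60))
  # compartments are disjoint
  expect_false(any(tr$arterial_mask & tr$venous_mask))
  expect_false(any(tr$arterial_mask & tr$myocardial_mask))
})

test_that("Gaussian blur conserves per-frame total activity", {
  sim <- simulate_dynamic_series(small_phantom_config(psf_fwhm_mm = 8))
  sim0 <- simulate_dynamic_series(small_phantom_config())
  for (j in c(1, 5, 15, 29)) {
    tot_b <- sum(sim$series$voxels[, , , j])
    tot_0 <- sum(sim0$series$voxels[, , , j])
    if (tot_0 > 0)
      expect_equal(tot_b, tot_0, tolerance = 1e-6)
  }
})

test_that("identical seeds give bit-identical series; different seeds differ", {
  c1 <- two_pop_config(noise = 0.1, seed = 42)
  s1 <- simulate_dynamic_series(c1)
  s2 <- simulate_dynamic_series(c1)
  expect_identical(s1$series$voxels, s2$series$voxels)
  s3 <- simulate_dynamic_series(two_pop_config(noise = 0.1, seed = 43))
  expect_false(identical(s1$series$voxels, s3$series$voxels))
})

test_that("overlapping compartments are rejected and config is validated", {
  geom <- list(arterial = list(center_frac = c(0.5, 0.5), radius_mm = 15,
                               z_margin_frac = 0.15),
               venous = list(center_frac = c(0.52, 0.5), radius_mm = 15,
                             z_margin_frac = 0.15),
               myocardium = NULL)
  cfg <- phantom_config(grid_shape = c(32, 32, 16), geometry = geom)
  expect_error(simulate_dynamic_series(cfg), "overlap")
  expect_error(phantom_config(fsv_true = -1), "> 0")
  expect_error(phantom_config(recirculation_fraction = 1), "recirculation_fraction")
})

test_that("myocardial TAC rises slowly and peaks late", {
  sim <- simulate_dynamic_series(small_phantom_config())
  myo <- extract_cluster_tac(sim$series, sim$truth$myocardial_mask)
  art <- sim$truth$arterial_tac
  expect_gt(myo$mid_time[which.max(myo$value)], art$mid_time[which.max(art$value)])
  expect_lt(max(myo$value), max(art$value))
})
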