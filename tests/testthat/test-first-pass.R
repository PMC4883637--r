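test_that("downslopes match hand arithmetic on the worked TAC", {
  ds <- frame_downslopes(worked_tac())
  expect_equal(ds$downslope, c(8.0, 4.0, 1.2, 0.8))
  expect_equal(ds$t1_index, 2:5)
  expect_equal(ds$t2_index, 3:6)
})

test_that("degenerate descending limbs are rejected", {
  sch <- frame_schedule(seq(0, 25, by = 5), rep(5, 6))
  rising <- tac(frame_mid(sch), 1:6, sch)
  expect_error(frame_downslopes(rising), "last frame")
  flat_desc <- tac(frame_mid(sch), c(1, 5, 5, 5, 5, 5), sch)
  # peak found at first maximal frame; all downslopes zero -> isolation fails
  expect_error(isolate_first_pass(flat_desc), "no positive downslope")
  expect_error(frame_downslopes(tac(c(1, 2), c(2, 1))), "3 frames")
})

test_that("worked example isolates anchors, lambda and midpoint AUC", {
  cfg <- first_pass_config(exp_frame_value_convention = "midpoint")
  fp <- isolate_first_pass(worked_tac(), cfg)
  expect_equal(fp$t1_index, 2L)  # mid-time 10 s
  expect_equal(fp$t2_index, 3L)  # mid-time 15 s
  expect_equal(fp$decay_rate, log(5 / 3) / 5, tolerance = 1e-12)
  expect_equal(fp$composite_values, c(0, 100, 60, 36, 21.6, 12.96))
  expect_equal(fp$auc, 1152.8)
  expect_equal(fp$extrapolated, c(rep(FALSE, 3), rep(TRUE, 3)))
})

test_that("analytic-mean convention agrees with a fine-grid trapezoid oracle", {
  tc <- worked_tac()
  fp_mid <- isolate_first_pass(tc, first_pass_config(exp_frame_value_convention = "midpoint"))
  fp_am <- isolate_first_pass(tc, first_pass_config())
  expect_lt(abs(fp_am$auc - fp_mid$auc) / fp_mid$auc, 0.02)

  # oracle: trapezoid at 0.01 s over the piecewise composite
  lam <- fp_am$decay_rate
  m2 <- tc$mid_time[fp_am$t2_index]
  v2 <- fp_am$anchor_value
  oracle_frame <- function(j) {
    a <- tc$schedule$frame_start[j]; b <- frame_end(tc$schedule)[j]
    ts <- seq(a, b, by = 0.01)
    vals <- v2 * exp(-lam * (ts - m2))
    mean_val <- (sum(vals) - (vals[1] + vals[length(vals)]) / 2) / (length(ts) - 1)
    mean_val
  }
  for (j in (fp_am$t2_index + 1):6)
    expect_equal(fp_am$composite_values[j], oracle_frame(j), tolerance = 1e-6)
})

test_that("threshold fraction 1 forces the maximum-downslope pair", {
  fp <- isolate_first_pass(worked_tac(),
                           first_pass_config(downslope_threshold_fraction = 1))
  expect_equal(c(fp$t1_index, fp$t2_index), c(2L, 3L))
})

test_that("an exactly exponential tail is reproduced by the extrapolation", {
  sch <- frame_schedule(seq(0, 55, by = 5), rep(5, 12))
  mid <- frame_mid(sch)
  lam <- 0.2
  v <- c(5, 100, 100 * exp(-lam * (mid[3:12] - mid[2])))
  tc <- tac(mid, v, sch)
  fp <- isolate_first_pass(tc, first_pass_config(exp_frame_value_convention = "midpoint"))
  expect_equal(fp$composite_values, v, tolerance = 1e-10)
  expect_equal(fp$decay_rate, lam, tolerance = 1e-10)
})

test_that("composite invariants hold on phantom blood curves", {
  for (rc in c(0, 0.3)) {
    cfg <- phantom_config(recirculation_fraction = rc)
    bt <- make_blood_tacs(cfg)
    tc <- frame_average_tac(bt$arterial, cfg$schedule)
    fp <- isolate_first_pass(tc)
    n <- length(tc$value)
    expect_equal(fp$t2_index, fp$t1_index + 1L)
    expect_gte(fp$t1_index, which.max(tc$value))
    expect_gt(fp$decay_rate, 0)
    expect_equal(fp$composite_values[1:fp$t2_index], tc$value[1:fp$t2_index])
    expect_true(all(diff(fp$composite_values[fp$t2_index:n]) <= 1e-12))
    # with recirculating tracer in the tail, cutting it can only shrink the
    # AUC (at rc = 0 the exponential slightly *over*estimates the
    # gamma-variate tail, so the inequality does not apply there; see the
    # methods vignette)
    if (rc > 0)
      expect_lte(fp$auc, sum(cfg$schedule$frame_duration * tc$value))
  }
})

test_that("isolated AUC is homogeneous of degree 1 in the TAC", {
  tc <- worked_tac()
  scaled <- tac(tc$mid_time, 3.7 * tc$value, tc$schedule)
  expect_equal(isolate_first_pass(scaled)$auc, 3.7 * isolate_first_pass(tc)$auc,
               tolerance = 1e-12)
})

test_that("isolation removes recirculation; raw integration does not", {
  # arterial curve; spec property: within 10% of the first-pass-only AUC for
  # recirculation up to 0.35
  for (rc in c(0.2, 0.35)) {
    cfg <- phantom_config(recirculation_fraction = rc)
    bt <- make_blood_tacs(cfg)
    tc <- frame_average_tac(bt$arterial, cfg$schedule)
    fp <- isolate_first_pass(tc)
    expect_lt(abs(fp$auc - bt$first_pass_auc) / bt$first_pass_auc, 0.10)
    raw <- sum(cfg$schedule$frame_duration * tc$value)
    expect_gt((raw - bt$first_pass_auc) / bt$first_pass_auc,
              rc - 0.05)  # raw AUC inflated by roughly sum(rc^k) - 1
  }
})

test_that("extend_beyond_scan adds the closed-form exponential tail", {
  tc <- worked_tac()
  fp0 <- isolate_first_pass(tc, first_pass_config(exp_frame_value_convention = "midpoint"))
  fp1 <- isolate_first_pass(tc, first_pass_config(exp_frame_value_convention = "midpoint",
                                                  extend_beyond_scan = TRUE))
  lam <- fp0$decay_rate
  v_end <- fp0$anchor_value * exp(-lam * (32.5 - 15))
  expect_equal(fp1$auc - fp0$auc, v_end / lam, tolerance = 1e-10)
})

test_that("composite curves export with an extrapolated flag", {
  fp <- isolate_first_pass(worked_tac())
  p <- tempfile(fileext = ".csv")
  write_first_pass(fp, p)
  df <- utils::read.csv(p)
  expect_true(all(c("frame_mid_s", "activity_Bq_per_mL", "extrapolated") %in% names(df)))
  expect_equal(sum(df$extrapolated), 3L)
})
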