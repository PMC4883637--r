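test_that("erosion follows 6-connected morphology", {
  cube3 <- array(TRUE, c(3, 3, 3))
  e1 <- erode_mask(cube3, 1)
  expect_equal(sum(e1), 1L)
  expect_true(e1[2, 2, 2])

  cube5 <- array(FALSE, c(7, 7, 7))
  cube5[2:6, 2:6, 2:6] <- TRUE
  e5 <- erode_mask(cube5, 1)
  expect_equal(sum(e5), 27L)            # solid 3x3x3 core
  expect_true(all(which(e5) %in% which(cube5)))

  expect_equal(erode_mask(cube5, 0), cube5)  # identity
  expect_equal(sum(erode_mask(cube5, 3)), 0L)  # vanishing permitted
})

test_that("eroded mask cardinality is non-increasing in iterations", {
  set.seed(42)
  m <- array(runif(16 * 16 * 8) > 0.35, c(16, 16, 8))
  sizes <- vapply(0:4, function(k) sum(erode_mask(m, k)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # each erosion result is a subset of the previous
  e1 <- erode_mask(m, 1); e2 <- erode_mask(m, 2)
  expect_true(all(!(e2 & !e1)))
})

test_that("extract_cluster_tac averages voxels per frame", {
  sch <- frame_schedule(seq(0, 35, by = 5), rep(5, 8))
  vox <- array(0, c(4, 4, 2, 8))
  v <- seq(100, 800, by = 100)
  vox[1, 1, 1, ] <- v
  vox[2, 1, 1, ] <- 3 * v
  ser <- dynamic_series(vox, c(3, 3, 3), sch)

  m1 <- array(FALSE, c(4, 4, 2)); m1[1, 1, 1] <- TRUE
  expect_equal(extract_cluster_tac(ser, m1)$value, v)

  m2 <- m1; m2[2, 1, 1] <- TRUE
  expect_equal(extract_cluster_tac(ser, m2)$value, 2 * v)

  expect_error(extract_cluster_tac(ser, array(FALSE, c(4, 4, 2))), "empty mask")
})

test_that("noiseless separable phantom is recovered exactly", {
  sim <- simulate_dynamic_series(two_pop_config())
  cc <- cluster_config(n_clusters = 2, seed = 1)
  labs <- suppressWarnings(cluster_voxel_tacs(sim$series, cc))
  ids <- setdiff(unique(as.vector(labs)), 0L)
  expect_length(ids, 2L)
  d <- vapply(ids, function(i)
    max(dice(labs == i, sim$truth$arterial_mask),
        dice(labs == i, sim$truth$venous_mask)), numeric(1))
  expect_equal(d, c(1, 1))

  # cluster-mean TAC of the arterial cluster equals the generating TAC
  art_id <- ids[[which.max(vapply(ids, function(i)
    dice(labs == i, sim$truth$arterial_mask), numeric(1)))]]
  ct <- extract_cluster_tac(sim$series, labs == art_id)
  expect_equal(ct$value, sim$truth$arterial_tac$value, tolerance = 1e-6)
})

test_that("clustering is deterministic given the seed and rejects degenerate input", {
  sim <- simulate_dynamic_series(two_pop_config(noise = 0.1, seed = 5))
  cc <- cluster_config(n_clusters = 2, seed = 99)
  l1 <- cluster_voxel_tacs(sim$series, cc)
  l2 <- cluster_voxel_tacs(sim$series, cc)
  expect_identical(l1, l2)

  sch <- frame_schedule(seq(0, 35, by = 5), rep(5, 8))
  flat <- dynamic_series(array(7, c(6, 6, 4, 8)), c(3, 3, 3), sch)
  expect_error(cluster_voxel_tacs(flat, cc), "constant")
  short <- dynamic_series(array(rnorm(6 * 6 * 4 * 5), c(6, 6, 4, 5)),
                          c(3, 3, 3),
                          frame_schedule(seq(0, 20, by = 5), rep(5, 5)))
  expect_error(cluster_voxel_tacs(short, cc), "8 frames")
})

test_that("auto selection orders pools by peak time; manual is checked verbatim", {
  sim <- simulate_dynamic_series(two_pop_config())
  labs <- suppressWarnings(cluster_voxel_tacs(sim$series, cluster_config(n_clusters = 2)))
  sel <- select_blood_clusters(labs, sim$series, "auto")
  expect_gt(dice(labs == sel$venous_id, sim$truth$venous_mask), 0.99)
  expect_gt(dice(labs == sel$arterial_id, sim$truth$arterial_mask), 0.99)
  # venous (peak 10 s) peaks before arterial (peak 18 s)
  smry <- cluster_summary(labs, sim$series)
  expect_lt(smry$peak_time_s[smry$cluster_id == sel$venous_id],
            smry$peak_time_s[smry$cluster_id == sel$arterial_id])

  sel2 <- select_blood_clusters(labs, sim$series, "manual",
                                manual_ids = c(sel$venous_id, sel$arterial_id))
  expect_equal(sel2$arterial_id, sel$venous_id)  # returned verbatim
  expect_error(select_blood_clusters(labs, sim$series, "manual",
                                     manual_ids = c(1, 1)), "differ")
  expect_error(select_blood_clusters(labs, sim$series, "manual",
                                     manual_ids = c(98, 99)), "not present")
})

test_that("segmentation erodes selected clusters into subsets", {
  sim <- simulate_dynamic_series(two_pop_config())
  seg <- suppressWarnings(
    segment_blood_pools(sim$series, cluster_config(n_clusters = 2, erosion_iterations = 1)))
  expect_true(all(!(seg$eroded_arterial_mask & !(seg$labels == seg$arterial_id))))
  expect_true(all(!(seg$eroded_venous_mask & !(seg$labels == seg$venous_id))))
  expect_lt(sum(seg$eroded_arterial_mask), sum(seg$labels == seg$arterial_id))
  expect_setequal(seg$summary$role, c("arterial", "venous"))
})
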