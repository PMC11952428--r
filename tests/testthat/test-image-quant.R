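test_that("the 3D median filter preserves constants and rejects impulses", {
  v <- array(5, c(9, 9, 5))
  expect_equal(median_filter_3d(v), v)
  imp <- array(0, c(9, 9, 5)); imp[5, 5, 3] <- 100
  expect_equal(median_filter_3d(imp), array(0, c(9, 9, 5)))
  expect_error(median_filter_3d(array(0, c(5, 5, 2))), "kernel larger")
  expect_error(median_filter_3d(v, kernel = c(4L, 7L, 3L)), "odd")
})

test_that("the median filter equals the nested-loop oracle on a random volume", {
  set.seed(11)
  v <- array(runif(11 * 11 * 7), c(11, 11, 7))
  expect_equal(median_filter_3d(v), oracle_median_3d(v))
})

ellipsoid <- function(dims, ctr, radii) {
  yy <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  xx <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  zz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  array(((yy - ctr[1]) / radii[1])^2 + ((xx - ctr[2]) / radii[2])^2 +
          ((zz - ctr[3]) / radii[3])^2 <= 1, dims)
}

test_that("segmentation recovers bright ellipsoids and applies the size filter", {
  dims <- c(48L, 48L, 26L)
  B <- ellipsoid(dims, c(24, 24, 13), c(18, 16, 10))
  v <- array(0, dims); v[B] <- 100
  set.seed(12)
  v <- v + rnorm(length(v), 0, 5)
  lab <- segment_chromosomes(median_filter_3d(v), min_size = 50L)
  expect_equal(max(lab), 1L)
  expect_gt(sum(lab[B] == 1L) / sum(B), 0.95)

  two <- array(0, c(50L, 50L, 16L))
  two[ellipsoid(c(50L, 50L, 16L), c(14, 14, 8), c(6, 6, 3))] <- 100
  two[ellipsoid(c(50L, 50L, 16L), c(36, 36, 8), c(6, 6, 3))] <- 100
  lab2 <- segment_chromosomes(median_filter_3d(two), min_size = 50L)
  expect_equal(max(lab2), 2L)
  expect_warning(lab0 <- segment_chromosomes(median_filter_3d(two),
                                             min_size = 10000L),
                 "no component")
  expect_equal(max(lab0), 0L)
})

test_that("the shell is a border-clipped dilation rind, disjoint from the mask", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  sh <- shell_mask(m, 2L)
  # radius-2 ball has 33 voxels; minus the center leaves 32
  expect_equal(sum(sh), 32L)
  expect_false(any(sh & m))
  # mask touching the border: shell clipped but still disjoint
  mb <- array(FALSE, c(5, 5, 5)); mb[1, 1, 1] <- TRUE
  shb <- shell_mask(mb, 2L)
  expect_false(any(shb & mb))
  expect_lt(sum(shb), 32L)
  expect_error(shell_mask(array(TRUE, c(3, 3, 3))), "shell is empty")
})

test_that("shell volume of a large cube tracks surface area times thickness", {
  dims <- c(46L, 46L, 46L)
  m <- array(FALSE, dims)
  m[4:43, 4:43, 4:43] <- TRUE  # 40^3 cube
  sh <- shell_mask(m, 2L)
  expect_lt(abs(sum(sh) / (6 * 40^2 * 2) - 1), 0.15)
})

test_that("cell measurement is a ratio of means, scale-invariant", {
  m <- array(FALSE, c(9, 9, 9)); m[4:6, 4:6, 4:6] <- TRUE
  sh <- shell_mask(m, 2L)
  v <- array(5, c(9, 9, 9)); v[m] <- 10
  meas <- measure_cell(v, m, sh)
  expect_equal(meas$ratio, 2)
  expect_equal(measure_cell(array(3, c(9, 9, 9)), m, sh)$ratio, 1)
  expect_equal(measure_cell(v * 7.3, m, sh)$ratio, 2)
  expect_error(measure_cell(array(0, c(9, 9, 9)), m, sh), "shell mean is zero")
})

test_that("noiseless phantoms are recovered exactly through the full pipeline", {
  groups <- data.frame(group = "g", true_ratio = 3, cytoplasm_level = 50,
                       noise_sd = 0, n_cells = 2L)
  cells <- simulate_cells(groups, dims = c(40L, 40L, 16L), seed = 5L)
  meas <- quantify_cohort(cells, min_size = 50L)
  expect_equal(meas$ratio, rep(3, 2), tolerance = 1e-12)
})

test_that("noisy phantom cohorts recover ratios and rank groups correctly", {
  groups <- data.frame(group = c("hi", "mid", "low", "ctl"),
                       true_ratio = c(3, 2, 1.2, 1), cytoplasm_level = 50,
                       noise_sd = 0.1, n_cells = 4L)
  cells <- simulate_cells(groups, dims = c(40L, 40L, 16L), seed = 6L)
  meas <- quantify_cohort(cells, min_size = 50L)
  means <- tapply(meas$ratio, meas$group, mean)[c("hi", "mid", "low", "ctl")]
  expect_true(all(diff(means) < 0))
  expect_lt(abs(means[["hi"]] / 3 - 1), 0.05)
  expect_lt(abs(means[["ctl"]] / 1 - 1), 0.05)
})

test_that("group comparison is a symmetric Welch t-test against the reference", {
  set.seed(7)
  meas <- data.frame(group = rep(c("a", "ref"), each = 6L),
                     ratio = c(rnorm(6, 3, 0.1), rnorm(6, 1, 0.1)))
  res <- compare_groups(meas, "ref")
  expect_equal(res$group, "a")
  expect_lt(res$p_value, 1e-6)
  # identical groups: t ~ 0, p ~ 1
  same <- data.frame(group = rep(c("a", "ref"), each = 5L),
                     ratio = rep(c(1.5, 1.6, 1.4, 1.55, 1.45), 2L))
  res_same <- compare_groups(same, "ref")
  expect_equal(res_same$t, 0, tolerance = 1e-12)
  expect_equal(res_same$p_value, 1, tolerance = 1e-12)
  # swapping the roles negates t and preserves p
  sw <- meas; sw$group <- ifelse(sw$group == "a", "ref", "a")
  res_sw <- compare_groups(sw, "ref")
  expect_equal(res_sw$t, -res$t, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
})
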