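test_that("dummy discard trims exactly the leading volumes", {
  m <- state_matrix(matrix(seq_len(3 * 245), 3, 245))
  out <- discard_dummies(m, 5)
  expect_equal(ncol(out), 240)
  expect_equal(unclass(out)[, 1], unclass(m)[, 6], ignore_attr = TRUE)
  expect_equal(unclass(discard_dummies(m, 0)), unclass(m),
               ignore_attr = TRUE)
  short <- state_matrix(matrix(rnorm(10), 2, 5))
  expect_error(discard_dummies(short, 5), "timepoints")
  # 4-D arrays trim along the time axis
  arr <- array(rnorm(2 * 2 * 2 * 10), dim = c(2, 2, 2, 10))
  expect_equal(dim(discard_dummies(arr, 4))[4], 6)
})

test_that("framewise displacement matches its definition", {
  zero <- matrix(0, 10, 6)
  expect_equal(compute_fd(zero), rep(0, 9))
  step <- zero; step[5, 1] <- 1  # single 1 mm x-translation step
  fd <- compute_fd(step)
  expect_equal(fd[4], 1)
  expect_equal(fd[5], 1)  # moving back is also a 1 mm transition
  rot <- zero; rot[3, 5] <- 1    # 1 degree rotation -> arc on 50 mm sphere
  expect_equal(compute_fd(rot)[2], 50 * pi / 180)
  set.seed(1)
  rand <- matrix(rnorm(240 * 6), 240, 6)
  expect_equal(compute_fd(rand), oracle_fd(rand), tolerance = 1e-12)
  bad <- zero; bad[2, 2] <- NA
  expect_error(compute_fd(bad), "non-finite")
})

test_that("motion exclusion uses strict peak-parameter thresholds", {
  base <- matrix(0, 50, 6)
  at_thresh <- base; at_thresh[10, 2] <- 3.4375
  over_rot <- base; over_rot[20, 5] <- 3.5
  part <- exclude_by_motion(list(a = at_thresh, b = over_rot, c = base))
  expect_setequal(part$retained, c("a", "c"))
  expect_identical(part$excluded, "b")
  # invariant to subject order
  part2 <- exclude_by_motion(list(c = base, b = over_rot, a = at_thresh))
  expect_setequal(part2$retained, part$retained)
  expect_true(all(sort(c(part$retained, part$excluded)) == c("a", "b", "c")))
})

test_that("confound regression produces orthogonal residuals", {
  set.seed(4)
  m <- state_matrix(matrix(rnorm(50 * 240), 50, 240))
  conf <- matrix(rnorm(240 * 6), 240, 6)
  out <- regress_confounds(m, conf)
  # matches an explicit normal-equations solve per voxel
  for (i in c(1, 25, 50)) {
    expect_equal(unclass(out)[i, ], oracle_residuals(unclass(m)[i, ], conf),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # residuals orthogonal to every confound column
  cross <- abs(unclass(out) %*% scale(conf, scale = FALSE))
  expect_lt(max(cross) / max(abs(unclass(m))), 1e-8)
  # single constant column (collinear with the intercept, hence the
  # pseudo-inverse path) degenerates to demeaning
  expect_warning(regress_confounds(m, matrix(1, 240, 1)), "rank-deficient")
  dem <- suppressWarnings(regress_confounds(m, matrix(1, 240, 1)))
  expect_equal(unclass(dem), unclass(m) - rowMeans(unclass(m)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # a voxel equal to a confound is annihilated
  m2 <- unclass(m); m2[3, ] <- conf[, 2]
  out2 <- regress_confounds(state_matrix(m2), conf)
  expect_lt(max(abs(unclass(out2)[3, ])), 1e-8)
})

test_that("rank-deficient confounds fall back to a pseudo-inverse", {
  set.seed(5)
  m <- state_matrix(matrix(rnorm(10 * 60), 10, 60))
  conf <- cbind(rnorm(60), rnorm(60))
  conf <- cbind(conf, conf[, 1] + conf[, 2])  # exactly collinear
  expect_warning(out <- regress_confounds(m, conf), "rank-deficient")
  cross <- abs(unclass(out) %*% scale(conf, scale = FALSE))
  expect_lt(max(cross) / max(abs(unclass(m))), 1e-8)
})

test_that("detrending and the passband behave as specified", {
  tt <- seq_len(240) * 2
  ramp <- state_matrix(rbind(3 * seq_len(240), -2 * seq_len(240)),
                       tr_seconds = 2)
  out <- detrend_bandpass(ramp)
  expect_lt(max(abs(out)), 1e-6 * 3 * 240)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- detrend_bandpass(state_matrix(rbind(x), tr_seconds = 2))[1, ]
    mid <- 40:200
    fit <- lm(y[mid] ~ sin(2 * pi * f * tt[mid]) +
                cos(2 * pi * f * tt[mid]) - 1)
    sqrt(sum(coef(fit)^2))
  }
  expect_gt(gain_at(0.04), 0.9)
  expect_lt(gain_at(0.04), 1.1)
  expect_lt(gain_at(0.2), 0.2)
  expect_lt(gain_at(0.002), 0.2)
  expect_error(detrend_bandpass(ramp, high_hz = 0.3), "Nyquist")
  expect_error(detrend_bandpass(ramp, low_hz = 0.1, high_hz = 0.05), "below")
})

test_that("masking extracts voxels in ascending linear-index order", {
  dims <- c(4, 4, 3)
  arr <- array(rnorm(prod(dims) * 6), dim = c(dims, 6))
  idx <- c(40, 2, 17, 33)
  mk <- roi_mask(idx, dims, label = "toy")
  out <- apply_mask(arr, mk)
  expect_equal(nrow(out), 4)
  flat <- matrix(arr, prod(dims), 6)
  expect_equal(unclass(out), flat[sort(idx), ], ignore_attr = TRUE)
  # exhaustive mask returns every voxel
  all_mask <- roi_mask(seq_len(prod(dims)), dims)
  expect_equal(nrow(apply_mask(arr, all_mask)), prod(dims))
  # constant volumes give constant rows
  carr <- array(7, dim = c(dims, 5))
  expect_true(all(apply_mask(carr, mk) == 7))
  expect_error(apply_mask(arr, roi_mask(1, c(2, 2, 2))), "grid")
  expect_error(roi_mask(integer(0), dims), "empty")
  expect_error(roi_mask(c(1, 1), dims), "unique")
})

test_that("the conditioning stage preserves shape and is near-idempotent", {
  set.seed(6)
  m <- state_matrix(matrix(rnorm(30 * 245), 30, 245), tr_seconds = 2)
  motion <- simulate_motion(245, fd_scale = 0.1, seed = 1)
  out <- condition_series(m, motion = motion, n_dummy = 5)
  expect_equal(dim(unclass(out)), c(30, 240))
  expect_false(any(!is.finite(unclass(out))))
  prov <- attr(out, "provenance")
  expect_match(prov$stages[1], "discard")
  expect_match(prov$stages[2], "regress")
  expect_match(prov$stages[3], "bandpass")
  expect_false(is.na(attr(out, "fd_mean")))
  # a second pass over already-conditioned data changes little
  again <- condition_series(out, n_dummy = 0)
  keep <- 20:220  # away from filter edge transients
  expect_gt(cor(as.vector(unclass(out)[, keep]),
                as.vector(unclass(again)[, keep])), 0.95)
})
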