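test_that("grand z-normalisation matches its definition and is idempotent", {
  m <- state_matrix(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4))
  z <- znormalize_matrix(m)
  v <- unclass(z)
  expect_lt(abs(mean(v)), 1e-10)
  expect_equal(sd(as.vector(v)), 1, tolerance = 1e-10)
  # explicit elementwise check against hand arithmetic
  raw <- matrix(1:12, 3, 4)
  expect_equal(v, (raw - mean(raw)) / sd(as.vector(raw)),
               tolerance = 1e-12, ignore_attr = TRUE)
  z2 <- znormalize_matrix(z)
  expect_equal(unclass(z2), v, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(attr(z, "normalized"))
  expect_error(znormalize_matrix(state_matrix(matrix(5, 3, 4))),
               "degenerate")
  # per-voxel alternative normalises each row
  pv <- znormalize_matrix(m, per_voxel = TRUE)
  expect_equal(unname(apply(unclass(pv), 1, sd)), rep(1, 3))
})

test_that("state distances are Euclidean, symmetric and match brute force", {
  m1 <- znormalize_matrix(state_matrix(matrix(c(0, 1, 3), 1, 3)))
  d <- as.matrix(state_distances(m1))
  s <- sd(c(0, 1, 3))
  expect_equal(d[1, 2], 1 / s)
  expect_equal(d[2, 3], 2 / s)
  expect_equal(d[1, 3], 3 / s)
  set.seed(8)
  m <- znormalize_matrix(state_matrix(matrix(rnorm(50 * 20), 50, 20)))
  d2 <- as.matrix(state_distances(m))
  expect_equal(d2, oracle_pairwise_dist(unclass(m)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(diag(d2), rep(0, 20), ignore_attr = TRUE)
  # duplicated timepoints are at distance zero
  vals <- unclass(m); vals[, 7] <- vals[, 3]
  d3 <- as.matrix(state_distances(restate_test(vals, m)))
  expect_equal(d3[3, 7], 0)
  expect_error(state_distances(state_matrix(matrix(rnorm(6), 2, 3))),
               "normalis")
})

test_that("exactly embeddable configurations are recovered with ~zero stress", {
  d <- as.dist(matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3))
  e <- embed_states(d, k_candidates = 2, restarts = 4, seed = 5)
  expect_lt(e$stress, 1e-3)
  expect_equal(sort(as.vector(dist(e$points))), c(1, 2, 3), tolerance = 1e-3)
})

test_that("a planted 3-D cloud embeds at k <= 3 below the stress threshold", {
  set.seed(2)
  cloud <- matrix(rnorm(60 * 3), 60, 3)
  e <- embed_states(dist(cloud), seed = 3)
  expect_lte(e$k, 3)
  expect_lt(e$stress, 0.10)
})

test_that("embedding is bitwise deterministic for a fixed seed", {
  set.seed(10)
  d <- dist(matrix(rnorm(40 * 5), 40, 5))
  a <- embed_states(d, seed = 21, restarts = 3)
  b <- embed_states(d, seed = 21, restarts = 3)
  expect_identical(a, b)
})

test_that("velocities are consecutive Euclidean step lengths", {
  expect_equal(transition_velocities(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(transition_velocities(matrix(2, 6, 3)), rep(0, 5))
  set.seed(12)
  coords <- matrix(rnorm(240 * 3), 240, 3)
  v <- transition_velocities(coords)
  brute <- sapply(1:239, function(t) {
    sqrt(sum((coords[t + 1, ] - coords[t, ])^2))
  })
  expect_equal(v, brute, tolerance = 1e-12)
  expect_true(all(v >= 0))
})

test_that("velocities are invariant to rigid motions of the embedding", {
  set.seed(13)
  coords <- matrix(rnorm(50 * 3), 50, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved <- coords %*% rot + matrix(c(5, -2, 11), 50, 3, byrow = TRUE)
  expect_equal(transition_velocities(coords), transition_velocities(moved),
               tolerance = 1e-10)
})

test_that("the mean velocity summarises the transition series", {
  expect_equal(mean_transition_velocity(c(5, 5, 5)), 5)
  expect_equal(mean_transition_velocity(rep(0, 239), n = 240), 0)
  set.seed(14)
  v <- runif(239)
  expect_equal(mean_transition_velocity(v, n = 240), sum(v) / 239,
               tolerance = 1e-12)
  expect_error(mean_transition_velocity(numeric(0)), "empty")
  expect_error(mean_transition_velocity(v, n = 100), "expected")
})

test_that("ROI-mean z-series averages per-ROI z-scores", {
  set.seed(15)
  base <- rnorm(240)
  same16 <- matrix(rep(base, each = 16), 16, 240, byrow = FALSE)
  zb <- roi_mean_zseries(same16)
  expect_equal(zb, as.vector(scale(base)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two series that are exact negatives after z-scoring cancel out
  pair <- rbind(base, -base)
  expect_equal(roi_mean_zseries(pair), rep(0, 240), tolerance = 1e-12,
               ignore_attr = TRUE)
  # random input matches the explicit two-step computation
  r <- matrix(rnorm(16 * 240), 16, 240)
  manual <- colMeans(t(apply(r, 1, function(x) (x - mean(x)) / oracle_sd(x))))
  expect_equal(roi_mean_zseries(r), manual, tolerance = 1e-12)
  const <- r; const[4, ] <- 2
  expect_error(roi_mean_zseries(const), "ROI 4")
})

test_that("rMSSD and SD agree with closed forms and brute force", {
  expect_equal(rmssd(c(0, 1, 0, 1)), 1)
  expect_equal(rmssd(rep(3.5, 100)), 0)
  expect_equal(series_sd(c(-1, 1)), sqrt(2))
  set.seed(16)
  z <- rnorm(240)
  expect_equal(rmssd(z), oracle_rmssd(z), tolerance = 1e-12)
  expect_equal(series_sd(z), oracle_sd(z), tolerance = 1e-12)
  expect_error(rmssd(1), "timepoints")
  expect_error(series_sd(1), "timepoints")
})

test_that("permuting timepoints changes muV and rMSSD but never SD", {
  set.seed(17)
  m <- simulate_voxel_timeseries(0.7, 30, 60, snr = 4, seed = 55)
  perm <- sample(60)
  roi <- factor(rep(1:6, each = 5))
  a <- state_dynamics(m, roi_assignment = roi, k_candidates = 2,
                      restarts = 1, seed = 1, maxit = 50)
  b <- state_dynamics(restate_test(unclass(m)[, perm], m),
                      roi_assignment = roi, k_candidates = 2,
                      restarts = 1, seed = 1, maxit = 50)
  expect_false(isTRUE(all.equal(a$mu_v, b$mu_v)))
  expect_false(isTRUE(all.equal(a$rmssd, b$rmssd)))
  expect_equal(a$sd, b$sd, tolerance = 1e-12)
})

test_that("time-constant input yields all-zero dynamics metrics", {
  const <- state_matrix(matrix(rep(rnorm(20), 50), 20, 50))
  dm <- state_dynamics(const, roi_assignment = factor(rep(1:4, each = 5)))
  expect_equal(dm$mu_v, 0)
  expect_equal(dm$rmssd, 0)
  expect_equal(dm$sd, 0)
})

test_that("muV decreases monotonically in the generator's persistence", {
  # 20 paired replicates over rho in {0, 0.3, 0.6, 0.9}; every adjacent
  # pair must order correctly far more often than chance (sign test)
  rhos <- c(0, 0.3, 0.6, 0.9)
  n_rep <- 20
  muv <- matrix(NA_real_, n_rep, length(rhos))
  for (r in seq_len(n_rep)) {
    for (j in seq_along(rhos)) {
      m <- simulate_voxel_timeseries(rhos[j], 200, 240, snr = 2,
                                     seed = 3000 + r)
      muv[r, j] <- state_dynamics(m, k_candidates = 3, restarts = 1,
                                  seed = 3000 + r, maxit = 50)$mu_v
    }
  }
  decreasing <- muv[, -length(rhos)] > muv[, -1]
  for (j in 1:(length(rhos) - 1)) {
    bt <- binom.test(sum(decreasing[, j]), n_rep, p = 0.5,
                     alternative = "greater")
    expect_lt(bt$p.value, 0.01)
  }
})

test_that("rMSSD/SD tracks sqrt(2(1 - r1)) on AR(1) mean series", {
  set.seed(18)
  for (r1 in c(0.2, 0.6)) {
    ratio <- replicate(120, {
      z <- as.vector(statevel:::ar1_series(240, r1))
      rmssd(z) / series_sd(z)
    })
    expect_equal(mean(ratio), sqrt(2 * (1 - r1)), tolerance = 0.1)
  }
})
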