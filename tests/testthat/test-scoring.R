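test_that("CD-RISC scoring sums 25 items over 0-4", {
  expect_equal(score_cdrisc(rep(4, 25)), 100)
  expect_equal(score_cdrisc(rep(0, 25)), 0)
  pattern <- rep(c(0, 1, 2, 3, 4), 5)
  expect_equal(score_cdrisc(pattern), sum(pattern))
  expect_error(score_cdrisc(rep(2, 24)), "25 items")
  expect_error(score_cdrisc(c(rep(2, 24), 5)), "0-4")
  expect_error(score_cdrisc(c(rep(2, 24), NA)), "missing")
})

test_that("BRS scoring averages with optional reverse-keying of 2, 4, 6", {
  expect_equal(score_brs(rep(5, 6), reverse_keyed = FALSE), 5)
  expect_equal(score_brs(rep(3, 6), reverse_keyed = TRUE), 3)
  expect_equal(score_brs(c(5, 1, 5, 1, 5, 1), reverse_keyed = TRUE), 5)
  expect_equal(score_brs(c(5, 1, 5, 1, 5, 1), reverse_keyed = FALSE), 3)
  expect_error(score_brs(c(0, 2, 3, 4, 5, 1)), "1-5")
})

test_that("RSA scoring spans 29-203 with consistent subscale sums", {
  top <- score_rsa(rep(7, 29))
  expect_equal(top$total, 203)
  bottom <- score_rsa(rep(1, 29))
  expect_equal(bottom$total, 29)
  set.seed(19)
  items <- sample(1:7, 29, replace = TRUE)
  res <- score_rsa(items)
  map <- rsa_subscale_map()
  for (s in names(res$subscales)) {
    expect_equal(res$subscales[[s]], sum(items[map$item[map$subscale == s]]))
  }
  expect_equal(sum(res$subscales), res$total)
  bad_map <- map; bad_map$subscale[1] <- "unknown_scale"
  expect_error(score_rsa(items, subscale_map = bad_map), "unknown")
  expect_error(score_rsa(items, subscale_map = map[-1, ]), "items 1-29")
})

test_that("the intra/inter composite follows its defining formula", {
  expect_equal(composite_intrainter(
    c(personal_strength = 10, future_structured_style = 10,
      family_cohesion = 9, social_competence = 9, social_resources = 9)),
    0.5 * 20 - 27 / 3)
  expect_equal(composite_intrainter(
    c(personal_strength = 0, future_structured_style = 0,
      family_cohesion = 0, social_competence = 0, social_resources = 0)), 0)
  # equal per-item mean m: composite = m (6+5)/2 - m (6+6+6)/3 = -0.5 m
  m <- 4
  sub <- c(personal_strength = 6 * m, future_structured_style = 5 * m,
           family_cohesion = 6 * m, social_competence = 6 * m,
           social_resources = 6 * m)
  expect_equal(composite_intrainter(sub), m * (11 / 2 - 18 / 3))
})

test_that("cohort scoring is invariant to subject order", {
  spec <- cohort_spec(12, n_voxels = 16, n_timepoints = 2, seed = 31)
  co <- simulate_cohort(spec)
  sc <- score_scales(co$items, brs_reverse_keyed = FALSE)
  perm <- sample(12)
  sc_perm <- score_scales(co$items[perm, ], brs_reverse_keyed = FALSE)
  expect_equal(sc_perm[order(sc_perm$subject), -1],
               sc[order(sc$subject), -1], ignore_attr = TRUE)
  expect_equal(sc$rsa,
               sc$rsa_family_cohesion + sc$rsa_social_competence +
                 sc$rsa_social_resources + sc$rsa_personal_strength +
                 sc$rsa_future_structured_style)
})

test_that("PCA on the correlation matrix has the documented structure", {
  set.seed(20)
  # rank-1 case: two measures correlated at exactly 1
  x <- rnorm(50)
  tab1 <- data.frame(a = x, b = 2 * x + 5)
  p1 <- pca_scales(tab1, measures = c("a", "b"))
  expect_equal(p1$variance_explained, c(1, 0), tolerance = 1e-12)
  # three independent measures split variance evenly at large n
  tab3 <- data.frame(a = rnorm(4000), b = rnorm(4000), c = rnorm(4000))
  p3 <- pca_scales(tab3, measures = c("a", "b", "c"))
  expect_equal(p3$variance_explained, rep(1 / 3, 3), tolerance = 0.05)
  # loadings reproduce the correlation matrix: L L^T = R
  spec <- cohort_spec(60, n_voxels = 16, n_timepoints = 2, seed = 33)
  sc <- score_scales(simulate_cohort(spec)$items, brs_reverse_keyed = FALSE)
  p <- pca_scales(sc, measures = c("cdrisc", "brs", "rsa"))
  R <- cor(as.matrix(sc[, c("cdrisc", "brs", "rsa")]))
  expect_equal(p$loadings %*% t(p$loadings), R, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  # scores of different components are uncorrelated
  cc <- cor(p$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # sign convention: the largest-magnitude loading of each component > 0
  for (j in 1:3) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(pca_scales(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant measure: a")
  expect_error(pca_scales(sc[1:2, ], measures = c("cdrisc", "brs")),
               "3 subjects")
})

test_that("planted self-recovery structure shows up in PC2 loadings", {
  spec <- cohort_spec(400, n_voxels = 16, n_timepoints = 2, seed = 35)
  sc <- score_scales(simulate_cohort(spec)$items, brs_reverse_keyed = FALSE)
  p <- pca_scales(sc, measures = c("cdrisc", "brs", "rsa"))
  expect_lt(p$loadings["brs", 2] * p$loadings["rsa", 2], 0)
  expect_true(all(p$loadings[, 1] > 0))
  # secondary PCA: intra vs inter subscales load PC2 with opposite signs
  subs <- paste0("rsa_", c("family_cohesion", "social_competence",
                           "social_resources", "personal_strength",
                           "future_structured_style"))
  p2 <- pca_scales(sc, measures = c("cdrisc", "brs", subs))
  pc2 <- orient_component(p2, 2, positive = "brs",
                          negative = "rsa_family_cohesion")
  l <- p2$loadings[, 2] * sign(p2$loadings["brs", 2])
  expect_gt(l[["rsa_personal_strength"]] * l[["brs"]], 0)
  expect_lt(l[["rsa_family_cohesion"]] * l[["brs"]], 0)
  expect_length(pc2, 400)
  # composite correlates positively with the oriented main PC2
  pc2_main <- orient_component(p, 2, positive = "brs", negative = "rsa")
  expect_gt(cor(sc$composite, pc2_main), 0)
})
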