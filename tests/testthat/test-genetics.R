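test_that("family-mean heritability reproduces the published arithmetic", {
  expect_equal(round(narrow_sense_heritability(13.5, 4.7, 49.6, 2), 2), 0.33)
  expect_equal(round(narrow_sense_heritability(2.2, 0.9, 10.2, 2), 2), 0.28)
  expect_equal(round(narrow_sense_heritability(23.3, 23.6, 220.6, 2), 2), 0.16)
  expect_equal(round(narrow_sense_heritability(3.4, 2.6, 30.7, 2), 2), 0.17)
  expect_equal(narrow_sense_heritability(5, 0, 0, 3), 1.0)
  expect_error(narrow_sense_heritability(0, 0, 0, 2), "undefined")
  expect_error(narrow_sense_heritability(-1, 0, 1, 2), ">= 0")
})

test_that("heritability is invariant to the trait scale", {
  h1 <- narrow_sense_heritability(13.5, 4.7, 49.6, 2)
  c2 <- 3.7^2
  h2 <- narrow_sense_heritability(13.5 * c2, 4.7 * c2, 49.6 * c2, 2)
  expect_equal(h1, h2)
})

test_that("heritability off a fit uses the identified interaction+residual sum", {
  plots <- recovery_plots(1)
  fit <- suppressWarnings(fit_reml(plots, trait = "shoot_dm",
                                   treatment = "TA1"))
  h <- heritability_from_fit(fit, 2)
  est <- setNames(fit$components$estimate, fit$components$term)
  expect_equal(h$h2, est[["family"]] /
                 (est[["family"]] + est[["residual"]] / 2))
  expect_gt(h$h2, 0)
  expect_lt(h$h2, 1)
  expect_true(is.finite(h$se) && h$se > 0)
})

test_that("the sum-trick covariance equals the ANOVA cross-product oracle", {
  set.seed(8)
  nf <- 12; nr <- 4
  fx <- rnorm(nf, 0, 2); fy <- 0.8 * fx + rnorm(nf, 0, 1)
  d <- expand.grid(family = 1:nf, replicate = 1:nr)
  x <- 10 + fx[d$family] + rnorm(nf * nr, 0, 1)
  y <- 5 + fy[d$family] + rnorm(nf * nr, 0, 1)
  long <- rbind(
    data.frame(d, trait = "x", value = x),
    data.frame(d, trait = "y", value = y))
  covA <- genetic_covariance(long, "x", "y", random = "family")
  # direct cross-product estimator for a balanced one-way layout:
  # (CP_between - CP_within) / n, mirroring the mean-square estimators
  xm <- tapply(x, d$family, mean); ym <- tapply(y, d$family, mean)
  cpb <- nr * sum((xm - mean(x)) * (ym - mean(y))) / (nf - 1)
  cpw <- sum((x - xm[d$family]) * (y - ym[d$family])) / (nf * (nr - 1))
  expect_equal(covA, (cpb - cpw) / nr, tolerance = 1e-5)
})

test_that("self- and reflected covariances behave like a covariance", {
  set.seed(9)
  nf <- 10; nr <- 3
  f <- rnorm(nf, 0, 2)
  d <- expand.grid(family = 1:nf, replicate = 1:nr)
  v <- f[d$family] + rnorm(nf * nr)
  long <- rbind(data.frame(d, trait = "x", value = v),
                data.frame(d, trait = "y", value = v),
                data.frame(d, trait = "yneg", value = -v))
  fitx <- fit_reml(long, trait = "x", random = "family")
  sfx <- fitx$components$estimate[fitx$components$term == "family"]
  expect_equal(genetic_covariance(long, "x", "y", random = "family"), sfx,
               tolerance = 1e-5)
  pair <- genetic_correlation_pair(long, "x", "y", random = "family")
  expect_equal(pair$r, 1, tolerance = 1e-6)
  flipped <- genetic_correlation_pair(long, "x", "yneg", random = "family")
  expect_equal(flipped$r, -1, tolerance = 1e-6)
})

test_that("the correlation matrix is symmetric with a unit diagonal", {
  plots <- recovery_plots(6)
  gm <- suppressWarnings(
    genetic_correlation_matrix(plots, c("shoot_dm", "root_dm"),
                               treatment = "TA1"))
  expect_equal(diag(gm$rA), c(shoot_dm = 1, root_dm = 1))
  expect_equal(gm$rA, t(gm$rA))
  expect_true(all(abs(gm$rA) <= 1))
  expect_gt(gm$rA["shoot_dm", "root_dm"], 0.5) # simulated truth is 0.97
})

test_that("traits disagreeing on plots raise a pairing error", {
  long <- data.frame(family = c(1, 2), replicate = 1,
                     trait = c("x", "y"), value = c(1, 2))
  expect_error(genetic_covariance(long, "x", "y"), "pairing")
})

test_that("BLUP trait matrices line families up across traits", {
  plots <- recovery_plots(2)
  tm <- suppressWarnings(blup_trait_matrix(plots, c("shoot_dm", "root_dm"),
                                           treatment = "TA1"))
  expect_equal(dim(tm), c(120, 2))
  expect_false(anyNA(tm))
  fit <- suppressWarnings(fit_reml(plots, trait = "shoot_dm",
                                   treatment = "TA1"))
  expect_equal(tm[names(fit$adjusted_means), "shoot_dm"],
               fit$adjusted_means)
})

test_that("phenotypic correlations recover known structure with p-values", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  pc <- phenotypic_correlations(m)
  expect_equal(pc$r["a", "b"], 1)
  expect_lt(pc$p["a", "b"], 1e-10)
  m2 <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  pc2 <- phenotypic_correlations(m2)
  expect_equal(pc2$r["a", "b"], 0)
  expect_equal(pc2$p["a", "b"], 1)
  expect_warning(pc3 <- phenotypic_correlations(
    cbind(a = c(1, 2, 3), b = c(2, 2, 2))), "constant")
  expect_true(is.na(pc3$r["a", "b"]))
  expect_error(phenotypic_correlations(m[1:2, ]), "3 families")
})

test_that("a moderate phenotypic association is recovered at trial size", {
  # target r = 0.47 over 120 families, averaged over seeded draws
  r_target <- 0.47
  sig <- matrix(c(1, r_target, r_target, 1), 2)
  est <- vapply(1:150, function(s) {
    set.seed(s)
    m <- rmvnorm_chol(120, sig)
    colnames(m) <- c("a", "b")
    phenotypic_correlations(m)$r["a", "b"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - r_target), 2 * mc_se + 1e-12)
})
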