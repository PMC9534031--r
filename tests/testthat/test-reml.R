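test_that("the balanced one-way optimum matches the ANOVA closed form", {
  toy <- one_way_toy()
  fit <- fit_reml(toy, random = "family")
  oracle <- one_way_anova_reml(toy)
  est <- setNames(fit$components$estimate, fit$components$term)
  expect_equal(est[["family"]], oracle[["family"]], tolerance = 1e-6)
  expect_equal(est[["residual"]], oracle[["residual"]], tolerance = 1e-6)
  expect_equal(fit$mu, 4, tolerance = 1e-8)
  expect_equal(unname(fit$blups$family["1"]), -1.75, tolerance = 1e-6)
  expect_equal(unname(fit$adjusted_means["1"]), 4 - 1.75, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the fitted components beat every point of a likelihood grid", {
  toy <- one_way_toy()
  fit <- fit_reml(toy, random = "family")
  est <- setNames(fit$components$estimate, fit$components$term)
  ll_hat <- restricted_log_likelihood(
    c(family = est[["family"]], residual = est[["residual"]]), toy,
    random = "family")
  grid <- expand.grid(f = seq(0, 20, by = 0.5), e = seq(0.5, 20, by = 0.5))
  ll <- mapply(function(f, e) {
    restricted_log_likelihood(c(family = f, residual = e), toy,
                              random = "family")
  }, grid$f, grid$e)
  expect_true(all(ll <= ll_hat + 1e-10))
  # and the best grid point sits at the closed-form optimum (7, 2)
  best <- grid[which.max(ll), ]
  expect_equal(best$f, 7)
  expect_equal(best$e, 2)
})

test_that("the balanced two-way optimum matches its ANOVA closed form", {
  set.seed(42)
  a <- 6; b <- 4
  fam <- rnorm(a, 0, 3)
  rep_eff <- rnorm(b, 0, 2)
  d <- expand.grid(family = 1:a, replicate = 1:b)
  d$value <- 10 + fam[d$family] + rep_eff[d$replicate] + rnorm(a * b, 0, 1)
  # additive two-way ANOVA estimators
  gm <- mean(d$value)
  fm <- tapply(d$value, d$family, mean)
  rm_ <- tapply(d$value, d$replicate, mean)
  msa <- b * sum((fm - gm)^2) / (a - 1)
  msb <- a * sum((rm_ - gm)^2) / (b - 1)
  sse <- sum((d$value - fm[d$family] - rm_[d$replicate] + gm)^2)
  mse <- sse / ((a - 1) * (b - 1))
  fit <- fit_reml(d, random = c("family", "replicate"))
  est <- setNames(fit$components$estimate, fit$components$term)
  expect_equal(est[["family"]], (msa - mse) / b, tolerance = 1e-6)
  expect_equal(est[["replicate"]], (msb - mse) / a, tolerance = 1e-6)
  expect_equal(est[["residual"]], mse, tolerance = 1e-6)
})

test_that("estimates agree with an independent mixed-model fit on trial data", {
  plots <- recovery_plots(7)
  sub <- plots[plots$trait == "shoot_dm" & plots$treatment == "TA1", ]
  fit <- suppressWarnings(fit_reml(sub))
  sub$rowf <- interaction(sub$replicate, sub$row)
  sub$colf <- interaction(sub$replicate, sub$column)
  lf <- suppressMessages(lme4::lmer(
    value ~ (1 | family) + (1 | replicate) + (1 | rowf) + (1 | colf),
    data = sub, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  est <- setNames(fit$components$estimate, fit$components$term)
  expect_equal(est[["family"]], ref[["family"]], tolerance = 1e-3)
  expect_equal(est[["residual"]], ref[["Residual"]], tolerance = 1e-3)
  expect_equal(est[["row"]], ref[["rowf"]], tolerance = 5e-3)
})

test_that("BLUPs shrink towards zero in balanced designs", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- expand.grid(family = 1:10, replicate = 1:4)
    d$value <- rnorm(10)[d$family] + rnorm(40, 0, 1.5)
    fit <- suppressWarnings(fit_reml(d, random = c("family", "replicate")))
    fm <- tapply(d$value, d$family, mean)
    raw_dev <- fm - mean(d$value)
    blup <- fit$blups$family[names(fm)]
    expect_true(all(abs(blup) <= abs(raw_dev) + 1e-8))
    expect_lt(abs(sum(blup)), 1e-8 * length(blup) * sd(d$value))
  }
})

test_that("a constant shift moves only the intercept", {
  plots <- recovery_plots(3)
  sub <- plots[plots$trait == "root_dm" & plots$treatment == "TA1", ]
  f1 <- suppressWarnings(fit_reml(sub))
  sub2 <- sub
  sub2$value <- sub2$value + 100
  f2 <- suppressWarnings(fit_reml(sub2))
  expect_equal(f2$mu, f1$mu + 100, tolerance = 1e-6)
  expect_equal(f2$components$estimate, f1$components$estimate,
               tolerance = 1e-5)
  expect_equal(f2$blups$family, f1$blups$family, tolerance = 1e-5)
})

test_that("rescaling the data rescales every component by the square", {
  toy <- one_way_toy()
  toy2 <- toy
  toy2$value <- toy2$value * 2
  f1 <- fit_reml(toy, random = "family")
  f2 <- fit_reml(toy2, random = "family")
  expect_equal(f2$components$estimate, 4 * f1$components$estimate,
               tolerance = 1e-6)
})

test_that("zero-variance data pins the family component at the boundary", {
  d <- data.frame(family = rep(1:4, each = 3), value = 5)
  fit <- fit_reml(d, random = "family")
  expect_equal(fit$components$estimate[fit$components$term == "family"], 0)
  expect_equal(fit$mu, 5)
  # pinned components are exactly zero, never tiny negatives
  expect_true(all(fit$components$estimate >= 0))
})

test_that("degenerate terms are dropped with an explanatory warning", {
  d <- data.frame(family = rep(1:6, each = 2), replicate = 1,
                  value = rnorm(12))
  expect_warning(fit_reml(d, random = c("family", "replicate")),
                 "single level")
  plots <- recovery_plots(2)
  sub <- plots[plots$trait == "shoot_dm" & plots$treatment == "TA1", ]
  expect_warning(fit_reml(sub), "confounded with the residual")
  expect_error(suppressWarnings(
    fit_reml(data.frame(family = 1, value = c(1, 2)))), "2 families")
})

test_that("one-sided Wald flags match the reported significance pattern", {
  expect_true(wald_significance(13.5, 2.5))
  expect_false(wald_significance(0.0002, 0.0005))
  # z just above / below the 5% one-sided critical value 1.6449
  s <- 0.37
  expect_true(wald_significance(1.64499 * s, s))
  expect_false(wald_significance(1.6448 * s, s))
  expect_true(is.na(wald_significance(1.2, NA)))
})

test_that("likelihood-ratio significance agrees with Wald on a clear effect", {
  plots <- recovery_plots(3)
  sub <- plots[plots$trait == "shoot_dm" & plots$treatment == "TA1", ]
  fw <- suppressWarnings(fit_reml(sub, sig_method = "wald"))
  fl <- suppressWarnings(fit_reml(sub, sig_method = "lrt"))
  gw <- fw$components$significant[fw$components$term == "family"]
  gl <- fl$components$significant[fl$components$term == "family"]
  expect_true(gw)
  expect_true(gl)
})

test_that("the restricted likelihood rejects bad inputs", {
  toy <- one_way_toy()
  expect_error(restricted_log_likelihood(c(family = -1, residual = 1), toy,
                                         random = "family"), "non-negative")
  expect_error(restricted_log_likelihood(c(family = 1), toy,
                                         random = "family"), "residual")
})
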