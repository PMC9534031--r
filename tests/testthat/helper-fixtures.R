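# Shared fixtures, all built in code.

# Balanced one-way toy with a known closed-form REML solution:
# groups {1,3} and {5,7}; MSW = 2, MSB = 16, so sigma_f2 = (16-2)/2 = 7,
# sigma_e2 = 2, and BLUP(group 1) = (7 / (7 + 2/2)) * (2 - 4) = -1.75.
one_way_toy <- function() {
  data.frame(family = rep(1:2, each = 2), value = c(1, 3, 5, 7))
}

# A single-treatment plot-scale trial config for parameter recovery at the
# shoot components 13.5 / 4.7 / 49.6 (root 2.2 / 0.9 / 10.2), with small
# room and spatial effects; one plant per quadrant so plot values are
# emitted directly.
recovery_config <- function(seed, rg = 0.97) {
  simulation_config(
    treatment_means = list(TA1 = c(shoot_dm = 11.4, root_dm = 5.03)),
    true_components = list(TA1 = list(
      shoot_dm = c(family = 13.5, replicate = 1, fam_rep = 4.7,
                   row = 0.5, column = 0.5, residual = 49.6),
      root_dm = c(family = 2.2, replicate = 0.5, fam_rep = 0.9,
                  row = 0.2, column = 0.2, residual = 10.2)
    )),
    trait_genetic_correlation = rg,
    plants_per_quadrant = 1,
    negative_control = NULL,
    seed = seed
  )
}

recovery_plots <- function(seed, rg = 0.97) {
  trial <- simulate_trial(recovery_config(seed, rg))
  suppressWarnings(derive_trait_table(trial$plants))
}

# Near-noiseless regime for genetic-correlation recovery: same 120-family x
# 2-replicate design, but plot residual 1 so the correlation-ratio
# estimator's error is dominated by family sampling, not by denominator
# noise (the ratio is biased when family variances are poorly identified).
ra_recovery_plots <- function(seed, rg) {
  comp <- c(family = 13.5, replicate = 1, fam_rep = 0, row = 0.5,
            column = 0.5, residual = 1)
  cfg <- simulation_config(
    treatment_means = list(TA1 = c(shoot_dm = 11.4, root_dm = 5.03)),
    true_components = list(TA1 = list(shoot_dm = comp, root_dm = comp)),
    trait_genetic_correlation = rg, plants_per_quadrant = 1,
    negative_control = NULL, seed = seed)
  suppressWarnings(derive_trait_table(simulate_trial(cfg)$plants))
}

# closed-form REML for a balanced one-way layout (ANOVA estimators)
one_way_anova_reml <- function(data) {
  grp <- split(data$value, data$family)
  n <- length(grp[[1]])
  means <- vapply(grp, mean, numeric(1))
  msw <- sum(vapply(grp, function(g) sum((g - mean(g))^2), numeric(1))) /
    (length(grp) * (n - 1))
  msb <- n * var(means)
  c(family = (msb - msw) / n, residual = msw)
}

# Table of pairwise additive correlations used as a synthetic truth for
# the 5-trait PCA check (shoot_dm, shoot_sp, root_dm, root_sp, rsr).
five_trait_correlation <- function() {
  r <- diag(1, 5)
  dimnames(r) <- rep(list(c("shoot_dm", "shoot_sp", "root_dm", "root_sp",
                            "rsr")), 2)
  vals <- rbind(
    c(1, 2, 0.62), c(1, 3, 0.97), c(1, 4, 0.53), c(1, 5, -0.33),
    c(2, 3, 0.63), c(2, 4, 0.85), c(2, 5, 0.01),
    c(3, 4, 0.60), c(3, 5, -0.12),
    c(4, 5, 0.32))
  for (i in seq_len(nrow(vals))) {
    r[vals[i, 1], vals[i, 2]] <- r[vals[i, 2], vals[i, 1]] <- vals[i, 3]
  }
  r
}

# two well-separated Gaussian point clouds
two_blob_matrix <- function(n_per = 25, d = 2, gap = 10, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  rownames(m) <- sprintf("e%02d", seq_len(2 * n_per))
  m
}

# MVN sampler via Cholesky with PD repair for a slightly indefinite target
rmvnorm_chol <- function(n, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  L <- ev$vectors %*% diag(sqrt(ev$values))
  matrix(rnorm(n * ncol(sigma)), n) %*% t(L)
}
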