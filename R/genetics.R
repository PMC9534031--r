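#' Narrow-sense heritability on a half-sib family-mean basis
#'
#' `h2 = sigma_f2 / (sigma_f2 + sigma_fr2 / n_rep + sigma_e2 / n_rep)`,
#' where `sigma_f2` is the family variance component (in a half-sib
#' structure this already equals one quarter of the total additive genetic
#' variance, so no rescaling is applied), `sigma_fr2` the family x replicate
#' interaction component, `sigma_e2` the plot residual and `n_rep` the
#' number of environmental replicates. Scale-invariant: multiplying the
#' trait by a constant multiplies every component by its square and leaves
#' h2 unchanged.
#'
#' @param sigma_f2,sigma_fr2,sigma_e2 Non-negative variance components in
#'   squared trait units. When the interaction is confounded with the
#'   residual (plot-mean data) pass their identified sum as `sigma_e2` and
#'   0 as `sigma_fr2`.
#' @param n_rep Number of environmental replicates (>= 1).
#' @return Heritability in `[0, 1]`.
#' @examples
#' narrow_sense_heritability(13.5, 4.7, 49.6, 2)
#' @export
narrow_sense_heritability <- function(sigma_f2, sigma_fr2, sigma_e2, n_rep) {
  if (any(c(sigma_f2, sigma_fr2, sigma_e2) < 0) || n_rep < 1) {
    stop("narrow_sense_heritability: components must be >= 0 and n_rep >= 1",
         call. = FALSE)
  }
  denom <- sigma_f2 + sigma_fr2 / n_rep + sigma_e2 / n_rep
  if (denom <= 0) {
    stop("narrow_sense_heritability: all components are zero; heritability undefined",
         call. = FALSE)
  }
  sigma_f2 / denom
}

# pull a named component (0 when pinned/dropped) out of a reml_fit
fit_component <- function(fit, term) {
  i <- match(term, fit$components$term)
  if (is.na(i)) 0 else fit$components$estimate[i]
}

#' Heritability from a fitted model, with a delta-method standard error
#'
#' Reads the family and residual components off a [fit_reml()] object. With
#' plot-mean data the family x replicate interaction is absorbed into the
#' residual, which is exactly the sum entering the heritability denominator.
#' The standard error is a first-order delta-method approximation from the
#' component covariance implied by the Fisher information.
#'
#' @param fit A `reml_fit`.
#' @param n_rep Number of environmental replicates.
#' @return A list with `h2` and `se`.
#' @export
heritability_from_fit <- function(fit, n_rep) {
  sf <- fit_component(fit, "family")
  sfr <- fit_component(fit, "fam_rep")
  se2 <- fit_component(fit, "residual")
  h2 <- narrow_sense_heritability(sf, sfr, se2, n_rep)
  comp <- fit$components
  i_f <- match("family", comp$term)
  i_e <- match("residual", comp$term)
  se <- NA_real_
  if (!is.na(comp$se[i_f]) && !is.na(comp$se[i_e])) {
    denom <- sf + sfr / n_rep + se2 / n_rep
    # gradient of h2 wrt (sigma_f2, sigma_e2); components treated as
    # independent (off-diagonal information ignored)
    d_f <- (denom - sf) / denom^2
    d_e <- -sf / (n_rep * denom^2)
    se <- sqrt((d_f * comp$se[i_f])^2 + (d_e * comp$se[i_e])^2)
  }
  list(h2 = h2, se = se)
}

# three univariate REML fits behind the sum-trick covariance; shared by the
# genetic covariance and the index machinery
pair_component_covariances <- function(data, trait_x, trait_y,
                                       treatment = NULL, response = "value",
                                       random = c("family", "replicate",
                                                  "fam_rep", "row", "column"),
                                       standardize = TRUE,
                                       control = reml_control()) {
  if (!is.null(treatment)) {
    data <- data[data$treatment == treatment, , drop = FALSE]
  }
  dx <- data[data$trait == trait_x, , drop = FALSE]
  dy <- data[data$trait == trait_y, , drop = FALSE]
  key <- intersect(c("family", "replicate", "treatment"), names(dx))
  xcols <- c(key, intersect(c("row", "column"), names(dx)), response)
  m <- merge(dx[, xcols, drop = FALSE], dy[, c(key, response), drop = FALSE],
             by = key, suffixes = c("_x", "_y"))
  m <- m[complete.cases(m[, c(paste0(response, "_x"),
                              paste0(response, "_y"))]), , drop = FALSE]
  if (!nrow(m)) {
    stop(sprintf(
      "pairing error: traits '%s' and '%s' share no plots", trait_x, trait_y),
      call. = FALSE)
  }
  x <- m[[paste0(response, "_x")]]
  y <- m[[paste0(response, "_y")]]
  sx <- if (standardize) sd(x) else 1
  sy <- if (standardize) sd(y) else 1
  m$value_x_std <- x / sx
  m$value_y_std <- y / sy
  m$value_sum <- m$value_x_std + m$value_y_std

  fx <- suppressWarnings(fit_reml(m, response = "value_x_std",
                                  random = random, control = control))
  fy <- suppressWarnings(fit_reml(m, response = "value_y_std",
                                  random = random, control = control))
  fs <- suppressWarnings(fit_reml(m, response = "value_sum",
                                  random = random, control = control))
  terms <- union(fx$components$term, fy$components$term)
  cov_comp <- setNames(numeric(length(terms)), terms)
  var_x <- setNames(numeric(length(terms)), terms)
  var_y <- setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    vx <- fit_component(fx, tm)
    vy <- fit_component(fy, tm)
    vs <- fit_component(fs, tm)
    cov_comp[tm] <- (vs - vx - vy) / 2 * sx * sy
    var_x[tm] <- vx * sx^2
    var_y[tm] <- vy * sy^2
  }
  list(cov = cov_comp, var_x = var_x, var_y = var_y,
       fits = list(x = fx, y = fy, sum = fs), scale = c(x = sx, y = sy))
}

#' Additive genetic covariance between two traits
#'
#' Estimates the family (additive) covariance by the variance-of-sums
#' identity: `cov_A(X, Y) = (sigma_f2(X + Y) - sigma_f2(X) - sigma_f2(Y)) /
#' 2`, from three univariate REML fits. Traits are rescaled to unit
#' phenotypic standard deviation before summation for numerical balance and
#' the covariance is returned on the original scale. At balanced designs
#' this estimator coincides with the direct cross-product (multivariate
#' analysis of variance) estimator.
#'
#' @inheritParams pair_component_covariances
#' @param trait_x,trait_y Trait names present in `data$trait`.
#' @return The additive covariance in product trait units.
#' @export
genetic_covariance <- function(data, trait_x, trait_y, treatment = NULL,
                               random = c("family", "replicate", "fam_rep",
                                          "row", "column"),
                               standardize = TRUE,
                               control = reml_control()) {
  pc <- pair_component_covariances(data, trait_x, trait_y,
                                   treatment = treatment, random = random,
                                   standardize = standardize,
                                   control = control)
  unname(pc$cov["family"])
}

#' Additive genetic correlation for one trait pair
#'
#' The raw (unclamped) correlation `cov_A / sqrt(sigma_f2(X) *
#' sigma_f2(Y))` together with the pieces it is built from; three
#' univariate REML fits. `r` is `NA` when either family variance is zero.
#'
#' @inheritParams genetic_covariance
#' @return List with `r`, `cov`, `var_x`, `var_y`.
#' @export
genetic_correlation_pair <- function(data, trait_x, trait_y, treatment = NULL,
                                     random = c("family", "replicate",
                                                "fam_rep", "row", "column"),
                                     standardize = TRUE,
                                     control = reml_control()) {
  pc <- pair_component_covariances(data, trait_x, trait_y,
                                   treatment = treatment, random = random,
                                   standardize = standardize,
                                   control = control)
  vx <- unname(pc$var_x["family"])
  vy <- unname(pc$var_y["family"])
  cv <- unname(pc$cov["family"])
  r <- if (vx > 0 && vy > 0) cv / sqrt(vx * vy) else NA_real_
  list(r = r, cov = cv, var_x = vx, var_y = vy)
}

#' Genetic correlation matrix across traits
#'
#' Pairwise additive correlations `r_A(X, Y) = cov_A / sqrt(sigma_f2(X) *
#' sigma_f2(Y))` from the variance-of-sums estimator. Entries that overshoot
#' `[-1, 1]` (common for small-sample REML correlations) are clamped to the
#' boundary and flagged; a trait with zero family variance yields an
#' undefined (`NA`) row, also flagged.
#'
#' @inheritParams pair_component_covariances
#' @param traits Character vector (>= 2) of trait names.
#' @return An object of class `genetic_corr`: `rA` (correlation matrix),
#'   `covA` (covariances), `varA` (family variances), `clamped` (logical
#'   matrix), and `component_cov` (per-component covariance matrices used by
#'   the selection-index machinery).
#' @export
genetic_correlation_matrix <- function(data, traits, treatment = NULL,
                                       random = c("family", "replicate",
                                                  "fam_rep", "row", "column"),
                                       standardize = TRUE,
                                       control = reml_control()) {
  stopifnot(length(traits) >= 2)
  p <- length(traits)
  rA <- diag(1, p)
  covA <- matrix(NA_real_, p, p)
  clamped <- matrix(FALSE, p, p)
  dimnames(rA) <- dimnames(covA) <- dimnames(clamped) <- list(traits, traits)
  varA <- setNames(numeric(p), traits)
  comp_cov <- list()

  fits <- lapply(traits, function(tr) {
    suppressWarnings(fit_reml(data, trait = tr, treatment = treatment,
                              random = random, control = control))
  })
  names(fits) <- traits
  for (i in seq_len(p)) {
    varA[i] <- fit_component(fits[[i]], "family")
    covA[i, i] <- varA[i]
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pc <- pair_component_covariances(data, traits[i], traits[j],
                                       treatment = treatment, random = random,
                                       standardize = standardize,
                                       control = control)
      covA[i, j] <- covA[j, i] <- pc$cov["family"]
      for (tm in names(pc$cov)) {
        if (is.null(comp_cov[[tm]])) {
          comp_cov[[tm]] <- matrix(NA_real_, p, p,
                                   dimnames = list(traits, traits))
        }
        comp_cov[[tm]][i, j] <- comp_cov[[tm]][j, i] <- pc$cov[tm]
      }
    }
  }
  for (tm in names(comp_cov)) {
    for (i in seq_len(p)) comp_cov[[tm]][i, i] <- fit_component(fits[[i]], tm)
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (varA[i] <= 0 || varA[j] <= 0) {
        rA[i, j] <- rA[j, i] <- NA_real_
        clamped[i, j] <- clamped[j, i] <- TRUE
        warning(sprintf(
          "genetic correlation undefined for (%s, %s): a family variance is zero",
          traits[i], traits[j]))
        next
      }
      r <- covA[i, j] / sqrt(varA[i] * varA[j])
      if (abs(r) > 1 + 1e-6) {
        warning(sprintf("genetic correlation (%s, %s) = %.3f clamped to %d",
                        traits[i], traits[j], r, sign(r)))
        clamped[i, j] <- clamped[j, i] <- TRUE
        r <- sign(r)
      } else if (abs(r) > 1) {
        r <- sign(r)  # numerical overshoot only
      }
      rA[i, j] <- rA[j, i] <- r
    }
  }
  structure(list(traits = traits, rA = rA, covA = covA, varA = varA,
                 clamped = clamped, component_cov = comp_cov, fits = fits),
            class = "genetic_corr")
}

#' @export
print.genetic_corr <- function(x, ...) {
  cat("Additive genetic correlations:\n")
  print(round(x$rA, 3))
  if (any(x$clamped)) cat("(entries clamped to [-1, 1] are flagged in $clamped)\n")
  invisible(x)
}

#' BLUP-adjusted family-by-trait matrix
#'
#' Fits each trait by REML and assembles the family x trait matrix of
#' BLUP-adjusted means (`mu + family BLUP`), the input to phenotypic
#' correlations, selection indices and pattern analysis.
#'
#' @inheritParams fit_reml
#' @param traits Trait names to include.
#' @return Numeric matrix, rows named by family, columns by trait.
#' @export
blup_trait_matrix <- function(data, traits, treatment = NULL,
                              random = c("family", "replicate", "fam_rep",
                                         "row", "column"),
                              control = reml_control()) {
  fits <- lapply(traits, function(tr) {
    suppressWarnings(fit_reml(data, trait = tr, treatment = treatment,
                              random = random, control = control))
  })
  fams <- sort(unique(unlist(lapply(fits, function(f) names(f$adjusted_means)))))
  m <- matrix(NA_real_, length(fams), length(traits),
              dimnames = list(fams, traits))
  for (i in seq_along(traits)) {
    am <- fits[[i]]$adjusted_means
    m[names(am), i] <- am
  }
  m
}

#' Pearson phenotypic correlations on family BLUPs
#'
#' Pairwise Pearson correlations of BLUP-adjusted family means with
#' two-sided t-test p-values; no multiplicity adjustment. Constant columns
#' yield undefined (`NA`) correlations with a warning.
#'
#' @param trait_matrix Family x trait matrix (e.g. from
#'   [blup_trait_matrix()]); needs at least 3 rows.
#' @return List with `r` (correlations), `p` (p-values) and `n` (pairwise
#'   complete sample sizes).
#' @export
phenotypic_correlations <- function(trait_matrix) {
  m <- as.matrix(trait_matrix)
  if (nrow(m) < 3) {
    stop("phenotypic_correlations: need at least 3 families", call. = FALSE)
  }
  p <- ncol(m)
  cn <- colnames(m) %||% paste0("trait", seq_len(p))
  r <- diag(1, p)
  pv <- matrix(NA_real_, p, p)
  nm <- matrix(nrow(m), p, p)
  dimnames(r) <- dimnames(pv) <- dimnames(nm) <- list(cn, cn)
  diag(pv) <- 0
  const <- apply(m, 2, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant trait column(s): ", paste(cn[const], collapse = ", "),
            "; correlations undefined")
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- complete.cases(m[, c(i, j)])
      n <- sum(ok)
      nm[i, j] <- nm[j, i] <- n
      if (n < 3 || const[i] || const[j]) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      rij <- cor(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) < 1) {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        pv[i, j] <- pv[j, i] <- 2 * pt(-abs(tstat), df = n - 2)
      } else {
        pv[i, j] <- pv[j, i] <- 0
      }
    }
  }
  list(r = r, p = pv, n = nm)
}
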