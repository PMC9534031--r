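#' Control parameters for the REML optimiser
#'
#' @param max_iter Maximum Newton-type (Fisher-scoring) iterations.
#' @param rel_tol Relative change in the restricted log-likelihood at which
#'   the optimiser stops.
#' @param em_iter Number of expectation-maximisation warm-start updates run
#'   before the quasi-Newton phase.
#' @param pin_tol A component below `pin_tol` times the phenotypic variance
#'   is a boundary candidate; it is pinned to exactly zero when removing it
#'   does not lower the restricted log-likelihood by more than `pin_ll_tol`.
#' @param pin_ll_tol See `pin_tol`.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(max_iter = 200L, rel_tol = 1e-8, em_iter = 10L,
                         pin_tol = 5e-3, pin_ll_tol = 1e-4) {
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 em_iter = as.integer(em_iter), pin_tol = pin_tol,
                 pin_ll_tol = pin_ll_tol),
            class = "reml_control")
}

# Build indicator matrices for the random terms present in a plot table.
# Row/column effects are nested within replicate. Terms whose design is
# degenerate are dropped with a warning:
#   * fewer than 2 levels (nothing to estimate),
#   * one observation per level (confounded with the residual).
build_random_terms <- function(data, random) {
  n <- nrow(data)
  fac <- list()
  if ("family" %in% random) fac$family <- factor(data$family)
  if ("replicate" %in% random) fac$replicate <- factor(data$replicate)
  if ("fam_rep" %in% random) {
    fac$fam_rep <- interaction(data$family, data$replicate, drop = TRUE)
  }
  if ("row" %in% random && "row" %in% names(data) && !all(is.na(data$row))) {
    fac$row <- interaction(data$replicate, data$row, drop = TRUE)
  }
  if ("column" %in% random && "column" %in% names(data) &&
      !all(is.na(data$column))) {
    fac$column <- interaction(data$replicate, data$column, drop = TRUE)
  }
  dropped <- character()
  keep <- list()
  for (nm in names(fac)) {
    q <- nlevels(fac[[nm]])
    if (q < 2L) {
      dropped <- c(dropped, nm)
      warning(sprintf("random term '%s' has a single level; dropped", nm))
    } else if (q >= n) {
      dropped <- c(dropped, nm)
      warning(sprintf(
        "random term '%s' has one observation per level and is confounded with the residual; dropped",
        nm))
    } else {
      keep[[nm]] <- fac[[nm]]
    }
  }
  Z <- lapply(keep, function(f) {
    m <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  })
  list(Z = Z, factors = keep, dropped = dropped)
}

# One evaluation of the restricted likelihood machinery at s2 (variances of
# the active terms, residual last). Returns NULL on a singular covariance.
reml_eval <- function(y, G, s2) {
  n <- length(y)
  K <- length(G)
  V <- diag(s2[K + 1L], n)
  for (k in seq_len(K)) V <- V + s2[k] * G[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  vi1 <- rowSums(Vi)              # Vi %*% 1 (intercept-only fixed part)
  xtvx <- sum(vi1)
  P <- Vi - tcrossprod(vi1) / xtvx
  Py <- as.numeric(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xtvx) + sum(y * Py)) -
    0.5 * (n - 1) * log(2 * pi)
  list(ll = ll, P = P, Py = Py, Vi = Vi, xtvx = xtvx)
}

# Gradient of the restricted log-likelihood wrt each variance (active terms
# then residual), given an evaluation.
reml_grad <- function(ev, Z) {
  K <- length(Z)
  g <- numeric(K + 1L)
  for (k in seq_len(K)) {
    PZ <- ev$P %*% Z[[k]]
    tr <- sum(Z[[k]] * PZ)
    quad <- sum(crossprod(Z[[k]], ev$Py)^2)
    g[k] <- -0.5 * (tr - quad)
  }
  g[K + 1L] <- -0.5 * (sum(diag(ev$P)) - sum(ev$Py^2))
  g
}

# Gradient plus expected (Fisher) information in one pass; the information
# block is I[j,k] = 0.5 tr(P G_j P G_k).
reml_grad_info <- function(ev, Z) {
  K <- length(Z)
  M <- lapply(Z, function(z) ev$P %*% z)
  g <- numeric(K + 1L)
  info <- matrix(0, K + 1L, K + 1L)
  for (k in seq_len(K)) {
    tr <- sum(Z[[k]] * M[[k]])
    quad <- sum(crossprod(Z[[k]], ev$Py)^2)
    g[k] <- -0.5 * (tr - quad)
  }
  g[K + 1L] <- -0.5 * (sum(diag(ev$P)) - sum(ev$Py^2))
  for (i in seq_len(K)) {
    for (j in i:K) {
      info[i, j] <- info[j, i] <- 0.5 * sum(crossprod(Z[[j]], M[[i]])^2)
    }
    info[i, K + 1L] <- info[K + 1L, i] <- 0.5 * sum(M[[i]]^2)
  }
  info[K + 1L, K + 1L] <- 0.5 * sum(ev$P^2)
  list(g = g, info = info)
}

reml_core <- function(y, Z, control = reml_control()) {
  n <- length(y)
  K <- length(Z)
  v0 <- var(y)
  terms <- names(Z)
  zero_fit <- function() {
    list(s2 = setNames(rep(0, K + 1L), c(terms, "residual")),
         se = setNames(rep(NA_real_, K + 1L), c(terms, "residual")),
         mu = mean(y), logLik = NA_real_, iterations = 0L, converged = TRUE,
         blups = lapply(Z, function(z) setNames(rep(0, ncol(z)), colnames(z))),
         pinned = setNames(rep(TRUE, K), terms))
  }
  if (!is.finite(v0) || v0 <= .Machine$double.eps * 100) return(zero_fit())

  lb <- v0 * 1e-12
  fit_active <- function(act, start = NULL) {
    Ka <- length(act)
    Za <- Z[act]
    Ga <- lapply(Za, tcrossprod)
    s2 <- start %||% rep(v0 / (Ka + 1L), Ka + 1L)
    ev <- reml_eval(y, Ga, s2)
    iterations <- 0L
    # EM warm start (skipped when restarting from a previous fit)
    em_iter <- if (is.null(start)) control$em_iter else 0L
    qk <- c(vapply(Za, ncol, 1L), n - 1L)
    for (i in seq_len(em_iter)) {
      if (is.null(ev)) break
      g <- reml_grad(ev, Za)
      s2n <- pmax(s2 + 2 * s2^2 * g / qk, lb)
      evn <- reml_eval(y, Ga, s2n)
      if (is.null(evn)) break
      s2 <- s2n
      ev <- evn
      iterations <- iterations + 1L
    }
    if (is.null(ev)) {
      return(list(s2 = s2, ll = -Inf, iterations = iterations,
                  converged = FALSE))
    }
    # Newton-type (Fisher-scoring) updates on log-variances, with step
    # halving so the restricted log-likelihood never decreases
    converged <- FALSE
    for (it in seq_len(control$max_iter)) {
      gi <- reml_grad_info(ev, Za)
      S <- s2  # d(logL)/d(log s2) = g * s2; info transforms by S I S
      A <- gi$info * tcrossprod(S)
      bvec <- gi$g * S
      delta <- tryCatch(solve(A, bvec), error = function(e) NULL)
      if (is.null(delta)) delta <- bvec / pmax(diag(A), .Machine$double.eps)
      delta <- pmin(pmax(delta, -30), 4)  # fast decay towards the boundary
      step <- 1
      ll_old <- ev$ll
      evn <- NULL
      repeat {
        s2n <- pmax(s2 * exp(step * delta), lb)
        evn <- reml_eval(y, Ga, s2n)
        if (!is.null(evn) && evn$ll >= ll_old - 1e-12) break
        step <- step / 2
        if (step < 1e-8) {
          evn <- NULL
          break
        }
      }
      iterations <- iterations + 1L
      if (is.null(evn)) {
        converged <- TRUE  # no uphill move exists: at a (boundary) optimum
        break
      }
      move <- max(abs(log(s2n / s2)))  # realised movement after clamping
      s2 <- s2n
      ev <- evn
      if (move < 1e-7 ||
          (move < 1e-3 &&
           abs(ev$ll - ll_old) <= control$rel_tol * (abs(ll_old) + 1))) {
        converged <- TRUE
        break
      }
    }
    list(s2 = s2, ll = ev$ll, iterations = iterations, converged = converged)
  }

  act <- seq_len(K)
  fit <- fit_active(act)
  iterations <- fit$iterations
  # boundary detection: profile out near-zero components
  repeat {
    if (!length(act)) break
    small <- act[fit$s2[seq_along(act)] < control$pin_tol * v0]
    progressed <- FALSE
    for (k in small) {
      act2 <- setdiff(act, k)
      fit2 <- fit_active(act2, start = fit$s2[-match(k, act)])
      iterations <- iterations + fit2$iterations
      if (fit2$ll >= fit$ll - control$pin_ll_tol) {
        act <- act2
        fit <- fit2
        progressed <- TRUE
        break
      }
    }
    if (!progressed) break
  }

  s2 <- setNames(rep(0, K + 1L), c(terms, "residual"))
  s2[act] <- fit$s2[seq_along(act)]
  s2[K + 1L] <- fit$s2[length(fit$s2)]
  pinned <- setNames(!(seq_len(K) %in% act), terms)

  Ga <- lapply(Z[act], tcrossprod)
  ev <- reml_eval(y, Ga, fit$s2)
  # expected (Fisher) information over the active variances + residual
  Ka <- length(act)
  M <- lapply(Z[act], function(z) ev$P %*% z)
  info <- matrix(NA_real_, Ka + 1L, Ka + 1L)
  for (i in seq_len(Ka)) {
    for (j in i:Ka) {
      info[i, j] <- info[j, i] <-
        0.5 * sum(crossprod(Z[[act[j]]], M[[i]])^2)
    }
    info[i, Ka + 1L] <- info[Ka + 1L, i] <- 0.5 * sum((M[[i]])^2)
  }
  info[Ka + 1L, Ka + 1L] <- 0.5 * sum(ev$P^2)
  se_act <- tryCatch(sqrt(diag(solve(info))), error = function(e) {
    rep(NA_real_, Ka + 1L)
  })
  se <- setNames(rep(NA_real_, K + 1L), c(terms, "residual"))
  se[act] <- se_act[seq_len(Ka)]
  se[K + 1L] <- se_act[Ka + 1L]

  mu <- sum(ev$Vi %*% y) / ev$xtvx
  blups <- setNames(vector("list", K), terms)
  for (k in seq_len(K)) {
    u <- if (k %in% act) {
      s2[k] * as.numeric(crossprod(Z[[k]], ev$Py))
    } else {
      rep(0, ncol(Z[[k]]))
    }
    blups[[k]] <- setNames(u, colnames(Z[[k]]))
  }

  list(s2 = s2, se = se, mu = mu, logLik = ev$ll,
       iterations = iterations, converged = fit$converged,
       blups = blups, pinned = pinned)
}

#' Fit the random-effects trial model by REML
#'
#' Fits, by restricted maximum likelihood, the additive random-effects model
#' for a plot-observation table: trait value = overall mean + family +
#' replicate + family x replicate + row-in-replicate + column-in-replicate +
#' residual, all random, intercept the only fixed effect. Estimation runs an
#' expectation-maximisation warm start followed by Newton-type
#' (Fisher-scoring) updates on log-variances with step halving; convergence
#' is declared when the update step is negligible or the relative change in
#' the restricted log-likelihood falls below `control$rel_tol`. Components near
#' the zero boundary are pinned to exactly zero when the profile likelihood
#' is indifferent to them. Standard errors come from the inverse Fisher
#' information at the optimum (absent for pinned components), significance
#' from a one-sided Wald test at the 5% level (or a 50:50 chi-square mixture
#' likelihood-ratio test with `sig_method = "lrt"`). Family BLUPs solve the
#' mixed-model equations at the estimated components.
#'
#' Degenerate terms are dropped with a warning: a term with a single level
#' (e.g. replicate in a one-room trial) or with one observation per level.
#' The latter matters for plot-mean data, where the family x replicate
#' interaction is confounded with the plot residual; the residual then
#' estimates the sum of the two.
#'
#' @param data Plot-observation data frame (long format from
#'   [derive_trait_table()], or any data frame with the named columns).
#' @param trait,treatment Optional filters applied to `data` before fitting.
#' @param response Name of the response column (default `"value"`).
#' @param random Random terms to include; any of `"family"`, `"replicate"`,
#'   `"fam_rep"`, `"row"`, `"column"`.
#' @param sig_method `"wald"` (default) or `"lrt"`.
#' @param control A [reml_control()] list.
#' @return An object of class `reml_fit`: `components` (data frame with
#'   `term`, `estimate`, `se`, `significant`), `mu`, `blups` (per-term
#'   lists; `$blups$family` are the family BLUPs), `adjusted_means`
#'   (`mu + family BLUP`), `logLik`, `iterations`, `converged`,
#'   `dropped_terms`, `n`.
#' @examples
#' toy <- data.frame(family = rep(1:2, each = 2), value = c(1, 3, 5, 7))
#' fit <- fit_reml(toy, random = "family")
#' fit$components
#' @export
fit_reml <- function(data, trait = NULL, treatment = NULL,
                     response = "value",
                     random = c("family", "replicate", "fam_rep", "row",
                                "column"),
                     sig_method = c("wald", "lrt"),
                     control = reml_control()) {
  sig_method <- match.arg(sig_method)
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  if (!is.null(treatment)) {
    data <- data[data$treatment == treatment, , drop = FALSE]
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (!("replicate" %in% names(data))) data$replicate <- 1L
  if (length(unique(data$family[!is.na(data$family)])) < 2L) {
    stop("fit_reml: need at least 2 families", call. = FALSE)
  }
  random <- intersect(random, c("family", "replicate", "fam_rep", "row",
                                "column"))
  bt <- build_random_terms(data, random)
  if (!("family" %in% names(bt$Z))) {
    stop("fit_reml: the family term is degenerate; nothing to estimate",
         call. = FALSE)
  }
  y <- data[[response]]
  core <- reml_core(y, bt$Z, control)
  if (!core$converged) {
    stop(sprintf(
      "fit_reml: REML did not converge within %d iterations (logL %.6g)",
      control$max_iter, core$logLik), call. = FALSE)
  }

  K <- length(bt$Z)
  est <- core$s2
  se <- core$se
  if (sig_method == "wald") {
    sig <- wald_significance(est, se)
  } else {
    sig <- setNames(rep(NA, K + 1L), names(est))
    for (nm in names(bt$Z)) {
      act2 <- setdiff(names(bt$Z), nm)
      core0 <- reml_core(y, bt$Z[act2], control)
      lr <- 2 * (core$logLik - core0$logLik)
      p <- 0.5 * pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      sig[nm] <- p <= 0.05
    }
  }

  components <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    significant = unname(sig),
    row.names = NULL
  )
  fam_blup <- core$blups$family
  structure(list(
    components = components,
    mu = core$mu,
    blups = core$blups,
    adjusted_means = core$mu + fam_blup,
    logLik = core$logLik,
    iterations = core$iterations,
    converged = core$converged,
    dropped_terms = bt$dropped,
    pinned = core$pinned,
    n = length(y)
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: %d observations, restricted logL %.4f (%s)\n",
              x$n, x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$dropped_terms)) {
    cat("  dropped terms:", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  print(x$components, digits = 4)
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the restricted (residual) log-likelihood of a set of variance
#' components for the random-effects trial model, exact up to the model
#' constant which is fixed across calls. Useful as a grid-search oracle for
#' the optimiser.
#'
#' @inheritParams fit_reml
#' @param components Named numeric vector of non-negative variances; must
#'   include `residual`, other names as in `random`.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(components, data, trait = NULL,
                                      treatment = NULL, response = "value",
                                      random = c("family", "replicate",
                                                 "fam_rep", "row", "column")) {
  if (any(components < 0)) {
    stop("restricted_log_likelihood: components must be non-negative",
         call. = FALSE)
  }
  if (!("residual" %in% names(components))) {
    stop("restricted_log_likelihood: components must name 'residual'",
         call. = FALSE)
  }
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  if (!is.null(treatment)) {
    data <- data[data$treatment == treatment, , drop = FALSE]
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (!("replicate" %in% names(data))) data$replicate <- 1L
  random <- intersect(intersect(random, names(components)),
                      c("family", "replicate", "fam_rep", "row", "column"))
  bt <- suppressWarnings(build_random_terms(data, random))
  Z <- bt$Z
  G <- lapply(Z, tcrossprod)
  s2 <- c(unname(components[names(Z)]), components[["residual"]])
  ev <- reml_eval(data[[response]], G, s2)
  if (is.null(ev)) {
    stop("restricted_log_likelihood: total covariance is singular at these components",
         call. = FALSE)
  }
  ev$ll
}

#' One-sided Wald significance for a variance component
#'
#' A component is flagged significant when the one-sided normal tail
#' probability of `estimate / se` is at most 0.05. With a missing standard
#' error (component pinned at the zero boundary) the flag is `NA`
#' (not assessable).
#'
#' @param estimate,se Component estimate(s) and standard error(s);
#'   vectorised.
#' @param alpha Significance level (default 0.05).
#' @return Logical vector (with `NA` where `se` is missing).
#' @examples
#' wald_significance(13.5, 2.5)
#' @export
wald_significance <- function(estimate, se, alpha = 0.05) {
  ifelse(is.na(se) | se <= 0, NA,
         pnorm(estimate / se, lower.tail = FALSE) <= alpha)
}
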