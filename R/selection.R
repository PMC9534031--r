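#' Standardised selection intensity from a selection pressure
#'
#' Infinite-population truncation selection on a standard normal trait:
#' `k = dnorm(z) / p` with `z` the upper-`p` quantile. Strictly decreasing
#' in `p`, tending to 0 as `p` tends to 1. The classical breeders'-table
#' values 2.06, 1.76 and 1.40 correspond to 5, 10 and 20% pressure.
#'
#' @param p Selection pressure(s), proportion selected in (0, 1);
#'   vectorised.
#' @return Selection intensity `k`.
#' @examples
#' selection_intensity(c(0.05, 0.10, 0.20))
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("selection_intensity: p must lie strictly in (0, 1)", call. = FALSE)
  }
  z <- qnorm(p, lower.tail = FALSE)
  dnorm(z) / p
}

#' Phenotypic standard deviation among half-sib family means
#'
#' `sigma_PF = sqrt(sigma_f2 + sigma_fr2 / n_rep + sigma_e2 / n_rep)`, the
#' denominator of the among-family genetic-gain prediction.
#'
#' @inheritParams narrow_sense_heritability
#' @return Standard deviation in trait units.
#' @examples
#' family_phenotypic_sd(13.5, 4.7, 49.6, 2)
#' @export
family_phenotypic_sd <- function(sigma_f2, sigma_fr2, sigma_e2, n_rep) {
  if (any(c(sigma_f2, sigma_fr2, sigma_e2) < 0) || n_rep < 1) {
    stop("family_phenotypic_sd: components must be >= 0 and n_rep >= 1",
         call. = FALSE)
  }
  sqrt(sigma_f2 + sigma_fr2 / n_rep + sigma_e2 / n_rep)
}

#' A selection plan: pressure, intensity, parental control, weights
#'
#' @param pressure Proportion of families selected, in (0, 1).
#' @param intensity Standardised selection differential `k`; computed from
#'   `pressure` by [selection_intensity()] when omitted.
#' @param parental_control Parental control factor `c` in (0, 1]; 0.5 for
#'   half-sib families (only the maternal parent is selected).
#' @param weights Economic (or desired-gain) weight vector for index
#'   selection; default equal weights for two traits.
#' @return A list of class `selection_plan`.
#' @export
selection_plan <- function(pressure, intensity = NULL, parental_control = 0.5,
                           weights = c(1, 1)) {
  if (pressure <= 0 || pressure >= 1) {
    stop("selection_plan: pressure must lie in (0, 1)", call. = FALSE)
  }
  if (parental_control <= 0 || parental_control > 1) {
    stop("selection_plan: parental_control must lie in (0, 1]", call. = FALSE)
  }
  k <- intensity %||% selection_intensity(pressure)
  if (k < 0) stop("selection_plan: intensity must be >= 0", call. = FALSE)
  structure(list(pressure = pressure, intensity = k,
                 parental_control = parental_control, weights = weights),
            class = "selection_plan")
}

#' Predicted genetic gain per cycle under among-family selection
#'
#' Breeder's equation for among half-sib family selection:
#' `dG = k * c * sigma_f2 / sigma_PF`. The family variance component of a
#' half-sib analysis already equals one quarter of the total additive
#' variance, so it enters directly. Linear in `k` and, at fixed `sigma_PF`,
#' in `sigma_f2`.
#'
#' @param plan A [selection_plan()].
#' @param sigma_f2 Family additive variance component (squared trait units).
#' @param sigma_pf Phenotypic standard deviation among family means
#'   ([family_phenotypic_sd()]); must be positive.
#' @param trait_mean Trait mean used to express the gain as a percentage;
#'   must be non-zero.
#' @return Data frame with `pressure`, `k`, `dG` (trait units per cycle)
#'   and `dG_percent` (percent of the absolute mean).
#' @examples
#' predicted_gain(selection_plan(0.05), 13.5,
#'                family_phenotypic_sd(13.5, 4.7, 49.6, 2), 11.4)
#' @export
predicted_gain <- function(plan, sigma_f2, sigma_pf, trait_mean) {
  stopifnot(inherits(plan, "selection_plan"))
  if (sigma_pf <= 0) {
    stop("predicted_gain: sigma_pf must be positive (degenerate population)",
         call. = FALSE)
  }
  if (trait_mean == 0) {
    stop("predicted_gain: trait_mean must be non-zero", call. = FALSE)
  }
  dg <- plan$intensity * plan$parental_control * sigma_f2 / sigma_pf
  data.frame(pressure = plan$pressure, k = plan$intensity, dG = dg,
             dG_percent = 100 * dg / abs(trait_mean))
}

#' Smith-Hazel selection-index coefficients
#'
#' Solves `P b = A w` for the index coefficients `b`, where `P` holds the
#' phenotypic (co)variances among family means, `A` the additive genetic
#' (co)variances and `w` the economic (or desired-gain) weights. The
#' returned solution satisfies `||P b - A w|| / ||A w|| < 1e-8`.
#'
#' @param P Symmetric positive-definite phenotypic covariance matrix.
#' @param A Symmetric additive covariance matrix, same dimension.
#' @param w Weight vector, length `ncol(P)`.
#' @return Coefficient vector `b`.
#' @examples
#' smith_hazel_coefficients(matrix(c(4, 1, 1, 2), 2),
#'                          matrix(c(2, 0.5, 0.5, 1), 2), c(1, 1))
#' @export
smith_hazel_coefficients <- function(P, A, w) {
  P <- as.matrix(P); A <- as.matrix(A); w <- as.numeric(w)
  if (!isTRUE(all.equal(P, t(P))) || !isTRUE(all.equal(A, t(A)))) {
    stop("smith_hazel_coefficients: P and A must be symmetric", call. = FALSE)
  }
  if (ncol(P) != length(w) || !all(dim(P) == dim(A))) {
    stop("smith_hazel_coefficients: dimension mismatch", call. = FALSE)
  }
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) {
    stop("smith_hazel_coefficients: P is not positive-definite",
         call. = FALSE)
  }
  rhs <- A %*% w
  b <- backsolve(ch, forwardsolve(t(ch), rhs))
  resid <- sqrt(sum((P %*% b - rhs)^2))
  scale <- sqrt(sum(rhs^2))
  if (scale > 0 && resid / scale >= 1e-8) {
    stop("smith_hazel_coefficients: linear solve did not reach tolerance",
         call. = FALSE)
  }
  setNames(as.numeric(b), colnames(P))
}

#' Index scores and ranking of families
#'
#' `score(family) = sum_t b_t * value(family, t)`; families are ranked by
#' descending score with ties broken deterministically by family ID.
#' Families with a missing trait value are excluded with a warning.
#'
#' @param b Coefficient vector, one entry per trait column.
#' @param trait_matrix Family x trait matrix of BLUP-adjusted means.
#' @return Data frame `family`, `score`, `rank` (class `index_result`).
#' @export
index_scores <- function(b, trait_matrix) {
  m <- as.matrix(trait_matrix)
  if (length(b) != ncol(m)) {
    stop("index_scores: length(b) must equal the number of traits",
         call. = FALSE)
  }
  fams <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ok <- complete.cases(m)
  if (any(!ok)) {
    warning("families excluded for missing trait values: ",
            paste(fams[!ok], collapse = ", "))
  }
  m <- m[ok, , drop = FALSE]
  fams <- fams[ok]
  score <- drop(m %*% b)
  ord <- order(-score, fams)
  out <- data.frame(family = fams[ord], score = score[ord],
                    rank = seq_along(ord), row.names = NULL)
  class(out) <- c("index_result", class(out))
  out
}

#' Correlated response to selection
#'
#' Expected change in primary trait Y per cycle when selection acts on a
#' secondary (target) trait X:
#' `dGc = k * c * h_X * h_Y * r_A * sigma_PY`, signed by the genetic
#' correlation. With `r_A = 1` and equal square-root heritabilities this
#' reduces to the direct-response form `k * c * h^2 * sigma_PY`.
#'
#' @param plan A [selection_plan()].
#' @param h_x,h_y Square roots of the narrow-sense heritabilities of the
#'   target and primary traits, in `[0, 1]`.
#' @param r_a Additive genetic correlation between the traits, in
#'   `[-1, 1]`.
#' @param sigma_py Among-family phenotypic standard deviation of the
#'   primary trait (>= 0).
#' @return Correlated response in primary-trait units per cycle.
#' @export
correlated_response <- function(plan, h_x, h_y, r_a, sigma_py) {
  stopifnot(inherits(plan, "selection_plan"))
  if (h_x < 0 || h_x > 1 || h_y < 0 || h_y > 1) {
    stop("correlated_response: h_x and h_y must lie in [0, 1]", call. = FALSE)
  }
  if (abs(r_a) > 1) {
    stop("correlated_response: |r_a| must be <= 1", call. = FALSE)
  }
  if (sigma_py < 0) {
    stop("correlated_response: sigma_py must be >= 0", call. = FALSE)
  }
  plan$intensity * plan$parental_control * h_x * h_y * r_a * sigma_py
}

#' Select the top fraction of families
#'
#' Picks the `ceiling(p * n)` families with the highest values;
#' deterministic tie-break by family ID (with a warning when the cut falls
#' inside a tie).
#'
#' @param values Named numeric vector, names are family IDs.
#' @param p Selection pressure in (0, 1].
#' @return Character vector of selected family IDs, best first.
#' @export
select_top <- function(values, p) {
  if (!length(values)) stop("select_top: empty input", call. = FALSE)
  if (p <= 0 || p > 1) stop("select_top: p must lie in (0, 1]", call. = FALSE)
  fams <- names(values) %||% as.character(seq_along(values))
  m <- ceiling(p * length(values))
  ord <- order(-values, fams)
  if (m < length(values) && values[ord[m]] == values[ord[m + 1]]) {
    warning("select_top: tie at the selection boundary broken by family ID")
  }
  fams[ord[seq_len(m)]]
}

#' Overlap among named family selections
#'
#' Pairwise and overall intersections of two or more selected-family sets,
#' e.g. single-trait selections vs a Smith-Hazel index selection.
#'
#' @param sets Named list (length >= 2) of character vectors of family IDs.
#' @return List with `sizes`, `pairwise` (data frame `set_a`, `set_b`,
#'   `overlap`), `pairwise_members`, `common` (families in every set), and
#'   `unique` (families found in exactly one set, per set).
#' @export
selection_overlap <- function(sets) {
  if (length(sets) < 2) {
    stop("selection_overlap: need at least 2 sets", call. = FALSE)
  }
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  names(sets) <- nm
  pairs <- utils::combn(nm, 2)
  members <- list()
  pw <- data.frame(set_a = pairs[1, ], set_b = pairs[2, ],
                   overlap = NA_integer_)
  for (i in seq_len(ncol(pairs))) {
    ab <- intersect(sets[[pairs[1, i]]], sets[[pairs[2, i]]])
    pw$overlap[i] <- length(ab)
    members[[paste(pairs[, i], collapse = ":")]] <- ab
  }
  common <- Reduce(intersect, sets)
  all_ids <- unlist(sets, use.names = FALSE)
  uniq <- lapply(sets, function(s) {
    s[vapply(s, function(id) sum(all_ids == id) == 1L, logical(1))]
  })
  list(sizes = vapply(sets, length, integer(1)), pairwise = pw,
       pairwise_members = members, common = common, unique = uniq)
}
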