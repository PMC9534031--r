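#' Hierarchical clustering of family trait profiles
#'
#' Agglomerative clustering of entries (families, or family x treatment
#' combinations) on their multi-trait profiles, using squared Euclidean
#' distance as the dissimilarity and Ward's minimum-variance linkage, the
#' natural companion of that dissimilarity. Columns are standardised to
#' zero mean and unit variance by default because traits carry
#' incommensurate units (mg, percent, ratio). Assignments are invariant to
#' the row order of the input.
#'
#' @param x Entry x trait numeric matrix (rownames identify entries).
#' @param k Number of groups to cut the merge tree into; `1 <= k <= n`.
#' @param standardize Standardise columns first (default `TRUE`).
#' @param k_max Largest group count for which the within-group sum of
#'   squares path is reported (for the Hartigan rule).
#' @return An object of class `cluster_result`: `assignments` (named
#'   integer vector), `k`, `wss` (within-group sum of squares for
#'   `1..k_max` groups, on the standardised scale), `tree` (the `hclust`
#'   object) and `sizes`.
#' @export
hierarchical_cluster <- function(x, k, standardize = TRUE,
                                 k_max = min(nrow(x) - 1L, 15L)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("hierarchical_cluster: need at least 2 entries",
                  call. = FALSE)
  if (k > n) stop("hierarchical_cluster: k cannot exceed the entry count",
                  call. = FALSE)
  xs <- if (standardize) standardize_columns(x) else x
  d2 <- dist(xs)^2
  tree <- hclust(d2, method = "ward.D")
  assignments <- cutree(tree, k = k)
  k_max <- max(1L, min(k_max, n))
  wss <- vapply(seq_len(k_max), function(kk) {
    cluster_wss(xs, cutree(tree, k = kk))
  }, numeric(1))
  structure(list(assignments = assignments, k = k, wss = wss, tree = tree,
                 sizes = as.integer(table(assignments))),
            class = "cluster_result")
}

standardize_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1  # constant column: centred only
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# total within-group sum of squares of a partition
cluster_wss <- function(x, assignments) {
  sum(vapply(split(seq_len(nrow(x)), assignments), function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

#' Optimal group count by the Hartigan rule
#'
#' Given a non-increasing within-group sum-of-squares path `W_1, W_2, ...`,
#' the Hartigan statistic `H(k) = (n - k - 1) * (W_k / W_{k+1} - 1)`
#' measures the gain from splitting `k` groups into `k + 1`. The optimal
#' count is the smallest `k` with `H(k) <= threshold` (classically 10):
#' the first `k` at which the next split is no longer worthwhile.
#'
#' @param wss Numeric vector of within-group sums of squares for 1, 2, ...
#'   groups (length >= 2), or a `cluster_result`.
#' @param n Number of entries (taken from the `cluster_result` when one is
#'   supplied).
#' @param threshold Stopping threshold, default 10.
#' @return The optimal group count (integer).
#' @export
hartigan_optimal_k <- function(wss, n = NULL, threshold = 10) {
  if (inherits(wss, "cluster_result")) {
    n <- n %||% length(wss$assignments)
    wss <- wss$wss
  }
  if (length(wss) < 2) {
    stop("hartigan_optimal_k: need the sum-of-squares path for at least 2 group counts",
         call. = FALSE)
  }
  if (is.null(n)) stop("hartigan_optimal_k: n is required", call. = FALSE)
  if (any(diff(wss) > 1e-8 * max(wss, 1))) {
    stop("hartigan_optimal_k: wss must be non-increasing in k", call. = FALSE)
  }
  for (k in seq_len(length(wss) - 1L)) {
    h <- if (wss[k + 1L] <= 0) {
      if (wss[k] <= 0) 0 else Inf
    } else {
      (n - k - 1) * (wss[k] / wss[k + 1L] - 1)
    }
    if (h <= threshold) return(k)
  }
  length(wss)
}

#' PCA biplot coordinates for a family-by-trait matrix
#'
#' Principal components of the column correlation matrix (columns are
#' centred and scaled to unit variance by default): entry scores, trait
#' loadings, and per-component variance proportions which sum to one over
#' all components. Angles between loading vectors reflect the trait
#' correlation structure (acute for positive correlations). Constant
#' columns are excluded with a warning.
#'
#' @param x Entry x trait numeric matrix with at least 2 rows and columns.
#' @param standardize Scale columns to unit variance (correlation-matrix
#'   PCA, default) or only centre them.
#' @return An object of class `biplot_result`: `scores`, `loadings`,
#'   `variance_proportions`, `sdev`.
#' @export
pca_biplot <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("pca_biplot: need at least 2 entries and 2 traits", call. = FALSE)
  }
  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    warning("constant column(s) excluded from PCA: ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) < 2) stop("pca_biplot: fewer than 2 varying traits",
                          call. = FALSE)
  }
  pr <- prcomp(x, center = TRUE, scale. = standardize)
  prop <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation,
                 variance_proportions = prop, sdev = pr$sdev),
            class = "biplot_result")
}

#' @export
print.biplot_result <- function(x, ...) {
  pc <- x$variance_proportions
  cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance (%d components)\n",
              100 * pc[1], 100 * pc[min(2, length(pc))], length(pc)))
  invisible(x)
}

#' Pattern analysis: clustering plus PCA of a BLUP trait matrix
#'
#' Convenience wrapper chaining [hierarchical_cluster()], the Hartigan
#' choice of group count, and [pca_biplot()] on the same standardised
#' matrix, so group memberships can be superimposed on the biplot.
#'
#' @inheritParams hierarchical_cluster
#' @param k Group count; chosen by [hartigan_optimal_k()] when `NULL`.
#' @param threshold Hartigan stopping threshold.
#' @return List with `clusters` (a `cluster_result`), `k`, and `pca` (a
#'   `biplot_result`).
#' @export
pattern_analysis <- function(x, k = NULL, standardize = TRUE, threshold = 10,
                             k_max = min(nrow(x) - 1L, 15L)) {
  probe <- hierarchical_cluster(x, k = 1L, standardize = standardize,
                                k_max = k_max)
  if (is.null(k)) {
    k <- hartigan_optimal_k(probe$wss, n = nrow(x), threshold = threshold)
  }
  clusters <- hierarchical_cluster(x, k = k, standardize = standardize,
                                   k_max = k_max)
  list(clusters = clusters, k = k, pca = pca_biplot(x, standardize))
}
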