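# Alpha diversity, principal component analysis and the PC-vs-diversity
# correlation linking host genotype structure to microbiome diversity.

#' Simpson alpha diversity of one sample
#'
#' Computes the Gini-Simpson index 1 - sum(p_i^2) of a relative-abundance
#' vector (higher = more diverse). The vector is renormalized to sum one, so
#' the index is invariant to rescaling by any positive constant.
#'
#' @param abundances non-negative abundance vector with positive sum.
#' @param type `"gini-simpson"` (default, 1 - D), `"simpson"` (D =
#'   sum(p_i^2)) or `"inverse"` (1/D).
#' @return diversity value.
#' @export
simpson_alpha <- function(abundances, type = c("gini-simpson", "simpson",
                                               "inverse")) {
  type <- match.arg(type)
  x <- as.numeric(abundances)
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative and non-missing")
  s <- sum(x)
  if (s <= 0) stop("abundance vector sums to zero")
  p <- x / s
  d <- sum(p^2)
  switch(type, "gini-simpson" = 1 - d, simpson = d, inverse = 1 / d)
}

#' Per-sample alpha diversity of an abundance table
#'
#' @param table samples x features abundance matrix.
#' @inheritParams simpson_alpha
#' @return named vector of per-sample diversities.
#' @export
alpha_diversity <- function(table, type = "gini-simpson") {
  x <- .check_feature_matrix(table, "abundance table")
  apply(x, 1, simpson_alpha, type = type)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Columns are centered (optionally unit-variance scaled); constant columns
#' are dropped. Components are the eigenvectors of the covariance of the
#' centered matrix; each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x samples x features numeric matrix (>= 2 samples).
#' @param n_components number of components to retain (default: all).
#' @param scale. unit-variance scale columns before the decomposition.
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance` (per-component
#'   variances, non-increasing, summing to the total variance of the centered
#'   matrix).
#' @export
pca <- function(x, n_components = NULL, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  keep <- apply(x, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) stop("all features are constant")
  x <- x[, keep, drop = FALSE]
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components %||% ncol(fit$rotation), ncol(fit$rotation))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = fit$sdev^2,
                 total_variance = sum(apply(scale(x, scale = scale.,
                                                  center = TRUE), 2,
                                            stats::var))),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components retained\n")
  cat("variance explained (%):",
      paste0(round(100 * ev[seq_len(min(5, length(ev)))] / sum(ev), 1),
             collapse = ", "), "...\n")
  invisible(x)
}

#' Correlate a principal component with a per-sample quantity
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value; the
#' Pearson p-value is the t-test on n - 2 degrees of freedom.
#'
#' @param scores_component per-sample component scores.
#' @param values per-sample values (e.g. alpha diversity), same order.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`.
#' @export
pc_correlation <- function(scores_component, values,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(scores_component); y <- as.numeric(values)
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
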