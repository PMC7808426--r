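# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (genotypes, abundance tables, per-trio permutations, ...) use seeds derived
#' deterministically from the root via a fixed affine map modulo 2^31 - 1, so
#' that any component is independently reproducible.
#'
#' @param root integer root seed.
#' @param k integer stream index (>= 0).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(root, k) {
  stopifnot(is.numeric(root), length(root) == 1L, is.numeric(k), length(k) == 1L)
  as.integer((abs(as.numeric(root)) * 48271 + as.numeric(k) * 104729) %% 2147483647)
}

# Orthonormal basis of the column span of cbind(1, Z); Z may be NULL.
.q_basis <- function(n, Z = NULL) {
  X <- cbind(rep(1, n), Z)
  qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
}

# Residualize columns of x (vector or matrix) against an orthonormal basis Q.
.resid_q <- function(x, Q) {
  x <- as.matrix(x)
  x - Q %*% crossprod(Q, x)
}

# t-test for the coefficient on x in y ~ x + Z (+ intercept), via
# Frisch-Waugh-Lovell partialling. Returns beta, se, t, p, df, n.
# Identical (to numerical precision) to the corresponding full OLS fit.
.ols_coef_test <- function(y, x, Z = NULL) {
  n <- length(y)
  Q <- .q_basis(n, Z)
  k <- ncol(Q)                       # intercept + covariates
  df <- n - k - 1L
  if (df < 1L) stop("not enough samples for the regression: n = ", n,
                    ", parameters = ", k + 1L)
  ex <- drop(.resid_q(x, Q))
  ey <- drop(.resid_q(y, Q))
  sxx <- sum(ex^2)
  if (sxx < .Machine$double.eps * n) {
    stop("predictor is constant (or collinear with covariates)")
  }
  beta <- sum(ex * ey) / sxx
  rss <- sum(ey^2) - beta^2 * sxx
  rss <- max(rss, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = beta, se = se, t = tstat, p = p, df = df, n = n)
}

# Covariate data.frame -> numeric matrix with columns age, sex.
.covariate_matrix <- function(covariates, samples = NULL) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) return(covariates)
  stopifnot(is.data.frame(covariates))
  df <- covariates
  if (!is.null(samples)) {
    idx <- match(samples, df$sample_id)
    if (anyNA(idx)) {
      stop("samples missing from covariate table: ",
           paste(samples[is.na(idx)], collapse = ", "))
    }
    df <- df[idx, , drop = FALSE]
  }
  sex <- df$sex
  if (!is.numeric(sex)) sex <- as.numeric(factor(sex)) - 1
  cbind(age = as.numeric(df$age), sex = sex)
}

# Validate a samples x features numeric matrix with rownames.
.check_feature_matrix <- function(x, what = "feature table") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x))) stop(what, " must have sample ids as rownames")
  x
}

# Default per-kind measurement transforms used by the association and CIT
# screens, so upstream hits and downstream mediation tests see identical data.
.transform_feature <- function(x, kind = c("species", "pathways", "metabolites",
                                           "cytokines", "identity")) {
  kind <- match.arg(kind)
  switch(kind,
    species = ,
    pathways = log10(x + 1e-6),
    cytokines = {
      if (any(x <= 0)) stop("cytokine values must be positive for log transform; ",
                            "configure an offset for zero measurements")
      log(x)
    },
    metabolites = {
      lx <- log10(x)
      if (is.matrix(lx)) scale(lx)[, , drop = FALSE] else as.numeric(scale(lx))
    },
    identity = x
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    na.strings = ".", stringsAsFactors = FALSE)
}
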