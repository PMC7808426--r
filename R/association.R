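# Pairwise screens: covariate-adjusted linear regression of features on
# genotype dosage, Benjamini-Hochberg FDR, Spearman correlation matrices,
# Mann-Whitney differential cytokines, and the PLS-DA VIP / t-test /
# fold-change differential-metabolite rule.

#' Covariate-adjusted association of one feature with one variant
#'
#' Ordinary least squares of the (optionally transformed) feature on
#' [intercept, dosage, age, sex]; the reported p-value is the two-sided
#' t-test on the dosage coefficient (n - 4 degrees of freedom with both
#' covariates).
#'
#' @param genotype per-sample dosage vector (0/1/2; carrier coding works
#'   equally).
#' @param feature per-sample feature values.
#' @param covariates data.frame with `sample_id`, `age`, `sex` (or a numeric
#'   matrix), aligned with the vectors.
#' @param transform measurement-scale transform applied to the feature before
#'   regression: one of `"identity"`, `"species"`/`"pathways"`
#'   (log10(x + 1e-6)), `"cytokines"` (natural log), `"metabolites"`
#'   (autoscaled log10 intensity).
#' @return one-row data.frame: beta, se, t_stat, p, df, n, skipped, reason.
#'   A constant genotype is skipped (NA statistics) rather than an error so
#'   screens can proceed.
#' @export
adjusted_regression <- function(genotype, feature, covariates = NULL,
                                transform = "identity") {
  g <- as.numeric(genotype)
  n <- length(g)
  if (length(feature) != n) stop("genotype and feature differ in length")
  if (n < 5) stop("need at least 5 samples")
  if (stats::var(g) == 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                      p = NA_real_, df = NA_integer_, n = n, skipped = TRUE,
                      reason = "constant_genotype", stringsAsFactors = FALSE))
  }
  y <- .transform_feature(as.numeric(feature), transform)
  Z <- .covariate_matrix(covariates)
  if (!is.null(Z)) {
    X <- cbind(dosage = g, Z)
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L
      stop("rank-deficient design; collinear columns: ",
           paste(colnames(X)[drop_idx], collapse = ", "))
    }
  }
  fit <- .ols_coef_test(y, g, Z)
  data.frame(beta = fit$beta, se = fit$se, t_stat = fit$t, p = fit$p,
             df = fit$df, n = n, skipped = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values q_(i) = min_{j >= i} m p_(j) / j, mapped back to
#' input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen every variant against every feature with covariate adjustment
#'
#' Runs [adjusted_regression()] for each (variant, feature) pair and applies
#' [bh_adjust()] across the whole screen family (one family per call, i.e.
#' per feature-table kind).
#'
#' @param genotypes samples x variants dosage matrix.
#' @param features samples x features table (same sample order).
#' @param covariates covariate data.frame.
#' @param transform feature transform, see [adjusted_regression()].
#' @return data.frame snv_id, feature_id, beta, se, t_stat, p, q, significant
#'   rows for skipped pairs are omitted (their count is attached as the
#'   `n_skipped` attribute).
#' @export
association_screen <- function(genotypes, features, covariates = NULL,
                               transform = "identity") {
  G <- .check_feature_matrix(genotypes, "genotype matrix")
  FT <- .check_feature_matrix(features, "feature table")
  if (!identical(rownames(G), rownames(FT))) {
    stop("genotype and feature tables must share the same samples in order")
  }
  Z <- .covariate_matrix(covariates, rownames(G))
  n <- nrow(G)
  Q <- .q_basis(n, Z)
  df <- n - ncol(Q) - 1L
  Y <- apply(FT, 2, function(col) .transform_feature(col, transform))
  EY <- .resid_q(Y, Q)
  EG <- .resid_q(G, Q)
  ok <- colSums(EG^2) > .Machine$double.eps * n
  res <- vector("list", sum(ok))
  k <- 0L
  for (j in which(ok)) {
    ex <- EG[, j]
    sxx <- sum(ex^2)
    beta <- colSums(ex * EY) / sxx
    rss <- pmax(colSums(EY^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / df / sxx)
    tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    p <- 2 * stats::pt(-abs(tstat), df)
    k <- k + 1L
    res[[k]] <- data.frame(snv_id = colnames(G)[j], feature_id = colnames(FT),
                           beta = beta, se = se, t_stat = tstat, p = p,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res) %||%
    data.frame(snv_id = character(0), feature_id = character(0),
               beta = numeric(0), se = numeric(0), t_stat = numeric(0),
               p = numeric(0))
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  attr(out, "n_skipped") <- sum(!ok) * ncol(FT)
  out
}

# Exact two-sided Mann-Whitney p-value. Without ties, uses the exact null
# distribution of U (dwilcox); with ties, enumerates all assignments of the
# midranks to the first group. Two-sided via symmetric distance from mn/2.
.mw_exact_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  d <- abs(u - mu) - 1e-9
  if (!anyDuplicated(c(x, y))) {
    us <- 0:(m * n)
    sum(stats::dwilcox(us[abs(us - mu) >= d], m, n))
  } else {
    combos <- utils::combn(m + n, m)
    usum <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    mean(abs(usum - mu) >= d)
  }
}

# Normal approximation with midrank tie correction and continuity correction.
.mw_approx_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - m * n / 2 - sign(u - m * n / 2) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mann-Whitney U test between two groups
#'
#' Exact two-sided p-value by full enumeration of rank arrangements when both
#' groups have at most `exact_max` observations, otherwise the normal
#' approximation with midrank tie correction and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max largest group size for which the exact null distribution
#'   is used (default 8).
#' @return list with `U` (statistic of `x`), `p`, `exact`.
#' @export
mannwhitney_u <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  exact <- length(x) <= exact_max && length(y) <= exact_max
  p <- if (exact) .mw_exact_p(x, y) else .mw_approx_p(x, y)
  list(U = u, p = p, exact = exact)
}

#' Differential cytokines by log-scale Mann-Whitney with FDR control
#'
#' Levels are natural-log transformed, each cytokine is tested between groups
#' with [mannwhitney_u()] (the rank test is unaffected by the monotone log,
#' which is retained for the reported fold change and effect direction), and
#' p-values are Benjamini-Hochberg adjusted across the panel. A cytokine is
#' significant iff FDR < `fdr_cut`.
#'
#' @param cytokines samples x cytokines intensity matrix (positive values).
#' @param groups per-sample group labels ("case"/"control"), aligned with the
#'   matrix rows, or a covariate data.frame with `sample_id` and `group`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return data.frame feature_id, stat (U of the case group), p, fdr,
#'   fold_change (case geometric mean / control geometric mean), significant.
#' @export
mannwhitney_diff <- function(cytokines, groups, fdr_cut = 0.05) {
  X <- .check_feature_matrix(cytokines, "cytokine table")
  g <- .group_vector(groups, rownames(X))
  if (!any(g == "case") || !any(g == "control")) {
    stop("both groups must be non-empty")
  }
  if (ncol(X) == 0) {
    return(data.frame(feature_id = character(0), stat = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      fold_change = numeric(0), significant = logical(0)))
  }
  if (any(X <= 0)) {
    stop("cytokine values must be positive for the log transform; ",
         "add a measurement offset to zero values before calling")
  }
  L <- log(X)
  res <- lapply(colnames(L), function(id) {
    mw <- mannwhitney_u(L[g == "case", id], L[g == "control", id])
    data.frame(feature_id = id, stat = mw$U, p = mw$p,
               fold_change = exp(mean(L[g == "case", id]) -
                                   mean(L[g == "control", id])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cut
  out[, c("feature_id", "stat", "p", "fdr", "fold_change", "significant")]
}

.group_vector <- function(groups, samples) {
  if (is.data.frame(groups)) {
    idx <- match(samples, groups$sample_id)
    if (anyNA(idx)) stop("samples missing from covariate table: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    groups <- groups$group[idx]
  }
  g <- as.character(groups)
  if (length(g) != length(samples)) stop("group labels do not match samples")
  if (!all(g %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  g
}

#' Spearman correlation screen between two feature tables
#'
#' Rank correlation (midranks for ties) for every feature pair across shared
#' samples, with two-sided p-values from the t approximation. Constant
#' features yield NA and are excluded from significance marking.
#'
#' @param table_a,table_b samples x features matrices with sample rownames.
#' @return list with matrices `rho` and `p` (rows = features of `table_a`),
#'   and `n`, the number of shared samples.
#' @export
spearman_screen <- function(table_a, table_b) {
  A <- .check_feature_matrix(table_a, "table_a")
  B <- .check_feature_matrix(table_b, "table_b")
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  A <- A[shared, , drop = FALSE]; B <- B[shared, , drop = FALSE]
  n <- length(shared)
  const_a <- apply(A, 2, function(v) stats::sd(v) == 0)
  const_b <- apply(B, 2, function(v) stats::sd(v) == 0)
  RA <- apply(A, 2, rank); RB <- apply(B, 2, rank)
  rho <- suppressWarnings(stats::cor(RA, RB))
  rho[const_a, ] <- NA; rho[, const_b] <- NA
  rc <- pmin(pmax(rho, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rc) >= 1 - 1e-12 & !is.na(rc)] <- 0
  list(rho = rho, p = p, n = n)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a NIPALS partial-least-squares regression of the centered binary
#' group code on the autoscaled feature matrix and returns per-feature VIP
#' scores
#' \deqn{VIP_j = \sqrt{p \sum_a w_{ja}^2 SSY_a / \sum_a SSY_a}}
#' with p the feature count, w the (unit-norm) loading weights and SSY_a the
#' response variance captured by component a. By construction the VIP squares
#' average to one over features.
#'
#' @param features samples x features matrix (intensities; transform upstream
#'   if desired — autoscaling to zero mean / unit variance happens here).
#' @param groups group labels or covariate data.frame (see
#'   [mannwhitney_diff()]).
#' @param n_components number of PLS components (default 2; reduced
#'   automatically if the response is exhausted first).
#' @param max_iter iteration cap per component for the NIPALS loop.
#' @return list with `vip` (named vector), `weights`, `scores`,
#'   `ssy` (per-component explained response variance), `n_components`.
#' @export
plsda_vip <- function(features, groups, n_components = 2, max_iter = 500) {
  X0 <- .check_feature_matrix(features, "feature table")
  g <- .group_vector(groups, rownames(X0))
  if (sum(g == "case") < 2 || sum(g == "control") < 2) {
    stop("need at least 2 samples per group")
  }
  sds <- apply(X0, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant features cannot be autoscaled: ",
         paste(colnames(X0)[sds == 0], collapse = ", "))
  }
  X <- scale(X0)
  y <- as.numeric(g == "case")
  y <- y - mean(y)
  p <- ncol(X)
  A <- min(n_components, p, nrow(X) - 1L)
  W <- matrix(0, p, A)
  Tm <- matrix(0, nrow(X), A)
  ssy <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12) break  # response exhausted
    # NIPALS (converges immediately for a univariate response; the loop
    # guards the general case)
    for (it in seq_len(max_iter)) {
      w <- w / nw
      t_ <- drop(X %*% w)
      q <- sum(y * t_) / sum(t_^2)
      u <- y / q
      w_new <- drop(crossprod(X, u))
      nw_new <- sqrt(sum(w_new^2))
      if (nw_new < 1e-12) break
      delta <- sqrt(sum((w_new / nw_new - w)^2))
      w <- w_new; nw <- nw_new
      if (delta < 1e-12) break
      if (it == max_iter) stop("NIPALS failed to converge for component ", a)
    }
    w <- w / sqrt(sum(w^2))
    t_ <- drop(X %*% w)
    tt <- sum(t_^2)
    p_load <- drop(crossprod(X, t_)) / tt
    q <- sum(y * t_) / tt
    X <- X - tcrossprod(t_, p_load)
    y <- y - t_ * q
    a_used <- a
    W[, a] <- w; Tm[, a] <- t_; ssy[a] <- q^2 * tt
  }
  if (a_used == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  ssy <- ssy[seq_len(a_used)]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X0)
  list(vip = vip, weights = W, scores = Tm[, seq_len(a_used), drop = FALSE],
       ssy = ssy, n_components = a_used)
}

#' Differential metabolites by the VIP / t-test / fold-change rule
#'
#' A metabolite is significant iff its PLS-DA VIP exceeds `vip_cut`, the
#' Welch t-test on log10 intensities gives p < `p_cut`, and the raw-scale
#' fold change (case mean / control mean) exceeds `fc_cut` (or, in the
#' default two-sided reading, falls below 1/`fc_cut` for depleted
#' metabolites).
#'
#' @param metabolites samples x metabolites raw intensity matrix (positive).
#' @param groups group labels or covariate data.frame.
#' @param vip_cut,p_cut,fc_cut the three rule thresholds (defaults 1, 0.05,
#'   1.5).
#' @param fc_mode `"two_sided"` (default) also admits FC < 1/`fc_cut`;
#'   `"greater"` applies the literal FC > `fc_cut` only.
#' @param n_components PLS components for the VIP.
#' @return data.frame feature_id, stat (Welch t), p, fdr (BH across the
#'   panel, reported for reference; the rule itself uses raw p), fold_change,
#'   vip, significant. Metabolites with an undefined fold change (zero
#'   control mean) are flagged via `fc_defined` and never significant.
#' @export
differential_metabolites <- function(metabolites, groups, vip_cut = 1,
                                     p_cut = 0.05, fc_cut = 1.5,
                                     fc_mode = c("two_sided", "greater"),
                                     n_components = 2) {
  fc_mode <- match.arg(fc_mode)
  X <- .check_feature_matrix(metabolites, "metabolite table")
  g <- .group_vector(groups, rownames(X))
  if (any(X < 0)) stop("metabolite intensities must be non-negative")
  vips <- plsda_vip(log10(X + 1e-12), g, n_components = n_components)$vip
  case <- g == "case"
  res <- lapply(colnames(X), function(id) {
    lt <- stats::t.test(log10(X[case, id] + 1e-12),
                        log10(X[!case, id] + 1e-12))  # Welch by default
    cm <- mean(X[case, id]); km <- mean(X[!case, id])
    fc <- if (km > 0) cm / km else NA_real_
    data.frame(feature_id = id, stat = unname(lt$statistic), p = lt$p.value,
               fold_change = fc, vip = unname(vips[id]),
               fc_defined = km > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  fc_hit <- !is.na(out$fold_change) &
    (out$fold_change > fc_cut |
       (fc_mode == "two_sided" & out$fold_change < 1 / fc_cut))
  out$significant <- out$fc_defined & out$vip > vip_cut & out$p < p_cut & fc_hit
  out[, c("feature_id", "stat", "p", "fdr", "fold_change", "vip",
          "fc_defined", "significant")]
}
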