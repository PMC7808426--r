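# Four-condition causal inference test for variant -> microbe -> metabolite
# trios, and the directional classification built from running it in both
# orientations.

#' Four-condition causal inference test for one trio
#'
#' Tests whether a mediator M transmits the effect of a genetic variant L to
#' an outcome T. The four component conditions, each adjusted for the
#' supplied covariates, are:
#' \enumerate{
#'   \item L and M are associated (t/F test for L in M ~ L + covariates);
#'   \item L remains associated with M after adjusting for T;
#'   \item M is associated with T after adjusting for L;
#'   \item L is independent of T given M.
#' }
#' The trio p-value is the maximum of the four component p-values, so all
#' four conditions must hold for a small `p_cit`.
#'
#' Condition 4 is an equivalence-type permutation test: surrogate outcomes
#' are built as the fitted marginal regression T ~ L + covariates plus
#' permuted residuals — datasets in which the entire observed marginal L-T
#' association is direct rather than mediated — and
#' `p4 = (1 + #\{F_b <= F_obs\}) / (B + 1)` where F is the statistic for L in
#' T ~ L + M + covariates. Under a genuine chain the conditional statistic
#' collapses while the surrogates keep the full marginal effect, so p4 is
#' small; under pleiotropy the conditional effect matches the marginal one
#' and p4 stays large. `method = "naive"` instead reports one minus the
#' parametric p-value of the conditional F test.
#'
#' @param L per-sample genotype dosage (non-constant).
#' @param M per-sample mediator values (transformed upstream).
#' @param T_ per-sample outcome values (transformed upstream).
#' @param covariates covariate data.frame or numeric matrix (or NULL).
#' @param n_perm number of permutations for condition 4 (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param method condition-4 construction: `"equivalence"` (default) or
#'   `"naive"`.
#' @return object of class `trio_result`: p1..p4, `p_cit` (= max of the
#'   four), component statistics, `n`, `n_perm`, `seed`, `method`.
#' @export
cit_test <- function(L, M, T_, covariates = NULL, n_perm = 1000, seed = 1,
                     method = c("equivalence", "naive")) {
  method <- match.arg(method)
  L <- as.numeric(L); M <- as.numeric(M); T_ <- as.numeric(T_)
  n <- length(L)
  if (length(M) != n || length(T_) != n) stop("L, M, T must have equal length")
  if (anyNA(L) || anyNA(M) || anyNA(T_)) stop("missing values not allowed")
  if (stats::var(L) == 0) stop("L is constant")
  if (stats::var(M) == 0 || stats::var(T_) == 0) stop("constant M or T")
  if (n_perm < 100) stop("n_perm must be >= 100")
  Z <- .covariate_matrix(covariates)
  n_cov <- if (is.null(Z)) 0L else ncol(Z)
  if (n < n_cov + 4L) stop("insufficient sample size for the component regressions")
  # canonical sample order: the OLS components are order-invariant anyway,
  # and anchoring the permutation stream to sorted data makes p4 invariant
  # to how the caller happened to order the samples
  ord <- order(L, M, T_)
  L <- L[ord]; M <- M[ord]; T_ <- T_[ord]
  if (!is.null(Z)) Z <- Z[ord, , drop = FALSE]

  t1 <- .ols_coef_test(M, L, Z)                      # (1) M ~ L + cov
  t2 <- .ols_coef_test(M, L, cbind(T_ = T_, Z))      # (2) M ~ L + T + cov
  t3 <- .ols_coef_test(T_, M, cbind(L = L, Z))       # (3) T ~ M + L + cov

  ## (4) L independent of T given M
  Q <- .q_basis(n, cbind(M = M, Z))
  df4 <- n - ncol(Q) - 1L
  eL <- drop(.resid_q(L, Q))
  eT <- drop(.resid_q(T_, Q))
  r_obs <- sum(eL * eT) / sqrt(sum(eL^2) * sum(eT^2))
  F_obs <- r_obs^2 * df4 / (1 - r_obs^2)
  if (method == "naive") {
    p4 <- 1 - 2 * stats::pt(-abs(r_obs * sqrt(df4 / (1 - r_obs^2))), df4)
  } else {
    Xm <- cbind(1, L, Z)
    bm <- qr.coef(qr(Xm), T_)
    bm[is.na(bm)] <- 0
    fit_m <- drop(Xm %*% bm)
    em <- T_ - fit_m
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
    E <- matrix(em[perm], n, n_perm)
    # resid of surrogate T* = fit_m + em[perm] against [1, M, cov]:
    R <- .resid_q(fit_m, Q)[, 1] + .resid_q(E, Q)
    num <- colSums(R * eL)
    den <- sqrt(colSums(R^2) * sum(eL^2))
    rb <- ifelse(den > 0, num / den, 0)
    Fb <- rb^2 * df4 / pmax(1 - rb^2, .Machine$double.eps)
    p4 <- (1 + sum(Fb <= F_obs)) / (n_perm + 1)
  }

  ps <- c(p1 = t1$p, p2 = t2$p, p3 = t3$p, p4 = p4)
  out <- list(p1 = ps[["p1"]], p2 = ps[["p2"]], p3 = ps[["p3"]],
              p4 = ps[["p4"]], p_cit = max(ps),
              stats = c(t1 = t1$t, t2 = t2$t, t3 = t3$t, F4 = F_obs),
              n = n, n_perm = n_perm, seed = seed, method = method)
  stopifnot(out$p_cit == max(out$p1, out$p2, out$p3, out$p4))
  structure(out, class = "trio_result")
}

#' @export
print.trio_result <- function(x, ...) {
  cat(sprintf("trio_result: p1=%.3g p2=%.3g p3=%.3g p4=%.3g -> p_cit=%.3g (n=%d, B=%d)\n",
              x$p1, x$p2, x$p3, x$p4, x$p_cit, x$n, x$n_perm))
  invisible(x)
}

#' Classify trio direction from forward and reverse tests
#'
#' The forward test treats the microbe as mediator and the metabolite as
#' outcome; the reverse test swaps them. At level `alpha`:
#' causal iff only the forward chain is supported, reactive iff only the
#' reverse chain is, independent iff neither, ambiguous iff both.
#'
#' @param forward,reverse `trio_result` objects computed on the same samples.
#' @param alpha significance level (default 0.05).
#' @return one of `"causal"`, `"reactive"`, `"independent"`, `"ambiguous"`.
#' @export
classify_direction <- function(forward, reverse, alpha = 0.05) {
  stopifnot(inherits(forward, "trio_result"), inherits(reverse, "trio_result"))
  if (forward$n != reverse$n) stop("forward and reverse tests used different samples")
  f <- forward$p_cit < alpha
  r <- reverse$p_cit < alpha
  if (f && !r) "causal" else if (!f && r) "reactive"
  else if (!f && !r) "independent" else "ambiguous"
}

#' Screen candidate trios with the causal inference test
#'
#' For every variant-microbe pair surviving the association screen and every
#' differential metabolite, runs [cit_test()] in both orientations and
#' classifies the direction. Mediator and outcome use the same measurement
#' transforms as the association screens, so upstream hits and the mediation
#' test see identical data. Per-trio permutation seeds are derived from the
#' root seed and the trio index, making each trio independently reproducible.
#'
#' @param snv_microbe_hits data.frame with columns `snv_id`, `feature_id`
#'   (microbe) — typically the significant rows of [association_screen()].
#' @param genotypes samples x variants dosage matrix.
#' @param species samples x species relative-abundance matrix.
#' @param metabolites samples x metabolites raw intensity matrix.
#' @param metabolite_ids metabolite ids to test (the differential set).
#' @param covariates covariate data.frame.
#' @param n_perm permutations per condition-4 test.
#' @param seed root seed.
#' @param alpha classification level.
#' @return data.frame sorted by forward `p_cit`: snv_id, microbe_id,
#'   metabolite_id, p1..p4 for both directions, p_cit_forward,
#'   p_cit_reverse, direction, n, n_perm, seed; pairs skipped for constant
#'   inputs are returned in the `skipped` attribute.
#' @export
screen_trios <- function(snv_microbe_hits, genotypes, species, metabolites,
                         metabolite_ids, covariates = NULL, n_perm = 1000,
                         seed = 1, alpha = 0.05) {
  G <- .check_feature_matrix(genotypes, "genotype matrix")
  SP <- .check_feature_matrix(species, "species table")
  MET <- .check_feature_matrix(metabolites, "metabolite table")
  if (!nrow(snv_microbe_hits) || !length(metabolite_ids)) {
    message("trio screen: empty candidate set; nothing to test")
    return(data.frame())
  }
  SPt <- apply(SP, 2, .transform_feature, kind = "species")
  METt <- apply(MET, 2, .transform_feature, kind = "metabolites")
  rownames(SPt) <- rownames(SP); rownames(METt) <- rownames(MET)
  rows <- list(); skipped <- list()
  k <- 0L
  for (i in seq_len(nrow(snv_microbe_hits))) {
    snv <- snv_microbe_hits$snv_id[i]
    mic <- snv_microbe_hits$feature_id[i]
    for (met in metabolite_ids) {
      k <- k + 1L
      L <- G[, snv]; M <- SPt[, mic]; T_ <- METt[, met]
      if (stats::var(M) == 0 || stats::var(T_) == 0 || stats::var(L) == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          snv_id = snv, microbe_id = mic, metabolite_id = met,
          reason = "constant input", stringsAsFactors = FALSE)
        next
      }
      trio_seed <- derive_seed(seed, 100 + k)
      fw <- cit_test(L, M, T_, covariates, n_perm = n_perm, seed = trio_seed)
      rv <- cit_test(L, T_, M, covariates, n_perm = n_perm,
                     seed = derive_seed(trio_seed, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        snv_id = snv, microbe_id = mic, metabolite_id = met,
        p1_fwd = fw$p1, p2_fwd = fw$p2, p3_fwd = fw$p3, p4_fwd = fw$p4,
        p1_rev = rv$p1, p2_rev = rv$p2, p3_rev = rv$p3, p4_rev = rv$p4,
        p_cit_forward = fw$p_cit, p_cit_reverse = rv$p_cit,
        direction = classify_direction(fw, rv, alpha),
        n = fw$n, n_perm = n_perm, seed = trio_seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame()
  if (nrow(out)) out <- out[order(out$p_cit_forward), , drop = FALSE]
  attr(out, "skipped") <- do.call(rbind, skipped) %||% data.frame()
  out
}
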