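test_that("an exact linear relationship gives beta = 2 and vanishing p", {
  set.seed(1)
  g <- rbinom(40, 2, 0.4)
  cov <- data.frame(sample_id = paste0("s", 1:40), age = runif(40, 3, 12),
                    sex = rbinom(40, 1, 0.5), group = "case")
  res <- adjusted_regression(g, 2 * g, cov)
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$p, 1e-15)
})

test_that("regression matches the normal-equations oracle on a 6-sample toy", {
  g <- c(0, 1, 2, 0, 1, 2)
  age <- c(4, 6, 8, 10, 5, 7)
  sex <- c(0, 1, 0, 1, 0, 1)
  y <- c(1.2, 2.5, 3.9, 0.8, 2.2, 4.4)
  X <- cbind(1, g, age, sex)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta_hat
  s2 <- sum(resid^2) / (6 - 4)
  se_hat <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  res <- adjusted_regression(g, y, data.frame(sample_id = paste0("s", 1:6),
                                              age = age, sex = sex,
                                              group = "case"))
  expect_equal(res$beta, beta_hat[2], tolerance = 1e-10)
  expect_equal(res$se, se_hat, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(beta_hat[2] / se_hat), 2), tolerance = 1e-10)
})

test_that("adding c*age to the feature leaves the genotype p untouched", {
  set.seed(2)
  n <- 50
  g <- rbinom(n, 2, 0.3)
  cov <- data.frame(sample_id = paste0("s", 1:n), age = runif(n, 3, 12),
                    sex = rbinom(n, 1, 0.5), group = "case")
  y <- rnorm(n)
  r0 <- adjusted_regression(g, y, cov)
  r1 <- adjusted_regression(g, y + 3.7 * cov$age, cov)
  expect_equal(r0$beta, r1$beta, tolerance = 1e-10)
  expect_equal(r0$p, r1$p, tolerance = 1e-10)
})

test_that("regression p-values are uniform under the null", {
  set.seed(3)
  n <- 40
  cov <- data.frame(sample_id = paste0("s", 1:n), age = runif(n, 3, 12),
                    sex = rbinom(n, 1, 0.5), group = "case")
  ps <- replicate(400, {
    g <- rbinom(n, 2, 0.3)
    while (var(g) == 0) g <- rbinom(n, 2, 0.3)
    adjusted_regression(g, rnorm(n), cov)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("constant genotypes are skipped and collinearity is named", {
  cov <- data.frame(sample_id = paste0("s", 1:10), age = 1:10,
                    sex = rep(0:1, 5), group = "case")
  res <- adjusted_regression(rep(1, 10), rnorm(10), cov)
  expect_true(res$skipped)
  expect_equal(res$reason, "constant_genotype")
  collinear <- cbind(age = 1:10, sex = 2 * (1:10))
  expect_error(adjusted_regression(rbinom(10, 2, 0.5), rnorm(10), collinear),
               "collinear.*(age|sex)")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "missing")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:80, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-14)
  }
})

test_that("the association screen equals per-pair regressions plus family BH", {
  co <- generate_cohort(small_config())
  scr <- association_screen(co$genotypes[, 1:8], co$species[, 1:6],
                            co$covariates, transform = "species")
  expect_equal(nrow(scr), 48)
  i <- which(scr$snv_id == colnames(co$genotypes)[3] &
               scr$feature_id == colnames(co$species)[5])
  single <- adjusted_regression(co$genotypes[, 3], co$species[, 5],
                                co$covariates, transform = "species")
  expect_equal(scr$beta[i], single$beta, tolerance = 1e-10)
  expect_equal(scr$p[i], single$p, tolerance = 1e-10)
  expect_equal(scr$q, bh_adjust(scr$p))
})

test_that("exact Mann-Whitney matches enumeration and rank invariance holds", {
  res <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_true(res$exact)
  same <- mannwhitney_u(c(5, 9, 2), c(5, 9, 2))
  expect_equal(same$p, 1)
  x <- c(0.3, 1.9, 2.2, 0.1); y <- c(1.4, 3.3, 0.7)
  expect_equal(mannwhitney_u(x, y)$U, mannwhitney_u(exp(x), exp(y))$U)
  expect_equal(mannwhitney_u(x, y)$p, enumerate_mw_p(x, y))
  # untied exact agrees with the base distribution function route
  expect_equal(mannwhitney_u(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("large-sample Mann-Whitney matches the corrected normal approximation", {
  set.seed(5)
  x <- round(rnorm(20, 0.4), 1)  # rounding forces ties
  y <- round(rnorm(15), 1)
  res <- mannwhitney_u(x, y)
  expect_false(res$exact)
  expect_equal(res$p, wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("differential cytokines recover the embedded shifts", {
  co <- generate_cohort(small_config(n_case = 26, n_control = 26))
  d <- mannwhitney_diff(co$cytokines, co$covariates)
  truth <- with(co$truth$differential_features,
                feature_id[table_kind == "cytokines"])
  expect_gte(sum(d$feature_id[d$significant] %in% truth), 2)
  expect_equal(sum(d$significant & !d$feature_id %in% truth), 0)
  neg <- co$cytokines; neg[1, 1] <- 0
  expect_error(mannwhitney_diff(neg, co$covariates), "positive")
})

test_that("VIP scores satisfy their algebraic identity and find the signal", {
  set.seed(6)
  g <- rep(c("case", "control"), each = 30)
  X1 <- matrix(rnorm(60), 60, 1,
               dimnames = list(paste0("s", 1:60), "only"))
  expect_equal(unname(plsda_vip(X1, g, n_components = 1)$vip), 1)
  for (i in 1:5) {
    X <- matrix(rnorm(60 * 8), 60, 8,
                dimnames = list(paste0("s", 1:60), paste0("f", 1:8)))
    v <- plsda_vip(X, g)$vip
    expect_equal(mean(v^2), 1, tolerance = 1e-6)
  }
  n <- 200
  g2 <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:10)))
  X[, 4] <- X[, 4] + 2 * (g2 == "case")
  v <- plsda_vip(X, g2)$vip
  expect_equal(names(which.max(v)), "f4")
  expect_gt(v["f4"], 1)
})

test_that("VIP agrees with the mixOmics implementation", {
  set.seed(7)
  n <- 50
  g <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * 9), n, 9,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:9)))
  X[, 1] <- X[, 1] + 1.2 * (g == "case")
  mine <- plsda_vip(X, g, n_components = 2)$vip
  fit <- mixOmics::plsda(X, factor(g), ncomp = 2)
  theirs <- mixOmics::vip(fit)[, 2]
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-8)
})

test_that("the three-part differential-metabolite rule gates correctly", {
  set.seed(8)
  n <- 60
  g <- rep(c("case", "control"), each = n / 2)
  base <- matrix(exp(rnorm(n * 6, 10, 0.3)), n, 6,
                 dimnames = list(paste0("s", 1:n), paste0("m", 1:6)))
  up <- base; up[g == "case", 1] <- up[g == "case", 1] * 3    # enriched
  up[g == "case", 2] <- up[g == "case", 2] / 3                # depleted
  d <- differential_metabolites(up, g)
  expect_true(d$significant[d$feature_id == "m1"])
  expect_gt(d$fold_change[d$feature_id == "m1"], 1.5)
  expect_true(d$significant[d$feature_id == "m2"])  # two-sided FC reading
  expect_lt(d$fold_change[d$feature_id == "m2"], 1 / 1.5)
  d1 <- differential_metabolites(up, g, fc_mode = "greater")
  expect_false(d1$significant[d1$feature_id == "m2"])
  # a strong t-test hit with VIP forced under 1 must not pass: thresholds are
  # conjunctive
  expect_false(any(d$significant & (d$vip <= 1 | d$p >= 0.05)))
})

test_that("Spearman screens respect rank invariances", {
  set.seed(9)
  A <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("a", 1:4)))
  B <- cbind(a1_monotone = exp(A[, 1]), flat = rep(1, 10),
             anti = -A[, 2])
  rownames(B) <- rownames(A)
  res <- spearman_screen(A, B)
  expect_equal(res$rho["a1", "a1_monotone"], 1)
  expect_equal(res$rho["a2", "anti"], -1)
  expect_true(is.na(res$rho["a1", "flat"]))
  expect_equal(res$p["a1", "a1_monotone"], 0)
  ct <- cor.test(A[, 3], B[, 1], method = "spearman", exact = FALSE)
  expect_equal(res$rho["a3", "a1_monotone"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(res$p["a3", "a1_monotone"], ct$p.value, tolerance = 1e-10)
})
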