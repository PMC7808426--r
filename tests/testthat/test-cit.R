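test_that("the trio p-value is the maximum of the four component p-values", {
  set.seed(1)
  for (kind in c("causal", "pleiotropy", "null")) {
    d <- sim_trio(n = 80, kind = kind)
    res <- cit_test(d$L, d$M, d$T, n_perm = 150, seed = 3)
    expect_equal(res$p_cit, max(res$p1, res$p2, res$p3, res$p4))
    expect_true(all(c(res$p1, res$p2, res$p3, res$p4) >= 0 &
                      c(res$p1, res$p2, res$p3, res$p4) <= 1))
  }
})

test_that("a strong causal chain yields a small trio p-value", {
  set.seed(2)
  d <- sim_trio(n = 500, b1 = 0.7, c1 = 0.7, noise = 0.3, kind = "causal")
  res <- cit_test(d$L, d$M, d$T, n_perm = 500, seed = 7)
  expect_lt(res$p_cit, 0.05)
})

test_that("pleiotropy is separated from mediation by condition 4", {
  set.seed(3)
  d <- sim_trio(n = 500, b1 = 0.7, noise = 0.3, kind = "pleiotropy")
  res <- cit_test(d$L, d$M, d$T, n_perm = 500, seed = 7)
  expect_gt(res$p4, 0.1)   # conditional effect matches the marginal one
  expect_lt(res$p1, 0.05)  # while the association conditions still hold
  expect_gt(res$p_cit, 0.05)
})

test_that("degenerate inputs are rejected", {
  d <- sim_trio(n = 50)
  expect_error(cit_test(rep(1, 50), d$M, d$T), "constant")
  expect_error(cit_test(d$L, rep(0, 50), d$T), "constant M or T")
  expect_error(cit_test(d$L, d$M, d$T, n_perm = 50), "n_perm")
  expect_error(cit_test(d$L, d$M[1:10], d$T), "equal length")
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  set.seed(4)
  d <- sim_trio(n = 120, kind = "causal")
  cov <- data.frame(sample_id = paste0("s", 1:120), age = runif(120, 3, 12),
                    sex = rbinom(120, 1, 0.5), group = "case")
  a <- cit_test(d$L, d$M, d$T, cov, n_perm = 200, seed = 11)
  b <- cit_test(d$L, d$M, d$T, cov, n_perm = 200, seed = 11)
  expect_identical(a[c("p1", "p2", "p3", "p4", "p_cit")],
                   b[c("p1", "p2", "p3", "p4", "p_cit")])
  perm <- sample(120)
  c_ <- cit_test(d$L[perm], d$M[perm], d$T[perm], cov[perm, ],
                 n_perm = 200, seed = 11)
  expect_equal(a$p4, c_$p4)
  expect_equal(a$p_cit, c_$p_cit, tolerance = 1e-12)
})

test_that("stronger chains give (weakly) smaller median trio p-values", {
  set.seed(5)
  med_p <- vapply(c(0.2, 0.5, 0.8), function(b) {
    median(replicate(15, {
      d <- sim_trio(n = 150, b1 = b, c1 = b, noise = 0.5, kind = "causal")
      cit_test(d$L, d$M, d$T, n_perm = 150, seed = 2)$p_cit
    }))
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("direction classification follows the two-sided rule", {
  tr <- function(p) structure(list(p_cit = p, n = 100), class = "trio_result")
  expect_equal(classify_direction(tr(0.01), tr(0.4)), "causal")
  expect_equal(classify_direction(tr(0.4), tr(0.01)), "reactive")
  expect_equal(classify_direction(tr(0.6), tr(0.6)), "independent")
  expect_equal(classify_direction(tr(0.01), tr(0.01)), "ambiguous")
  mismatch <- structure(list(p_cit = 0.5, n = 99), class = "trio_result")
  expect_error(classify_direction(tr(0.5), mismatch), "different samples")
})

test_that("the trio screen crosses hits with differential metabolites", {
  co <- generate_cohort(small_config())
  hits <- data.frame(snv_id = colnames(co$genotypes)[1:4],
                     feature_id = colnames(co$species)[1:4],
                     stringsAsFactors = FALSE)
  mets <- colnames(co$metabolites)[1:2]
  tr <- screen_trios(hits, co$genotypes, co$species, co$metabolites, mets,
                     co$covariates, n_perm = 100, seed = 1)
  expect_equal(nrow(tr), 8)
  expect_true(all(tr$p_cit_forward == pmax(tr$p1_fwd, tr$p2_fwd, tr$p3_fwd,
                                           tr$p4_fwd)))
  expect_true(!is.unsorted(tr$p_cit_forward))
  expect_message(
    out <- screen_trios(hits, co$genotypes, co$species, co$metabolites,
                        character(0), co$covariates, n_perm = 100, seed = 1),
    "empty candidate")
  expect_equal(nrow(out), 0)
  # constant microbe abundance: pair skipped with a reason, others proceed
  sp <- co$species
  sp[, 1] <- sp[1, 1]
  tr2 <- screen_trios(hits[1:2, ], co$genotypes, sp, co$metabolites, mets[1],
                      co$covariates, n_perm = 100, seed = 1)
  expect_equal(nrow(tr2), 1)
  expect_equal(attr(tr2, "skipped")$reason, "constant input")
})
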