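test_that("identical configs give bit-identical cohorts and streams", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a, b)
  sa <- generate_variant_stream(40, seed = 9)
  sb <- generate_variant_stream(40, seed = 9)
  expect_identical(sa, sb)
  expect_false(identical(a, generate_cohort(small_config(seed = 43))))
})

test_that("a null config embeds nothing and genotype-feature correlations vanish", {
  cfg <- cohort_config(n_case = 250, n_control = 250, n_snv = 40,
                       n_species = 30, n_metabolites = 20, n_cytokines = 5,
                       n_causal_trios = 0, n_reactive_trios = 0,
                       n_pleiotropy_trios = 0, n_diff_cytokines = 0,
                       n_diff_metabolites = 0, effect_snv_to_microbe = 0,
                       effect_microbe_to_metabolite = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth$trio_labels), 0)
  expect_equal(nrow(co$truth$differential_features), 0)
  cors <- vapply(1:30, function(j) cor(co$genotypes[, j], co$species[, j]),
                 numeric(1))
  expect_lt(mean(abs(cors)), 0.06)  # ~ E|r| for null r at n = 500
})

test_that("causal chains carry the configured effect through closure", {
  cfg <- cohort_config(n_case = 250, n_control = 250, n_snv = 20,
                       n_species = 20, n_metabolites = 20,
                       n_causal_trios = 5, n_reactive_trios = 0,
                       n_pleiotropy_trios = 0, n_diff_metabolites = 0,
                       effect_snv_to_microbe = 0.8,
                       effect_microbe_to_metabolite = 0.8,
                       noise_sd = 0.3, seed = 11)
  co <- generate_cohort(cfg)
  for (i in seq_len(nrow(co$truth$trio_labels))) {
    tr <- co$truth$trio_labels[i, ]
    expect_gt(cor(co$genotypes[, tr$snv_id], co$species[, tr$species_id]), 0.5)
  }
})

test_that("the truth ledger covers exactly the injected effects", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  tl <- co$truth$trio_labels
  expect_equal(as.vector(table(factor(tl$label, c("causal", "reactive",
                                                  "pleiotropy")))),
               c(2, 1, 1))
  expect_false(any(duplicated(tl$snv_id)))
  expect_false(any(duplicated(tl$species_id)))
  expect_false(any(duplicated(tl$metabolite_id)))
  df <- co$truth$differential_features
  expect_equal(sum(df$table_kind == "cytokines"), cfg$n_diff_cytokines)
  # trio metabolites are group-shifted too, so they appear in the ledger
  expect_equal(sum(df$table_kind == "metabolites"),
               cfg$n_diff_metabolites + nrow(tl))
  expect_true(all(tl$metabolite_id %in%
                    df$feature_id[df$table_kind == "metabolites"]))
})

test_that("species rows are compositional and cytokines carry the group shift", {
  co <- generate_cohort(small_config())
  expect_true(all(abs(rowSums(co$species) - 1) < 1e-9))
  expect_true(all(abs(rowSums(co$pathways) - 1) < 1e-9))
  diff_ids <- with(co$truth$differential_features,
                   feature_id[table_kind == "cytokines"])
  case <- co$covariates$group == "case"
  shift <- colMeans(log(co$cytokines[case, diff_ids, drop = FALSE])) -
    colMeans(log(co$cytokines[!case, diff_ids, drop = FALSE]))
  expect_true(all(shift > 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_causal_trios = 60, n_species = 50),
               "more embedded trios")
  expect_error(cohort_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(cohort_config(n_diff_cytokines = 9, n_cytokines = 7),
               "n_diff_cytokines")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(n_snv = -1), "non-negative")
})

test_that("the variant stream spans every declared fate category", {
  st <- generate_variant_stream(40, seed = 5)
  expect_equal(nrow(st$records), 40)
  fates <- st$truth$variant_fate$fate
  expect_setequal(unique(fates),
                  c("pass", "fail:qc_quality", "fail:qc_depth",
                    "fail:qc_alt_reads", "fail:qc_gap",
                    "fail:control_carrier", "fail:common_variant",
                    "fail:carrier_count"))
  expect_setequal(unique(st$records$effect),
                  c("nonsynonymous", "stopgain", "stoploss", "synonymous",
                    "noncoding"))
  # stated examples: bq 29 fails quality; a record passing every rule passes
  expect_equal(fates[st$records$base_quality == 29][1], "fail:qc_quality")
  absent <- !paste(st$records$chrom, st$records$pos) %in%
    paste(st$frequencies$chrom, st$frequencies$pos)
  clean <- absent & st$records$carriers_control == "" &
    st$records$base_quality >= 30 & st$records$depth >= 30 &
    st$records$alt_reads >= 3 & st$records$gap_distance >= 6
  expect_true(all(fates[clean] == "pass"))
  expect_error(generate_variant_stream(0), "n_records")
})
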