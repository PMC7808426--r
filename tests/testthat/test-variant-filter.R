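test_that("qc filter keeps the boundary complement of each removal rule", {
  cases <- list(
    list(rec = toy_record(base_quality = 30, depth = 30, alt_reads = 3,
                          gap_distance = 6), kept = TRUE, reason = NA),
    list(rec = toy_record(base_quality = 29), kept = FALSE,
         reason = "fail:qc_quality"),
    list(rec = toy_record(depth = 29, alt_reads = 10), kept = FALSE,
         reason = "fail:qc_depth"),
    list(rec = toy_record(base_quality = 35, depth = 100, alt_reads = 2,
                          gap_distance = 100), kept = FALSE,
         reason = "fail:qc_alt_reads"),
    list(rec = toy_record(base_quality = 35, depth = 100, alt_reads = 10,
                          gap_distance = 5), kept = FALSE,
         reason = "fail:qc_gap"))
  for (cs in cases) {
    out <- qc_filter(cs$rec)
    expect_equal(nrow(out$kept) == 1, cs$kept)
    if (!cs$kept) expect_equal(out$removed$reason, cs$reason)
  }
  # a record failing several rules reports the first rule in quoted order
  multi <- qc_filter(toy_record(base_quality = 10, depth = 5, alt_reads = 0))
  expect_equal(multi$removed$reason, "fail:qc_quality")
  empty <- qc_filter(toy_record()[0, ])
  expect_equal(nrow(empty$kept) + nrow(empty$removed), 0)
})

test_that("qc filter with thresholds disabled returns the input unchanged", {
  st <- generate_variant_stream(30, seed = 8)
  out <- qc_filter(st$records, min_bq = -Inf, min_depth = 0, min_alt = 0,
                   min_gap_dist = -Inf)
  expect_equal(out$kept, st$records)
  expect_equal(nrow(out$removed), 0)
})

test_that("control-carried variants are removed", {
  out <- remove_control_variants(toy_record(carriers_control = "TD07"))
  expect_equal(nrow(out$kept), 0)
  expect_equal(out$removed$reason, "fail:control_carrier")
  out2 <- remove_control_variants(toy_record(carriers_case = "ASD01",
                                             carriers_control = ""))
  expect_equal(nrow(out2$kept), 1)
  all_ctrl <- rbind(toy_record("a", carriers_control = "TD01"),
                    toy_record("b", carriers_control = "TD02,TD03"))
  expect_equal(nrow(remove_control_variants(all_ctrl)$kept), 0)
})

test_that("the MAF filter is strict at 5% and keeps database-absent variants", {
  rec <- toy_record()
  rare <- do.call(rbind, lapply(c("1000G", "ExAC", "CMDB"),
                                function(db) freq_row(rec, db, 0.049)))
  expect_equal(nrow(frequency_filter(rec, rare)$kept), 1)
  one_common <- rbind(freq_row(rec, "1000G", 0.01), freq_row(rec, "ExAC", 0.05))
  expect_equal(frequency_filter(rec, one_common)$removed$reason,
               "fail:common_variant")
  expect_equal(nrow(frequency_filter(rec, empty_freqs())$kept), 1)
})

test_that("the carrier filter reads 'more than two cases' as >= 3", {
  expect_equal(nrow(carrier_filter(toy_record())$kept), 1)  # 3 carriers
  two <- toy_record(carriers_case = "ASD01,ASD02")
  expect_equal(carrier_filter(two)$removed$reason, "fail:carrier_count")
  one <- toy_record(carriers_case = "ASD01")
  expect_equal(nrow(carrier_filter(one, min_case_carriers = 1)$kept), 1)
})

test_that("functional selection keeps exactly the protein-altering classes", {
  recs <- do.call(rbind, Map(function(id, eff) toy_record(id, effect = eff),
                             paste0("v", 1:5),
                             c("nonsynonymous", "stopgain", "stoploss",
                               "synonymous", "noncoding")))
  kept <- select_functional(recs)
  expect_setequal(kept$snv_id, c("v1", "v2", "v3"))
  bad <- toy_record(effect = "missense")
  expect_error(select_functional(bad), "unknown effect")
})

test_that("the cascade kept set is the intersection of the individual rules", {
  st <- generate_variant_stream(120, seed = 13)
  casc <- filter_cascade(st$records, st$frequencies)
  ind <- Reduce(intersect, list(
    qc_filter(st$records)$kept$snv_id,
    remove_control_variants(st$records)$kept$snv_id,
    frequency_filter(st$records, st$frequencies)$kept$snv_id,
    carrier_filter(st$records)$kept$snv_id))
  expect_setequal(casc$kept$snv_id, ind)
  expect_equal(casc$counts$kept + nrow(casc$removed), nrow(st$records))
})

test_that("cascade verdicts match the generator's fate ledger", {
  st <- generate_variant_stream(80, seed = 21)
  casc <- filter_cascade(st$records, st$frequencies)
  expect_equal(unname(casc$verdict[st$truth$variant_fate$snv_id]),
               st$truth$variant_fate$fate)
})
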