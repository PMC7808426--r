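# Labeled variant-stream generator: a fixture factory for the triage cascade.
# Every filter rule is exercised on both sides of its boundary and the
# expected verdict of each record is written to the truth ledger.

.freq_dbs <- c("1000G", "ExAC", "CMDB")

.stream_categories <- function() {
  # Each entry: a tweak applied to a passing base record, rows for the
  # frequency table ("default" = rare in all three databases), and the
  # expected fate under the cascade.
  list(
    qc_quality_fail    = list(tweak = list(base_quality = 29), fate = "fail:qc_quality"),
    qc_quality_edge    = list(tweak = list(base_quality = 30), fate = "pass"),
    qc_depth_fail      = list(tweak = list(depth = 29), fate = "fail:qc_depth"),
    qc_depth_edge      = list(tweak = list(depth = 30), fate = "pass"),
    qc_alt_fail        = list(tweak = list(alt_reads = 2), fate = "fail:qc_alt_reads"),
    qc_alt_edge        = list(tweak = list(alt_reads = 3), fate = "pass"),
    qc_gap_fail        = list(tweak = list(gap_distance = 5), fate = "fail:qc_gap"),
    qc_gap_edge        = list(tweak = list(gap_distance = 6), fate = "pass"),
    control_carrier    = list(tweak = list(n_control_carriers = 1), fate = "fail:control_carrier"),
    common_one_db      = list(maf = c(0.05, 0.01, 0.01), fate = "fail:common_variant"),
    common_all_db      = list(maf = c(0.2, 0.2, 0.2), fate = "fail:common_variant"),
    rare_edge          = list(maf = c(0.049, 0.049, 0.049), fate = "pass"),
    absent_from_dbs    = list(maf = numeric(0), fate = "pass"),
    carrier_fail       = list(tweak = list(n_case_carriers = 2), fate = "fail:carrier_count"),
    carrier_edge       = list(tweak = list(n_case_carriers = 3), fate = "pass"),
    effect_nonsyn      = list(tweak = list(effect = "nonsynonymous"), fate = "pass"),
    effect_stopgain    = list(tweak = list(effect = "stopgain"), fate = "pass"),
    effect_stoploss    = list(tweak = list(effect = "stoploss"), fate = "pass"),
    effect_synonymous  = list(tweak = list(effect = "synonymous"), fate = "pass"),
    effect_noncoding   = list(tweak = list(effect = "noncoding"), fate = "pass")
  )
}

.random_context <- function() {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  context <- paste0(sample(bases, 1), ref, sample(bases, 1))
  list(ref = ref, alt = alt, context = context)
}

#' Generate a labeled stream of variant records for the triage cascade
#'
#' Emits records spanning both sides of every filter boundary: base quality
#' and depth straddling 30, alternate-read support straddling 3, gap distance
#' straddling 5 bp, control-group presence, database MAF straddling 0.05 and
#' database absence, case-carrier counts straddling the carrier threshold, and
#' all five functional annotation classes. The expected verdict of every
#' record is recorded in the returned truth ledger.
#'
#' @param n_records number of records (>= 1). The first records walk through
#'   every category once; the remainder are random draws over the categories.
#' @param seed integer seed.
#' @param case_samples,control_samples sample id pools used for carrier sets.
#' @return list with `records` (data.frame of variant records; carrier sets as
#'   comma-separated strings), `frequencies` (population allele-frequency
#'   table: chrom, pos, ref, alt, db_name, maf) and `truth` (list whose
#'   `variant_fate` maps snv_id to "pass" or "fail:<rule>").
#' @export
generate_variant_stream <- function(n_records = 40, seed = 1,
                                    case_samples = sprintf("ASD%02d", 1:26),
                                    control_samples = sprintf("TD%02d", 1:26)) {
  if (!is.numeric(n_records) || n_records < 1) {
    stop("n_records must be >= 1")
  }
  set.seed(derive_seed(seed, 11))
  cats <- .stream_categories()
  idx <- seq_len(n_records)
  cat_ids <- c(seq_along(cats), sample.int(length(cats),
                                           max(0, n_records - length(cats)),
                                           replace = TRUE))[idx]
  recs <- vector("list", n_records)
  freq_rows <- list()
  fates <- character(n_records)
  for (i in idx) {
    cat <- cats[[cat_ids[i]]]
    ctx <- .random_context()
    rec <- list(snv_id = sprintf("v%03d", i),
                chrom = paste0("chr", ((i - 1) %% 22) + 1),
                pos = 1000L * i,
                ref = ctx$ref, alt = ctx$alt,
                base_quality = 40, depth = 60, alt_reads = 12,
                gap_distance = 50,
                gene = sprintf("GENE%03d", i),
                effect = sample(c("nonsynonymous", "stopgain", "stoploss",
                                  "synonymous", "noncoding"), 1,
                                prob = c(0.5, 0.15, 0.05, 0.2, 0.1)),
                context = ctx$context,
                n_case_carriers = sample(3:6, 1), n_control_carriers = 0)
    for (nm in names(cat$tweak %||% list())) rec[[nm]] <- cat$tweak[[nm]]
    maf <- if (is.null(cat$maf)) rep(0.01, 3) else cat$maf
    if (length(maf)) {
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
        db_name = .freq_dbs[seq_along(maf)], maf = maf,
        stringsAsFactors = FALSE)
    }
    rec$carriers_case <- paste(sample(case_samples, rec$n_case_carriers),
                               collapse = ",")
    rec$carriers_control <- if (rec$n_control_carriers > 0) {
      paste(sample(control_samples, rec$n_control_carriers), collapse = ",")
    } else ""
    rec$n_case_carriers <- rec$n_control_carriers <- NULL
    recs[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    fates[i] <- cat$fate
  }
  records <- do.call(rbind, recs)
  frequencies <- if (length(freq_rows)) do.call(rbind, freq_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), db_name = character(0), maf = numeric(0),
               stringsAsFactors = FALSE)
  truth <- list(variant_fate = data.frame(snv_id = records$snv_id,
                                          fate = fates,
                                          stringsAsFactors = FALSE))
  list(records = records, frequencies = frequencies, truth = truth)
}
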