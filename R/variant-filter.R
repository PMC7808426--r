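# Rare-variant triage cascade. Each rule is a pure predicate on the record
# table, so the final kept set is the intersection of the individually kept
# sets; removal reasons report the first failing rule in cascade order.

.carrier_count <- function(x) {
  lengths(strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE))
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("variant records lack columns: ",
                         paste(miss, collapse = ", "))
  if (any(records$ref == records$alt)) stop("ref equals alt in some records")
  if (!is.null(records$alt_reads) && !is.null(records$depth) &&
      any(records$alt_reads > records$depth)) {
    stop("alt_reads exceeds depth in some records")
  }
  invisible(records)
}

#' Sequencing quality filter for variant records
#'
#' Keeps a record iff base quality >= `min_bq`, depth >= `min_depth`,
#' alternate-allele reads >= `min_alt` and the distance to the nearest
#' alignment gap is at least `min_gap_dist` bp (i.e. variants within 5 bp of a
#' gap are removed at the defaults).
#'
#' @param records variant record data.frame.
#' @param min_bq,min_depth,min_alt,min_gap_dist thresholds; defaults are the
#'   standard exome triage values (30 / 30 / 3 / 6).
#' @return list with `kept` and `removed` (removed carries a `reason` column
#'   naming the first failing rule).
#' @export
qc_filter <- function(records, min_bq = 30, min_depth = 30, min_alt = 3,
                      min_gap_dist = 6) {
  .check_records(records)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$base_quality < min_bq] <- "fail:qc_quality"
  reason[is.na(reason) & records$depth < min_depth] <- "fail:qc_depth"
  reason[is.na(reason) & records$alt_reads < min_alt] <- "fail:qc_alt_reads"
  reason[is.na(reason) & records$gap_distance < min_gap_dist] <- "fail:qc_gap"
  removed <- records[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], removed = removed)
}

#' Remove variants present in the control group
#'
#' @param records variant record data.frame with a `carriers_control` column
#'   (comma-separated sample ids, empty string for none).
#' @return list with `kept` (control-absent records) and `removed`.
#' @export
remove_control_variants <- function(records) {
  .check_records(records)
  ctrl <- .carrier_count(records$carriers_control) > 0
  removed <- records[ctrl, , drop = FALSE]
  removed$reason <- rep("fail:control_carrier", nrow(removed))
  list(kept = records[!ctrl, , drop = FALSE], removed = removed)
}

#' Rarity filter against population allele-frequency databases
#'
#' A variant is kept iff every matching database entry reports a minor allele
#' frequency strictly below `max_maf`. A variant absent from all databases is
#' kept: unseen in large population panels implies rarer than the cutoff.
#'
#' @param records variant record data.frame.
#' @param freqs frequency table: columns chrom, pos, ref, alt, db_name, maf.
#' @param max_maf strict upper bound on database MAF (default 0.05).
#' @return list with `kept` and `removed` (reason `fail:common_variant`).
#' @export
frequency_filter <- function(records, freqs, max_maf = 0.05) {
  .check_records(records)
  need <- c("chrom", "pos", "ref", "alt", "db_name", "maf")
  miss <- setdiff(need, names(freqs))
  if (length(miss)) stop("frequency table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(is.na(freqs$maf) | freqs$maf < 0 | freqs$maf > 0.5)
  if (length(bad)) stop("malformed frequency rows (maf outside [0, 0.5]) at line",
                        if (length(bad) > 1) "s " else " ",
                        paste(bad, collapse = ", "))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  common_keys <- unique(key(freqs)[freqs$maf >= max_maf])
  common <- key(records) %in% common_keys
  removed <- records[common, , drop = FALSE]
  removed$reason <- rep("fail:common_variant", nrow(removed))
  list(kept = records[!common, , drop = FALSE], removed = removed)
}

#' Recurrence filter on case carriers
#'
#' Keeps variants detected in at least `min_case_carriers` case samples
#' (default 3, i.e. "more than two" cases).
#'
#' @param records variant record data.frame with `carriers_case`.
#' @param min_case_carriers minimum number of case carriers.
#' @return list with `kept` and `removed` (reason `fail:carrier_count`).
#' @export
carrier_filter <- function(records, min_case_carriers = 3) {
  .check_records(records)
  few <- .carrier_count(records$carriers_case) < min_case_carriers
  removed <- records[few, , drop = FALSE]
  removed$reason <- rep("fail:carrier_count", nrow(removed))
  list(kept = records[!few, , drop = FALSE], removed = removed)
}

#' Select protein-altering (functional) variants
#'
#' Functional variants are the non-synonymous, stop-gain and stop-loss class.
#'
#' @param records variant record data.frame with an `effect` column.
#' @return the subset of functional records.
#' @export
select_functional <- function(records) {
  .check_records(records)
  known <- c("nonsynonymous", "stopgain", "stoploss", "synonymous", "noncoding")
  bad <- setdiff(unique(records$effect), known)
  if (length(bad)) stop("unknown effect labels: ", paste(bad, collapse = ", "))
  records[records$effect %in% c("nonsynonymous", "stopgain", "stoploss"), ,
          drop = FALSE]
}

#' Run the full variant triage cascade
#'
#' Applies, in order: sequencing QC ([qc_filter()]), removal of variants seen
#' in controls ([remove_control_variants()]), the population-frequency rarity
#' filter ([frequency_filter()]) and the case-carrier recurrence filter
#' ([carrier_filter()]). Because every rule is a pure predicate, the final
#' kept set does not depend on the order; the order only determines which
#' reason a multiply-failing record is tagged with.
#'
#' @param records variant record data.frame.
#' @param freqs frequency table (see [frequency_filter()]).
#' @param min_bq,min_depth,min_alt,min_gap_dist,max_maf,min_case_carriers
#'   stage thresholds.
#' @return list with `kept`, `removed` (all removed records with `reason`),
#'   `verdict` (named character vector snv_id -> "pass"/"fail:<rule>") and
#'   `counts` (records in/out per stage).
#' @export
filter_cascade <- function(records, freqs,
                           min_bq = 30, min_depth = 30, min_alt = 3,
                           min_gap_dist = 6, max_maf = 0.05,
                           min_case_carriers = 3) {
  n_in <- nrow(records)
  s1 <- qc_filter(records, min_bq, min_depth, min_alt, min_gap_dist)
  s2 <- remove_control_variants(s1$kept)
  s3 <- frequency_filter(s2$kept, freqs, max_maf)
  s4 <- carrier_filter(s3$kept, min_case_carriers)
  removed <- rbind(s1$removed, s2$removed, s3$removed, s4$removed)
  verdict <- c(stats::setNames(rep("pass", nrow(s4$kept)), s4$kept$snv_id),
               stats::setNames(removed$reason, removed$snv_id))
  verdict <- verdict[records$snv_id]
  counts <- list(input = n_in,
                 qc_removed = nrow(s1$removed),
                 control_removed = nrow(s2$removed),
                 common_removed = nrow(s3$removed),
                 carrier_removed = nrow(s4$removed),
                 kept = nrow(s4$kept))
  stopifnot(counts$kept + nrow(removed) == n_in)
  list(kept = s4$kept, removed = removed, verdict = verdict, counts = counts)
}
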