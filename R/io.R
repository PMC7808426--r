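# Plain-text interchange: tab-separated tables (first column sample_id,
# '.' for missing), a VCF v4.2 writer/reader for variant records, and the
# population allele-frequency table.

#' Write a samples x features table as TSV
#'
#' @param x numeric matrix with sample rownames.
#' @param path output file.
#' @export
write_feature_table <- function(x, path) {
  x <- .check_feature_matrix(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tryCatch(.write_tsv(df, path),
           error = function(e) stop("failed to write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a samples x features TSV into a matrix
#'
#' @param path TSV written by [write_feature_table()] (first column
#'   sample_id).
#' @return numeric matrix with sample rownames (0 columns for a header-only
#'   feature set).
#' @export
read_feature_table <- function(path) {
  df <- .read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("no sample_id column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

#' Read a covariate table (sample_id, age, sex, group)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "age", "sex", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- df$sample_id[!stats::complete.cases(df[, need])]
  if (length(bad)) stop("missing covariate values for sample: ",
                        paste(bad, collapse = ", "))
  df
}

#' Write the frequency table
#' @param freqs data.frame chrom, pos, ref, alt, db_name, maf.
#' @param path TSV path.
#' @export
write_frequency_table <- function(freqs, path) {
  .write_tsv(freqs, path)
  invisible(path)
}

#' Read a population allele-frequency table
#' @param path TSV with columns chrom, pos, ref, alt, db_name, maf.
#' @return data.frame.
#' @export
read_frequency_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "db_name", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("frequency table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

.vcf_info_keys <- c(BQ = "base_quality", DP = "depth", AO = "alt_reads",
                    GAPDIST = "gap_distance", GENE = "gene",
                    EFFECT = "effect", CONTEXT = "context")

#' Write variant records as VCF v4.2
#'
#' INFO keys: BQ, DP, AO, GAPDIST, GENE, EFFECT, CONTEXT. Per-sample GT is
#' 0/1 for carriers and 0/0 otherwise, over the union of the case and
#' control sample pools.
#'
#' @param records variant record data.frame (see
#'   [generate_variant_stream()]).
#' @param path output file.
#' @param samples column order of the genotype block; defaults to all
#'   carriers observed.
#' @export
write_variant_vcf <- function(records, path, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(unlist(strsplit(
      c(records$carriers_case, records$carriers_control), ",", fixed = TRUE))))
    samples <- samples[samples != ""]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=triocit",
    '##INFO=<ID=BQ,Number=1,Type=Float,Description="Mean base quality">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=AO,Number=1,Type=Integer,Description="Alternate allele read count">',
    '##INFO=<ID=GAPDIST,Number=1,Type=Integer,Description="Distance in bp to nearest alignment gap">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Functional class">',
    '##INFO=<ID=CONTEXT,Number=1,Type=String,Description="Trinucleotide context, reference strand">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  carrier_sets <- strsplit(paste0(records$carriers_case, ",",
                                  records$carriers_control), ",", fixed = TRUE)
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- paste0("BQ=", r$base_quality, ";DP=", r$depth, ";AO=", r$alt_reads,
                   ";GAPDIST=", r$gap_distance, ";GENE=", r$gene,
                   ";EFFECT=", r$effect, ";CONTEXT=", r$context)
    gt <- ifelse(samples %in% carrier_sets[[i]], "0/1", "0/0")
    paste(c(r$chrom, r$pos, r$snv_id, r$ref, r$alt, ".", ".", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  tryCatch(writeLines(c(hdr, body), path),
           error = function(e) stop("failed to write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a VCF of variant records
#'
#' Parses a VCF v4.2 with the INFO keys written by [write_variant_vcf()] and
#' reconstructs the variant record table plus a dosage matrix from GT.
#'
#' @param path VCF file.
#' @param case_samples,control_samples sample id sets used to split carriers.
#' @return list with `records` (data.frame) and `genotypes` (samples x
#'   variants dosage matrix over all VCF samples).
#' @export
read_variant_vcf <- function(path, case_samples = NULL,
                             control_samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  get_info <- function(key, numeric = FALSE) {
    v <- vcfR::extract.info(vcf, element = key)
    if (numeric) as.numeric(v) else v
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(0L, ncol(gt), nrow(gt),
                   dimnames = list(colnames(gt), fix$ID))
  if (length(gt)) {
    # vapply over variants yields a samples x variants matrix directly
    dosage[] <- vapply(seq_len(nrow(gt)), function(i) {
      vapply(strsplit(gt[i, ], "[/|]"), function(a)
        sum(suppressWarnings(as.integer(a)), na.rm = TRUE), integer(1))
    }, integer(ncol(gt)))
  }
  samples <- colnames(gt)
  case_samples <- case_samples %||% samples[!samples %in% (control_samples %||% character(0))]
  carriers <- function(pool) {
    apply(dosage[pool, , drop = FALSE] > 0, 2, function(z)
      paste(pool[z], collapse = ","))
  }
  records <- data.frame(
    snv_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    base_quality = get_info("BQ", TRUE), depth = get_info("DP", TRUE),
    alt_reads = get_info("AO", TRUE), gap_distance = get_info("GAPDIST", TRUE),
    gene = get_info("GENE"), effect = get_info("EFFECT"),
    context = get_info("CONTEXT"),
    carriers_case = carriers(intersect(case_samples, samples)),
    carriers_control = carriers(intersect(control_samples %||% character(0),
                                          samples)),
    stringsAsFactors = FALSE)
  list(records = records, genotypes = dosage)
}

#' Write all tables of a synthetic cohort to a directory
#'
#' Writes genotypes, species, pathways, metabolites and cytokines as TSV,
#' the covariates and variant annotation as TSV, and the truth ledger
#' (trio labels, differential features, variant fates) as TSV. Everything
#' round-trips losslessly through the corresponding readers.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param outdir writable directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes = file.path(outdir, "genotypes.tsv"),
    species = file.path(outdir, "species.tsv"),
    pathways = file.path(outdir, "pathways.tsv"),
    metabolites = file.path(outdir, "metabolites.tsv"),
    cytokines = file.path(outdir, "cytokines.tsv"),
    covariates = file.path(outdir, "covariates.tsv"),
    snv_info = file.path(outdir, "snv_info.tsv"),
    truth_trios = file.path(outdir, "truth_trios.tsv"),
    truth_differential = file.path(outdir, "truth_differential.tsv"),
    truth_variant_fate = file.path(outdir, "truth_variant_fate.tsv"))
  for (nm in c("genotypes", "species", "pathways", "metabolites", "cytokines")) {
    write_feature_table(cohort[[nm]], paths[[nm]])
  }
  .write_tsv(cohort$covariates, paths[["covariates"]])
  .write_tsv(cohort$snv_info, paths[["snv_info"]])
  .write_tsv(cohort$truth$trio_labels, paths[["truth_trios"]])
  .write_tsv(cohort$truth$differential_features, paths[["truth_differential"]])
  .write_tsv(cohort$truth$variant_fate, paths[["truth_variant_fate"]])
  invisible(paths)
}
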