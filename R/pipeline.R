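# End-to-end orchestration: simulate or ingest inputs, variant triage,
# spectra, diversity/composition, association and differential screens, and
# the trio causal inference screen, with a reproducible run report.

.default_thresholds <- function() {
  list(min_base_quality = 30, min_depth = 30, min_alt_reads = 3,
       min_gap_distance = 6, max_maf = 0.05, min_case_carriers = 3,
       fdr = 0.05, vip = 1, metabolite_p = 0.05, fold_change = 1.5,
       cit_alpha = 0.05, n_perm = 1000)
}

#' Build a pipeline configuration
#'
#' Exactly one of `simulate` (a [cohort_config()] or argument list for it) or
#' `input` (named file paths: vcf, frequencies, species, pathways,
#' metabolites, cytokines, covariates) must be given. All stage thresholds
#' default to the standard values of the analysis (QC 30/30/3/>5 bp,
#' MAF < 0.05, >= 3 case carriers, FDR 0.05, VIP > 1, t-test p < 0.05,
#' FC > 1.5, trio alpha 0.05).
#'
#' @param simulate simulation block, or NULL for ingest mode.
#' @param input named list of input paths, or NULL for simulate mode.
#' @param outdir output directory.
#' @param seed root seed for the run.
#' @param thresholds named list overriding individual default thresholds.
#' @param n_variant_records simulate mode: size of the generated variant
#'   stream fed to the triage cascade.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL, outdir = tempfile("triocit_run_"),
                            seed = 1, thresholds = list(),
                            n_variant_records = 40) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  if (!is.null(simulate) && !inherits(simulate, "cohort_config")) {
    simulate <- do.call(cohort_config, utils::modifyList(simulate,
                                                         list(seed = simulate$seed %||% seed)))
  }
  structure(list(simulate = simulate, input = input, outdir = outdir,
                 seed = seed, thresholds = th,
                 n_variant_records = n_variant_records),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys simulate/input, outdir, seed, thresholds.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(simulate = y$simulate, input = y$input,
                  outdir = y$outdir %||% tempfile("triocit_run_"),
                  seed = y$seed %||% 1, thresholds = y$thresholds %||% list(),
                  n_variant_records = y$n_variant_records %||% 40)
}

#' Validate a pipeline configuration
#'
#' Schema and range checks plus, in ingest mode, file existence and
#' cross-file sample-id consistency. All problems are returned, not just the
#' first.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems (empty if the config is valid).
#' @export
validate_pipeline_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$simulate) == is.null(config$input)) {
    add("exactly one of 'simulate' or 'input' must be configured")
  }
  th <- config$thresholds
  chk_range <- function(name, lo, hi) {
    v <- th[[name]]
    if (!is.numeric(v) || length(v) != 1 || v < lo || v > hi) {
      add(sprintf("threshold %s = %s outside [%s, %s]", name,
                  paste(v, collapse = ","), lo, hi))
    }
  }
  chk_range("max_maf", 0, 0.5)
  chk_range("fdr", 0, 1)
  chk_range("metabolite_p", 0, 1)
  chk_range("cit_alpha", 0, 1)
  chk_range("min_base_quality", 0, Inf)
  chk_range("min_depth", 0, Inf)
  chk_range("min_alt_reads", 0, Inf)
  chk_range("min_gap_distance", 0, Inf)
  chk_range("min_case_carriers", 0, Inf)
  chk_range("fold_change", 1, Inf)
  chk_range("vip", 0, Inf)
  chk_range("n_perm", 100, Inf)
  if (!is.null(config$input)) {
    need <- c("vcf", "frequencies", "species", "pathways", "metabolites",
              "cytokines", "covariates")
    miss <- setdiff(need, names(config$input))
    if (length(miss)) add(paste("missing input paths:",
                                paste(miss, collapse = ", ")))
    for (nm in intersect(need, names(config$input))) {
      if (!file.exists(config$input[[nm]])) {
        add(paste0("input file not found: ", nm, " = ", config$input[[nm]]))
      }
    }
    if (!length(problems)) {
      cov <- tryCatch(read_covariates(config$input$covariates),
                      error = function(e) { add(conditionMessage(e)); NULL })
      if (!is.null(cov)) {
        for (nm in c("species", "pathways", "metabolites", "cytokines")) {
          tab <- tryCatch(read_feature_table(config$input[[nm]]),
                          error = function(e) { add(conditionMessage(e)); NULL })
          if (!is.null(tab)) {
            orphan <- setdiff(rownames(tab), cov$sample_id)
            if (length(orphan)) {
              add(paste0(nm, " samples absent from covariates: ",
                         paste(orphan, collapse = ", ")))
            }
          }
        }
      }
    }
  }
  problems
}

.stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    try(writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                   file.path(outdir, "FAILED")), silent = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, the variant triage cascade, mutation spectra,
#' genotype and microbiome PCA with Simpson-diversity correlation, the
#' covariate-adjusted association screens with BH FDR, differential cytokines
#' and metabolites, and the trio causal inference screen. Every stage's
#' output is written to `config$outdir` before the next stage starts, and a
#' run with the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly; also written as
#'   `report.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  problems <- validate_pipeline_config(config)
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  th <- config$thresholds

  ## --- inputs -------------------------------------------------------------
  sim_mode <- !is.null(config$simulate)
  inp <- .stage("input", outdir, {
    if (sim_mode) {
      cohort <- generate_cohort(config$simulate)
      stream <- generate_variant_stream(config$n_variant_records,
                                        seed = config$seed,
                                        case_samples = cohort$covariates$sample_id[cohort$covariates$group == "case"],
                                        control_samples = cohort$covariates$sample_id[cohort$covariates$group == "control"])
      write_cohort(cohort, file.path(outdir, "input"))
      write_variant_vcf(stream$records, file.path(outdir, "input", "variants.vcf"),
                        samples = cohort$covariates$sample_id)
      write_frequency_table(stream$frequencies,
                            file.path(outdir, "input", "frequencies.tsv"))
      .write_tsv(stream$truth$variant_fate,
                 file.path(outdir, "input", "truth_variant_fate.tsv"))
      list(cohort = cohort, records = stream$records,
           frequencies = stream$frequencies)
    } else {
      cov <- read_covariates(config$input$covariates)
      vcf <- read_variant_vcf(config$input$vcf,
                              case_samples = cov$sample_id[cov$group == "case"],
                              control_samples = cov$sample_id[cov$group == "control"])
      cohort <- list(
        genotypes = vcf$genotypes[cov$sample_id, , drop = FALSE],
        snv_info = data.frame(snv_id = vcf$records$snv_id,
                              effect = vcf$records$effect,
                              stringsAsFactors = FALSE),
        species = read_feature_table(config$input$species),
        pathways = read_feature_table(config$input$pathways),
        metabolites = read_feature_table(config$input$metabolites),
        cytokines = read_feature_table(config$input$cytokines),
        covariates = cov, truth = NULL)
      list(cohort = cohort, records = vcf$records,
           frequencies = read_frequency_table(config$input$frequencies))
    }
  })
  cohort <- inp$cohort

  ## --- variant triage -----------------------------------------------------
  triage <- .stage("variant_filter", outdir, {
    casc <- filter_cascade(inp$records, inp$frequencies,
                           min_bq = th$min_base_quality,
                           min_depth = th$min_depth,
                           min_alt = th$min_alt_reads,
                           min_gap_dist = th$min_gap_distance,
                           max_maf = th$max_maf,
                           min_case_carriers = th$min_case_carriers)
    .write_tsv(casc$kept, file.path(outdir, "variants_kept.tsv"))
    .write_tsv(casc$removed, file.path(outdir, "variants_removed.tsv"))
    casc
  })

  ## --- mutation spectrum --------------------------------------------------
  spectrum <- .stage("mutation_spectrum", outdir, {
    src <- if (nrow(triage$kept)) triage$kept else inp$records
    sp <- mutation_spectrum(src)
    .write_tsv(data.frame(class = names(sp$six_class), count = sp$six_class),
               file.path(outdir, "spectrum_six_class.tsv"))
    .write_tsv(data.frame(bin = names(sp$ninety_six), count = sp$ninety_six),
               file.path(outdir, "spectrum_96bin.tsv"))
    sp
  })

  ## --- diversity & composition --------------------------------------------
  div <- .stage("diversity", outdir, {
    functional_ids <- cohort$snv_info$snv_id[
      cohort$snv_info$effect %in% c("nonsynonymous", "stopgain", "stoploss")]
    functional_ids <- intersect(functional_ids, colnames(cohort$genotypes))
    gmat <- cohort$genotypes[, functional_ids, drop = FALSE]
    geno_pca <- if (length(functional_ids) >= 2) pca(gmat, n_components = 5) else NULL
    sp_pca <- pca(cohort$species, n_components = 5)
    alpha <- alpha_diversity(cohort$species)
    pc1_div <- pc1_pc1 <- NULL
    if (!is.null(geno_pca)) {
      pc1_div <- pc_correlation(geno_pca$scores[, 1], alpha)
      pc1_pc1 <- pc_correlation(geno_pca$scores[, 1], sp_pca$scores[, 1])
    }
    .write_tsv(data.frame(sample_id = rownames(cohort$species),
                          simpson_alpha = alpha,
                          genotype_pc1 = if (is.null(geno_pca)) NA else geno_pca$scores[, 1],
                          microbiome_pc1 = sp_pca$scores[, 1]),
               file.path(outdir, "diversity.tsv"))
    list(alpha = alpha, pc1_diversity = pc1_div, pc1_pc1 = pc1_pc1,
         n_functional = length(functional_ids))
  })

  ## --- association screens ------------------------------------------------
  assoc <- .stage("association", outdir, {
    res <- list()
    for (kind in c("species", "pathways")) {
      scr <- association_screen(cohort$genotypes, cohort[[kind]],
                                cohort$covariates, transform = kind)
      scr$significant <- scr$q < th$fdr
      .write_tsv(scr, file.path(outdir, paste0("association_", kind, ".tsv")))
      res[[kind]] <- scr
    }
    res
  })

  ## --- differential cytokines & metabolites -------------------------------
  cyt <- .stage("cytokines", outdir, {
    d <- mannwhitney_diff(cohort$cytokines, cohort$covariates,
                          fdr_cut = th$fdr)
    .write_tsv(d, file.path(outdir, "differential_cytokines.tsv"))
    d
  })
  met <- .stage("metabolites", outdir, {
    d <- differential_metabolites(cohort$metabolites, cohort$covariates,
                                  vip_cut = th$vip, p_cut = th$metabolite_p,
                                  fc_cut = th$fold_change)
    .write_tsv(d, file.path(outdir, "differential_metabolites.tsv"))
    d
  })

  ## --- trio causal inference ----------------------------------------------
  trios <- .stage("cit", outdir, {
    hits <- assoc$species[assoc$species$significant, c("snv_id", "feature_id")]
    diff_mets <- met$feature_id[met$significant]
    tr <- screen_trios(hits, cohort$genotypes, cohort$species,
                       cohort$metabolites, diff_mets, cohort$covariates,
                       n_perm = th$n_perm, seed = config$seed,
                       alpha = th$cit_alpha)
    if (nrow(tr)) .write_tsv(tr, file.path(outdir, "trios.tsv"))
    tr
  })

  ## --- report ---------------------------------------------------------------
  report <- .stage("report", outdir, {
    rep <- list(
      package = "triocit",
      version = as.character(utils::packageVersion("triocit")),
      mode = if (sim_mode) "simulate" else "ingest",
      seed = config$seed,
      thresholds = th,
      counts = list(
        variants = triage$counts,
        functional_snvs = div$n_functional,
        spectrum_records = spectrum$n,
        association = lapply(assoc, function(a)
          list(tested = nrow(a), significant = sum(a$significant),
               skipped = attr(a, "n_skipped"))),
        cytokines = list(tested = nrow(cyt),
                         significant = sum(cyt$significant)),
        metabolites = list(tested = nrow(met),
                           significant = sum(met$significant)),
        trios = list(evaluated = nrow(trios),
                     by_direction = if (nrow(trios))
                       as.list(table(trios$direction)) else list())),
      correlations = list(
        genotype_pc1_vs_alpha = div$pc1_diversity,
        genotype_pc1_vs_microbiome_pc1 = div$pc1_pc1))
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    rep
  })
  invisible(list(report = report, triage = triage, diversity = div,
                 association = assoc, cytokines = cyt, metabolites = met,
                 trios = trios, cohort = cohort, outdir = outdir))
}
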