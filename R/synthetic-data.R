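#' Configuration for a synthetic two-group cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' describe a small case-control exome + metagenome + metabolome + cytokine
#' study: 26 cases and 26 controls, a panel of 7 serum cytokines of which 5
#' carry a one log-unit group shift, and a handful of embedded
#' variant-microbe-metabolite chains.
#'
#' @param n_case,n_control group sizes.
#' @param n_snv number of biallelic variants in the genotype matrix.
#' @param maf_range range (within (0, 0.5)) from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param n_species,n_pathways,n_metabolites,n_cytokines feature counts of the
#'   omics tables.
#' @param n_causal_trios,n_reactive_trios,n_pleiotropy_trios numbers of
#'   embedded trios of each class (see Details).
#' @param n_diff_cytokines number of cytokines given a group mean shift on the
#'   log scale.
#' @param n_diff_metabolites number of additional (non-trio) metabolites given
#'   a group mean shift on the log scale.
#' @param effect_snv_to_microbe,effect_microbe_to_metabolite standardized
#'   slopes of the injected chain links.
#' @param noise_sd standard deviation of the noise terms on the injected
#'   chain links (log scale).
#' @param cytokine_shift,metabolite_shift group mean shift, in log units, for
#'   differential cytokines / metabolites.
#' @param confound_age if `TRUE`, case ages are shifted upwards so covariate
#'   adjustment is exercised under confounding.
#' @param seed root seed; every random stream is derived from it via
#'   [derive_seed()].
#'
#' @details Three trio classes are embedded on the latent (pre-closure) log
#' scale, with `G` the standardized dosage of the trio's variant:
#' \describe{
#'   \item{causal}{microbe = b1 G + e1, metabolite = c1 microbe + e2 (chain).}
#'   \item{reactive}{metabolite = b1 G + e1, microbe = c1 metabolite + e2.}
#'   \item{pleiotropy}{microbe = b1 G + e1, metabolite = b1 G + e2 with
#'     independent noises — the null that mediation tests must not call
#'     causal.}
#' }
#' Trio metabolites additionally receive the group shift so they satisfy the
#' differential-metabolite gate that feeds the trio screen.
#'
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 26, n_control = 26,
                          n_snv = 100, maf_range = c(0.1, 0.4),
                          n_species = 50, n_pathways = 30,
                          n_metabolites = 40, n_cytokines = 7,
                          n_causal_trios = 3, n_reactive_trios = 2,
                          n_pleiotropy_trios = 2,
                          n_diff_cytokines = 5, n_diff_metabolites = 5,
                          effect_snv_to_microbe = 0.8,
                          effect_microbe_to_metabolite = 0.8,
                          noise_sd = 0.5,
                          cytokine_shift = 1, metabolite_shift = 1,
                          confound_age = FALSE,
                          seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control, n_snv = n_snv,
              maf_range = maf_range, n_species = n_species,
              n_pathways = n_pathways, n_metabolites = n_metabolites,
              n_cytokines = n_cytokines, n_causal_trios = n_causal_trios,
              n_reactive_trios = n_reactive_trios,
              n_pleiotropy_trios = n_pleiotropy_trios,
              n_diff_cytokines = n_diff_cytokines,
              n_diff_metabolites = n_diff_metabolites,
              effect_snv_to_microbe = effect_snv_to_microbe,
              effect_microbe_to_metabolite = effect_microbe_to_metabolite,
              noise_sd = noise_sd, cytokine_shift = cytokine_shift,
              metabolite_shift = metabolite_shift,
              confound_age = confound_age, seed = seed)
  counts <- c("n_case", "n_control", "n_snv", "n_species", "n_pathways",
              "n_metabolites", "n_cytokines", "n_causal_trios",
              "n_reactive_trios", "n_pleiotropy_trios", "n_diff_cytokines",
              "n_diff_metabolites")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("configuration error: ", nm, " must be a non-negative integer")
    }
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("configuration error: maf_range must lie within (0, 0.5)")
  }
  if (noise_sd <= 0) stop("configuration error: noise_sd must be positive")
  n_trios <- n_causal_trios + n_reactive_trios + n_pleiotropy_trios
  if (n_trios > min(n_snv, n_species, n_metabolites)) {
    stop("configuration error: more embedded trios (", n_trios,
         ") than available variants, species or metabolites")
  }
  if (n_diff_cytokines > n_cytokines) {
    stop("configuration error: n_diff_cytokines exceeds n_cytokines")
  }
  if (n_trios + n_diff_metabolites > n_metabolites) {
    stop("configuration error: trio metabolites plus differential metabolites ",
         "exceed n_metabolites")
  }
  structure(cfg, class = "cohort_config")
}

.cytokine_names <- function(n) {
  panel <- c("IL-1b", "IL-4", "IL-6", "IL-10", "IL-17a", "MCP-1", "TGF-b")
  if (n <= length(panel)) panel[seq_len(n)] else
    c(panel, sprintf("cyt%02d", seq_len(n - length(panel)) + length(panel)))
}

# Draw a dosage column with non-zero variance (retry degenerate draws so the
# embedded-effect columns always admit a regression).
.draw_dosage <- function(n, maf) {
  for (i in 1:50) {
    g <- stats::rbinom(n, 2L, maf)
    if (stats::var(g) > 0) return(g)
  }
  g[1] <- ifelse(g[1] == 0L, 1L, 0L)
  g
}

#' Generate a seeded synthetic cohort with embedded ground truth
#'
#' Draws a two-group cohort with the statistical structure the downstream
#' screens assume: binomial genotype dosages, log-normal species and pathway
#' abundances closed to relative abundances per sample, log-normal metabolite
#' intensities, log-normal cytokine levels with group shifts on a chosen
#' subset, uniform child ages and Bernoulli(0.5) sex independent of group
#' (unless `confound_age`), and the embedded trio chains described in
#' [cohort_config()]. All injections are recorded in a truth ledger.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `genotypes`
#'   (samples x variants dosage matrix), `snv_info` (per-variant annotation),
#'   `species`, `pathways` (samples x features relative abundances),
#'   `metabolites`, `cytokines` (samples x features intensities), `covariates`
#'   (data.frame sample_id, age, sex, group) and `truth` (list with
#'   `trio_labels`, `differential_features`, `variant_fate`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_case + config$n_control
  samples <- c(sprintf("ASD%02d", seq_len(config$n_case)),
               sprintf("TD%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  is_case <- group == "case"

  ## covariates (stream 1)
  set.seed(derive_seed(config$seed, 1))
  age <- stats::runif(n, 3, 12)
  if (config$confound_age) age <- age + 2 * is_case
  sex <- stats::rbinom(n, 1L, 0.5)
  covariates <- data.frame(sample_id = samples, age = age, sex = sex,
                           group = group, stringsAsFactors = FALSE)

  ## genotypes (stream 2)
  set.seed(derive_seed(config$seed, 2))
  snv_ids <- sprintf("snv%03d", seq_len(config$n_snv))
  mafs <- stats::runif(config$n_snv, config$maf_range[1], config$maf_range[2])
  G <- vapply(mafs, function(m) .draw_dosage(n, m), integer(n))
  dimnames(G) <- list(samples, snv_ids)
  effects <- c("nonsynonymous", "stopgain", "stoploss", "synonymous", "noncoding")
  snv_effect <- sample(effects, config$n_snv, replace = TRUE,
                       prob = c(0.55, 0.10, 0.05, 0.20, 0.10))
  snv_info <- data.frame(
    snv_id = snv_ids, chrom = paste0("chr", sample(1:22, config$n_snv, TRUE)),
    pos = sort(sample.int(5e7, config$n_snv)),
    gene = sprintf("GENE%03d", seq_len(config$n_snv)),
    effect = snv_effect, maf = mafs, stringsAsFactors = FALSE)

  ## trio assignment (stream 3)
  set.seed(derive_seed(config$seed, 3))
  n_trios <- config$n_causal_trios + config$n_reactive_trios +
    config$n_pleiotropy_trios
  trio_snv <- if (n_trios) sample.int(config$n_snv, n_trios) else integer(0)
  trio_sp <- if (n_trios) sample.int(config$n_species, n_trios) else integer(0)
  trio_met <- if (n_trios) sample.int(config$n_metabolites, n_trios) else integer(0)
  trio_label <- rep(c("causal", "reactive", "pleiotropy"),
                    c(config$n_causal_trios, config$n_reactive_trios,
                      config$n_pleiotropy_trios))
  b1 <- config$effect_snv_to_microbe
  c1 <- config$effect_microbe_to_metabolite
  nsd <- config$noise_sd
  microbe_signal <- metabolite_signal <- matrix(0, n, max(n_trios, 1L))
  if (n_trios) {
    for (j in seq_len(n_trios)) {
      g <- G[, trio_snv[j]]
      gz <- if (stats::var(g) > 0) as.numeric(scale(g)) else rep(0, n)
      if (trio_label[j] == "causal") {
        m <- b1 * gz + stats::rnorm(n, 0, nsd)
        t_ <- c1 * m + stats::rnorm(n, 0, nsd)
      } else if (trio_label[j] == "reactive") {
        t_ <- b1 * gz + stats::rnorm(n, 0, nsd)
        m <- c1 * t_ + stats::rnorm(n, 0, nsd)
      } else {
        m <- b1 * gz + stats::rnorm(n, 0, nsd)
        t_ <- b1 * gz + stats::rnorm(n, 0, nsd)
      }
      microbe_signal[, j] <- m
      metabolite_signal[, j] <- t_
    }
  }

  ## species and pathways (streams 4, 5): log-normal latent then closure
  close_rows <- function(latent) {
    ab <- exp(latent)
    sweep(ab, 1, rowSums(ab), "/")
  }
  set.seed(derive_seed(config$seed, 4))
  sp_ids <- sprintf("sp%03d", seq_len(config$n_species))
  sp_mu <- stats::rnorm(config$n_species, 0, 1.5)
  sp_latent <- matrix(stats::rnorm(n * config$n_species, 0, 1), n) +
    matrix(sp_mu, n, config$n_species, byrow = TRUE)
  if (n_trios) {
    for (j in seq_len(n_trios)) {
      sp_latent[, trio_sp[j]] <- sp_mu[trio_sp[j]] + microbe_signal[, j]
    }
  }
  species <- close_rows(sp_latent)
  dimnames(species) <- list(samples, sp_ids)

  set.seed(derive_seed(config$seed, 5))
  pw_ids <- sprintf("path%03d", seq_len(config$n_pathways))
  pw_latent <- matrix(stats::rnorm(n * config$n_pathways, 0, 1), n) +
    matrix(stats::rnorm(config$n_pathways, 0, 1), n, config$n_pathways,
           byrow = TRUE)
  pathways <- close_rows(pw_latent)
  dimnames(pathways) <- list(samples, pw_ids)

  ## metabolites (stream 6): log-normal intensities, meanlog ~ 10
  set.seed(derive_seed(config$seed, 6))
  met_ids <- sprintf("met%03d", seq_len(config$n_metabolites))
  met_mu <- stats::rnorm(config$n_metabolites, 10, 1)
  met_log <- matrix(stats::rnorm(n * config$n_metabolites, 0, 1), n) +
    matrix(met_mu, n, config$n_metabolites, byrow = TRUE)
  diff_met <- integer(0)
  if (config$n_diff_metabolites) {
    pool <- setdiff(seq_len(config$n_metabolites), trio_met)
    diff_met <- sample(pool, config$n_diff_metabolites)
    met_log[, diff_met] <- met_log[, diff_met] + config$metabolite_shift * is_case
  }
  if (n_trios) {
    for (j in seq_len(n_trios)) {
      met_log[, trio_met[j]] <- met_mu[trio_met[j]] + metabolite_signal[, j] +
        config$metabolite_shift * is_case
    }
  }
  metabolites <- exp(met_log)
  dimnames(metabolites) <- list(samples, met_ids)

  ## cytokines (stream 7)
  set.seed(derive_seed(config$seed, 7))
  cyt_ids <- .cytokine_names(config$n_cytokines)
  cyt_mu <- stats::rnorm(config$n_cytokines, 2, 0.5)
  cyt_log <- matrix(stats::rnorm(n * config$n_cytokines, 0, 1), n) +
    matrix(cyt_mu, n, config$n_cytokines, byrow = TRUE)
  diff_cyt <- integer(0)
  if (config$n_diff_cytokines) {
    diff_cyt <- sample.int(config$n_cytokines, config$n_diff_cytokines)
    cyt_log[, diff_cyt] <- cyt_log[, diff_cyt] + config$cytokine_shift * is_case
  }
  cytokines <- exp(cyt_log)
  dimnames(cytokines) <- list(samples, cyt_ids)

  ## truth ledger
  trio_labels <- data.frame(
    snv_id = snv_ids[trio_snv], species_id = sp_ids[trio_sp],
    metabolite_id = met_ids[trio_met],
    label = if (n_trios) trio_label else character(0),
    stringsAsFactors = FALSE)
  diff_rows <- function(kind, ids, shift) {
    data.frame(table_kind = rep(kind, length(ids)), feature_id = ids,
               direction = rep(if (shift >= 0) "up" else "down", length(ids)),
               stringsAsFactors = FALSE)
  }
  differential_features <- rbind(
    diff_rows("cytokines", cyt_ids[sort(diff_cyt)], config$cytokine_shift),
    diff_rows("metabolites", met_ids[sort(c(diff_met, trio_met))],
              config$metabolite_shift))
  truth <- list(trio_labels = trio_labels,
                differential_features = differential_features,
                variant_fate = data.frame(snv_id = character(0),
                                          fate = character(0),
                                          stringsAsFactors = FALSE))

  structure(list(genotypes = G, snv_info = snv_info, species = species,
                 pathways = pathways, metabolites = metabolites,
                 cytokines = cytokines, covariates = covariates,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$genotypes), "samples (",
      sum(x$covariates$group == "case"), "case /",
      sum(x$covariates$group == "control"), "control ),",
      ncol(x$genotypes), "variants,", ncol(x$species), "species,",
      ncol(x$metabolites), "metabolites,", ncol(x$cytokines), "cytokines\n")
  cat("embedded trios:", nrow(x$truth$trio_labels), "(",
      paste(table(x$truth$trio_labels$label), collapse = "/"), ")\n")
  invisible(x)
}
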