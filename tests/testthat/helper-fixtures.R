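# Shared fixture builders. Everything is generated in code at test time.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_case = 15, n_control = 15, n_snv = 30, n_species = 20,
         n_pathways = 10, n_metabolites = 15, n_cytokines = 7,
         n_causal_trios = 2, n_reactive_trios = 1,
         n_pleiotropy_trios = 1, n_diff_cytokines = 3,
         n_diff_metabolites = 3, seed = 42),
    list(...))
  do.call(cohort_config, args)
}

# One variant record with every filter rule satisfied; tweak fields to build
# boundary cases.
toy_record <- function(snv_id = "v1", base_quality = 40, depth = 60,
                       alt_reads = 10, gap_distance = 50,
                       effect = "nonsynonymous",
                       ref = "C", alt = "A", context = "ACA",
                       carriers_case = "ASD01,ASD02,ASD03",
                       carriers_control = "") {
  data.frame(snv_id = snv_id, chrom = "chr1", pos = 100, ref = ref, alt = alt,
             base_quality = base_quality, depth = depth,
             alt_reads = alt_reads, gap_distance = gap_distance,
             gene = "GENE1", effect = effect, context = context,
             carriers_case = carriers_case,
             carriers_control = carriers_control, stringsAsFactors = FALSE)
}

empty_freqs <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), db_name = character(0), maf = numeric(0),
             stringsAsFactors = FALSE)
}

freq_row <- function(rec, db = "ExAC", maf = 0.01) {
  data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
             db_name = db, maf = maf, stringsAsFactors = FALSE)
}

# Simulate one mediation trio; kind selects the generative structure.
sim_trio <- function(n = 200, b1 = 0.5, c1 = 0.5, noise = 0.5,
                     kind = c("causal", "pleiotropy", "null"), maf = 0.3) {
  kind <- match.arg(kind)
  L <- rbinom(n, 2, maf)
  while (var(L) == 0) L <- rbinom(n, 2, maf)
  Lz <- as.numeric(scale(L))
  if (kind == "causal") {
    M <- b1 * Lz + rnorm(n, 0, noise)
    T_ <- c1 * M + rnorm(n, 0, noise)
  } else if (kind == "pleiotropy") {
    M <- b1 * Lz + rnorm(n, 0, noise)
    T_ <- b1 * Lz + rnorm(n, 0, noise)
  } else {
    M <- rnorm(n)
    T_ <- rnorm(n)
  }
  list(L = L, M = M, T = T_)
}

# Independent brute-force step-up FDR: literal min over j >= i of m p_(j)/j.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q <- vapply(seq_len(m), function(i) min(m * po[i:m] / (i:m)), numeric(1))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of rank arrangements.
enumerate_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  combos <- utils::combn(m + n, m)
  u_all <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
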