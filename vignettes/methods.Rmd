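---
title: "Methods: from rare exonic variants to variant-microbe-metabolite trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from rare exonic variants to variant-microbe-metabolite trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triocit` implements an integration analysis for small case-control cohorts
in which four data layers are measured on the same individuals: exonic
single-nucleotide variants (SNVs), gut metagenome relative abundances
(species and functional pathways), fecal metabolite intensities, and serum
cytokine levels. The question the pipeline is built around is whether host
genetic variation shapes the gut microbiome, and whether particular variants
act on particular metabolites *through* a microbe — a mediation question,
answered by a causal inference test run on (SNV, microbe, metabolite) trios.

This vignette describes each stage's model and assumptions, the tunable
parameters and their defaults, the synthetic-cohort generator used for
validation, and the numerical and design choices that were genuinely open.

## Variant triage

Exome variant calls are triaged by four pure predicates, applied as a
cascade but equivalent to an intersection:

1. **Sequencing QC** — keep a record iff base quality >= 30, depth >= 30,
   alternate-allele reads >= 3, and distance to the nearest alignment gap
   greater than 5 bp. "Within 5 bp of a gap" is read inclusively: a record
   at distance exactly 5 is removed.
2. **Control absence** — variants carried by any control individual are
   removed; the candidate set is case-private.
3. **Population rarity** — a variant is removed if *any* reference panel
   (three emulated databases: a thousand-genomes-style panel, an exome
   aggregation panel, and a large Chinese population panel) reports
   MAF >= 5%. The boundary is strict (`maf < 0.05` keeps). A variant absent
   from every panel is **kept**: being unseen in population panels of that
   size is stronger evidence of rarity than a small recorded frequency.
4. **Recurrence** — keep variants detected in at least 3 cases ("more than
   two"); the threshold is a flag (`min_case_carriers`) for the alternative
   >= 2 reading.

Because each rule is a predicate on a single record, the kept set is
order-independent; order matters only for which reason tag a
multiply-failing record receives (the QC sentence order is used).

Functional (protein-altering) variants — non-synonymous, stop-gain,
stop-loss — are the subset used for genotype PCA.

## Mutation spectra

Candidate sets are summarized as a six-class substitution spectrum and the
96-bin trinucleotide-context spectrum (COSMIC bin order, `A[C>A]A` ...
`T[T>G]T`). Purine-reference records are reverse-complement folded onto the
pyrimidine-reference classes; folding is idempotent. Two spectra are
compared by cosine similarity of the (normalized) 96-bin vectors; the
six-class cosine is also available. Cosine is a deliberate choice — it is
the standard metric for signature comparison and is invariant to the total
mutation count.

## Diversity and composition

Alpha diversity is the Gini-Simpson index \(1 - \sum_i p_i^2\) of a
sample's species relative abundances (higher = more diverse); plain Simpson
\(\sum p_i^2\) and inverse Simpson are options. PCA is performed on the
column-centered functional-SNV dosage matrix (not variance-scaled: dosages
share a scale) and on centered species relative abundances (no log-ratio
transform by default; that choice is exposed). Each component's sign is
fixed by making its largest-magnitude loading positive, so results are
deterministic. The link between host genetic structure and microbiome
diversity is reported as the Pearson correlation (with the usual
\(t_{n-2}\) p-value) between genotype PC1 and per-sample Simpson diversity;
Spearman is available.

## Association and differential screens

Variant-feature association uses ordinary least squares of the transformed
feature on `[intercept, dosage, age, sex]`, with the two-sided t-test on the
dosage coefficient. Default measurement transforms, applied consistently in
the association screen *and* in the trio test so both see identical data:

| table | transform |
|---|---|
| species, pathways | `log10(x + 1e-6)` (relative abundances) |
| metabolites | z-scored `log10` intensity |
| cytokines | natural log |

Dosage is additive (0/1/2); a carrier (0/1) collapse can be passed instead,
since the regression accepts any numeric coding. Multiple testing is
controlled with Benjamini-Hochberg step-up FDR *within each screen family*
(one family per feature-table kind), matching per-analysis reporting.

Differential cytokines: Mann-Whitney U on log levels, exact two-sided
p-value by the null distribution of U when both groups have <= 8 samples
(full enumeration with midranks when ties are present), otherwise the
normal approximation with tie and continuity corrections; BH across the
panel; significant iff FDR < 0.05. The exact/approximate switch at 8 caps
enumeration cost at `choose(16, 8) = 12870` arrangements.

Differential metabolites use the three-part rule: PLS-DA VIP > 1, Welch
t-test p < 0.05 on log10 intensities, and raw-scale fold change
(case mean / control mean) > 1.5. The fold-change rule is two-sided by
default (FC > 1.5 **or** FC < 1/1.5) because depleted metabolites are as
relevant as enriched ones; the literal one-sided reading is a flag. VIP is
computed from a NIPALS partial-least-squares fit of the centered group code
on autoscaled features:
\[
VIP_j = \sqrt{p \cdot \sum_a w_{ja}^2\, SSY_a / \sum_a SSY_a},
\]
which forces \(\mathrm{mean}_j(VIP_j^2) = 1\) — the identity the test suite
asserts. Plain PLS-DA is used rather than the orthogonal variant: orthogonal
signal filtering does not change the VIP identity, and the plain fit agrees
with the reference implementation in `mixOmics` to machine precision (a
cross-check in the test suite). The t-test is Welch's, since equal group
variances are not assumed.

## The four-condition trio test

For a trio (L = SNV dosage, M = microbe, T = metabolite), all four
conditions must hold for mediation, each adjusted for age and sex:

1. L associated with M (`M ~ L + cov`);
2. L associated with M given T (`M ~ L + T + cov`);
3. M associated with T given L (`T ~ M + L + cov`);
4. L independent of T given M.

`p_cit = max(p1, p2, p3, p4)`, asserted on every call. Conditions 1-3 are
t/F tests on one coefficient, computed by Frisch-Waugh partialling
(numerically identical to the full OLS fit, and fast enough for thousands
of permutations).

Condition 4 is the delicate one: it asks for evidence *for* a null. A naive
"1 minus the association p-value" has essentially no power, and neither
does comparing the observed conditional F statistic with a permutation
distribution that is itself central — under a genuine chain the observed
statistic is just another central draw, so such a p-value is uniform, and a
max-p test built on it can never call a chain causal at any usable rate. The
package therefore uses an equivalence-test construction: fit the *marginal*
regression `T ~ L + cov`, and build surrogate outcomes
`T*_b = fitted + permuted residuals`. Each surrogate retains the full
observed marginal L-T effect but, by construction, none of it is mediated
by M, so the conditional statistics `F_b` (for L in `T* ~ L + M + cov`)
embody the "dependence at the observed strength" alternative. Then
\[
p_4 = \frac{1 + \#\{F_b \le F_{obs}\}}{B + 1}.
\]
Under a chain, \(F_{obs}\) collapses while the `F_b` stay large, so
\(p_4 \to 0\); under pleiotropy (L drives M and T separately) the
conditional effect equals the marginal one, \(F_{obs}\) sits inside the
`F_b` distribution, and \(p_4\) is roughly uniform — which is exactly what
separates the two cases. Under a global null the max-p construction is
conservative. The naive parametric variant remains available as
`method = "naive"` for comparison.

Directionality is decided by running the test in both orientations
(microbe as mediator vs metabolite as mediator): **causal** iff only the
forward chain is supported at `alpha = 0.05`, **reactive** iff only the
reverse, **independent** iff neither, **ambiguous** iff both.

Numerical details: `B = 1000` permutations by default (tests and the
pipeline use 100-500 where stated); per-trio seeds are derived from the
root seed and trio index by a fixed affine map mod \(2^{31}-1\)
(`derive_seed()`), so any single trio is reproducible in isolation; inputs
are internally sorted into a canonical sample order before the permutation
stream is drawn, making `p4` exactly invariant to how the caller ordered
the samples.

## The synthetic cohort generator

No processed cohort tables are publicly available at desk scale for this
kind of study, so validation is simulation-based and recovery-oriented. The
generator emulates the study design the pipeline targets, with defaults:
26 cases / 26 controls; 100 variants with per-variant MAF uniform on
(0.1, 0.4) and binomial(2, maf) dosages; 50 species and 30 pathways drawn
log-normal (between-feature spread sd 1.5, within-feature noise sd 1 on the
log scale) and closed to relative abundances; 40 metabolites, log-normal
with meanlog ~ 10; the 7-cytokine serum panel (IL-1b, IL-4, IL-6, IL-10,
IL-17a, MCP-1, TGF-b), log-normal with sd 1, of which 5 receive a one
log-unit case shift; ages uniform on 3-12 years and sex Bernoulli(0.5),
independent of group (a `confound_age` mode shifts case ages for testing
adjustment under confounding).

Embedded effects, with `G` the standardized trio-variant dosage and
defaults `b1 = c1 = 0.8`, noise sd 0.5:

- **causal**: microbe latent = `b1*G + e1`; metabolite = `c1*microbe + e2`;
- **reactive**: metabolite = `b1*G + e1`; microbe = `c1*metabolite + e2`;
- **pleiotropy**: both driven by G with independent noises — the null that
  condition 4 must reject calling causal.

Injection acts on the *latent* (pre-closure) log abundance so the stated
slope is not distorted by compositional closure. Trio metabolites also
receive the one log-unit group shift, so they pass the
differential-metabolite gate that feeds the trio screen — mirroring a
pipeline in which trio candidates are drawn from the differential set.
Every injection is recorded in a truth ledger (`trio_labels`,
`differential_features`, `variant_fate`), which the recovery tests treat as
ground truth. All randomness flows from one root seed through
`derive_seed()`; identical configurations reproduce identical bytes on
disk.

What the generator does **not** emulate: sequencing noise and zero
inflation in abundance tables, phylogenetic correlation between species,
batch effects, metabolite-metabolite correlation structure, covariate
matching between groups (ages are independent draws, not matched pairs).
Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated generative model, not robustness to
every artifact of real multi-omic data.

The labeled variant stream walks every filter boundary (quality/depth
straddling 30, alternate reads straddling 3, gap distance straddling 5,
MAF straddling 0.05 per panel and database absence, carrier counts
straddling 3, control presence, all five functional classes) and records
each record's expected verdict, giving the cascade an exact, enumerable
oracle.

## Problem sizes and runtime choices

The test suite validates the trio test's operating characteristics at
n = 200 (1,000 null trios at B = 200 for type-I error; 500 causal and 500
pleiotropy trios at slopes 0.5, noise 0.5, B = 500 for discrimination), and
end-to-end recovery at the cohort's own 26+26 across 20 root seeds. These
sizes were chosen so the whole suite runs in about a minute on one core
while keeping Monte-Carlo error well below the margins being asserted;
the vectorized permutation scheme (one `n x B` projection per trio) is what
makes that cheap.

## Known limitations

- The trio test assumes linear relations on the transformed scales and a
  single mediator; non-linear mediation and multi-mediator structures are
  out of scope.
- No omnibus FDR is computed across trios; `p_cit` values are reported
  per-trio and sorted, with classification at a fixed `alpha = 0.05`.
- The compositional nature of relative abundances is handled only by the
  log transform; no CLR/ALR machinery or compositionally-aware differential
  methods are included.
- Mutation-signature *decomposition* (NMF against reference signatures) is
  out of scope; only spectra and their cosine comparison are provided.
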