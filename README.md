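# triocit

Host-genetics × gut-microbiome × metabolome × immune integration for small
case-control cohorts, centered on a four-condition **causal inference test**
that classifies (SNV, microbe, metabolite) trios as causal chains, reactive
chains, independent, or ambiguous.

The package is aimed at studies in which a case-control cohort (the
motivating design is 26 cases and 26 matched controls of an exome +
metagenome + metabolome + serum-cytokine study) is profiled on four layers,
and the analysis asks: which rare exonic variants are enriched in cases,
whether host genetic structure relates to gut microbial diversity, which
variant-feature associations survive covariate adjustment and FDR control,
which cytokines and metabolites differ between groups — and, for variants
associated with a microbe, whether the microbe *mediates* an effect of the
variant on a metabolite.

## What it provides

- **Rare-variant triage**: QC predicates (base quality ≥ 30, depth ≥ 30,
  alt reads ≥ 3, > 5 bp from a gap), removal of control-carried variants,
  strict MAF < 5% rarity against population allele-frequency panels
  (database-absent variants are kept), and a ≥ 3-case-carrier recurrence
  rule — each exposed individually and as a cascade with per-record verdicts.
- **Mutation spectra**: six-class and 96-trinucleotide-context counts
  (pyrimidine-reference folding, COSMIC bin order) and cosine comparison.
- **Diversity & composition**: Gini-Simpson alpha diversity, PCA with a
  deterministic sign convention, and PC-vs-diversity correlation.
- **Screens**: covariate-adjusted (age, sex) linear regression of features
  on dosage with Benjamini-Hochberg FDR per family; Spearman matrices;
  exact/corrected Mann-Whitney differential cytokines; and the PLS-DA
  VIP > 1 & Welch-t p < 0.05 & fold-change > 1.5 differential-metabolite
  rule (NIPALS VIP, validated against `mixOmics` to machine precision).
- **Trio causal inference**: the four-condition test — (1) L~M, (2) L~M|T,
  (3) M~T|L, (4) L⊥T|M — with `p_cit = max(p1..p4)`, an equivalence-type
  permutation construction for condition 4, and two-directional
  classification.
- **A seeded synthetic-cohort generator** with embedded causal / reactive /
  pleiotropic trios, differential cytokines/metabolites, and a truth ledger,
  so the whole pipeline is validated by recovery.

The model, parameter defaults, and every open design choice are documented
in `vignettes/methods.Rmd`.

## Worked example

Simulate a 26 + 26 cohort with 3 embedded causal trios and run the whole
pipeline:

```r
library(triocit)

cfg <- pipeline_config(simulate = list(seed = 5), seed = 5,
                       thresholds = list(n_perm = 200),
                       outdir = "demo_run")
res <- run_pipeline(cfg)
res$trios[1:4, c("snv_id", "microbe_id", "metabolite_id",
                 "p_cit_forward", "p_cit_reverse", "direction")]
#>  snv_id microbe_id metabolite_id p_cit_forward p_cit_reverse direction
#>  snv013      sp022        met030       0.00498        0.5416    causal
#>  snv030      sp024        met025       0.01493        0.1261    causal
#>  snv093      sp034        met019       0.01493        0.0348 ambiguous
#>  snv017      sp007        met036       0.04778        0.0199 ambiguous
```

The run report (`demo_run/report.json`) reconciles counts at every stage:
of 40 simulated variant records, 7 fail sequencing QC, 1 is control-carried,
5 are common in a population panel, 4 lack case recurrence, leaving 23
candidates; 5 of 7 cytokines and 11 metabolites are called differential;
66 trios (6 significant SNV-microbe pairs × 11 differential metabolites)
are evaluated, of which 2 are classified causal — and those two are
embedded causal chains of the generator (`res$cohort$truth$trio_labels`).
The third embedded chain is the first "ambiguous" row: its forward p-value
is small, but at n = 52 the reverse direction cannot be excluded.

Single-stage use is just as direct:

```r
co <- generate_cohort(cohort_config(seed = 1))
mannwhitney_diff(co$cytokines, co$covariates)
#>   feature_id stat        p      fdr fold_change significant
#> 1      IL-1b  380 4.48e-01 5.22e-01       1.264       FALSE
#> 2       IL-4  304 5.40e-01 5.40e-01       0.839       FALSE
#> 3       IL-6  596 2.45e-06 1.71e-05       4.470        TRUE
#> 4      IL-10  578 1.17e-05 4.09e-05       3.907        TRUE
#> 5     IL-17a  444 5.35e-02 7.49e-02       1.647       FALSE
#> 6      MCP-1  509 1.81e-03 3.16e-03       2.924        TRUE
#> 7      TGF-b  516 1.16e-03 2.71e-03       3.256        TRUE
```

(The cohort's truth ledger embeds a one log-unit shift in five of the seven
cytokines; at this seed four of the five are recovered at FDR < 0.05 and no
unshifted cytokine is called.)

A thin command-line wrapper for YAML-configured runs is installed at
`inst/scripts/run-pipeline.R`.

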