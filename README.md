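# oxisig

Cross-species scoring of hyperoxia gene-expression signatures.

Neonatal hyperoxia is the classic experimental model of bronchopulmonary
dysplasia (BPD), the chronic lung disease of prematurity. A recurring
analysis pattern in this field is to (i) derive sex- and genotype-specific
*hyperoxia signatures* — the genes up- and down-regulated in
hyperoxia-exposed versus room-air mouse lungs — and then (ii) ask whether
those murine signatures are reflected in independent human cohorts: do the
signature scores co-vary across healthy human lungs, and do they track BPD
severity and its clinical correlates in preterm-infant blood
transcriptomes? `oxisig` implements that pipeline end to end for
bioinformaticians and lung biologists, together with a synthetic-data
module that generates every input with planted ground truth, so the whole
chain is testable without any external download.

## The statistic at the core

Each signature is a pair of disjoint gene sets (U, D). Expression is first
standardized per gene across the samples of the cohort,

    z_gs = (x_gs − mean_g) / sd_g        (sample SD, n − 1)

and the per-sample **summed z-score** is

    score_s = Σ_{g ∈ U} z_gs − Σ_{g ∈ D} z_gs .

Around this sit: log2-CPM normalization and per-contrast Welch tests with
Benjamini–Hochberg FDR (signatures thresholded at q ≤ 0.05 and fold
change ≥ 1.5×); Biomart-style ortholog translation (human symbols into
mouse symbol space, per the conventional orientation); Pearson correlation
of scores with each other and with clinical covariates (exact t reference,
stratified by sex); preranked gene-set enrichment (weighted
Kolmogorov–Smirnov running sum, permutation NES/p/FDR, significance at
FDR < 0.25) with cross-contrast discordant-pathway detection; and a
2^−ΔΔCt qRT-PCR fold-change utility with multi-housekeeping, sex-stratified
normalization.

## Worked example

```r
library(oxisig)

# mouse cohort: 2x2x2 factorial, 120 genes planted to respond in the
# knockout female hyperoxia contrast
g   <- simulated_genes(2000)
eff <- planted_effects(tibble::tibble(
  contrast = "F_KO", gene = g[1:120], log2_fc = rep(c(2, -2), c(60, 60))))
sim  <- simulate_mouse_counts(mouse_design(n_per_group = 5, n_genes = 2000),
                              eff, seed = 42)
expr <- cpm_normalize(sim$counts)
degs <- hyperoxia_contrasts(expr, sim$metadata)
sig  <- extract_signature(degs$F_KO, fdr_max = 0.05, min_fold = 1.5)
sig
#> <gene_signature> F_KO: 58 up, 53 down

# project the signature onto a healthy reference cohort (n = 578)
ref    <- simulate_reference_cohort(n_samples = 578, n_genes = 2000, seed = 43)
scores <- score_signatures(ref, list(sig))
glance(scores)
#> # A tibble: 1 × 8
#>   signature n_samples mean_score sd_score n_up_used n_down_used n_missing
#> 1 F_KO            578  -1.30e-15     9.55        58          53         0

# clinical cohort (43/40/13/15 none/mild/moderate/severe) with a 0.5 SD
# per-severity-level shift planted on the signature genes
cs     <- simulate_clinical_cohort(delta = 0.5, signature = sig,
                                   n_genes = 2000, seed = 44)
cscore <- score_signatures(cs$expression, list(sig))
dplyr::filter(clinical_correlation(cscore, cs$clinical), stratum == "all")
#>   signature variable              stratum      r  p_value     n computable
#> 1 F_KO      gestational_age_weeks all     -0.567 8.39e-11   111 TRUE
#> 2 F_KO      birth_weight_g        all     -0.389 2.47e- 5   111 TRUE
#> 3 F_KO      bpd_severity          all      0.984 2.34e-83   111 TRUE
#> 4 F_KO      oxygen_28d            all      0.604 2.19e-12   111 TRUE
```

The recovered pattern is the planted one: the signature score rises
steeply with BPD severity (r = 0.98 over 111 subjects) and falls with
gestational age and birth weight, which the generator draws negatively
correlated with severity. `run_pipeline(pipeline_config(seed = 1))`
executes the same chain — plus ortholog translation, inter-signature
correlation with clustering, GSEA and discordant-pathway detection — and
writes every table, an `inst/scripts/oxisig-pipeline.R` wrapper exposes it
to the shell, and `autoplot()` / `plot_score_severity()` /
`plot_nes_heatmap()` draw the standard figures.

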