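---
title: "Methods: hyperoxia signature scoring, correlation and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperoxia signature scoring, correlation and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxisig)
```

`oxisig` analyses the transcriptomic response of the neonatal lung to
hyperoxia and its projection onto human cohorts. This vignette is the
package's account of the methods: the models and their assumptions, the
parameters that matter, the numerical conventions, and what the synthetic
data can and cannot establish.

## The analysis chain

1. **Differential expression per contrast.** Counts are normalized to
   `log2((count + 0.5) / (library + 1) × 1e6)` and each sex-by-genotype
   cell is tested hyperoxia vs room air with a per-gene Welch t-test on
   the log scale; q-values are Benjamini–Hochberg within each contrast.
   The Welch test is a deliberately simple, self-contained engine: the
   downstream signature machinery consumes only a table of
   (gene, log2FC, p, q), so tables from a negative-binomial GLM fit can be
   substituted via `import_deg_table()` without touching anything else.
2. **Signature extraction.** A gene enters the signature when q ≤ 0.05
   and |log2FC| ≥ log2(1.5). Both bounds are inclusive; "1.5-fold" is read
   symmetrically on the log scale.
3. **Ortholog translation.** The default orientation converts the *human*
   matrix into *mouse* symbol space and scores it with untouched mouse
   signatures (the conventional direction for mouse-derived signatures);
   `translate_signature()` offers the opposite orientation. Many-to-one
   collapses average log-scale rows (order-independent, variance-stable);
   one-to-many duplicates rows; matching is case-sensitive because the
   mouse/human capitalization difference is exactly what distinguishes the
   two symbol spaces — case-folding would hide a wrong-direction map.
4. **Summed z-scores.** Genes are standardized across the cohort's
   samples with the sample SD (n − 1); the score is the plain sum of
   up-gene z-scores minus down-gene z-scores. No size normalization is
   applied: every downstream use is a Pearson correlation, which is
   scale-invariant, and a plain sum keeps the statistic exactly additive
   over disjoint signatures and exactly antisymmetric under up/down
   exchange. Zero-variance genes contribute 0 (the only value preserving
   antisymmetry); signature genes missing from the matrix are skipped and
   counted in a coverage report, mirroring how non-conserved genes drop
   out of a cross-species projection.
5. **Correlation.** Pearson r with the exact t reference
   (t = r√((n−2)/(1−r²)), n − 2 df). Constant vectors give a
   *not-computable* cell, never r = 0. BPD status is encoded as the
   ordinal severity 0–3 (none/mild/moderate/severe), consistent with a
   four-level severity axis; a binary any-BPD encoding is available.
   Strata smaller than 3 are reported as not-computable rather than
   dropped — with 13 moderate subjects, sex-splitting can empty cells, and
   silence would be misleading. No multiple-testing correction is applied
   across clinical cells by default (raw r and p are reported).
6. **Clustering.** Average-linkage agglomeration on d = 1 − r. Rows are
   sorted lexicographically first so tied merge heights resolve
   deterministically.
7. **Enrichment.** Preranked weighted-KS running sum (weight exponent 1;
   0 reduces to the classical KS statistic). The ranking metric defaults
   to sign(log2FC) × (−log10 p) — effect direction weighted by evidence —
   with plain log2FC as an option; p is floored at 1e-300 before the log
   and ties break lexicographically. The null is gene-set (label)
   permutation: the input is a preranked list, so phenotype permutation is
   unavailable. NES divides ES by the mean |null ES| of the same sign; the
   permutation p compares |ES| against the full null distribution with a
   +1 pseudo-count, which is exactly calibrated under the null and can
   reach 1/(n_perm + 1); FDR q uses the standard signed NES-pool
   procedure. Significance is the conventional FDR < 0.25. Discordant
   pathways are those significant with opposite NES sign in two
   contrasts, ranked by the NES gap.
8. **qRT-PCR.** 2^−ΔΔCt with the arithmetic mean of housekeeping Cts as
   the per-sample normalizer (equivalent to the geometric mean of their
   expression) and the room-air group *of the same sex* as baseline, so
   reference samples have geometric-mean fold 1 within each sex.

## What the generators emulate

`simulate_mouse_counts()` draws negative-binomial counts for a full
2×2×2 factorial (sex × genotype × treatment), mean–dispersion
parameterization with a constant per-gene dispersion (default 0.05,
typical of inbred-mouse bulk RNA-seq) and baseline log2 means uniform on
2–12, wide enough that CPM normalization and low-count noise are exercised
nontrivially. Planted genes shift their mean by the specified log2FC in
the hyperoxia samples of their targeted contrast only. Defaults are 5
replicates per cell and 2000 genes.

`simulate_reference_cohort()` emulates a large healthy cohort (default
n = 578) as log-scale Gaussian expression with heterogeneous per-gene
means and SDs plus a rank-3 shared-factor component, so distinct gene
sets can show correlated scores — the property the reference-cohort
analysis is designed to expose.

`simulate_clinical_cohort()` uses the 43/40/13/15
(none/mild/moderate/severe) composition, n = 111, as default. Up-genes
shift by +δ per severity level in per-gene SD units (down-genes by −δ;
default δ = 0.5, a moderate, clinically plausible blood effect);
gestational age and birth weight are drawn with r ≈ −0.5 against severity
(slope 1 week and 120 g per level with matched noise), oxygen-at-28-days
rises from 10% to 90% across grades, and sexes alternate within strata.
Under this model the expected score–severity correlation has the closed
form r = δ√V / √(δ²V + 1/k) with V the severity variance of the
composition and k the number of signature genes — the oracle the recovery
tests check against.

Deliberately **not** modeled: batch structure (the real cohorts'
batch-correction steps are out of scope, so synthetic data are
batch-free), blood-vs-lung tissue differences (the clinical cohort is
simply "an expression cohort with an ordinal outcome"), microarray
artifacts, and read-level noise. Passing tests therefore demonstrate the
statistical machinery recovers planted structure under the stated noise
model — not robustness to batch effects or platform idiosyncrasies.
The clinical generator emits already-normalized log-scale values, since
upstream normalization of such cohorts varies by platform and is not part
of this package's claim.

`simulate_ortholog_map()` mixes 1:1 pairs, 1:2 expansions and unmapped
symbols (defaults 0.8/0.1/0.1); when the fractions sum to less than one
the remainder is treated as 1:1.

## Numerical conventions

* CPM pseudocounts (0.5 count, +1 library) are fixed so outputs are
  bit-reproducible.
* Zero within-group variance in both groups: p = 1 when means are equal;
  p = 0 with a `degenerate` flag when they differ (exact separation kept
  auditable rather than silently assigned a finite p).
* Sample SD (n − 1) everywhere a z-score is formed; fixed so external
  reimplementations can match bit-for-bit.
* Every generator and the GSEA permutation block run under
  `withr::with_seed`: one integer seed reproduces any output exactly, and
  the pipeline derives stage seeds by fixed offsets from the config seed.
* The Welch test at n = 5 per group is slightly conservative (its true
  size at α = 0.05 is ≈ 0.045 even for Gaussian data); this is a property
  of the Welch–Satterthwaite approximation, not of the count model, and
  is visible in the null-calibration diagnostics.
* Summed scores are exactly antisymmetric under up/down exchange; the
  additivity identity holds to accumulation rounding (~1e-15), since the
  union accumulates in a different order than the parts.

## Problem sizes

The test-suite simulations use 2000 genes with 5–10 replicates per cell
for differential-expression properties, 100 replicate clinical cohorts of
111 subjects for severity-recovery, and 200–400 random gene sets at
500–1000 permutations for enrichment calibration — sizes at which the
Monte-Carlo bands asserted in the tests are tight enough to be
informative while the whole suite stays interactive. The pipeline default
(1000 genes, 200 reference samples, 1000 permutations) is a desk-scale
configuration of the same machinery; all sizes scale through
`pipeline_config()`.

## Limitations

The differential-expression engine is a two-group location test, not a
GLM: no covariates, no dispersion shrinkage — import external tables when
that matters. Enrichment uses gene-permutation nulls, which are known to
be less conservative than phenotype permutation in the presence of
inter-gene correlation. The ortholog simulator produces symbol
conventions, not real homology; real Biomart exports should be used for
real data. And the clinical generator's additive severity shift is the
simplest model that makes the recovery question well-posed — real BPD
blood signatures will be noisier and partially non-linear in severity.
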