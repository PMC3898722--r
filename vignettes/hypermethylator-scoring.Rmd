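---
title: "Scoring the hypermethylator phenotype from miR and gene qPCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the hypermethylator phenotype from miR and gene qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeth)
```

## The biological question and the model

A subset of basal-like breast cancers carries a *hypermethylator phenotype*:
concurrent, methylation-dependent silencing of many genes, driven by
overexpression of the de novo DNA methyltransferase DNMT3b. Because DNMT3b
is post-transcriptionally repressed by a group of microRNAs (the miR-29 and
miR-148 families plus miR-26a/b, miR-203 and miR-222), loss of those
regulatory miRs is a candidate mechanism for the phenotype. `mirmeth`
implements the complete quantitative analysis that links the two
observations in a tumor cohort profiled by TaqMan qPCR:

1. **Relative quantification.** Triplicate Ct values are collapsed to a
   mean, normalized to a class-matched reference assay (RNU66 for miRs,
   beta-actin for mRNAs) to give dCt, then to the mean dCt of the normal
   mammoplasty calibrator group (ddCt); relative expression is
   `2^-ddCt`. Amplification efficiency is fixed at 2 — the classic
   comparative-Ct model without efficiency correction; if your assays need
   a Pfaffl-style correction this package is not the right tool.
2. **Median binarization and scores.** Each assay is dichotomized at its
   median over the configured population; a tumor's *gene-expression score*
   (0–9) counts below-median methylation-sensitive genes and its *miR
   score* (0–9) counts below-median regulatory miRs.
3. **Classification rules.** A tumor is a *hypermethylator* when its gene
   score is >= 7; it belongs to the *low miR-expression group* when its miR
   score is >= 6.
4. **Diagnostics.** Each miR's continuous expression is evaluated as a
   predictor of hypermethylator status by choosing the threshold that
   maximizes correct assignments (CA), reporting
   sensitivity/specificity/PPV/NPV/CA as integer percentages.
5. **Associations.** Subtype group summaries (mean ± SEM), unpaired
   two-tailed t-tests between hypermethylator groups, and Pearson
   correlations (score vs score, miR vs miR).

## Numerical and design choices

Several points in the original analysis are underdetermined; the package
fixes each one explicitly and records it in the run configuration or the
report metadata.

* **Calibrator aggregation.** dCt values are averaged across calibrator
  samples per assay before ddCt (an arithmetic mean of dCt equals a
  geometric mean on the fold scale). Consequence: the calibrator group's
  geometric mean expression is exactly 1 per assay, and its mean ddCt is
  exactly 0 — both are asserted in tests to machine precision.
* **Tie at the median.** "Below the median" is read strictly: a value
  exactly equal to the median is called *normal*. With continuous qPCR
  folds ties are essentially impossible in real data, but the rule matters
  for constant (degenerate) assays.
* **Median population.** Binarization medians default to tumors only;
  `median_population = "all_samples"` includes calibrators. The choice is
  configurable because either reading of "the dataset" is defensible.
* **miR group partition.** The published group definitions (low: >= 6 miRs
  diminished; high: >= 3 miRs normal) overlap at score 6 and miss score 5.
  The implementation uses the exact partition: low iff miR score >= 6,
  high otherwise.
* **Missing values.** A sample-by-assay cell with zero usable replicates is
  missing; missing binary calls count as *normal*, which is conservative
  against calling the hypermethylator phenotype, and every such imputation
  is visible in the call columns of `scores.tsv`. Downstream statistics
  drop missing cells pairwise.
* **Rounding.** Diagnostic percentages round half-up (63 for 10/16, 69 for
  11/16); base R's round-half-even is available as `rounding = "banker"`.
  CA is maximized on unrounded fractions so rounding cannot induce ties.
  Two cells of the published diagnostics table disagree with exact
  fractions (a specificity printed 58 where 4/7 gives 57; a text "87%"
  where 6/7 gives 86); the package reproduces the exact fractions and
  documents the discrepancy rather than matching both.
* **Threshold candidates and tie-breaks.** Candidate thresholds are
  midpoints between consecutive distinct observed values plus one point
  below the minimum and one above the maximum (the two constant
  classifiers). The prediction direction is fixed a priori — low
  expression predicts the phenotype — so the optimizer never searches the
  reverse orientation. Among CA-maximizing candidates the tie-break
  prefers the highest sensitivity, then the largest (most
  positive-inclusive) threshold; `tie_set_size` makes residual ambiguity
  visible.
* **t-test variant.** "Unpaired t-test" defaults to the Student
  pooled-variance form; Welch is available by configuration. No
  multiple-testing correction is applied anywhere, matching the source
  analysis; the pairwise-correlation output records that 36 tests were
  performed.

## The synthetic cohort generator

Raw per-tumor measurements for this study design exist only in published
figures, so validation rests on simulated cohorts with known ground truth.
`simulate_cohort()` emulates the study design — 36 luminal A-like, 13
luminal B-like, 5 HER2-enriched and 16 basal-like tumors plus 18 normal
mammoplasty calibrators — with a latent hypermethylator state drawn per
subtype (prevalence 9/16 among basal-like, 0.08 elsewhere, a softened
2/17). Effects are additive on the log2 fold scale:

| parameter | default | meaning |
|---|---|---|
| `gene_suppression_log2` | -3 | hypermethylator effect on the 9 biomarker genes |
| `mir_suppression_log2` | -1.5 | hypermethylator effect on regulatory miRs except miR-29c |
| `mir29c_basal_log2` | -1.5 | miR-29c loss in *all* basal-like tumors, irrespective of the latent state |
| `mir203_luminalA_log2` | -1.5 | miR-203 effect in luminal A-like tumors |
| `biological_sd_log2` | 0.8 | per-sample per-assay log-normal biological variation |
| `mir26_shared_sd_log2` | 0.6 | shared latent factor on miR-26a and miR-26b |
| `ct_replicate_sd` | 0.15 cycles | technical triplicate noise |
| `baseline_delta_ct` | 4 cycles | fixed target-minus-reference offset at fold 1 |

Log-normal biological variation is the standard model for expression data.
The default effect sizes are chosen to be *realistic*, not fitted: a -3
log2 (8-fold) silencing effect against 0.8 log2 biological noise is
strongly separable by a median split, which is what the published
gene-expression heatmaps show qualitatively; the -1.5 log2 miR effects
give the partial, overlapping separation the per-miR bar plots show. The
shared miR-26a/26b factor (about 30% shared variance on top of the joint
hypermethylator effect) encodes the observation that this pair is the most
strongly co-regulated; it is a noise-structure parameter, not a claim
about effect size. The baseline 4-cycle target-vs-reference offset is
arbitrary but recorded, so zero-noise simulations round-trip exactly
through quantification.

What the generator does **not** emulate: assay-specific baselines and
efficiencies, FFPE degradation gradients, plate effects, undetermined-well
censoring at high Ct, and any methylation-level (beta-value) structure.
A green simulation test therefore establishes that the pipeline's
arithmetic and rules behave as specified under the stated statistical
model — not that the model captures every property of archival tumor qPCR.

## What the tests establish, and one deliberate red

The unit suites pin every closed form to hand-computed or independently
derived values (brute-force threshold enumeration, `stats::t.test` /
`stats::cor.test` as oracles for the authored closed forms) and assert the
structural invariants: scale invariance and monotonicity of the ddCt
transform, exact calibrator centering, the median-split property of
binarization, rank-invariance and constant-classifier dominance of the
threshold optimizer, and the exact Bayes identity
`PPV = sens * pi / (sens * pi + (1 - spec)(1 - pi))`.

End-to-end, at default generator settings the hypermethylator call
recovers the latent truth for ~98% of basal-like tumors (asserted >= 85%
over 100 seeds). One acceptance assertion is left failing on purpose: with
all effect sizes set to zero, the per-miR *optimized* CA is asserted to
fall to the `max(pi, 1 - pi)` baseline within Monte-Carlo error. It does
not, and cannot: the optimizer reports an in-sample maximum, which at
n = 16 carries an optimism bias of about +0.01 (measured: mean CA 0.878 vs
baseline 0.868 over 100 null seeds, SE 0.0013). The bias is a property of
maximizing accuracy in-sample, not an implementation defect; removing it
would require out-of-sample evaluation, which the published analysis does
not perform. The assertion is kept, red, as an honest record.

## Limitations

* No efficiency-corrected quantification, no inter-plate calibration, no
  vendor-native instrument file parsing.
* Methylation status is *inferred* from the expression signature; the
  package never touches bisulfite or array methylation data.
* The diagnostic thresholds are in-sample optima over 16 tumors; their
  reported CA values are optimistic (see above) and should not be read as
  out-of-sample performance.
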