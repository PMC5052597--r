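---
title: "Network-state stratification of tumor cohorts: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-state stratification of tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstrat)
```

## The model

`netstrat` treats a curated signaling network as a binary circuit. Given
a features × samples matrix of log-scale expression (mRNA as
`log2(RPKM + 1)`, miRNA as `log2(RPM + eps)`), each feature is
binarized cohort-wide by **largest-gap edge detection**: sort the
feature's values ascending, locate the largest gap between adjacent
values, and threshold at the gap's lower member (`≤ cutoff → 0`,
`> cutoff → 1`). A sample's **network state** is its ordered 0/1 vector
over the network's node order; the unique largest state defines the
**prevalent group**, which is then dissected by driver and partner
mutation status into the nested A1/A2 and B1–B4 subgroups, screened
with Fisher/BH, log-rank and proportion tests, aligned to cell lines by
Spearman rank correlation, and summarized into fold-change drug-query
signatures.

The modeling assumptions are explicit:

* expression is approximately bimodal per network gene, so a single gap
  separates "on" from "off" — the binarization is only meaningful where
  that holds (a unimodal gene gets an arbitrary split at its widest
  spacing);
* the cohort concentrates in one network state; a tie for the largest
  state is treated as an error rather than resolved silently, because
  the downstream dissection presumes a single dominant group;
* mutation co-occurrence is screened marginally per gene, with the 2×2
  Fisher test; survival effects are screened marginally per gene with
  no covariate adjustment (no Cox model), matching the scope of the
  analysis this package implements.

## Tunable parameters

All thresholds live in one `analysis_config()` object:

| parameter | default | role |
|---|---|---|
| `rate_diff_cutoff` | 0.05 | strict shortlisting bound on the A2–A1 mutation-rate difference (fraction) |
| `fdr_cutoff` | 0.15 | BH-adjusted p-value bound for a screened gene to pass |
| `fold_change_cutoff` | 50 | strict linear fold-change bound (up > 50, down < 1/50) |
| `bootstrap_reps` | 5 | resampling replicates per non-randomness design |
| `alpha` | 0.05 | per-category significance level |
| `min_mutant_group` | 3 | smallest mutant group entered into the survival screen |
| `mirna_log_eps` | 1 | pseudo-count for miRNA `log2(x + eps)`; keeps zero counts at 0, matching the mRNA convention |

The defaults are the values of the analysis the package implements; the
FDR bound of 0.15 sits inside the 0.1–0.25 range accepted across
popular genomics tools. `min_mutant_group` guards the log-rank test
against 1–2-mutant groups whose "curves" are single steps.

## Decisions where the design was open

* **Binarize after normalization.** Per-sample median subtraction
  precedes binarization. Median normalization shifts each sample by a
  constant, which is *not* feature-wise shift invariant, but with many
  features the per-sample medians are nearly constant and the planted
  bimodality dominates; the per-feature shift invariance of the cutoff
  is tested separately.
* **Ties among maximal gaps** go to the lowest sorted position, making
  the cutoff deterministic. **Constant features** map to all zeros
  (every value equals the cutoff, and `≤ cutoff → 0`).
* **State identity is over unique nodes.** The flattened per-edge table
  sometimes used to present states duplicates nodes once per edge;
  duplicated columns always carry equal bits, so they cannot change
  state identity. The flat table is available as a report
  (`state_flat_table()`), not as the state definition.
* **BH over the candidate set only.** The screen filters (rate
  difference > 5%), then tests, then adjusts across the candidates —
  the stated order of the analysis — rather than adjusting across the
  whole gene universe.
* **Two-sided Fisher convention.** `fisher_exact_2x2()` sums the
  probabilities of all same-margin tables whose hypergeometric
  probability does not exceed the observed table's (the convention of
  R's `fisher.test`). Other two-sided conventions exist; this one is
  pinned by tests against full enumeration.
* **No continuity correction in category contrasts.** The published
  race contrast (11/19 vs 15/66 ASIAN) reproduces its p-value
  (≈ 0.0034) only without the Yates correction (≈ 0.008 with), so
  `category_profile_compare()` defaults to `correct = FALSE` and
  exposes the flag. Whole-table Pearson chi-square and per-level
  one-vs-rest two-proportion tests are both reported, since either
  reading of "proportional tests" is defensible.
* **Survival screening is reported on raw log-rank p-values**, as the
  headline analysis; a BH column is emitted per endpoint for reference
  but does not drive the screen.
* **Cell-line alignment correlates against the group centroid** (mean
  profile). Averaging the per-patient correlations instead is available
  via `method = "mean_cor"`; on clean profiles the two agree, and the
  centroid is the cheaper default. The correlation panel defaults to
  the network's gene-kind nodes only, since cell-line panels are mRNA.
* **The driver gene is excluded from its own screen** (its association
  with the strata it defines is tautological), and the pipeline's
  automatic partner pick mirrors the published logic: among
  FDR-passing genes, the largest absolute rate difference.
* **Degenerate tests are flagged, not silently computed.** A log-rank
  comparison with no events, or with one group never at risk at any
  event time, returns p = 1 with `degenerate = TRUE` and a warning; a
  category with a single observed level likewise reports p = 1 and a
  flag; a 2×2 table with a zero margin has Fisher p = 1 by convention.

## What the synthetic generator emulates

`generate_cohort()` plants every structure the pipeline assumes, with
defaults matching the emulated study cohort: 233 samples, a dominant
state carrying a fraction 180/233 of them, a 64-entry network (34
genes, 10 miRNAs, 20 upstream regulators), a driver mutated at 85/180,
a partner mutated at 8.42% (driver-WT) vs 22.35% (driver-MUT) within
the dominant state, exponential survival with hazard ratio 3 for the
planted survival gene under uniform censoring (≈ 30%), category
distributions skewed in the driver-MUT/partner-MUT subgroup (Lauren
class deliberately left unskewed, as the one category expected
non-significant), and cell lines drawn as group centroids plus Gaussian
noise, with a planted ±6.5 log2 shift on a few background features
between partner-MUT and partner-WT lines so the fold-change-50
signature stage has genuine positives.

Expression per network feature is bimodal Gaussian with gap
`g = 8·sigma` (defaults `g = 4`, `sigma = 0.5` log2 units); background
features are unimodal. Background genes mutate at 2% — chosen so that
a few percent of background genes pass the 5% rate-difference filter,
the same order as the cohort-scale screen the generator emulates (537
candidates among roughly 15,000 genes); most exome genes are rarely
mutated, and the heavy tail of frequently mutated genes is *not*
modeled. All randomness flows from one master seed through named
substreams (`substream_seed()`), so adding a table never perturbs the
draws of existing ones. `truth_audit()` recounts every planted quantity
from the emitted tables and is used as a fixture guard in the tests.

What the generator does **not** emulate: batch structure, copy-number
segmentation, realistic mutational signatures, correlated expression
beyond the planted network states, or the mixture of many partially
shared states real cohorts show outside the dominant group (non-dominant
samples get independent random vectors). Passing recovery tests on these
cohorts therefore demonstrates correctness of the machinery under the
stated model, not performance on real tumors.

## Numerical behavior at the noise boundary

Two quantitative properties of the largest-gap rule are worth stating
because they bound what "recovery" can mean:

* At exactly 8·sigma separation, a lone extreme sample occasionally
  forms a larger gap than the class gap and is split off on its own —
  about 1–2% of features at cohort sizes of 200–300 (confirmed against
  the brute-force gap-scan oracle; it is a property of the rule, not of
  the implementation). Recovery is therefore tested at the bit level
  (≥ 99% of features with ≥ 99% of bits correct, ≥ 96% exact vectors).
* Exact recovery of the *entire* dominant-state member set requires
  zero such corruptions among the dominant samples across all network
  features, so its probability decays with network size: roughly
  0.6% per node per cohort at these settings, i.e. ≈ 95–98% for an
  8–12-node module but only ≈ 70–75% for the full 64-entry network.
  The end-to-end state-recovery experiment accordingly runs on a
  compact 8-node module network (6 genes, 1 miRNA, 1 TF), where exact
  recovery is expected in ≈ 98% of cohorts; the full 64-entry network
  remains the default everywhere else.

The mutation-screen recovery experiment (dominant group ≈ 135, rates
0.05 vs 0.25, FDR 0.15) runs near its statistical ceiling: Fisher power
at strata of ~70 samples with BH over a handful of candidates is about
0.91 per cohort, so 20-seed batches typically land 18–20 recoveries.

## Problem sizes used by the test suite

Unit tests run on 120-sample cohorts with small networks (seconds in
total). The end-to-end recovery experiments use 300-sample cohorts over
20 seeds; null calibration uses 50 cohorts of 150 samples for the FDR
check and one 200-gene cohort for log-rank uniformity
(Kolmogorov–Smirnov distance from U(0,1) < 0.15). The exhaustive
Fisher check covers all 135,750 non-empty 2×2 tables with total ≤ 40,
evaluated once per orbit of the row-swap/column-swap/transpose symmetry
group (the oracle is evaluated on the full orbit and the
implementation's symmetry is verified separately on random tables).

## Known limitations

* The binarization presumes cohort-wide bimodality; batch effects or
  continuous gradients violate it, and the package deliberately ships
  no batch correction.
* The screen tests genes marginally; co-mutation structure among
  screened genes (beyond the driver) is ignored.
* The bootstrap non-randomness check is descriptive (five replicates,
  per-replicate fraction of significant categories), not a calibrated
  hypothesis test.
* Cell-line alignment against a scattered "other" group correlates
  against a nearly flat centroid, which is intrinsically fragile at
  high noise; assignments report their margin so weak calls are
  visible, and exact rho ties are left `UNASSIGNED`.
* Connectivity-map enrichment scoring of the exported `.grp` lists is
  the job of the external query service and out of scope here.
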