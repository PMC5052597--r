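# netstrat

Patient stratification by signaling-network expression states, with
mutation-driven subgroup dissection, survival and clinical screening,
cell-line alignment and drug-query signature export.

## The problem

Tumor cohorts are heterogeneous, and single-gene markers often fail to
split them into clinically coherent subgroups. An alternative is to read
a curated signaling network (for example a WNT-centered module with its
regulating miRNAs and transcription factors) as a *binary circuit*: each
gene is either on or off in each tumor, and the ordered on/off vector
over the network — its **network state** — characterizes the sample.
Empirically, a large share of a cohort concentrates in one state (the
**prevalent group**), and dissecting that group by driver-gene mutation
status (a TP53-like driver, then a co-mutated partner) exposes subgroups
with distinct mutation spectra, survival, and clinico-molecular
profiles, down to cell lines and candidate drugs that match each
subgroup.

## The method

1. **Binarization (largest-gap edge detection).** For each feature,
   sort the cohort's expression values ascending, find the largest gap
   between adjacent values, and set the cutoff at the gap's lower value:
   `x ≤ cutoff → 0`, `x > cutoff → 1`. Applied per gene, cohort-wide,
   after per-sample median normalization of `log2(x+1)` expression.
2. **State enumeration.** Each sample's 0/1 vector over the network's
   node order is its state; samples sharing a vector share a state.
   States are labeled `1..k` by descending size; the unique largest is
   the prevalent group.
3. **Mutation screen.** Split the prevalent group into driver-WT (A1)
   and driver-MUT (A2); per gene *G*, compare mutation rates, shortlist
   candidates with `|rate(A2) − rate(A1)| > 5%`, test each candidate's
   2×2 driver-status × *G*-status table with a two-sided Fisher exact
   test, and adjust over the candidate set with Benjamini–Hochberg
   (significant at FDR-adjusted p ≤ 0.15).
4. **Survival screen.** Within each stratum, a log-rank test of MUT vs
   WT per gene (≥ 3 mutants) on overall and disease-free survival.
5. **Clinical profiles.** Partner-split subgroups (B3/B4) are compared
   per clinical category (molecular subtype, race, Lauren, CIMP, copy
   number, MSI) with proportion chi-square tests (no continuity
   correction), plus bootstrap resampling (5 replicates against three
   reference populations) to show the contrast is non-random.
6. **Cell-line alignment (CCM).** Each cell line is assigned to the
   patient group whose mean expression profile over the network genes it
   best matches by Spearman rank correlation.
7. **Signature export.** Between partner-MUT and partner-WT cell
   lines, linear fold-changes `2^(Δ mean log2)` are computed; genes with
   FC > 50 or < 1/50 become the up/down `.grp` query lists for
   connectivity-map style drug search.

A bundled synthetic-cohort generator plants every structure the pipeline
assumes (a dominant network state, driver/partner co-mutation, a
survival-associated gene, skewed clinical categories, group-derived cell
lines) so that all stages are testable without external data.

## Worked example

```r
library(netstrat)

co     <- generate_cohort(sim_params(seed = 42))    # 233-sample cohort
expr   <- median_normalize(co$expression)
states <- enumerate_states(binarize_matrix(expr), co$network)
states
#> State partition: 60 states over 64 nodes, 233 samples
#>   label     vector                                                  count
#> 1     1     1011000100001000111001011000010010010011000111011010...   174

prev <- prevalent_group(states)
prev
#> Patient group 'prevalent': 174 samples [network state 10110001...]

sp     <- split_by_mutation(prev, "DRIVER", co$mutations,
                            wt_name = "A1", mut_name = "A2")
screen <- mutation_screen(sp$wt, sp$mut, co$mutations, exclude = "DRIVER")
head(as.data.frame(screen), 3)
#>      gene rate_a1 rate_a2 p_fisher   q_bh passed
#> 1 PARTNER  0.0595   0.211  0.00406 0.0115   TRUE
#> 2   BG018  0.0714   0.000  0.01151 0.0115   TRUE
#> 3   BG090  0.0714   0.000  0.01151 0.0115   TRUE

srv <- survival_screen(sp$mut, co$mutations, co$clinical)
head(srv[srv$endpoint == "OS", ], 3)
#>       gene n_mut n_wt  chi2        p
#> 1 SURVGENE    23   67 18.63 1.58e-05
#> 4    BG081     3   87  7.87 5.04e-03
#> 8    BG030     3   87  2.80 9.44e-02
```

Reading the output: 174 of 233 samples share one network state and form
the prevalent group. The screen recovers the planted co-mutated partner
gene (rate 6% in driver-WT vs 21% in driver-MUT, FDR-adjusted
p = 0.012), and the survival screen ranks the planted hazard-ratio-3
gene first by a wide margin. `run_pipeline()` executes all stages over
files on disk from a config list or YAML file and writes per-stage TSV/
JSON outputs plus a run manifest with digests.

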