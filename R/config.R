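#' Analysis configuration
#'
#' Bundles the tunable constants of the stratification pipeline. Defaults are
#' the values used throughout the analysis: a 5% mutation-rate difference to
#' shortlist candidate genes, an FDR-adjusted p-value cutoff of 0.15, a
#' linear fold-change cutoff of 50 for drug-query signatures, five bootstrap
#' replicates for the non-randomness checks, and a minimum of 3 mutant
#' samples for a gene to enter the survival screen.
#'
#' @param rate_diff_cutoff fraction in (0,1); genes whose mutation-rate
#'   difference between driver strata exceeds this (strictly) are candidates.
#' @param fdr_cutoff fraction in (0,1); Benjamini-Hochberg adjusted p-value
#'   threshold for calling a screened gene significant.
#' @param fold_change_cutoff positive real > 1; linear fold-change bound for
#'   up/down signature membership (strict, symmetric: > cutoff or < 1/cutoff).
#' @param bootstrap_reps positive integer; bootstrap resampling replicates.
#' @param alpha significance level for per-category tests.
#' @param min_mutant_group integer; minimum mutant-group size for a gene to
#'   be tested in the survival screen.
#' @param rng_seed integer master seed; all stage randomness derives from it
#'   via [substream_seed()].
#' @param mirna_log_eps pseudo-count added before log2 for miRNA features
#'   (keeps zero counts at 0 and matches the mRNA log2(x+1) convention).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(rate_diff_cutoff = 0.05,
                            fdr_cutoff = 0.15,
                            fold_change_cutoff = 50,
                            bootstrap_reps = 5L,
                            alpha = 0.05,
                            min_mutant_group = 3L,
                            rng_seed = 1L,
                            mirna_log_eps = 1) {
  stopifnot(rate_diff_cutoff > 0, rate_diff_cutoff < 1,
            fdr_cutoff > 0, fdr_cutoff < 1,
            fold_change_cutoff > 1,
            bootstrap_reps >= 1,
            alpha > 0, alpha < 1,
            min_mutant_group >= 1,
            mirna_log_eps > 0)
  structure(list(rate_diff_cutoff = rate_diff_cutoff,
                 fdr_cutoff = fdr_cutoff,
                 fold_change_cutoff = fold_change_cutoff,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 alpha = alpha,
                 min_mutant_group = as.integer(min_mutant_group),
                 rng_seed = as.integer(rng_seed),
                 mirna_log_eps = mirna_log_eps),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
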