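#' Split a patient group by the mutation status of one gene
#'
#' Partitions the group into wild-type and mutant subgroups by the gene's
#' status; members with a MISSING call are reported separately and belong to
#' neither subgroup.
#'
#' @param group a `patient_group`.
#' @param gene gene id present in the mutation table.
#' @param mut a `mutation_table`.
#' @param wt_name,mut_name labels for the resulting subgroups (defaults
#'   `<group>.<gene>WT` / `<group>.<gene>MUT`).
#' @return list with `wt` and `mut` (`patient_group`s) and `missing`
#'   (character vector of unassigned members).
#' @export
split_by_mutation <- function(group, gene, mut,
                              wt_name = paste0(group$name, ".", gene, "WT"),
                              mut_name = paste0(group$name, ".", gene, "MUT")) {
  stopifnot(inherits(group, "patient_group"), inherits(mut, "mutation_table"))
  if (!gene %in% colnames(mut$status))
    stopf("gene '%s' absent from the mutation table", gene)
  absent <- setdiff(group$members, rownames(mut$status))
  if (length(absent)) stopf("group member(s) absent from mutation table: %s",
                            paste(absent, collapse = ", "))
  st <- mut$status[group$members, gene]
  list(wt = patient_group(wt_name, group$members[st == "WT"],
                          predicate = sprintf("%s & %s WT", group$predicate, gene)),
       mut = patient_group(mut_name, group$members[st == "MUT"],
                           predicate = sprintf("%s & %s MUT", group$predicate, gene)),
       missing = group$members[st == "MISSING"])
}

#' Per-gene mutation rates within a patient group
#'
#' Rate = MUT / (MUT + WT) among group members; MISSING calls are excluded
#' from the denominator. Genes with no non-MISSING call in the group are
#' omitted from the result.
#'
#' @param group a nonempty `patient_group`.
#' @param mut a `mutation_table`.
#' @return named numeric vector of fractions, one entry per gene with data.
#' @export
mutation_rates <- function(group, mut) {
  stopifnot(inherits(group, "patient_group"), inherits(mut, "mutation_table"))
  if (!length(group$members)) stopf("cannot compute mutation rates of an empty group")
  st <- mut$status[group$members, , drop = FALSE]
  n_mut <- colSums(st == "MUT")
  n_obs <- colSums(st != "MISSING")
  rates <- n_mut / n_obs
  rates[n_obs > 0]
}

#' Shortlist candidate genes by mutation-rate difference
#'
#' Keeps genes whose absolute rate difference between the two strata
#' strictly exceeds the cutoff (default 5%). Only genes present in both
#' rate maps (i.e. with data in both strata) are considered.
#'
#' @param rates_a1,rates_a2 named rate vectors from [mutation_rates()] for
#'   the driver-WT and driver-MUT strata.
#' @param cutoff fraction; strict threshold on `|rate_a2 - rate_a1|`.
#' @return character vector of candidate gene ids (in `rates_a1` order).
#' @export
candidate_genes <- function(rates_a1, rates_a2, cutoff = 0.05) {
  shared <- intersect(names(rates_a1), names(rates_a2))
  keep <- abs(rates_a2[shared] - rates_a1[shared]) > cutoff
  shared[keep]
}

#' Two-sided Fisher exact test on a 2x2 contingency table
#'
#' Rows are the driver mutation status (WT, MUT), columns the screened
#' gene's status. Two-sided p sums the probabilities of all tables with the
#' same margins whose hypergeometric probability does not exceed the
#' observed one (the convention of [stats::fisher.test()]). A table with a
#' zero margin carries no information; p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab) || any(dim(tab) != 2L)) stopf("expected a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be non-negative integers")
  if (sum(tab) == 0L) stopf("empty contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, the adjusted value at
#' rank i is `min over j >= i of p_(j) * m / j`, capped at 1, returned in
#' the input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mutation co-occurrence screen between driver strata
#'
#' The full screen of the prevalent group: per-gene mutation rates in the
#' driver-WT (A1) and driver-MUT (A2) strata, candidate shortlisting at the
#' rate-difference cutoff, a Fisher exact test per candidate on the 2x2
#' driver-status x gene-status table, and Benjamini-Hochberg adjustment over
#' the candidate set only (filter, then test, then adjust). Rates and counts
#' use non-MISSING calls only.
#'
#' @param a1,a2 disjoint `patient_group`s (driver-WT and driver-MUT).
#' @param mut a `mutation_table`.
#' @param cfg an [analysis_config()].
#' @param exclude gene ids never screened — most importantly the driver
#'   gene the strata were split on, whose association with itself is
#'   tautological.
#' @return data.frame of class `screen_result`, one row per candidate gene:
#'   counts and rates per stratum, `rate_diff` (= rate_a2 - rate_a1),
#'   `p_fisher`, `q_bh` and `passed` at `cfg$fdr_cutoff`; ordered by `q_bh`,
#'   then `p_fisher`, then gene id. Zero candidates yield an empty
#'   data.frame with the same columns.
#' @export
mutation_screen <- function(a1, a2, mut, cfg = analysis_config(),
                            exclude = character(0)) {
  stopifnot(inherits(a1, "patient_group"), inherits(a2, "patient_group"))
  if (length(intersect(a1$members, a2$members)))
    stopf("strata must be disjoint")
  r1 <- mutation_rates(a1, mut)
  r2 <- mutation_rates(a2, mut)
  cand <- setdiff(candidate_genes(r1, r2, cfg$rate_diff_cutoff), exclude)
  empty <- data.frame(gene = character(0), x_a1 = integer(0), n_a1 = integer(0),
                      rate_a1 = numeric(0), x_a2 = integer(0), n_a2 = integer(0),
                      rate_a2 = numeric(0), rate_diff = numeric(0),
                      p_fisher = numeric(0), q_bh = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE)
  if (!length(cand)) {
    message("mutation_screen: no candidate genes at rate-difference cutoff ",
            cfg$rate_diff_cutoff)
    return(structure(empty, class = c("screen_result", "data.frame")))
  }
  s1 <- mut$status[a1$members, cand, drop = FALSE]
  s2 <- mut$status[a2$members, cand, drop = FALSE]
  x1 <- colSums(s1 == "MUT"); n1 <- colSums(s1 != "MISSING")
  x2 <- colSums(s2 == "MUT"); n2 <- colSums(s2 != "MISSING")
  p <- vapply(seq_along(cand), function(i) {
    fisher_exact_2x2(matrix(c(x1[i], n1[i] - x1[i],
                              x2[i], n2[i] - x2[i]), 2L, byrow = TRUE))
  }, numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(gene = cand, x_a1 = unname(x1), n_a1 = unname(n1),
                    rate_a1 = unname(x1 / n1), x_a2 = unname(x2),
                    n_a2 = unname(n2), rate_a2 = unname(x2 / n2),
                    rate_diff = unname(x2 / n2 - x1 / n1),
                    p_fisher = p, q_bh = q, passed = q <= cfg$fdr_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_bh, out$p_fisher, out$gene), ]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"))
}

#' Choose the partner gene from a mutation screen
#'
#' Mirrors the study's selection logic: among the genes passing the FDR
#' cutoff, take the one with the largest absolute mutation-rate difference
#' between strata (ties broken by adjusted p, then gene id). When nothing
#' passes, the screen's top-ranked gene is returned with a warning, so
#' downstream stages remain runnable on weak cohorts.
#'
#' @param screen a `screen_result` from [mutation_screen()].
#' @return a single gene id.
#' @export
select_partner_gene <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  if (!nrow(screen)) stopf("cannot pick a partner gene from an empty screen")
  hits <- screen[screen$passed, , drop = FALSE]
  if (!nrow(hits)) {
    warnf("no gene passed the FDR cutoff; falling back to the top-ranked gene")
    return(screen$gene[1L])
  }
  hits <- hits[order(-abs(hits$rate_diff), hits$q_bh, hits$gene), ]
  hits$gene[1L]
}
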