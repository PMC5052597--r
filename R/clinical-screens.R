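#' Per-gene log-rank survival screen within a stratum
#'
#' For every gene with at least `cfg$min_mutant_group` mutant samples (and
#' at least one wild-type sample) in the stratum, compares mutant versus
#' wild-type survival by the log-rank test, on overall survival and — when
#' the clinical table carries it — disease-free survival. Samples with a
#' MISSING mutation call or missing endpoint are excluded per gene. Each
#' gene is tested marginally; the headline screen uses raw log-rank
#' p-values, with a Benjamini-Hochberg column (`q_bh`, per endpoint)
#' emitted for reference only.
#'
#' @param stratum a `patient_group` (e.g. the driver-WT or driver-MUT part
#'   of the prevalent group).
#' @param mut a `mutation_table`.
#' @param clin a `clinical_table` covering the stratum.
#' @param cfg an [analysis_config()].
#' @param genes optional gene universe (default: all genes in `mut`).
#' @return data.frame, one row per (gene, endpoint) tested: `gene`,
#'   `stratum`, `endpoint` ("OS"/"DFS"), `n_mut`, `n_wt`, `chi2`, `p`,
#'   `degenerate`, `q_bh`; sorted by `p`.
#' @export
survival_screen <- function(stratum, mut, clin, cfg = analysis_config(),
                            genes = colnames(mut$status)) {
  stopifnot(inherits(stratum, "patient_group"), inherits(mut, "mutation_table"),
            inherits(clin, "clinical_table"))
  absent <- setdiff(stratum$members, clin$sample_id)
  if (length(absent)) stopf("stratum member(s) absent from clinical table: %s",
                            paste(absent, collapse = ", "))
  idx <- match(stratum$members, clin$sample_id)
  endpoints <- list(OS = list(time = clin$os_time[idx], event = clin$os_event[idx]))
  if ("dfs_time" %in% colnames(clin))
    endpoints$DFS <- list(time = clin$dfs_time[idx], event = clin$dfs_event[idx])
  st <- mut$status[stratum$members, intersect(genes, colnames(mut$status)),
                   drop = FALSE]
  rows <- list()
  for (ep in names(endpoints)) {
    tm <- endpoints[[ep]]$time; ev <- endpoints[[ep]]$event
    for (g in colnames(st)) {
      ok <- st[, g] != "MISSING" & !is.na(tm) & !is.na(ev)
      is_mut <- st[ok, g] == "MUT"
      n_mut <- sum(is_mut); n_wt <- sum(!is_mut)
      if (n_mut < cfg$min_mutant_group || n_wt < 1L) next
      lr <- suppressWarnings(logrank_test(tm[ok], ev[ok],
                                          ifelse(is_mut, "MUT", "WT")))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, stratum = stratum$name, endpoint = ep,
                   n_mut = n_mut, n_wt = n_wt, chi2 = lr$chi2, p = lr$p,
                   degenerate = lr$degenerate, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), stratum = character(0),
                      endpoint = character(0), n_mut = integer(0),
                      n_wt = integer(0), chi2 = numeric(0), p = numeric(0),
                      degenerate = logical(0), q_bh = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_bh <- NA_real_
  for (ep in unique(out$endpoint))
    out$q_bh[out$endpoint == ep] <- bh_adjust(out$p[out$endpoint == ep])
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Compare clinico-molecular category profiles of two patient groups
#'
#' Per category, builds the 2 x L table of level counts in the two groups
#' (MISSING annotations excluded) and tests it. The whole-table test is the
#' Pearson chi-square (a k-proportion test when only two levels are
#' observed); per-level one-vs-rest two-proportion tests are attached as
#' the `per_level` attribute, run without continuity correction by default.
#' A category with a single observed level carries no contrast: p = 1,
#' flagged degenerate.
#'
#' @param g1,g2 disjoint `patient_group`s.
#' @param clin a `clinical_table`.
#' @param cfg an [analysis_config()].
#' @param categories category columns to compare (default: all declared).
#' @param correct apply the Yates correction in the per-level two-proportion
#'   tests.
#' @return data.frame, one row per category: `category`, `n1`, `n2`
#'   (non-MISSING counts), `levels`, `chi2`, `df`, `p`, `degenerate`;
#'   attribute `per_level` holds the level-wise tests.
#' @export
category_profile_compare <- function(g1, g2, clin, cfg = analysis_config(),
                                     categories = attr(clin, "categories"),
                                     correct = FALSE) {
  stopifnot(inherits(g1, "patient_group"), inherits(g2, "patient_group"),
            inherits(clin, "clinical_table"))
  i1 <- match(g1$members, clin$sample_id)
  i2 <- match(g2$members, clin$sample_id)
  if (anyNA(i1) || anyNA(i2)) stopf("group member(s) absent from clinical table")
  rows <- list(); lev_rows <- list()
  for (cc in categories) {
    v1 <- clin[[cc]][i1]; v1 <- v1[v1 != "MISSING"]
    v2 <- clin[[cc]][i2]; v2 <- v2[v2 != "MISSING"]
    levs <- sort(unique(c(v1, v2)))
    c1 <- vapply(levs, function(l) sum(v1 == l), integer(1))
    c2 <- vapply(levs, function(l) sum(v2 == l), integer(1))
    stopifnot(sum(c1) == length(v1), sum(c2) == length(v2))  # conservation audit
    if (length(levs) < 2L || !length(v1) || !length(v2)) {
      rows[[cc]] <- data.frame(category = cc, n1 = length(v1), n2 = length(v2),
                               levels = paste(levs, collapse = ","),
                               chi2 = 0, df = 0L, p = 1, degenerate = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    tab <- rbind(c1, c2)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[cc]] <- data.frame(category = cc, n1 = length(v1), n2 = length(v2),
                             levels = paste(levs, collapse = ","),
                             chi2 = unname(ht$statistic),
                             df = unname(ht$parameter), p = ht$p.value,
                             degenerate = FALSE, stringsAsFactors = FALSE)
    for (l in levs) {
      pt <- two_proportion_test(sum(v1 == l), length(v1),
                                sum(v2 == l), length(v2), yates = correct)
      lev_rows[[paste(cc, l)]] <-
        data.frame(category = cc, level = l,
                   x1 = sum(v1 == l), n1 = length(v1),
                   x2 = sum(v2 == l), n2 = length(v2),
                   chi2 = pt$chi2, p = pt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_level") <- if (length(lev_rows)) {
    pl <- do.call(rbind, lev_rows); rownames(pl) <- NULL; pl
  } else NULL
  attr(out, "groups") <- c(g1$name, g2$name)
  out
}

#' Bootstrap non-randomness check of a two-group category contrast
#'
#' Draws, per replicate, two pseudo-groups of the observed subgroup sizes
#' with replacement from a reference population and re-runs the category
#' comparison. If the observed contrast between the real subgroups reflects
#' genuine structure rather than sampling noise, the bootstrapped
#' pseudo-groups should show few significant categories. The three study
#' designs differ only in the reference population (all patients, the
#' driver-mutant stratum, or the driver-wild-type stratum).
#'
#' @param reference a `patient_group` to resample from.
#' @param g1,g2 the observed subgroups (their sizes are reused).
#' @param clin a `clinical_table`.
#' @param cfg an [analysis_config()]; `cfg$bootstrap_reps` replicates,
#'   significance at `cfg$alpha`.
#' @param seed integer seed for the resampling substream.
#' @param design label recorded in the report (1 = all patients, 2 =
#'   driver-MUT, 3 = driver-WT reference).
#' @return object of class `bootstrap_report`: `design`, `reps`, `alpha`,
#'   `pvalues` (data.frame rep x category with p), `summary` (per-rep
#'   fraction of categories significant at alpha).
#' @export
bootstrap_nonrandomness <- function(reference, g1, g2, clin,
                                    cfg = analysis_config(), seed = cfg$rng_seed,
                                    design = 1L) {
  stopifnot(inherits(reference, "patient_group"))
  if (length(g1$members) > length(reference$members) ||
      length(g2$members) > length(reference$members))
    stopf("subgroup larger than the reference population")
  set.seed(substream_seed(seed, paste0("bootstrap", design)))
  pv <- list(); frac <- numeric(cfg$bootstrap_reps)
  for (r in seq_len(cfg$bootstrap_reps)) {
    p1 <- patient_group("boot1", sample(reference$members,
                                        length(g1$members), replace = TRUE))
    p2 <- patient_group("boot2", sample(reference$members,
                                        length(g2$members), replace = TRUE))
    cmp <- category_profile_compare(p1, p2, clin, cfg)
    pv[[r]] <- data.frame(rep = r, category = cmp$category, p = cmp$p,
                          significant = cmp$p < cfg$alpha,
                          stringsAsFactors = FALSE)
    frac[r] <- mean(cmp$p < cfg$alpha)
  }
  structure(list(design = design, reps = cfg$bootstrap_reps, alpha = cfg$alpha,
                 pvalues = do.call(rbind, pv),
                 summary = data.frame(rep = seq_len(cfg$bootstrap_reps),
                                      frac_significant = frac)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap report (design %s): %d replicates, alpha %.3f\n",
              x$design, x$reps, x$alpha))
  cat(sprintf("  fraction of categories significant per replicate: %s\n",
              paste(format(x$summary$frac_significant, digits = 2),
                    collapse = " ")))
  invisible(x)
}
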