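#' Two-group proportion test
#'
#' Chi-square test of equal proportions for two binomial samples, via
#' [stats::prop.test()]. The Yates continuity correction is applied only
#' when requested; the clinico-molecular category comparisons in this
#' pipeline run without it.
#'
#' @param x1,n1 successes and size of the first sample.
#' @param x2,n2 successes and size of the second sample.
#' @param yates apply the continuity correction.
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, yates = TRUE) {
  if (n1 <= 0 || n2 <= 0) stopf("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stopf("successes must lie in [0, n]")
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = yates))
  list(chi2 = unname(ht$statistic), df = 1L, p = ht$p.value)
}

#' k-group proportion test
#'
#' Chi-square test that all k proportions are equal (a 2 x k contingency
#' table), via [stats::prop.test()] with no continuity correction.
#'
#' @param xs integer vector of successes (length >= 2).
#' @param ns integer vector of sample sizes, all positive.
#' @return list with `chi2`, `df` (= k - 1) and `p`.
#' @export
k_proportion_test <- function(xs, ns) {
  if (length(xs) != length(ns) || length(xs) < 2L)
    stopf("need matched success/size vectors of length >= 2")
  if (any(ns <= 0)) stopf("all sample sizes must be positive")
  if (any(xs < 0) || any(xs > ns)) stopf("successes must lie in [0, n]")
  ht <- suppressWarnings(stats::prop.test(xs, ns, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves via
#' [survival::survdiff()]: at each distinct event time the observed minus
#' hypergeometric-expected events in group 1 are accumulated with the
#' hypergeometric variance (ties handled by the standard variance formula);
#' chi2 = (O - E)^2 / V, p from a chi-square with 1 df.
#'
#' A cohort with no events at all, or one where the variance degenerates to
#' zero (e.g. one group entirely censored before any event), carries no
#' log-rank information: chi2 = 0, p = 1 with a warning and
#' `degenerate = TRUE`.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @param labels two-group assignment (any vector with exactly 2 distinct
#'   values; both groups must be nonempty).
#' @return list with `chi2`, `p`, `n` (per-group sizes) and `degenerate`.
#' @export
logrank_test <- function(times, events, labels) {
  if (length(times) != length(events) || length(times) != length(labels))
    stopf("times, events and labels must have equal length")
  if (any(times < 0)) stopf("negative follow-up time")
  if (!all(events %in% c(0L, 1L))) stopf("events must be 0/1")
  g <- factor(labels)
  if (nlevels(g) != 2L)
    stopf("need exactly two nonempty groups (got %d)", nlevels(g))
  n <- table(g)
  if (sum(events) == 0L) {
    warnf("no events in either group; log-rank p set to 1")
    return(list(chi2 = 0, p = 1, n = n, degenerate = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- unname(sd$chisq)
  if (!is.finite(chi2) || any(sd$exp == 0)) {
    warnf("degenerate log-rank comparison (zero variance); p set to 1")
    return(list(chi2 = 0, p = 1, n = n, degenerate = TRUE))
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       n = n, degenerate = FALSE)
}
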