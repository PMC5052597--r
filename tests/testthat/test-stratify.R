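mk_mut <- function(status_vec, gene = "TP53", samples = names(status_vec)) {
  mutation_table(matrix(status_vec, ncol = 1,
                        dimnames = list(samples, gene)))
}

test_that("splitting by mutation partitions members and reports MISSING", {
  st <- c(rep("WT", 6), rep("MUT", 4))
  names(st) <- sprintf("S%02d", 1:10)
  g <- patient_group("prevalent", names(st))
  sp <- split_by_mutation(g, "TP53", mk_mut(st))
  expect_length(sp$wt$members, 6)
  expect_length(sp$mut$members, 4)
  expect_length(sp$missing, 0)

  st[c(3, 8)] <- "MISSING"
  sp <- split_by_mutation(g, "TP53", mk_mut(st))
  expect_length(sp$wt$members, 5)
  expect_length(sp$mut$members, 3)
  expect_setequal(sp$missing, c("S03", "S08"))
  expect_length(c(sp$wt$members, sp$mut$members, sp$missing), 10)

  all_wt <- mk_mut(setNames(rep("WT", 10), names(st)))
  sp <- split_by_mutation(g, "TP53", all_wt)
  expect_length(sp$mut$members, 0)
  expect_error(split_by_mutation(g, "NOPE", all_wt), "absent")
})

test_that("mutation rates use non-MISSING denominators", {
  st <- matrix("WT", 85, 2, dimnames = list(sprintf("S%02d", 1:85),
                                            c("NRXN1", "SPTA1")))
  st[1:19, "NRXN1"] <- "MUT"
  st[, "SPTA1"] <- "MISSING"
  g <- patient_group("A2", rownames(st))
  r <- mutation_rates(g, mutation_table(st))
  expect_equal(unname(r["NRXN1"]), 19 / 85, tolerance = 1e-12)
  expect_false("SPTA1" %in% names(r))          # all-MISSING gene omitted
  st[1:19, "NRXN1"] <- "WT"
  expect_equal(unname(mutation_rates(g, mutation_table(st))["NRXN1"]), 0)
  expect_error(mutation_rates(patient_group("empty", character(0)),
                              mutation_table(st)), "empty")
})

test_that("candidate shortlisting is strictly greater than the cutoff", {
  r1 <- c(g1 = 0.10, g2 = 0.10, g3 = 0.20)
  r2 <- c(g1 = 0.16, g2 = 0.15, g3 = 0.20)
  expect_identical(candidate_genes(r1, r2, 0.05), "g1")   # 0.06 in, 0.05 out
  expect_identical(candidate_genes(r1, r1, 0.05), character(0))
})

test_that("Fisher exact p matches enumeration on worked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  # counts implied by the published 22.35% vs 8.42% rates on strata 95/85
  tab <- matrix(c(8, 87, 19, 66), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(8, 87, 19, 66),
               tolerance = 1e-7)
  expect_lt(fisher_exact_2x2(tab), 0.02)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher exact p matches enumeration on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab),
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone along sort order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])       # permutation invariance
  }
})

test_that("the mutation screen recovers a planted co-mutated gene", {
  set.seed(31)
  n <- 100
  samples <- sprintf("P%03d", 1:(2 * n))
  a1 <- patient_group("A1", samples[1:n])
  a2 <- patient_group("A2", samples[(n + 1):(2 * n)])
  st <- matrix("WT", 2 * n, 21,
               dimnames = list(samples, c("PLANT", sprintf("NULL%02d", 1:20))))
  st[samples[1:n], "PLANT"][rbinom(n, 1, 0.05) == 1] <- "MUT"
  st[samples[(n + 1):(2 * n)], "PLANT"][rbinom(n, 1, 0.25) == 1] <- "MUT"
  for (g in sprintf("NULL%02d", 1:20))
    st[rbinom(2 * n, 1, 0.10) == 1, g] <- "MUT"
  res <- mutation_screen(a1, a2, mutation_table(st))
  expect_s3_class(res, "screen_result")
  expect_true(res$passed[res$gene == "PLANT"])
  expect_identical(res$gene[1], "PLANT")
  # ordering is deterministic: q, then p, then gene id
  expect_false(is.unsorted(res$q_bh))
  # counts recorded in the row reproduce the Fisher input
  row <- res[res$gene == "PLANT", ]
  expect_equal(row$p_fisher,
               fisher_exact_2x2(matrix(c(row$x_a1, row$n_a1 - row$x_a1,
                                         row$x_a2, row$n_a2 - row$x_a2),
                                       2, byrow = TRUE)))
})

test_that("screen edge cases: single candidate and exclusions", {
  samples <- sprintf("P%02d", 1:40)
  a1 <- patient_group("A1", samples[1:20])
  a2 <- patient_group("A2", samples[21:40])
  st <- matrix("WT", 40, 2, dimnames = list(samples, c("GA", "GB")))
  st[21:30, "GA"] <- "MUT"                     # 0 vs 0.5: the one candidate
  res <- mutation_screen(a1, a2, mutation_table(st))
  expect_identical(res$gene, "GA")
  expect_equal(res$q_bh, res$p_fisher)         # BH with m = 1
  res2 <- mutation_screen(a1, a2, mutation_table(st), exclude = "GA")
  expect_identical(nrow(res2), 0L)
  expect_message(
    mutation_screen(a1, a2, mutation_table(st[, "GB", drop = FALSE])),
    "no candidate")
})
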