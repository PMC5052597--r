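mk_expr <- function(values) expr_matrix(values, transform = "log2_x_plus_1")

test_that("group centroid is the per-gene mean over members", {
  v <- matrix(c(1, 3, 2, 4, 10, 20), 3, 2, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  e <- mk_expr(v)
  g2 <- patient_group("g", c("S1", "S2"))
  expect_equal(group_centroid(g2, e, c("G1", "G2")), c(G1 = 2, G2 = 3))
  expect_equal(group_centroid(patient_group("one", "S1"), e, rownames(v)),
               v[, "S1"])
  set.seed(8)
  big <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:20)))
  cent <- group_centroid(patient_group("g", colnames(big)[3:17]),
                         mk_expr(big), rownames(big))
  manual <- apply(big[, 3:17], 1, mean)
  expect_lt(max(abs(cent - manual)), 1e-12)
  expect_error(group_centroid(patient_group("e", character(0)), e, "G1"),
               "empty")
  expect_error(group_centroid(g2, e, "G9"), "G9")
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  x <- c(1, 5, 2, 9, 7)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  tied_x <- c(1, 2, 2, 3); tied_y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(tied_x, tied_y),
               oracle_spearman(tied_x, tied_y), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:100) {
    a <- round(rnorm(sample(3:30, 1)), 1)
    b <- round(rnorm(length(a)), 1)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
  }
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "3")
})

test_that("cell lines are assigned to the best-correlated group", {
  set.seed(21)
  panel <- sprintf("G%02d", 1:20)
  samples <- sprintf("S%02d", 1:40)
  v <- matrix(rnorm(20 * 40, 5, 2), 20, 40, dimnames = list(panel, samples))
  e <- mk_expr(v)
  gA <- patient_group("grpA", samples[1:20])
  gB <- patient_group("grpB", samples[21:40])
  centA <- group_centroid(gA, e, panel)
  centB <- group_centroid(gB, e, panel)

  lines <- cell_line_panel(cbind(LA = centA,                  # exact centroid
                                 LM = 2^centA,                # monotone transform
                                 LB = centB + rnorm(20, 0, 0.01),
                                 LX = rev(centA)))
  res <- assign_cell_lines(lines, list(gA, gB), e, panel)
  expect_identical(res$assigned_group[res$cell_line == "LA"], "grpA")
  expect_equal(res$rho.grpA[res$cell_line == "LA"], 1)
  expect_identical(res$assigned_group[res$cell_line == "LM"], "grpA")
  expect_equal(res$rho.grpA[res$cell_line == "LM"], 1)       # rank invariance
  expect_identical(res$assigned_group[res$cell_line == "LB"], "grpB")
  expect_true(all(res$margin >= 0))
  expect_true(all(abs(c(res$rho.grpA, res$rho.grpB)) <= 1))

  # anti-correlated to A and correlated to B lands in B
  anti <- cell_line_panel(cbind(LANTI = -centA + 0.3 * centB))
  res2 <- assign_cell_lines(anti, list(gA, gB), e, panel)
  expect_identical(res2$assigned_group, "grpB")
})

test_that("ties, incomplete panels and the mean-correlation variant behave", {
  panel <- sprintf("G%02d", 1:10)
  samples <- sprintf("S%02d", 1:10)
  set.seed(3)
  v <- matrix(rnorm(100, 5, 2), 10, 10, dimnames = list(panel, samples))
  e <- mk_expr(v)
  gA <- patient_group("grpA", samples[1:5])
  gB <- patient_group("grpB", samples[6:10])

  # duplicate groups force an exact rho tie
  gA2 <- patient_group("grpA2", gA$members)
  line <- cell_line_panel(cbind(L1 = group_centroid(gA, e, panel)))
  expect_warning(res <- assign_cell_lines(line, list(gA, gA2), e, panel),
                 "tie")
  expect_identical(res$assigned_group, "UNASSIGNED")

  # missing panel gene: line skipped with a warning
  short <- v[1:8, 1, drop = FALSE]
  colnames(short) <- "LSHORT"
  expect_warning(res2 <- assign_cell_lines(cell_line_panel(short),
                                           list(gA, gB), e, panel), "skipped")
  expect_identical(nrow(res2), 0L)

  # mean-of-correlations variant agrees on a clean centroid line
  res3 <- assign_cell_lines(line, list(gA, gB), e, panel, method = "mean_cor")
  expect_identical(res3$assigned_group, "grpA")
})

test_that("generated cell lines recover their generating group at low noise", {
  hits <- 0; total <- 0
  for (seed in 1:5) {
    co <- generate_cohort(sim_params(n_samples = 120L, n_gene_nodes = 34L,
                                     n_mirna_nodes = 4L, n_tf_nodes = 4L,
                                     n_background_features = 30L,
                                     n_background_genes = 30L,
                                     cell_line_noise = 0.2, seed = seed))
    prev <- patient_group("prevalent", co$truth$dominant_members)
    other <- patient_group("other",
                           setdiff(colnames(co$expression$values),
                                   prev$members))
    res <- assign_cell_lines(co$cell_lines, list(prev, other),
                             co$expression, network_panel(co$network))
    truth <- co$truth$cell_line_groups[res$cell_line]
    hits <- hits + sum(res$assigned_group == truth)
    total <- total + nrow(res)
  }
  expect_identical(hits, total)
})
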