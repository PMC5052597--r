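mk_clin <- function(n, seed = 1, categories = TRUE) {
  set.seed(seed)
  df <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   os_time = round(rexp(n, 1 / 500), 1),
                   os_event = rbinom(n, 1, 0.7),
                   stringsAsFactors = FALSE)
  if (categories) {
    df$race <- sample(c("ASIAN", "WHITE"), n, replace = TRUE)
    df$msi <- sample(c("MSI-H", "MSS"), n, replace = TRUE)
  }
  clinical_table(df)
}

test_that("survival screen filters small mutant groups and finds a planted effect", {
  set.seed(13)
  n <- 150
  samples <- sprintf("S%03d", 1:n)
  st <- matrix("WT", n, 12,
               dimnames = list(samples, c("HIT", "TINY", sprintf("N%02d", 1:10))))
  hit_mut <- rbinom(n, 1, 0.4) == 1
  st[hit_mut, "HIT"] <- "MUT"
  st["S001", "TINY"] <- "MUT"                     # 1 mutant only
  for (g in sprintf("N%02d", 1:10)) st[rbinom(n, 1, 0.3) == 1, g] <- "MUT"
  tm <- rexp(n, (1 / 500) * ifelse(hit_mut, 3, 1))  # hazard ratio 3 on HIT
  clin <- clinical_table(data.frame(sample_id = samples,
                                    os_time = round(tm, 1),
                                    os_event = rep(1L, n),
                                    stringsAsFactors = FALSE))
  g <- patient_group("A2", samples)
  res <- survival_screen(g, mutation_table(st), clin,
                         analysis_config(min_mutant_group = 3))
  expect_false("TINY" %in% res$gene)
  expect_identical(res$gene[1], "HIT")
  expect_false(is.unsorted(res$p))
  expect_true(all(res$n_mut >= 3))
  expect_true(all(res$endpoint == "OS"))          # no DFS columns supplied
})

test_that("survival screen covers DFS when present and respects strata", {
  co <- generate_cohort(small_sim(3))
  g <- patient_group("prevalent", co$truth$dominant_members)
  res <- survival_screen(g, co$mutations, co$clinical,
                         analysis_config(min_mutant_group = 3))
  expect_setequal(unique(res$endpoint), c("OS", "DFS"))
  os <- res[res$endpoint == "OS", ]
  expect_true("SURVGENE" %in% os$gene[1:3])
  expect_lt(os$p[os$gene == "SURVGENE"], 1e-3)
  expect_true("SURVGENE" %in% res$gene[res$endpoint == "DFS"])
  expect_true(all(res$stratum == "prevalent"))
})

test_that("category comparison: identical profiles give p = 1, skews are detected", {
  clin <- mk_clin(80, seed = 2)
  # two groups with exactly the same category composition
  asian <- clin$sample_id[clin$race == "ASIAN"]
  white <- clin$sample_id[clin$race == "WHITE"]
  g1 <- patient_group("g1", c(asian[1:10], white[1:10]))
  g2 <- patient_group("g2", c(asian[11:20], white[11:20]))
  cmp <- category_profile_compare(g1, g2, clin,
                                  categories = "race")
  expect_equal(cmp$p, 1)
  expect_equal(cmp$chi2, 0)

  # a planted skew is detected at alpha 0.05
  g3 <- patient_group("g3", asian[1:20])
  g4 <- patient_group("g4", white[1:20])
  cmp2 <- category_profile_compare(g3, g4, clin, categories = "race")
  expect_lt(cmp2$p, 0.05)
})

test_that("category counts conserve group sizes and MISSING is excluded", {
  clin <- mk_clin(60, seed = 4)
  clin$race[1:5] <- "MISSING"
  g1 <- patient_group("g1", clin$sample_id[1:30])
  g2 <- patient_group("g2", clin$sample_id[31:60])
  cmp <- category_profile_compare(g1, g2, clin)
  pl <- attr(cmp, "per_level")
  for (cc in cmp$category) {
    sub <- pl[pl$category == cc, ]
    expect_identical(sum(sub$x1), unique(sub$n1))
    expect_identical(sum(sub$x2), unique(sub$n2))
  }
  expect_identical(cmp$n1[cmp$category == "race"], 25L)   # 5 MISSING dropped

  # single observed level: degenerate, p = 1
  clin$msi <- "MSS"
  attr(clin, "categories") <- c("race", "msi")
  cmp3 <- category_profile_compare(g1, g2, clin)
  expect_true(cmp3$degenerate[cmp3$category == "msi"])
  expect_equal(cmp3$p[cmp3$category == "msi"], 1)
})

test_that("per-level race contrast reproduces the published convention", {
  # groups built to carry exactly 11/19 vs 15/66 ASIAN
  df <- data.frame(sample_id = sprintf("P%02d", 1:85),
                   os_time = rep(100, 85), os_event = rep(1L, 85),
                   race = c(rep("ASIAN", 11), rep("WHITE", 8),
                            rep("ASIAN", 15), rep("WHITE", 51)),
                   stringsAsFactors = FALSE)
  clin <- clinical_table(df)
  b4 <- patient_group("B4", df$sample_id[1:19])
  b3 <- patient_group("B3", df$sample_id[20:85])
  cmp <- category_profile_compare(b4, b3, clin)
  pl <- attr(cmp, "per_level")
  p_asian <- pl$p[pl$level == "ASIAN"]
  expect_equal(p_asian, 0.00337, tolerance = 2e-3)
})

test_that("bootstrap reports are deterministic and sized by config", {
  co <- generate_cohort(small_sim(5))
  clin <- co$clinical
  all_pat <- patient_group("all", clin$sample_id)
  g1 <- patient_group("g1", clin$sample_id[1:12])
  g2 <- patient_group("g2", clin$sample_id[13:50])
  cfg <- analysis_config(bootstrap_reps = 5)
  rep1 <- bootstrap_nonrandomness(all_pat, g1, g2, clin, cfg, seed = 99)
  rep2 <- bootstrap_nonrandomness(all_pat, g1, g2, clin, cfg, seed = 99)
  expect_identical(rep1$pvalues, rep2$pvalues)
  expect_identical(nrow(rep1$summary), 5L)
  expect_identical(max(rep1$pvalues$rep), 5L)

  # resampling a homogeneous reference: most categories non-significant
  expect_true(all(rep1$summary$frac_significant <= 0.5))
  expect_error(bootstrap_nonrandomness(g1, all_pat, g2, clin, cfg),
               "larger than the reference")
})
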