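# Independent oracles, deliberately naive: each reimplements the definition
# by direct enumeration/hand formula, sharing no code with the package.

# largest-gap cutoff by exhaustive scan of every adjacent pair
oracle_gap_cutoff <- function(values) {
  s <- sort(values)
  if (length(s) == 1L) return(s)
  best_gap <- -Inf
  cutoff <- s[1L]
  for (i in seq_len(length(s) - 1L)) {
    gap <- s[i + 1L] - s[i]
    if (gap > best_gap) {       # strictly greater: first maximal gap wins
      best_gap <- gap
      cutoff <- s[i]
    }
  }
  if (best_gap <= 0) s[1L] else cutoff
}

# two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- min(prev, 1)
  }
  adj
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# two-group log-rank by the O-E-V accumulation at each distinct event time
oracle_logrank <- function(times, events, labels) {
  g1 <- labels == sort(unique(labels))[1L]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# small deterministic expression fixture: two bimodal features, one flat
toy_expression <- function() {
  v <- rbind(FX1 = c(0.1, 0.2, 4.1, 4.3, 0.3),
             FX2 = c(5.0, 1.0, 1.2, 5.2, 5.1),
             FX3 = c(2.0, 2.0, 2.0, 2.0, 2.0))
  colnames(v) <- paste0("S", 1:5)
  expr_matrix(v, c("mRNA", "mRNA", "miRNA"), transform = "log2_x_plus_1")
}

toy_network_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("source\tsource_kind\ttarget\ttarget_kind",
               "G1\tgene\tG2\tgene",
               "G2\tgene\tG3\tgene"), path)
  path
}

# small fast simulation used across pipeline-level unit tests
small_sim <- function(seed, ...) {
  sim_params(n_samples = 120L, n_gene_nodes = 8L, n_mirna_nodes = 2L,
             n_tf_nodes = 2L, n_background_features = 30L,
             n_background_genes = 40L, seed = seed, ...)
}
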