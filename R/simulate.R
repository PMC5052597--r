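#' Simulation parameters for a synthetic cohort
#'
#' Defaults emulate the real study cohort: 233 patients of whom a fraction
#' 180/233 occupy the dominant network state; a 64-entry signaling network
#' (34 genes, 10 miRNAs, 20 upstream regulators); a driver gene mutated in
#' 85/180 of the dominant group; a co-mutated partner gene at rates
#' 0.0842 (driver-WT) vs 0.2235 (driver-MUT); a planted survival gene with
#' hazard ratio 3; and per-category clinical skews concentrated in the
#' driver-MUT/partner-MUT subgroup. Expression per network feature is
#' bimodal Gaussian with gap 8 times the noise SD, so largest-gap
#' binarization recovers the planted bits with high probability;
#' background features are unimodal noise.
#'
#' @param n_samples cohort size.
#' @param n_gene_nodes,n_mirna_nodes,n_tf_nodes network composition.
#' @param n_background_features unimodal background expression features.
#' @param n_background_genes background genes in the mutation table.
#' @param dominant_state_fraction probability a sample carries the dominant
#'   state vector.
#' @param expression_gap bimodal separation in log2 units.
#' @param noise_sd per-feature Gaussian noise SD (log2 units).
#' @param mu_low low-mode mean expression (log2 units).
#' @param driver_mut_rate driver-gene mutation probability.
#' @param partner_q0,partner_q1 partner-gene mutation probability given
#'   driver WT / driver MUT (dominant-state samples; q0 elsewhere).
#' @param background_mut_rate background-gene mutation probability; the
#'   default reflects that most exome genes are rarely mutated, so only a
#'   few percent of background genes pass the 5% rate-difference filter at
#'   cohort scale.
#' @param survival_mut_rate planted survival gene mutation probability.
#' @param baseline_hazard exponential hazard per day for non-mutants.
#' @param hazard_ratio multiplicative hazard for survival-gene mutants.
#' @param censoring_fraction target fraction censored (uniform censoring).
#' @param category_skews named list per category: `levels`, `base`
#'   (probabilities for ordinary samples), `skew` (probabilities for the
#'   driver-MUT/partner-MUT dominant subgroup). Defaults emulate the
#'   molecular-subtype, race, Lauren, CIMP, copy-number and MSI profiles.
#' @param n_cell_lines cell lines generated per patient group.
#' @param cell_line_noise SD of the Gaussian noise added to the group
#'   centroid for each generated line (log2 units).
#' @param n_signature_genes background features given a planted
#'   differential shift between partner-MUT and partner-WT cell lines
#'   (half up, half down).
#' @param signature_lfc planted log2 shift for those features; the default
#'   puts them past the linear fold-change cutoff of 50.
#' @param missing_rate fraction of mutation calls set to MISSING.
#' @param seed master seed; every table draws from a named substream.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 233L,
                       n_gene_nodes = 34L, n_mirna_nodes = 10L, n_tf_nodes = 20L,
                       n_background_features = 100L,
                       n_background_genes = 100L,
                       dominant_state_fraction = 180 / 233,
                       expression_gap = 4, noise_sd = 0.5, mu_low = 4,
                       driver_mut_rate = 85 / 180,
                       partner_q0 = 0.0842, partner_q1 = 0.2235,
                       background_mut_rate = 0.02,
                       survival_mut_rate = 0.30,
                       baseline_hazard = 1 / 1000,
                       hazard_ratio = 3,
                       censoring_fraction = 0.30,
                       category_skews = default_category_skews(),
                       n_cell_lines = 3L,
                       cell_line_noise = 0.25,
                       n_signature_genes = 6L,
                       signature_lfc = 6.5,
                       missing_rate = 0,
                       seed = 1L) {
  p <- list(n_samples = as.integer(n_samples),
            n_gene_nodes = as.integer(n_gene_nodes),
            n_mirna_nodes = as.integer(n_mirna_nodes),
            n_tf_nodes = as.integer(n_tf_nodes),
            n_background_features = as.integer(n_background_features),
            n_background_genes = as.integer(n_background_genes),
            dominant_state_fraction = dominant_state_fraction,
            expression_gap = expression_gap, noise_sd = noise_sd,
            mu_low = mu_low, driver_mut_rate = driver_mut_rate,
            partner_q0 = partner_q0, partner_q1 = partner_q1,
            background_mut_rate = background_mut_rate,
            survival_mut_rate = survival_mut_rate,
            baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
            censoring_fraction = censoring_fraction,
            category_skews = category_skews,
            n_cell_lines = as.integer(n_cell_lines),
            cell_line_noise = cell_line_noise,
            n_signature_genes = as.integer(n_signature_genes),
            signature_lfc = signature_lfc,
            missing_rate = missing_rate, seed = as.integer(seed))
  with(p, {
    if (dominant_state_fraction <= 0 || dominant_state_fraction >= 1)
      stopf("dominant_state_fraction must lie in (0, 1)")
    if (dominant_state_fraction * n_samples < 2)
      stopf("infeasible: expected dominant group below 2 samples")
    if (expression_gap <= 0 || noise_sd <= 0) stopf("gap and noise must be positive")
    if (partner_q0 < 0 || partner_q1 > 1 || partner_q0 > partner_q1)
      stopf("need 0 <= partner_q0 <= partner_q1 <= 1")
    if (hazard_ratio <= 0 || baseline_hazard <= 0) stopf("hazards must be positive")
    if (censoring_fraction < 0 || censoring_fraction >= 1)
      stopf("censoring_fraction must lie in [0, 1)")
    if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  })
  structure(p, class = "sim_params")
}

#' Default clinical-category generating distributions
#'
#' Base distributions follow the published prevalent-group composition
#' (e.g. molecular subtypes 89/41/34/16 of 180); skew distributions give
#' the driver-MUT/partner-MUT subgroup a distinct profile in every
#' category except Lauren class, which stays at base (the one category
#' reported as not significantly different).
#'
#' @return named list of per-category `levels`/`base`/`skew` specs.
#' @export
default_category_skews <- function() {
  list(
    molecular_subtype = list(levels = c("CIN", "MSI", "GS", "EBV"),
                             base = c(89, 41, 34, 16) / 180,
                             skew = c(0.20, 0.50, 0.20, 0.10)),
    race = list(levels = c("ASIAN", "WHITE", "OTHER"),
                base = c(0.25, 0.70, 0.05),
                skew = c(0.60, 0.27, 0.13)),
    lauren = list(levels = c("INTESTINAL", "DIFFUSE", "MIXED"),
                  base = c(0.55, 0.35, 0.10),
                  skew = c(0.55, 0.35, 0.10)),
    cimp = list(levels = c("HIGH", "LOW", "NEG"),
                base = c(0.30, 0.40, 0.30),
                skew = c(0.60, 0.25, 0.15)),
    cn_cluster = list(levels = c("HIGH", "LOW"),
                      base = c(0.55, 0.45),
                      skew = c(0.15, 0.85)),
    msi = list(levels = c("MSI-H", "MSS"),
               base = c(0.20, 0.80),
               skew = c(0.55, 0.45))
  )
}

## uniform-censoring horizon U with P(censored) = target under Exp(lambda)
censoring_horizon <- function(lambda, target) {
  if (target <= 0) return(Inf)
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - target
  stats::uniroot(f, lower = 1e-8 / lambda, upper = 1e8 / lambda)$root
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Draws, from named substreams of the master seed: (i) a per-sample binary
#' network-state vector (the dominant vector with probability
#' `dominant_state_fraction`, a random distinct vector otherwise, with both
#' bit classes guaranteed per network feature); (ii) bimodal log2
#' expression over the network features plus unimodal background features;
#' (iii) a mutation table with planted driver, co-mutated partner (rate q1
#' given driver-MUT, else q0, within the dominant state), survival gene and
#' background genes; (iv) exponential survival with hazard
#' `baseline_hazard * hazard_ratio^mutant` and independent uniform
#' censoring; (v) clinical categories multinomial with subgroup-specific
#' skews; (vi) cell lines as group centroids plus Gaussian noise.
#'
#' @param p a [sim_params()] object.
#' @return object of class `synthetic_cohort`: `expression`, `mutations`,
#'   `clinical`, `network`, `cell_lines`, `params` and `truth` (planted
#'   state bits, group memberships, gene identities and generating
#'   distributions, auditable via [truth_audit()]).
#' @export
generate_cohort <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  samples <- sprintf("S%03d", seq_len(p$n_samples))

  ## network: gene chain, miRNAs targeting random genes, TFs -> miRNAs
  set.seed(substream_seed(p$seed, "network"))
  genes <- sprintf("G%02d", seq_len(p$n_gene_nodes))
  mirnas <- sprintf("MIR%02d", seq_len(p$n_mirna_nodes))
  tfs <- sprintf("TF%02d", seq_len(p$n_tf_nodes))
  edges <- data.frame(source = genes[-length(genes)], target = genes[-1L],
                      stringsAsFactors = FALSE)
  if (length(mirnas))
    edges <- rbind(edges, data.frame(source = mirnas,
                                     target = sample(genes, length(mirnas),
                                                     replace = TRUE),
                                     stringsAsFactors = FALSE))
  if (length(tfs) && length(mirnas))
    edges <- rbind(edges, data.frame(source = tfs,
                                     target = sample(mirnas, length(tfs),
                                                     replace = TRUE),
                                     stringsAsFactors = FALSE))
  nodes <- data.frame(id = c(genes, mirnas, tfs),
                      kind = rep(c("gene", "miRNA", "TF"),
                                 c(length(genes), length(mirnas), length(tfs))),
                      stringsAsFactors = FALSE)
  net <- network_spec(nodes, edges)
  n_nodes <- nrow(nodes)

  ## states: dominant vector + scattered alternatives, both classes per node
  set.seed(substream_seed(p$seed, "states"))
  dominant <- stats::rbinom(n_nodes, 1L, 0.5)
  is_dom <- stats::runif(p$n_samples) < p$dominant_state_fraction
  if (sum(is_dom) < 2L || !any(!is_dom))
    stopf("infeasible draw: dominant group %d, others %d; enlarge the cohort",
          sum(is_dom), sum(!is_dom))
  bits <- matrix(0L, n_nodes, p$n_samples,
                 dimnames = list(net$node_order, samples))
  bits[, is_dom] <- dominant
  for (j in which(!is_dom)) {
    repeat {
      v <- stats::rbinom(n_nodes, 1L, 0.5)
      if (any(v != dominant)) break
    }
    bits[, j] <- v
  }
  for (i in seq_len(n_nodes)) {         # guarantee both classes per feature
    if (length(unique(bits[i, ])) == 1L) {
      cand <- which(!is_dom)
      flip <- cand[which.max(vapply(cand, function(j)
        sum(bits[, j] != dominant), 0L))]  # flip where it cannot recreate dominant
      bits[i, flip] <- 1L - bits[i, flip]
    }
  }

  ## expression: bimodal network features + unimodal background
  set.seed(substream_seed(p$seed, "expression"))
  ev <- p$mu_low + p$expression_gap * bits +
    matrix(stats::rnorm(n_nodes * p$n_samples, 0, p$noise_sd),
           n_nodes, p$n_samples)
  bg <- matrix(stats::rnorm(p$n_background_features * p$n_samples,
                            p$mu_low + p$expression_gap / 2, p$noise_sd),
               p$n_background_features, p$n_samples,
               dimnames = list(sprintf("BGF%03d", seq_len(p$n_background_features)),
                               samples))
  values <- rbind(ev, bg)
  rownames(values) <- c(net$node_order, rownames(bg))
  kind <- stats::setNames(nodes$kind, nodes$id)
  kinds <- c(ifelse(kind[net$node_order] == "miRNA", "miRNA",
                    ifelse(kind[net$node_order] == "TF", "TF", "mRNA")),
             rep("mRNA", p$n_background_features))
  expr <- expr_matrix(values, kinds, transform = "log2_x_plus_1")

  ## mutations: driver, partner (co-occurring in the dominant state),
  ## survival gene, background genes
  set.seed(substream_seed(p$seed, "mutations"))
  driver <- stats::rbinom(p$n_samples, 1L, p$driver_mut_rate)
  q <- ifelse(is_dom & driver == 1L, p$partner_q1, p$partner_q0)
  partner <- stats::rbinom(p$n_samples, 1L, q)
  survg <- stats::rbinom(p$n_samples, 1L, p$survival_mut_rate)
  bg_genes <- sprintf("BG%03d", seq_len(p$n_background_genes))
  bgm <- matrix(stats::rbinom(p$n_samples * p$n_background_genes, 1L,
                              p$background_mut_rate),
                p$n_samples, p$n_background_genes,
                dimnames = list(samples, bg_genes))
  status <- cbind(DRIVER = driver, PARTNER = partner, SURVGENE = survg, bgm)
  status <- matrix(ifelse(status == 1L, "MUT", "WT"), nrow(status), ncol(status),
                   dimnames = dimnames(status))
  rownames(status) <- samples
  if (p$missing_rate > 0) {
    set.seed(substream_seed(p$seed, "missing"))
    drop <- stats::runif(length(status)) < p$missing_rate
    status[drop] <- "MISSING"
  }
  mut <- mutation_table(status)

  ## survival: exponential with planted hazard ratio, uniform censoring
  set.seed(substream_seed(p$seed, "survival"))
  hz <- p$baseline_hazard * p$hazard_ratio^(status[, "SURVGENE"] == "MUT")
  t_os <- stats::rexp(p$n_samples, hz)
  u_os <- censoring_horizon(p$baseline_hazard, p$censoring_fraction)
  c_os <- if (is.finite(u_os)) stats::runif(p$n_samples, 0, u_os) else rep(Inf, p$n_samples)
  t_dfs <- stats::rexp(p$n_samples, 1.3 * hz)
  u_dfs <- censoring_horizon(1.3 * p$baseline_hazard, p$censoring_fraction)
  c_dfs <- if (is.finite(u_dfs)) stats::runif(p$n_samples, 0, u_dfs) else rep(Inf, p$n_samples)

  ## categories: multinomial, skewed in the driver-MUT/partner-MUT dominant set
  set.seed(substream_seed(p$seed, "categories"))
  b4 <- is_dom & status[, "DRIVER"] == "MUT" & status[, "PARTNER"] == "MUT"
  cats <- lapply(names(p$category_skews), function(cc) {
    spec <- p$category_skews[[cc]]
    vapply(seq_len(p$n_samples), function(i) {
      pr <- if (b4[i]) spec$skew else spec$base
      sample(spec$levels, 1L, prob = pr)
    }, "")
  })
  names(cats) <- names(p$category_skews)
  clin <- clinical_table(data.frame(
    sample_id = samples,
    os_time = round(pmin(t_os, c_os), 2), os_event = as.integer(t_os <= c_os),
    dfs_time = round(pmin(t_dfs, c_dfs), 2), dfs_event = as.integer(t_dfs <= c_dfs),
    cats, stringsAsFactors = FALSE), categories = names(cats))

  ## cell lines: group centroid + noise over the panel genes and background
  ## features; the signature shift lives on background features only, so it
  ## never perturbs the correlation panel
  set.seed(substream_seed(p$seed, "cell_lines"))
  panel <- network_panel(net)
  cl_rows <- c(panel, rownames(bg))
  cent_prev <- rowMeans(values[cl_rows, is_dom, drop = FALSE])
  cent_other <- rowMeans(values[cl_rows, !is_dom, drop = FALSE])
  mk_lines <- function(cent, ids) {
    matrix(rep(cent, length(ids)), length(cent),
           dimnames = list(cl_rows, ids)) +
      matrix(stats::rnorm(length(cent) * length(ids), 0, p$cell_line_noise),
             length(cent))
  }
  ids_prev <- sprintf("CLP%d", seq_len(p$n_cell_lines))
  ids_other <- sprintf("CLO%d", seq_len(p$n_cell_lines))
  cl_expr <- cbind(mk_lines(cent_prev, ids_prev), mk_lines(cent_other, ids_other))
  cl_mut <- matrix("WT", ncol(cl_expr), 3L,
                   dimnames = list(colnames(cl_expr),
                                   c("DRIVER", "PARTNER", "SURVGENE")))
  cl_mut[ids_prev, "DRIVER"] <- "MUT"
  case_lines <- ids_prev[seq_len(ceiling(p$n_cell_lines / 2))]
  cl_mut[case_lines, "PARTNER"] <- "MUT"
  k <- min(p$n_signature_genes, nrow(bg))
  sig_up <- sig_down <- character(0)
  if (k > 0) {
    sig_genes <- rownames(bg)[seq_len(k)]
    sig_up <- sig_genes[seq_len(ceiling(k / 2))]
    sig_down <- setdiff(sig_genes, sig_up)
    cl_expr[sig_up, case_lines] <- cl_expr[sig_up, case_lines] + p$signature_lfc
    cl_expr[sig_down, case_lines] <- cl_expr[sig_down, case_lines] - p$signature_lfc
  }
  lines <- cell_line_panel(cl_expr, cl_mut)

  truth <- list(dominant_vector = paste(dominant, collapse = ""),
                dominant_members = samples[is_dom],
                state_bits = bits,
                bit_threshold = p$mu_low + p$expression_gap / 2,
                driver_gene = "DRIVER", partner_gene = "PARTNER",
                survival_gene = "SURVGENE",
                b4_members = samples[b4],
                mutation_status = status,
                category_specs = p$category_skews,
                cell_line_groups = stats::setNames(
                  rep(c("prevalent", "other"), each = p$n_cell_lines),
                  c(ids_prev, ids_other)),
                signature_up = sig_up, signature_down = sig_down)

  structure(list(expression = expr, mutations = mut, clinical = clin,
                 network = net, cell_lines = lines, params = p, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d samples, %d network nodes, ",
                     "%d dominant-state members\n"),
              x$params$n_samples, nrow(x$network$nodes),
              length(x$truth$dominant_members)))
  invisible(x)
}

#' Audit a synthetic cohort against its planted truth
#'
#' Recounts every planted quantity directly from the emitted tables:
#' sample-id consistency across tables, per-feature separation of the two
#' planted expression classes (every low-class value below every
#' high-class value, with both classes occupied), dominant-group
#' membership recounted from the planted state bits, cell-by-cell
#' agreement of the mutation table with the planted calls, category levels
#' within their declared vocabulary (with empty categories flagged), and
#' survival column validity. Any discrepancy makes the corresponding
#' check fail.
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame of class `truth_audit` with one row per check:
#'   `check`, `n_discrepancies`, `ok`.
#' @export
truth_audit <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  ev <- cohort$expression$values
  rows <- list()
  add <- function(check, n) rows[[length(rows) + 1L]] <<-
    data.frame(check = check, n_discrepancies = as.integer(n), ok = n == 0L,
               stringsAsFactors = FALSE)

  sample_sets <- list(expression = colnames(ev),
                      mutations = rownames(cohort$mutations$status),
                      clinical = cohort$clinical$sample_id)
  add("sample ids consistent across tables",
      sum(vapply(sample_sets, function(s) !identical(sort(s),
                                                     sort(sample_sets[[1]])), TRUE)))

  nodes <- rownames(tr$state_bits)
  overlap <- vapply(nodes, function(nd) {
    b <- tr$state_bits[nd, ]
    if (length(unique(b)) < 2L) return(TRUE)       # both classes must be occupied
    max(ev[nd, b == 0L]) >= min(ev[nd, b == 1L])
  }, TRUE)
  add("per-feature class separation preserved", sum(overlap))

  key <- apply(tr$state_bits, 2L, paste, collapse = "")
  dom <- colnames(tr$state_bits)[key == tr$dominant_vector]
  add("dominant membership matches planted state bits",
      length(setdiff(dom, tr$dominant_members)) +
        length(setdiff(tr$dominant_members, dom)))

  add("mutation table matches planted calls",
      sum(cohort$mutations$status != tr$mutation_status))

  n_cat <- 0L; n_empty <- 0L
  for (cc in names(tr$category_specs)) {
    v <- cohort$clinical[[cc]]
    n_cat <- n_cat + sum(!v %in% c(tr$category_specs[[cc]]$levels, "MISSING"))
    if (all(v == "MISSING")) n_empty <- n_empty + 1L
  }
  add("category levels within declared vocabulary", n_cat)
  add("no empty clinical category", n_empty)

  add("survival columns valid",
      sum(cohort$clinical$os_time < 0, na.rm = TRUE) +
        sum(!cohort$clinical$os_event %in% c(0L, 1L)))

  out <- do.call(rbind, rows)
  structure(out, class = c("truth_audit", "data.frame"))
}

#' Write a synthetic cohort to a directory in the standard file formats
#'
#' Emits `expression.tsv`, `mutations.tsv`, `clinical.tsv`, `network.tsv`,
#' `cell_lines_expression.tsv`, `cell_lines_mutations.tsv` and
#' `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_network(cohort$network, file.path(dir, "network.tsv"))
  write_cell_lines(cohort$cell_lines, file.path(dir, "cell_lines_expression.tsv"))
  cl_mut <- cohort$cell_lines$mutations
  write_mutations(mutation_table(cl_mut), file.path(dir, "cell_lines_mutations.tsv"))
  tr <- cohort$truth
  jsonlite::write_json(list(dominant_vector = tr$dominant_vector,
                            dominant_members = tr$dominant_members,
                            driver_gene = tr$driver_gene,
                            partner_gene = tr$partner_gene,
                            survival_gene = tr$survival_gene,
                            b4_members = tr$b4_members),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
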