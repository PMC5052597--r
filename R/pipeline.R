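#' Run the full network-state stratification pipeline
#'
#' Orchestrates every stage over files on disk: read inputs, median
#' normalization, largest-gap binarization, network-state enumeration,
#' prevalent-group identification, driver split (A1/A2), mutation
#' co-occurrence screen, per-stratum survival screens, partner split
#' (B1-B4), category comparison (B4 vs B3), bootstrap non-randomness
#' checks (designs 1-3), cell-line alignment and signature export. Each
#' stage writes its table under `outdir`; a run manifest records the
#' config, seed, input/output digests, row counts and timings. Stages can
#' be skipped via `config$skip`; the cell-line stages are skipped
#' automatically when no cell-line files are configured.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `files` (named paths: `expression`, `mutations`, `clinical`,
#'   `network`, optionally `cell_lines_expression`,
#'   `cell_lines_mutations`), `driver_gene` (required), `partner_gene`
#'   (default: top mutation-screen hit), `expression_transform`
#'   (provenance of the expression file, default `"log2_x_plus_1"`; use
#'   `"raw"` to apply the log transform in-pipeline), `normalize`
#'   (default TRUE), `analysis` (arguments to [analysis_config()]), and
#'   `skip` (character vector among `"survival"`, `"categories"`,
#'   `"bootstrap"`, `"ccm"`, `"signature"`).
#' @param outdir output directory, created if needed.
#' @param seed master seed (overrides `config$analysis$rng_seed`).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$files), !is.null(config$driver_gene))
  cfg_args <- config$analysis
  if (!is.null(seed)) cfg_args$rng_seed <- as.integer(seed)
  cfg <- do.call(analysis_config, if (is.null(cfg_args)) list() else cfg_args)
  skip <- config$skip %||% character(0)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  need <- c("expression", "mutations", "clinical", "network")
  files <- config$files
  miss <- setdiff(need, names(files))
  if (length(miss)) stopf("config$files missing: %s", paste(miss, collapse = ", "))
  gone <- unlist(files)[!file.exists(unlist(files))]
  if (length(gone)) stopf("input file(s) not found: %s", paste(gone, collapse = ", "))

  manifest <- list(config = config, seed = cfg$rng_seed,
                   tool = paste("netstrat",
                                as.character(utils::packageVersion("netstrat"))),
                   inputs = as.list(tools::md5sum(unlist(files))),
                   stages = list())
  res <- list(config = cfg)
  t0 <- NULL
  stage <- function(name, rows, outputs = character(0)) {
    manifest$stages[[name]] <<- list(
      rows = rows, seconds = round(as.numeric(Sys.time()) - t0, 3),
      outputs = if (length(outputs)) as.list(tools::md5sum(outputs)) else list(),
      status = "ok")
  }
  run <- function(name, expr) {
    t0 <<- as.numeric(Sys.time())
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, outdir)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  out <- function(...) file.path(outdir, ...)

  ## -- read + normalize ---------------------------------------------------
  run("read", {
    net <- read_network(files$network)
    kind_map <- stats::setNames(
      ifelse(net$nodes$kind == "miRNA", "miRNA",
             ifelse(net$nodes$kind == "TF", "TF", "mRNA")), net$nodes$id)
    expr <- read_expression(files$expression, kind_map = kind_map,
                            transform = config$expression_transform %||%
                              "log2_x_plus_1")
    mut <- read_mutations(files$mutations)
    clin <- read_clinical(files$clinical)
    res$network <- net; res$expression <- expr
    res$mutations <- mut; res$clinical <- clin
    stage("read", nrow(expr$values))
  })
  run("normalize", {
    if (res$expression$transform == "raw")
      res$expression <- log_transform(res$expression, eps = cfg$mirna_log_eps)
    if (config$normalize %||% TRUE)
      res$expression <- median_normalize(res$expression)
    stage("normalize", nrow(res$expression$values))
  })

  ## -- binarize + states + prevalent -------------------------------------
  run("binarize", {
    res$binary <- binarize_matrix(res$expression)
    write_binary_matrix(res$binary, out("binary_matrix.tsv"), out("cutoffs.tsv"))
    stage("binarize", nrow(res$binary$bits),
          c(out("binary_matrix.tsv"), out("cutoffs.tsv")))
  })
  run("states", {
    res$states <- enumerate_states(res$binary, res$network)
    write_states(res$states, out("states.tsv"))
    res$prevalent <- prevalent_group(res$states)
    stage("states", nrow(res$states$states), out("states.tsv"))
  })

  ## -- driver split + mutation screen -------------------------------------
  run("stratify", {
    sp <- split_by_mutation(res$prevalent, config$driver_gene, res$mutations,
                            wt_name = "A1", mut_name = "A2")
    res$A1 <- sp$wt; res$A2 <- sp$mut
    res$screen <- mutation_screen(res$A1, res$A2, res$mutations, cfg,
                                  exclude = config$driver_gene)
    write_tsv(as.data.frame(res$screen), out("mutation_screen.tsv"))
    stage("stratify", nrow(res$screen), out("mutation_screen.tsv"))
  })

  ## -- survival screens ----------------------------------------------------
  if (!"survival" %in% skip) run("survival", {
    res$survival_A1 <- survival_screen(res$A1, res$mutations, res$clinical, cfg)
    res$survival_A2 <- survival_screen(res$A2, res$mutations, res$clinical, cfg)
    write_tsv(res$survival_A1, out("survival_screen_A1.tsv"))
    write_tsv(res$survival_A2, out("survival_screen_A2.tsv"))
    stage("survival", nrow(res$survival_A1) + nrow(res$survival_A2),
          c(out("survival_screen_A1.tsv"), out("survival_screen_A2.tsv")))
  })

  ## -- partner split (B lattice) + category comparison --------------------
  run("partner", {
    partner <- config$partner_gene %||% select_partner_gene(res$screen)
    res$partner_gene <- partner
    b_a1 <- split_by_mutation(res$A1, partner, res$mutations,
                              wt_name = "B1", mut_name = "B2")
    b_a2 <- split_by_mutation(res$A2, partner, res$mutations,
                              wt_name = "B3", mut_name = "B4")
    res$B1 <- b_a1$wt; res$B2 <- b_a1$mut
    res$B3 <- b_a2$wt; res$B4 <- b_a2$mut
    groups <- lapply(list(res$prevalent, res$A1, res$A2, res$B1, res$B2,
                          res$B3, res$B4),
                     function(g) list(name = g$name, n = length(g$members),
                                      members = g$members))
    jsonlite::write_json(groups, out("groups.json"), auto_unbox = TRUE)
    stage("partner", 7L, out("groups.json"))
  })
  if (!"categories" %in% skip) run("categories", {
    res$category_compare <- category_profile_compare(res$B4, res$B3,
                                                      res$clinical, cfg)
    write_tsv(res$category_compare, out("category_compare.tsv"))
    jsonlite::write_json(list(
      groups = attr(res$category_compare, "groups"),
      table = res$category_compare,
      per_level = attr(res$category_compare, "per_level")),
      out("category_compare.json"), auto_unbox = TRUE, digits = NA)
    stage("categories", nrow(res$category_compare),
          c(out("category_compare.tsv"), out("category_compare.json")))
  })
  if (!"bootstrap" %in% skip) run("bootstrap", {
    all_pat <- patient_group("all", res$clinical$sample_id)
    res$bootstrap <- list(
      design1 = bootstrap_nonrandomness(all_pat, res$B4, res$B3, res$clinical,
                                        cfg, seed = cfg$rng_seed, design = 1L),
      design2 = bootstrap_nonrandomness(res$A2, res$B4, res$B3, res$clinical,
                                        cfg, seed = cfg$rng_seed, design = 2L),
      design3 = bootstrap_nonrandomness(res$A1, res$B4, res$B3, res$clinical,
                                        cfg, seed = cfg$rng_seed, design = 3L))
    for (d in names(res$bootstrap))
      jsonlite::write_json(unclass(res$bootstrap[[d]]),
                           out(paste0("bootstrap_", d, ".json")),
                           auto_unbox = TRUE, digits = NA)
    stage("bootstrap", 3L * cfg$bootstrap_reps,
          out(paste0("bootstrap_design", 1:3, ".json")))
  })

  ## -- cell-line alignment + signature -------------------------------------
  has_lines <- !is.null(files$cell_lines_expression)
  if (!has_lines) {
    manifest$stages$ccm <- list(status = "skipped (no cell-line input)")
    manifest$stages$signature <- list(status = "skipped (no cell-line input)")
  }
  if (has_lines && !"ccm" %in% skip) run("ccm", {
    res$cell_lines <- read_cell_lines(files$cell_lines_expression,
                                       files$cell_lines_mutations)
    other <- patient_group("other",
                           setdiff(colnames(res$expression$values),
                                   res$prevalent$members))
    panel <- network_panel(res$network)
    res$ccm <- assign_cell_lines(res$cell_lines,
                                  list(res$prevalent, other),
                                  res$expression, panel)
    write_tsv(as.data.frame(res$ccm), out("ccm_assignment.tsv"))
    stage("ccm", nrow(res$ccm), out("ccm_assignment.tsv"))
  })
  if (has_lines && !any(c("ccm", "signature") %in% skip)) run("signature", {
    cl_mut <- res$cell_lines$mutations
    if (is.null(cl_mut)) stopf("signature stage needs cell-line mutation calls")
    if (!res$partner_gene %in% colnames(cl_mut))
      stopf("partner gene '%s' has no cell-line mutation calls", res$partner_gene)
    prev_lines <- res$ccm$cell_line[res$ccm$assigned_group == "prevalent"]
    case <- prev_lines[cl_mut[prev_lines, res$partner_gene] == "MUT"]
    control <- prev_lines[cl_mut[prev_lines, res$partner_gene] == "WT"]
    if (!length(case) || !length(control))
      stopf("no case/control cell lines among prevalent-assigned lines")
    fc <- fold_changes(res$cell_lines, case, control)
    res$signature <- select_signature(fc, cfg$fold_change_cutoff)
    write_signature_table(res$signature, out("signature.tsv"))
    write_grp(res$signature, out("signature_up.grp"), out("signature_down.grp"))
    stage("signature", length(fc),
          c(out("signature.tsv"), out("signature_up.grp"),
            out("signature_down.grp")))
  })

  res$manifest <- manifest
  write_manifest(manifest, outdir)
  invisible(res)
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
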