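#' Cell-line expression and mutation panel
#'
#' Log-scale expression (genes x cell lines) and per-line mutation calls
#' for a panel of cell lines, the cell-line counterpart of the patient
#' expression and mutation tables.
#'
#' @param expression numeric matrix, genes in rows, cell lines in columns
#'   (dimnames required); log2-scale values.
#' @param mutations optional character matrix (cell lines x genes) with
#'   entries `WT`/`MUT`/`MISSING`.
#' @return an object of class `cell_line_panel`.
#' @export
cell_line_panel <- function(expression, mutations = NULL) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stopf("cell-line expression must be a numeric matrix")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stopf("cell-line expression needs gene rownames and line colnames")
  if (anyDuplicated(colnames(expression))) stopf("duplicate cell-line ids")
  if (!is.null(mutations)) {
    mutations <- mutation_table(mutations)$status
    absent <- setdiff(colnames(expression), rownames(mutations))
    if (length(absent)) stopf("cell line(s) missing from mutation panel: %s",
                              paste(absent, collapse = ", "))
  }
  structure(list(expression = expression, mutations = mutations),
            class = "cell_line_panel")
}

#' @export
print.cell_line_panel <- function(x, ...) {
  cat(sprintf("Cell-line panel: %d lines x %d genes%s\n",
              ncol(x$expression), nrow(x$expression),
              if (is.null(x$mutations)) "" else " (with mutation calls)"))
  invisible(x)
}

#' Read a cell-line panel from TSV files
#' @param expression_path expression TSV (first column gene ids, header =
#'   cell-line ids).
#' @param mutation_path optional mutation TSV in either [read_mutations()]
#'   layout (sample ids are cell-line ids).
#' @return a `cell_line_panel`.
#' @export
read_cell_lines <- function(expression_path, mutation_path = NULL) {
  df <- read_tsv(expression_path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  muts <- if (is.null(mutation_path)) NULL else read_mutations(mutation_path)$status
  cell_line_panel(m, muts)
}

#' Write a cell-line panel's expression as TSV
#' @param panel a `cell_line_panel`.
#' @param path output path.
#' @export
write_cell_lines <- function(panel, path) {
  stopifnot(inherits(panel, "cell_line_panel"))
  df <- data.frame(gene_id = rownames(panel$expression), panel$expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Mean expression profile of a patient group
#'
#' Per-gene arithmetic mean over the group members, on the panel genes.
#'
#' @param group a nonempty `patient_group`.
#' @param expr an `expr_matrix` covering the group members.
#' @param panel character vector of panel gene ids, all present in `expr`.
#' @return named numeric vector (one mean per panel gene).
#' @export
group_centroid <- function(group, expr, panel) {
  stopifnot(inherits(group, "patient_group"), inherits(expr, "expr_matrix"))
  if (!length(group$members)) stopf("cannot profile an empty group")
  missing_genes <- setdiff(panel, rownames(expr$values))
  if (length(missing_genes)) stopf("panel gene(s) absent from expression: %s",
                                   paste(missing_genes, collapse = ", "))
  missing_samples <- setdiff(group$members, colnames(expr$values))
  if (length(missing_samples)) stopf("group member(s) absent from expression: %s",
                                     paste(missing_samples, collapse = ", "))
  rowMeans(expr$values[panel, group$members, drop = FALSE])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged), via
#' [stats::cor()] with `method = "spearman"`. Undefined for a constant
#' vector (zero rank variance), which is an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (length(x) < 3L) stopf("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stopf("NA in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Assign cell lines to patient groups by rank correlation
#'
#' The correlation classification rule: each cell line is assigned to the
#' patient group whose expression profile it matches best by Spearman rank
#' correlation over the panel genes. The group profile is the group mean
#' (centroid) by default; `method = "mean_cor"` instead averages the
#' line-vs-patient correlations over the group members. A line missing any
#' panel gene (NA) is skipped with a warning; an exact tie in rho leaves
#' the line `UNASSIGNED`.
#'
#' @param lines a `cell_line_panel`.
#' @param groups list of `patient_group`s (>= 2).
#' @param expr patient `expr_matrix`.
#' @param panel character vector of panel gene ids (length >= 3); defaults
#'   to the gene-kind nodes of `net` when supplied via [network_panel()].
#' @param method `"centroid"` (default) or `"mean_cor"`.
#' @return data.frame of class `ccm_assignment`: `cell_line`,
#'   `assigned_group` (or `"UNASSIGNED"`), one `rho.<group>` column per
#'   group, and `margin` (best minus second-best rho).
#' @export
assign_cell_lines <- function(lines, groups, expr, panel,
                              method = c("centroid", "mean_cor")) {
  method <- match.arg(method)
  stopifnot(inherits(lines, "cell_line_panel"), length(groups) >= 2L)
  if (length(panel) < 3L) stopf("panel must contain at least 3 genes")
  gnames <- vapply(groups, function(g) g$name, "")
  if (anyDuplicated(gnames)) stopf("duplicate group names")
  profiles <- if (method == "centroid")
    lapply(groups, group_centroid, expr = expr, panel = panel)
  else
    lapply(groups, function(g) {
      missing_genes <- setdiff(panel, rownames(expr$values))
      if (length(missing_genes)) stopf("panel gene(s) absent from expression: %s",
                                       paste(missing_genes, collapse = ", "))
      expr$values[panel, g$members, drop = FALSE]
    })
  rows <- list()
  for (cl in colnames(lines$expression)) {
    v <- lines$expression[match(panel, rownames(lines$expression)), cl]
    if (anyNA(v)) {
      warnf("cell line '%s' lacks panel gene(s); skipped", cl)
      next
    }
    rho <- vapply(seq_along(groups), function(i) {
      if (method == "centroid") spearman_rho(v, profiles[[i]])
      else mean(apply(profiles[[i]], 2L, function(p) spearman_rho(v, p)))
    }, numeric(1))
    best <- which(rho == max(rho))
    assigned <- if (length(best) > 1L) {
      warnf("cell line '%s': exact rho tie between groups %s; UNASSIGNED",
            cl, paste(gnames[best], collapse = ", "))
      "UNASSIGNED"
    } else gnames[best]
    margin <- max(rho) - if (length(rho) > 1L) max(rho[-which.max(rho)]) else max(rho)
    row <- data.frame(cell_line = cl, assigned_group = assigned,
                      stringsAsFactors = FALSE)
    for (i in seq_along(gnames)) row[[paste0("rho.", gnames[i])]] <- rho[i]
    row$margin <- margin
    rows[[cl]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else {
    e <- data.frame(cell_line = character(0), assigned_group = character(0),
                    stringsAsFactors = FALSE)
    for (g in gnames) e[[paste0("rho.", g)]] <- numeric(0)
    e$margin <- numeric(0)
    e
  }
  rownames(out) <- NULL
  structure(out, class = c("ccm_assignment", "data.frame"))
}

#' Default correlation panel from a network
#'
#' The gene-kind nodes of the network (cell-line panels are mRNA, so miRNA
#' and TF-annotated nodes are excluded by default).
#'
#' @param net a `network_spec`.
#' @param kinds node kinds to keep.
#' @return character vector of node ids in node order.
#' @export
network_panel <- function(net, kinds = "gene") {
  stopifnot(inherits(net, "network_spec"))
  kind <- stats::setNames(net$nodes$kind, net$nodes$id)
  net$node_order[kind[net$node_order] %in% kinds]
}
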