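#' Case-vs-control fold-changes between cell-line groups
#'
#' On log2-scale expression, the linear fold-change of a gene is
#' 2^(mean log2 case - mean log2 control). Genes absent (NA) in any profile
#' are omitted with a warning. Swapping case and control inverts every
#' fold-change exactly.
#'
#' @param lines a `cell_line_panel` with log2 expression.
#' @param case,control nonempty character vectors of cell-line ids.
#' @param genes gene universe (default: all panel genes).
#' @return named numeric vector of linear fold-changes.
#' @export
fold_changes <- function(lines, case, control,
                         genes = rownames(lines$expression)) {
  stopifnot(inherits(lines, "cell_line_panel"))
  if (!length(case) || !length(control)) stopf("case and control must be nonempty")
  absent <- setdiff(c(case, control), colnames(lines$expression))
  if (length(absent)) stopf("cell line(s) absent from panel: %s",
                            paste(absent, collapse = ", "))
  genes <- intersect(genes, rownames(lines$expression))
  ec <- lines$expression[genes, case, drop = FALSE]
  eo <- lines$expression[genes, control, drop = FALSE]
  ok <- !apply(is.na(cbind(ec, eo)), 1L, any)
  if (any(!ok)) warnf("omitting %d gene(s) with missing expression", sum(!ok))
  2^(rowMeans(ec[ok, , drop = FALSE]) - rowMeans(eo[ok, , drop = FALSE]))
}

#' Select an up/down drug-query signature at a fold-change cutoff
#'
#' With only a handful of cell lines per side, fold-changes replace
#' p-values: genes with linear fold-change strictly greater than the cutoff
#' are "up", strictly less than 1/cutoff are "down" (default cutoff 50).
#' The two lists are disjoint by construction for any cutoff > 1.
#'
#' @param fc named numeric vector from [fold_changes()].
#' @param cutoff positive real > 1.
#' @return object of class `cmap_signature`: `fold_changes`, `up_genes`,
#'   `down_genes`, `cutoff`.
#' @export
select_signature <- function(fc, cutoff = 50) {
  if (cutoff <= 1) stopf("fold-change cutoff must exceed 1")
  if (any(fc <= 0)) stopf("fold-changes must be positive")
  structure(list(fold_changes = fc,
                 up_genes = names(fc)[fc > cutoff],
                 down_genes = names(fc)[fc < 1 / cutoff],
                 cutoff = cutoff),
            class = "cmap_signature")
}

#' @export
print.cmap_signature <- function(x, ...) {
  cat(sprintf("Drug-query signature (cutoff %g): %d up, %d down of %d genes\n",
              x$cutoff, length(x$up_genes), length(x$down_genes),
              length(x$fold_changes)))
  invisible(x)
}

#' Write signature gene lists in .grp format
#'
#' One uppercase gene identifier per line, no header — the query-list
#' convention of connectivity-map style tools. Empty lists produce empty
#' files.
#'
#' @param sig a `cmap_signature`.
#' @param up_path,down_path output paths for the up and down lists.
#' @export
write_grp <- function(sig, up_path, down_path) {
  stopifnot(inherits(sig, "cmap_signature"))
  writeLines(toupper(sig$up_genes), up_path)
  writeLines(toupper(sig$down_genes), down_path)
  invisible(c(up_path, down_path))
}

#' Read a .grp gene list
#' @param path file with one gene id per line.
#' @return character vector (possibly empty).
#' @export
read_grp <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Write the full signature table as TSV
#' @param sig a `cmap_signature`.
#' @param path output path.
#' @export
write_signature_table <- function(sig, path) {
  stopifnot(inherits(sig, "cmap_signature"))
  fc <- sig$fold_changes
  call <- rep("none", length(fc))
  call[names(fc) %in% sig$up_genes] <- "up"
  call[names(fc) %in% sig$down_genes] <- "down"
  write_tsv(data.frame(gene = names(fc), log2_fc = log2(fc), fc = fc,
                       call = call, stringsAsFactors = FALSE), path)
}
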