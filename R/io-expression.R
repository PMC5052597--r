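#' Expression matrix container
#'
#' A features x samples matrix of (typically log-scale) expression values,
#' with a per-feature kind label (`mRNA`, `miRNA` or `TF`) and a provenance
#' tag recording which transforms have been applied.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param feature_kinds character vector (recycled if length 1) of per-feature
#'   kinds in `c("mRNA","miRNA","TF")`, named by feature id or positional.
#' @param transform provenance tag, one of `"raw"`, `"log2_x_plus_1"`,
#'   `"log2_x"`, `"median_normalized"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, feature_kinds = "mRNA", transform = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stopf("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(fid)) stopf("duplicate feature ids: %s",
                                paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid)) stopf("duplicate sample ids: %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (length(feature_kinds) == 1L) feature_kinds <- rep(feature_kinds, nrow(values))
  if (length(feature_kinds) != nrow(values))
    stopf("feature_kinds length (%d) != number of features (%d)",
          length(feature_kinds), nrow(values))
  if (!all(feature_kinds %in% c("mRNA", "miRNA", "TF")))
    stopf("feature kinds must be mRNA, miRNA or TF")
  transform <- match.arg(transform,
                         c("raw", "log2_x_plus_1", "log2_x", "median_normalized"))
  names(feature_kinds) <- fid
  structure(list(values = values, feature_kinds = feature_kinds,
                 transform = transform),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$transform))
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$feature_kinds)),
                                table(x$feature_kinds)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' Duplicate feature or sample ids and non-numeric cells are errors (the
#' offending row/column is named); no rows are ever silently dropped.
#'
#' @param path TSV file path.
#' @param kind_map optional named character vector mapping feature id to kind;
#'   unmapped features default to `default_kind`.
#' @param default_kind kind for features absent from `kind_map`.
#' @param transform provenance tag of the values on disk (the study's public
#'   matrices ship already log-transformed, so `"log2_x_plus_1"` is common).
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, kind_map = NULL, default_kind = "mRNA",
                            transform = "raw") {
  raw <- read_tsv(path)
  if (ncol(raw) < 2L) stopf("expression file %s has no sample columns", path)
  sid <- colnames(raw)[-1L]        # before subsetting: `[` de-duplicates names
  if (anyDuplicated(sid)) stopf("duplicate sample column(s): %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  fid <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stopf("non-numeric expression value in row '%s', column '%s'",
              fid[bad[1L]], colnames(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- fid
  kinds <- rep(default_kind, length(fid))
  names(kinds) <- fid
  if (!is.null(kind_map)) {
    hit <- intersect(fid, names(kind_map))
    kinds[hit] <- kind_map[hit]
  }
  expr_matrix(m, kinds, transform = transform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: feature ids in the first column, sample
#' ids as header.
#' @param m an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Log-transform raw expression values
#'
#' mRNA and TF rows (RPKM scale) are mapped by log2(x + 1); miRNA rows
#' (reads-per-million scale) by log2(x + eps). The reads-per-million log is
#' undefined at zero, so a pseudo-count `eps` (default 1) keeps zero counts
#' at 0, matching the mRNA convention.
#'
#' @param m an `expr_matrix` with `transform == "raw"` and values >= 0.
#' @param eps pseudo-count for miRNA rows.
#' @return the transformed `expr_matrix` (tag `"log2_x_plus_1"`).
#' @export
log_transform <- function(m, eps = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$transform != "raw")
    stopf("log_transform expects raw values (got '%s')", m$transform)
  if (any(m$values < 0)) stopf("negative expression values cannot be log-transformed")
  v <- m$values
  is_mir <- m$feature_kinds == "miRNA"
  v[!is_mir, ] <- log2(v[!is_mir, , drop = FALSE] + 1)
  v[is_mir, ] <- log2(v[is_mir, , drop = FALSE] + eps)
  m$values <- v
  m$transform <- "log2_x_plus_1"
  m
}

#' Median-normalize samples
#'
#' Subtracts each sample's median from its column, so every sample has
#' median 0 in log space.
#'
#' @param m an `expr_matrix` with log-scale values.
#' @return the normalized `expr_matrix` (tag `"median_normalized"`).
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) == 0L || ncol(m$values) == 0L)
    stopf("cannot median-normalize an empty matrix")
  med <- apply(m$values, 2L, stats::median)
  m$values <- sweep(m$values, 2L, med)
  m$transform <- "median_normalized"
  m
}
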