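#' Mutation status table
#'
#' Samples x genes character matrix with entries `WT`, `MUT` or `MISSING`.
#' `MISSING` is first-class (some genes have no call for some samples, as in
#' curated somatic mutation panels) and is excluded from per-gene
#' denominators, never conflated with `WT`.
#'
#' @param status character matrix (samples in rows, genes in columns) with
#'   entries in `c("WT","MUT","MISSING")`; dimnames required.
#' @return an object of class `mutation_table`.
#' @export
mutation_table <- function(status) {
  if (!is.matrix(status) || !is.character(status))
    stopf("mutation status must be a character matrix")
  if (is.null(rownames(status)) || is.null(colnames(status)))
    stopf("mutation matrix needs sample rownames and gene colnames")
  if (anyDuplicated(rownames(status))) stopf("duplicate sample ids in mutation table")
  if (anyDuplicated(colnames(status))) stopf("duplicate gene ids in mutation table")
  bad <- setdiff(unique(as.vector(status)), c("WT", "MUT", "MISSING"))
  if (length(bad)) stopf("invalid mutation status value(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(status = status), class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("Mutation table: %d samples x %d genes (%d MUT, %d MISSING calls)\n",
              nrow(x$status), ncol(x$status),
              sum(x$status == "MUT"), sum(x$status == "MISSING")))
  invisible(x)
}

#' Read a mutation table from TSV
#'
#' Accepts either the long form (columns `sample_id`, `gene_id`, `status`)
#' or a wide 0/1/NA matrix (first column sample ids, one column per gene;
#' 1 = MUT, 0 = WT, NA = MISSING). The layout is auto-detected from the
#' header. In long form, any (sample, gene) pair absent from the file is
#' MISSING.
#'
#' @param path TSV file path.
#' @return a `mutation_table`.
#' @export
read_mutations <- function(path) {
  df <- read_tsv(path)
  if (all(c("sample_id", "gene_id", "status") %in% colnames(df))) {
    samples <- unique(df$sample_id); genes <- unique(df$gene_id)
    st <- matrix("MISSING", length(samples), length(genes),
                 dimnames = list(samples, genes))
    if (anyDuplicated(paste(df$sample_id, df$gene_id)))
      stopf("duplicate (sample, gene) entry in long mutation table")
    st[cbind(match(df$sample_id, samples), match(df$gene_id, genes))] <-
      toupper(df$status)
    return(mutation_table(st))
  }
  samples <- as.character(df[[1L]])
  wide <- as.matrix(df[, -1L, drop = FALSE])
  st <- matrix("MISSING", length(samples), ncol(wide),
               dimnames = list(samples, colnames(wide)))
  st[wide == 1] <- "MUT"
  st[wide == 0] <- "WT"
  mutation_table(st)
}

#' Write a mutation table as long TSV
#' @param mut a `mutation_table`.
#' @param path output path.
#' @param keep_missing write MISSING rows too (default TRUE, so the
#'   round-trip is the identity).
#' @export
write_mutations <- function(mut, path, keep_missing = TRUE) {
  stopifnot(inherits(mut, "mutation_table"))
  st <- mut$status
  df <- data.frame(sample_id = rep(rownames(st), ncol(st)),
                   gene_id = rep(colnames(st), each = nrow(st)),
                   status = as.vector(st), stringsAsFactors = FALSE)
  if (!keep_missing) df <- df[df$status != "MISSING", ]
  write_tsv(df, path)
}

#' Clinical annotation table
#'
#' One row per sample: survival endpoints (overall survival always; disease
#' free survival optional) and categorical clinico-molecular annotations.
#' Category columns use the string `"MISSING"` (or NA, normalized to
#' `"MISSING"`) for unavailable annotations.
#'
#' @param df data.frame with columns `sample_id`, `os_time`, `os_event`,
#'   optionally `dfs_time`, `dfs_event`, plus one column per category.
#' @param categories character vector naming the category columns; defaults
#'   to every non-survival column present among the standard vocabulary
#'   (`molecular_subtype`, `race`, `lauren`, `cimp`, `cn_cluster`, `msi`)
#'   plus any remaining extra columns.
#' @return a `clinical_table` (a data.frame with a `categories` attribute).
#' @export
clinical_table <- function(df, categories = NULL) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("clinical table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in clinical table")
  if (any(df$os_time < 0, na.rm = TRUE)) stopf("negative os_time")
  if (!all(df$os_event %in% c(0L, 1L, NA))) stopf("os_event must be 0/1")
  if ("dfs_time" %in% colnames(df)) {
    if (any(df$dfs_time < 0, na.rm = TRUE)) stopf("negative dfs_time")
    if (!all(df$dfs_event %in% c(0L, 1L, NA))) stopf("dfs_event must be 0/1")
  }
  reserved <- c("sample_id", "os_time", "os_event", "dfs_time", "dfs_event")
  if (is.null(categories)) categories <- setdiff(colnames(df), reserved)
  for (cc in categories) df[[cc]][is.na(df[[cc]])] <- "MISSING"
  structure(df, categories = categories,
            class = c("clinical_table", "data.frame"))
}

#' Read a clinical table from TSV
#' @param path TSV file path with the [clinical_table()] column layout.
#' @param categories optional category column names (default: auto-detect).
#' @return a `clinical_table`.
#' @export
read_clinical <- function(path, categories = NULL) {
  clinical_table(read_tsv(path), categories = categories)
}

#' Write a clinical table as TSV
#' @param clin a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  stopifnot(inherits(clin, "clinical_table"))
  write_tsv(as.data.frame(clin), path)
}
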