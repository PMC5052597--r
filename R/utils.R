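#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed for a named random substream
#'
#' One master seed drives every source of randomness; each table or stage
#' draws from its own substream so that adding a new consumer never perturbs
#' the draws of existing ones. The substream seed is a deterministic hash of
#' the master seed and the stream name, kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param name character stream name (e.g. "expression", "mutations").
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629 + 1)
}

## write a data.frame as a plain TSV, no quoting, deterministic layout
write_tsv <- function(df, path, row.names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}
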