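#' Signaling network specification
#'
#' Directed network over genes, miRNAs and transcription factors. The node
#' order is the deterministic ordering used to lay out binary state vectors;
#' two cohorts binarized against the same network are therefore directly
#' comparable state-by-state.
#'
#' @param nodes data.frame with columns `id`, `kind` (kind in
#'   `c("gene","miRNA","TF")`).
#' @param edges data.frame with columns `source`, `target` (directed).
#' @param node_order character permutation of `nodes$id`; defaults to the
#'   order of `nodes`.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(nodes, edges, node_order = nodes$id) {
  stopifnot(is.data.frame(nodes), all(c("id", "kind") %in% colnames(nodes)),
            is.data.frame(edges), all(c("source", "target") %in% colnames(edges)))
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids in network")
  if (!all(nodes$kind %in% c("gene", "miRNA", "TF")))
    stopf("node kinds must be gene, miRNA or TF")
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling)) stopf("edge endpoint(s) not in node list: %s",
                              paste(dangling, collapse = ", "))
  if (!setequal(node_order, nodes$id) || length(node_order) != nrow(nodes))
    stopf("node_order must be a permutation of the node ids")
  structure(list(nodes = nodes, edges = edges,
                 node_order = as.character(node_order)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Network: %d nodes (%s), %d directed edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$kind)),
                            table(x$nodes$kind)), collapse = " "),
              nrow(x$edges)))
  invisible(x)
}

#' Read a network from an edge-list TSV
#'
#' Columns: `source`, `source_kind`, `target`, `target_kind`. Nodes are
#' deduplicated; the node order is first-appearance order in the file
#' (scanning source then target per row). A self-loop is retained with a
#' warning; the same id declared with two different kinds is an error.
#'
#' @param path TSV edge-list path.
#' @return a `network_spec`.
#' @export
read_network <- function(path) {
  df <- read_tsv(path)
  need <- c("source", "source_kind", "target", "target_kind")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("network file missing column(s): %s",
                          paste(miss, collapse = ", "))
  ids <- as.character(rbind(df$source, df$target))       # interleaved s,t per row
  kinds <- as.character(rbind(df$source_kind, df$target_kind))
  first <- !duplicated(ids)
  node_order <- ids[first]
  node_kind <- kinds[first]
  conflict <- tapply(kinds, ids, function(k) length(unique(k)) > 1L)
  if (any(conflict)) stopf("conflicting kinds for node(s): %s",
                           paste(names(conflict)[conflict], collapse = ", "))
  loops <- df$source == df$target
  if (any(loops)) warnf("self-loop retained for node(s): %s",
                        paste(unique(df$source[loops]), collapse = ", "))
  network_spec(nodes = data.frame(id = node_order, kind = node_kind,
                                  stringsAsFactors = FALSE),
               edges = data.frame(source = as.character(df$source),
                                  target = as.character(df$target),
                                  stringsAsFactors = FALSE),
               node_order = node_order)
}

#' Write a network as an edge-list TSV
#' @param net a `network_spec`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "network_spec"))
  kind <- stats::setNames(net$nodes$kind, net$nodes$id)
  df <- data.frame(source = net$edges$source,
                   source_kind = kind[net$edges$source],
                   target = net$edges$target,
                   target_kind = kind[net$edges$target],
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
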