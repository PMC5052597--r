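#' Binarize one feature by largest-gap (edge-detection) thresholding
#'
#' Sorts the expression values of a feature in ascending order, computes all
#' gaps between neighboring sorted values, and finds the greatest gap. The
#' lower of its two adjacent values becomes the cutoff: values less than or
#' equal to the cutoff map to 0, values greater map to 1. Ties among maximal
#' gaps are broken toward the lowest sorted position; a constant feature has
#' no positive gap and maps entirely to 0 (every value equals the cutoff).
#'
#' @param values numeric vector of one feature's expression across samples.
#' @return list with `cutoff` (numeric) and `bits` (integer 0/1 vector in
#'   input order).
#' @export
binarize_feature <- function(values) {
  if (length(values) == 0L) stopf("cannot binarize an empty expression vector")
  if (any(!is.finite(values))) stopf("non-finite value in expression vector")
  s <- sort(values)
  if (length(s) == 1L || s[length(s)] == s[1L]) {
    cutoff <- s[1L]
  } else {
    gaps <- diff(s)
    cutoff <- s[which.max(gaps)]     # which.max takes the first maximum
  }
  list(cutoff = cutoff, bits = as.integer(values > cutoff))
}

#' Binary expression matrix
#'
#' Per-feature binarized expression with the per-feature cutoffs recorded.
#' Invariant: `bits == 0` exactly where the original value was less than or
#' equal to the feature's cutoff.
#'
#' @param bits integer 0/1 matrix (features x samples, dimnames required).
#' @param cutoffs named numeric vector of per-feature thresholds.
#' @return an object of class `binary_matrix`.
#' @export
binary_matrix <- function(bits, cutoffs) {
  stopifnot(is.matrix(bits), all(bits %in% c(0L, 1L)),
            !is.null(rownames(bits)), !is.null(colnames(bits)),
            length(cutoffs) == nrow(bits))
  names(cutoffs) <- rownames(bits)
  structure(list(bits = bits, cutoffs = cutoffs), class = "binary_matrix")
}

#' Binarize a whole expression matrix
#'
#' Applies [binarize_feature()] independently to every feature row, cohort
#' wide (all samples jointly, never per batch). Errors from a feature are
#' re-raised with the feature id attached.
#'
#' @param m an `expr_matrix` (normalized log-scale values).
#' @return a `binary_matrix` with the same dimnames.
#' @export
binarize_matrix <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  bits <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  cutoffs <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    b <- tryCatch(binarize_feature(v[i, ]),
                  error = function(e) stopf("feature '%s': %s",
                                            rownames(v)[i], conditionMessage(e)))
    bits[i, ] <- b$bits
    cutoffs[i] <- b$cutoff
  }
  binary_matrix(bits, cutoffs)
}

#' Write a binary matrix as TSV (with a per-feature cutoff sidecar)
#' @param b a `binary_matrix`.
#' @param path output path for the 0/1 matrix.
#' @param cutoff_path optional path for the cutoff sidecar TSV.
#' @export
write_binary_matrix <- function(b, path, cutoff_path = NULL) {
  stopifnot(inherits(b, "binary_matrix"))
  df <- data.frame(feature_id = rownames(b$bits), b$bits,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(cutoff_path))
    write_tsv(data.frame(feature_id = names(b$cutoffs), cutoff = b$cutoffs,
                         stringsAsFactors = FALSE), cutoff_path)
  invisible(path)
}

#' Enumerate network expression states
#'
#' A network state is the ordered 0/1 vector of a sample's binarized
#' expression over the network's node order (unique nodes; the flattened
#' per-edge table sometimes drawn for presentation duplicates nodes but
#' duplicated columns always carry equal bits, so state identity is defined
#' over unique nodes). Samples sharing a vector share a state. States are
#' labeled 1, 2, ..., k by descending member count, ties broken by
#' lexicographic vector string, so State 1 is always the prevalent state.
#'
#' @param b a `binary_matrix` whose features cover the network nodes.
#' @param net a `network_spec`.
#' @param drop_missing if TRUE, network nodes absent from the matrix are
#'   excluded with a warning instead of raising an error.
#' @return an object of class `state_partition`: `states` (data.frame with
#'   `label`, `vector`, `count`), `members` (list of sample-id vectors per
#'   label) and `node_order` (nodes actually used).
#' @export
enumerate_states <- function(b, net, drop_missing = FALSE) {
  stopifnot(inherits(b, "binary_matrix"), inherits(net, "network_spec"))
  nodes <- net$node_order
  absent <- setdiff(nodes, rownames(b$bits))
  if (length(absent)) {
    if (!drop_missing)
      stopf("network node(s) missing from binary matrix: %s",
            paste(absent, collapse = ", "))
    warnf("dropping network node(s) missing from matrix: %s",
          paste(absent, collapse = ", "))
    nodes <- setdiff(nodes, absent)
  }
  if (!length(nodes)) stopf("no network nodes left to enumerate states over")
  sub <- b$bits[nodes, , drop = FALSE]
  key <- apply(sub, 2L, paste, collapse = "")
  members <- split(colnames(sub), key)
  counts <- lengths(members)
  ord <- order(-counts, names(members))
  members <- members[ord]
  states <- data.frame(label = seq_along(members),
                       vector = names(members),
                       count = unname(lengths(members)),
                       stringsAsFactors = FALSE)
  names(members) <- states$label
  structure(list(states = states, members = members, node_order = nodes),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("State partition: %d states over %d nodes, %d samples\n",
              nrow(x$states), length(x$node_order), sum(x$states$count)))
  print(utils::head(x$states, 5L))
  invisible(x)
}

#' Patient group
#'
#' A named set of sample ids with a human-readable defining predicate
#' (network state and/or mutation statuses).
#'
#' @param name group label (e.g. `"prevalent"`, `"A1"`, `"B4"`).
#' @param members character vector of sample ids.
#' @param predicate description of the defining condition.
#' @return an object of class `patient_group`.
#' @export
patient_group <- function(name, members, predicate = "") {
  structure(list(name = name, members = as.character(members),
                 predicate = predicate),
            class = "patient_group")
}

#' @export
print.patient_group <- function(x, ...) {
  cat(sprintf("Patient group '%s': %d samples%s\n", x$name, length(x$members),
              if (nzchar(x$predicate)) paste0(" [", x$predicate, "]") else ""))
  invisible(x)
}

#' Identify the prevalent-state patient group
#'
#' Returns the members of the unique state with the most samples as the
#' group `"prevalent"`. A tie for the maximum is an error listing the tied
#' states: the method presumes a single dominant state (cohorts where most
#' samples concentrate in one network state), and a tie means that premise
#' does not hold.
#'
#' @param states a `state_partition` from [enumerate_states()].
#' @return a `patient_group` named `"prevalent"`.
#' @export
prevalent_group <- function(states) {
  stopifnot(inherits(states, "state_partition"))
  if (!nrow(states$states)) stopf("no states to choose a prevalent group from")
  top <- max(states$states$count)
  tied <- states$states$label[states$states$count == top]
  if (length(tied) > 1L)
    stopf("tie for the most prevalent state between states %s (count %d each)",
          paste(tied, collapse = ", "), top)
  patient_group("prevalent", states$members[[as.character(tied)]],
                predicate = sprintf("network state %s",
                                    states$states$vector[states$states$label == tied]))
}

#' Write the state table as TSV
#' @param states a `state_partition`.
#' @param path output path.
#' @export
write_states <- function(states, path) {
  stopifnot(inherits(states, "state_partition"))
  df <- states$states
  df$member_ids <- vapply(states$members, paste, "", collapse = ",")
  write_tsv(df, path)
}

#' Flattened per-edge state report
#'
#' Optional presentational table mirroring the flat per-edge layout: one
#' column per edge endpoint (nodes repeated once per edge), one row per
#' state with its bit under each endpoint column and the member count.
#'
#' @param states a `state_partition`.
#' @param net the `network_spec` the states were enumerated over.
#' @return a data.frame (state label, one 0/1 column per edge endpoint,
#'   member count).
#' @export
state_flat_table <- function(states, net) {
  stopifnot(inherits(states, "state_partition"), inherits(net, "network_spec"))
  pos <- match(c(rbind(net$edges$source, net$edges$target)), states$node_order)
  cols <- c(rbind(net$edges$source, net$edges$target))
  keep <- !is.na(pos)
  bitmat <- do.call(rbind, lapply(strsplit(states$states$vector, ""), as.integer))
  out <- data.frame(state = states$states$label,
                    bitmat[, pos[keep], drop = FALSE],
                    count = states$states$count, check.names = FALSE)
  colnames(out) <- c("state", cols[keep], "count")
  out
}
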