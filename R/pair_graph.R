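# Pair-node PPI graph construction: every labelled protein pair becomes a
# node; two nodes are adjacent iff the pairs share a protein.

#' Canonicalize a protein pair
#'
#' Orders the two protein identifiers lexicographically (byte-wise, locale
#' independent) so that `(A,B)` and `(B,A)` name the same node. Self pairs
#' are rejected, mirroring the dataset filter that discards self-interacting
#' protein pairs.
#'
#' @param a,b Non-empty protein identifier strings.
#' @return Character vector of length 2, sorted ascending.
#' @export
#' @examples
#' canonicalize_pair("P2", "P1")
canonicalize_pair <- function(a, b) {
  if (!is.character(a) || !is.character(b) ||
      length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    gb_stop("gb_invalid_id", "protein identifiers must be non-empty strings")
  }
  if (a == b) {
    gb_stop("gb_self_pair", "self-interacting pair rejected: %s", a)
  }
  lex_sorted(a, b)
}

pair_key <- function(a, b) paste(lex_sorted(a, b), collapse = "\x1f")

#' Read labelled interaction records from TSV
#'
#' Expects a header line with columns `protein_a`, `protein_b`, `label`
#' (label 1 = interacting, 0 = non-interacting).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with character id columns and an integer label.
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("protein_a", "protein_b", "label")
  if (!all(need %in% names(df))) {
    gb_stop("gb_config", "interaction TSV must have columns %s",
            paste(need, collapse = ", "))
  }
  df$label <- as.integer(df$label)
  if (anyNA(df$label) || !all(df$label %in% c(0L, 1L))) {
    gb_stop("gb_invalid_label", "labels must be 0 or 1")
  }
  df[need]
}

#' Write interaction records to TSV
#' @param records Data frame with `protein_a`, `protein_b`, `label`.
#' @param path Output path.
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter interaction records by sequence criteria
#'
#' Drops records whose proteins have sequences shorter than `min_len`
#' residues or (optionally) containing non-standard amino acids; records
#' referencing proteins absent from the sequence map are dropped too. With
#' no sequence map the records pass through unchanged. Drop counts by
#' reason are attached as attribute `"drop_counts"`.
#'
#' @param records Interaction data frame (`protein_a`, `protein_b`, `label`).
#' @param sequences Named character vector of protein sequences, or NULL.
#' @param min_len Minimum sequence length retained (default 50).
#' @param drop_unknown Drop proteins whose sequence contains characters
#'   outside the 20 standard amino acids (default TRUE).
#' @return Filtered data frame.
#' @export
filter_records <- function(records, sequences = NULL, min_len = 50,
                           drop_unknown = TRUE) {
  if (is.null(sequences)) {
    attr(records, "drop_counts") <-
      c(missing_sequence = 0L, too_short = 0L, unknown_aa = 0L)
    return(records)
  }
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad_missing <- bad_short <- bad_unknown <- character(0)
  ids <- unique(c(records$protein_a, records$protein_b))
  for (id in ids) {
    if (!id %in% names(sequences)) {
      bad_missing <- c(bad_missing, id)
      next
    }
    s <- sequences[[id]]
    if (nchar(s) < min_len) bad_short <- c(bad_short, id)
    if (drop_unknown && !all(strsplit(s, "")[[1]] %in% std)) {
      bad_unknown <- c(bad_unknown, id)
    }
  }
  bad <- unique(c(bad_missing, bad_short, bad_unknown))
  keep <- !(records$protein_a %in% bad | records$protein_b %in% bad)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(
    missing_sequence = sum(records$protein_a %in% bad_missing |
                             records$protein_b %in% bad_missing),
    too_short = sum(records$protein_a %in% bad_short |
                      records$protein_b %in% bad_short),
    unknown_aa = sum(records$protein_a %in% bad_unknown |
                       records$protein_b %in% bad_unknown)
  )
  out
}

#' Build the pair-node PPI graph
#'
#' One node per unique canonical pair, in first-appearance order; an edge
#' joins two nodes iff their protein-id sets intersect. Duplicate records
#' with a consistent label are merged silently; the same pair carrying both
#' labels is an error (corrupt input rather than a voting situation).
#'
#' @param records Interaction data frame (`protein_a`, `protein_b`, `label`).
#' @return An object of class `pair_graph`: list with `nodes` (data frame
#'   `protein_a`, `protein_b`, `label` in node order), `adjacency`
#'   (symmetric 0/1 matrix, zero diagonal), `adj_list` (per-node integer
#'   neighbour vectors) and `n`.
#' @export
#' @examples
#' recs <- data.frame(protein_a = c("A", "A", "C"),
#'                    protein_b = c("B", "C", "D"),
#'                    label = c(1L, 1L, 0L))
#' g <- build_pair_graph(recs)
#' g$adjacency
build_pair_graph <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    gb_stop("gb_empty_input", "no interaction records supplied")
  }
  n_in <- nrow(records)
  pa <- pb <- character(n_in)
  for (i in seq_len(n_in)) {
    cp <- canonicalize_pair(records$protein_a[i], records$protein_b[i])
    pa[i] <- cp[1]
    pb[i] <- cp[2]
  }
  key <- paste(pa, pb, sep = "\x1f")
  first <- !duplicated(key)
  idx_of <- match(key, key[first])
  lab <- as.integer(records$label)
  agg_lab <- lab[first]
  if (any(agg_lab[idx_of] != lab)) {
    bad <- key[which(agg_lab[idx_of] != lab)[1]]
    gb_stop("gb_conflicting_label",
            "pair (%s) appears with both labels",
            gsub("\x1f", ",", bad))
  }
  nodes <- data.frame(protein_a = pa[first], protein_b = pb[first],
                      label = agg_lab, stringsAsFactors = FALSE)
  n <- nrow(nodes)

  # Edge construction via protein -> node inverted index: O(sum m_p^2)
  # rather than O(n^2) string-set comparisons.
  prot_nodes <- split(rep(seq_len(n), 2L),
                      c(nodes$protein_a, nodes$protein_b))
  A <- matrix(0L, n, n)
  for (members in prot_nodes) {
    if (length(members) > 1L) {
      A[as.matrix(expand.grid(members, members))] <- 1L
    }
  }
  diag(A) <- 0L
  adj_list <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  structure(list(nodes = nodes, adjacency = A, adj_list = adj_list, n = n),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf(
    "pair_graph: %d pair-nodes (%d positive / %d negative), %d edges\n",
    x$n, sum(x$nodes$label == 1L), sum(x$nodes$label == 0L),
    sum(x$adjacency) / 2L))
  invisible(x)
}

node_keys <- function(graph) {
  paste(graph$nodes$protein_a, graph$nodes$protein_b, sep = "\x1f")
}

graph_proteins <- function(graph) {
  unique(c(graph$nodes$protein_a, graph$nodes$protein_b))
}

#' Write node and edge tables for a pair graph
#'
#' Emits `nodes.tsv` (`node_id`, `protein_a`, `protein_b`, `label`) and
#' `edges.tsv` (`node_i`, `node_j`, each undirected edge once with i < j),
#' plus an optional GraphML export.
#'
#' @param graph A `pair_graph`.
#' @param dir Output directory (created if absent).
#' @param graphml Also write `graph.graphml` (default FALSE).
#' @return Invisibly, the paths written.
#' @export
write_pair_graph <- function(graph, dir, graphml = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes_path <- file.path(dir, "nodes.tsv")
  edges_path <- file.path(dir, "edges.tsv")
  nd <- cbind(node_id = seq_len(graph$n) - 1L, graph$nodes)
  utils::write.table(nd, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ew <- which(upper.tri(graph$adjacency) & graph$adjacency == 1L,
              arr.ind = TRUE)
  ed <- data.frame(node_i = ew[, 1] - 1L, node_j = ew[, 2] - 1L)
  ed <- ed[order(ed$node_i, ed$node_j), , drop = FALSE]
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(nodes_path, edges_path)
  if (graphml) {
    gml <- file.path(dir, "graph.graphml")
    ig <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                              mode = "undirected")
    igraph::V(ig)$label <- graph$nodes$label
    igraph::V(ig)$pair <- paste(graph$nodes$protein_a, graph$nodes$protein_b,
                                sep = "-")
    igraph::write_graph(ig, gml, format = "graphml")
    paths <- c(paths, gml)
  }
  invisible(paths)
}
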