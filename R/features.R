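# Per-protein embeddings and per-node (pair) feature assembly.
#
# The pooling arithmetic mirrors what ELMO-style protein language models
# export: three layer outputs of shape L x d are summed into a per-residue
# embedding, then averaged over the L sequence positions into a single
# per-protein d-vector. Running such an embedder is out of scope; the
# embedding store ingests exported vectors, and a deterministic mock
# embedder stands in for tests and simulations.

#' Sum three embedder-layer outputs into a per-residue embedding
#'
#' @param layer1,layer2,layer3 Numeric L x d matrices of identical shape.
#' @return The elementwise sum (L x d).
#' @export
combine_layers <- function(layer1, layer2, layer3) {
  if (!identical(dim(layer1), dim(layer2)) ||
      !identical(dim(layer1), dim(layer3))) {
    gb_stop("gb_shape_mismatch", "layer matrices must share one shape")
  }
  layer1 + layer2 + layer3
}

#' Pool a per-residue embedding into a per-protein vector
#'
#' Column-wise mean over the L sequence positions.
#'
#' @param e Numeric L x d matrix, L >= 1.
#' @return Numeric vector of length d.
#' @export
pool_per_protein <- function(e) {
  if (!is.matrix(e) || nrow(e) < 1L) {
    gb_stop("gb_empty_sequence", "per-residue embedding must have L >= 1 rows")
  }
  colMeans(e)
}

#' Construct an embedding store
#'
#' A store maps protein ids to fixed-dimension real vectors. It may carry a
#' companion per-pair offset table (used by the synthetic generator to
#' plant class signal at pair-feature assembly time).
#'
#' @param vectors Numeric matrix, one row per protein, rownames = ids.
#' @param pair_offsets Optional numeric matrix of per-pair additive offsets
#'   (rows named by canonical pair, width 2d).
#' @return An object of class `embedding_store`.
#' @export
embedding_store <- function(vectors, pair_offsets = NULL) {
  if (!is.matrix(vectors) || is.null(rownames(vectors))) {
    gb_stop("gb_config", "vectors must be a matrix with protein-id rownames")
  }
  if (anyDuplicated(rownames(vectors))) {
    gb_stop("gb_config", "duplicate protein ids in embedding store")
  }
  if (!all(is.finite(vectors))) {
    gb_stop("gb_config", "embedding store contains non-finite values")
  }
  structure(list(vectors = vectors, d = ncol(vectors),
                 pair_offsets = pair_offsets),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("embedding_store: %d proteins, d = %d%s\n",
              nrow(x$vectors), x$d,
              if (is.null(x$pair_offsets)) "" else
                sprintf(", %d pair offsets", nrow(x$pair_offsets))))
  invisible(x)
}

#' Per-node raw feature vector for a protein pair
#'
#' Concatenates the two per-protein embeddings in canonical (lexicographic)
#' pair order, so the same pair written in either order yields the
#' identical 2d-vector. With `symmetrize = TRUE` the average of both
#' concatenation orders is returned instead. Any per-pair offset recorded
#' in the store is added afterwards.
#'
#' @param pair Character vector of two protein ids.
#' @param store An `embedding_store`.
#' @param symmetrize Average the two concatenation orders (default FALSE).
#' @return Numeric vector of length `2 * store$d`.
#' @export
pair_feature <- function(pair, store, symmetrize = FALSE) {
  cp <- canonicalize_pair(pair[1], pair[2])
  for (id in cp) {
    if (!id %in% rownames(store$vectors)) {
      gb_stop("gb_missing_protein", "protein absent from store: %s", id)
    }
  }
  e1 <- store$vectors[cp[1], ]
  e2 <- store$vectors[cp[2], ]
  x <- if (symmetrize) c((e1 + e2) / 2, (e2 + e1) / 2) else c(e1, e2)
  if (!is.null(store$pair_offsets)) {
    kk <- pair_key(cp[1], cp[2])
    if (kk %in% rownames(store$pair_offsets)) {
      x <- x + store$pair_offsets[kk, ]
    }
  }
  unname(x)
}

#' Deterministic mock per-protein embedding
#'
#' Draws a standard-normal vector from a private RNG keyed by a stable
#' hash of `(protein_id, seed)`; repeated calls are bitwise identical and
#' the caller's RNG state is untouched. A stand-in for a pretrained
#' sequence embedder in tests and simulations.
#'
#' @param protein_id Identifier string.
#' @param d Embedding dimension (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length d.
#' @export
mock_embedding <- function(protein_id, d, seed = 0L) {
  if (d < 1L) gb_stop("gb_config", "embedding dimension must be >= 1")
  with_seed(stream_seed(seed, paste0("mock-embed:", protein_id)), stats::rnorm(d))
}

#' Assemble the node feature matrix X
#'
#' One row per graph node, in node order, via [pair_feature()]; width 2d.
#' With a 1024-dim store this is the 2048-wide node feature matrix the
#' pair-node formulation calls for.
#'
#' @param graph A `pair_graph`.
#' @param store An `embedding_store` covering every protein in the graph.
#' @param symmetrize Passed to [pair_feature()].
#' @return Numeric `n x 2d` matrix.
#' @export
build_node_features <- function(graph, store, symmetrize = FALSE) {
  X <- matrix(0, graph$n, 2L * store$d)
  for (i in seq_len(graph$n)) {
    X[i, ] <- pair_feature(c(graph$nodes$protein_a[i],
                             graph$nodes$protein_b[i]),
                           store, symmetrize = symmetrize)
  }
  X
}

#' Write an embedding store as TSV
#'
#' One line per protein: id followed by d floats at full (17 significant
#' digit) precision, so a round-trip reproduces vectors bit-exactly. A
#' companion pair-offset table, if present, is written next to it as
#' `<path>.pairs.tsv` with the canonical pair ids in the first two columns.
#'
#' @param store An `embedding_store`.
#' @param path Output TSV path.
#' @export
write_embedding_store <- function(store, path) {
  fmt_row <- function(id, v) {
    paste(c(id, sprintf("%.17g", v)), collapse = "\t")
  }
  lines <- vapply(rownames(store$vectors),
                  function(id) fmt_row(id, store$vectors[id, ]), "")
  writeLines(lines, path)
  if (!is.null(store$pair_offsets)) {
    keys <- rownames(store$pair_offsets)
    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    plines <- vapply(seq_along(keys), function(i) {
      paste(c(parts[[i]][1], parts[[i]][2],
              sprintf("%.17g", store$pair_offsets[i, ])), collapse = "\t")
    }, "")
    writeLines(plines, paste0(path, ".pairs.tsv"))
  }
  invisible(path)
}

#' Read an embedding store from TSV
#'
#' @param path TSV path as written by [write_embedding_store()]; a
#'   `<path>.pairs.tsv` companion is picked up automatically.
#' @return An `embedding_store`.
#' @export
read_embedding_store <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  ids <- raw[[1]]
  vec <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vec) <- "double"
  rownames(vec) <- ids
  colnames(vec) <- NULL
  offsets <- NULL
  ppath <- paste0(path, ".pairs.tsv")
  if (file.exists(ppath)) {
    praw <- utils::read.table(ppath, sep = "\t", header = FALSE,
                              colClasses = "character", quote = "",
                              comment.char = "")
    offsets <- as.matrix(praw[, -(1:2), drop = FALSE])
    storage.mode(offsets) <- "double"
    rownames(offsets) <- mapply(pair_key, praw[[1]], praw[[2]],
                                USE.NAMES = FALSE)
    colnames(offsets) <- NULL
  }
  embedding_store(vec, pair_offsets = offsets)
}

#' Read protein sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences (names = first header token).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write protein sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}
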