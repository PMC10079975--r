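# Subgraph machinery for the graph transformer: PageRank-style intimacy
# matrix, top-k context sampling, Weisfeiler-Lehman role codes, sinusoidal
# positional encoding and hop distances.

#' Column-normalized adjacency matrix
#'
#' Computes `M = A D^-1` where D holds the column sums of A. Columns with
#' nonzero degree sum to 1; zero-degree columns are left all-zero (no
#' teleportation is added for isolated nodes).
#'
#' @param A Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return Real matrix of the same shape.
#' @export
column_normalized_adjacency <- function(A) {
  deg <- colSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  sweep(A, 2L, scale, `*`)
}

#' Intimacy matrix
#'
#' The PageRank-based closeness score
#' `S = alpha * (I - (1 - alpha) * A D^-1)^-1`,
#' equivalently the series `sum_t alpha (1-alpha)^t M^t`. Entry `S[u, v]`
#' scores the intimacy of node u to target v; each target's top-k most
#' intimate nodes define its learning context.
#'
#' @param A Symmetric 0/1 adjacency matrix, zero diagonal.
#' @param alpha Teleport probability in (0, 1]; default 0.15, the usual
#'   PageRank restart convention.
#' @return Object of class `intimacy_matrix`: list with `S` and `alpha`.
#' @export
intimacy_matrix <- function(A, alpha = 0.15) {
  if (!(alpha > 0 && alpha <= 1)) {
    gb_stop("gb_config", "alpha must lie in (0, 1]")
  }
  n <- nrow(A)
  M <- column_normalized_adjacency(A)
  S <- tryCatch(
    alpha * solve(diag(n) - (1 - alpha) * M),
    error = function(e) gb_stop("gb_singular_system",
                                "intimacy linear solve failed: %s",
                                conditionMessage(e)))
  structure(list(S = S, alpha = alpha), class = "intimacy_matrix")
}

#' Top-k intimacy context for a target node
#'
#' The `min(k, n-1)` nodes u != v with the largest intimacy `S[u, v]`,
#' sorted by descending intimacy, ties broken by ascending node index.
#'
#' @param S An `intimacy_matrix` (or a bare numeric matrix).
#' @param v Target node index (1-based).
#' @param k Context size (>= 1).
#' @return Integer vector of context node indices.
#' @export
top_k_context <- function(S, v, k) {
  if (k < 1L) gb_stop("gb_config", "k must be >= 1")
  Sm <- if (inherits(S, "intimacy_matrix")) S$S else S
  n <- nrow(Sm)
  others <- setdiff(seq_len(n), v)
  sc <- Sm[others, v]
  ord <- order(-sc, others)
  others[ord][seq_len(min(k, n - 1L))]
}

#' Weisfeiler-Lehman structural role codes
#'
#' One-dimensional WL color refinement from uniform initial colors,
#' iterated until the partition is stable (capped at n rounds); final
#' colors are mapped to dense integers 0..C-1 in sorted-signature order,
#' which makes the integer code itself invariant under node relabeling
#' (two isomorphic graphs give corresponding nodes the same code).
#' Codes are computed once on the full graph, so a node's role code is
#' invariant across the subgraphs it appears in.
#'
#' @param A Symmetric 0/1 adjacency matrix.
#' @return Integer vector of codes, one per node.
#' @export
wl_codes <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(integer(0))
  adj <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  colors <- rep(1L, n)
  for (round in seq_len(n)) {
    sigs <- vapply(seq_len(n), function(i) {
      paste(colors[i],
            paste(sort(colors[adj[[i]]]), collapse = ","), sep = "|")
    }, "")
    # densify in sorted-signature order (byte-wise, locale independent):
    # codes stay canonical under node relabeling
    lev <- sort(unique(sigs), method = "radix")
    new_colors <- match(sigs, lev)
    # refinement only ever splits classes, so the partition is stable as
    # soon as the class count stops growing
    if (length(lev) == length(unique(colors))) {
      colors <- new_colors
      break
    }
    colors <- new_colors
  }
  colors - 1L
}

#' Sinusoidal positional encoding
#'
#' The transformer encoding: component `2i` (0-based) is
#' `sin(index / 10000^(2i/d_h))` and component `2i+1` is
#' `cos(index / 10000^(2i/d_h))`. The same encoder serves the WL role
#' code, the intimacy rank and the hop distance, all non-negative
#' integers.
#'
#' @param index Non-negative integer (vectorized).
#' @param d_h Even embedding width.
#' @return Numeric vector of length `d_h` (or matrix if `index` has
#'   length > 1, one row per index).
#' @export
position_embed <- function(index, d_h) {
  if (d_h %% 2L != 0L) gb_stop("gb_config", "d_h must be even")
  i2 <- 2 * (seq_len(d_h / 2L) - 1L)
  freq <- 1 / 10000^(i2 / d_h)
  out <- matrix(0, length(index), d_h)
  ang <- outer(index, freq)
  out[, seq(1L, d_h, by = 2L)] <- sin(ang)
  out[, seq(2L, d_h, by = 2L)] <- cos(ang)
  if (length(index) == 1L) out[1, ] else out
}

#' Hop distances from context nodes to a target
#'
#' Unweighted shortest-path length in the original graph (not the linkless
#' subgraph) from each context node to the target; the target maps to 0
#' and unreachable nodes to `max_hop`.
#'
#' @param graph A `pair_graph`.
#' @param target Target node index.
#' @param context Integer vector of context node indices.
#' @param max_hop Distance assigned to unreachable nodes (default 20).
#' @return Integer vector aligned with `context`.
#' @export
hop_distances <- function(graph, target, context, max_hop = 20L) {
  dist <- rep(NA_integer_, graph$n)
  dist[target] <- 0L
  frontier <- target
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(unlist(graph$adj_list[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  out <- dist[context]
  out[is.na(out)] <- as.integer(max_hop)
  pmin(out, as.integer(max_hop))
}

#' Sample the linkless subgraph for a target node
#'
#' The target comes first with positional index 0 and hop 0, followed by
#' its top-k intimacy context with positional indices 1..k in rank order
#' (closer nodes get smaller indices). Edges among the sampled nodes are
#' deliberately not represented: the encoder attends over all of them.
#'
#' @param graph A `pair_graph`.
#' @param S An `intimacy_matrix` for the graph.
#' @param wl Integer WL codes from [wl_codes()].
#' @param v Target node index.
#' @param k Context size.
#' @param max_hop Passed to [hop_distances()].
#' @return List with `target`, `nodes` (target first), `pos`, `hop`, `wl`.
#' @export
sample_subgraph <- function(graph, S, wl, v, k, max_hop = 20L) {
  ctx <- top_k_context(S, v, k)
  nodes <- c(v, ctx)
  list(target = v,
       nodes = nodes,
       pos = seq_along(nodes) - 1L,
       hop = c(0L, hop_distances(graph, v, ctx, max_hop = max_hop)),
       wl = wl[nodes])
}
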