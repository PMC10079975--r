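# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately re-derives its quantity by a different route
# than the implementation under test.

# Random labelled interaction records over a protein universe; duplicate
# canonical pairs are collapsed keeping the first label, so the result is
# always a valid (conflict-free) record set.
random_records <- function(n_records, n_proteins, seed) {
  set.seed(seed)
  ids <- sprintf("PR%03d", seq_len(n_proteins))
  a <- sample(ids, n_records, replace = TRUE)
  b <- sample(ids, n_records, replace = TRUE)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  key <- mapply(function(x, y) paste(sort(c(x, y)), collapse = "|"), a, b)
  first <- !duplicated(key)
  data.frame(protein_a = a[first], protein_b = b[first],
             label = sample(0:1, sum(first), replace = TRUE),
             stringsAsFactors = FALSE)
}

# O(n^2) brute-force pair-graph adjacency: set intersection per node pair.
oracle_adjacency <- function(nodes) {
  n <- nrow(nodes)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    si <- c(nodes$protein_a[i], nodes$protein_b[i])
    for (j in seq_len(n)) {
      if (i != j && length(intersect(si, c(nodes$protein_a[j],
                                           nodes$protein_b[j]))) > 0) {
        A[i, j] <- 1L
      }
    }
  }
  A
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1L, p)
  A + t(A)
}

# Truncated power-series evaluation of the intimacy matrix:
# sum_{t=0}^{tmax} alpha (1-alpha)^t M^t.
oracle_intimacy_series <- function(A, alpha, tmax = 500L) {
  n <- nrow(A)
  deg <- colSums(A)
  M <- sweep(A, 2L, ifelse(deg > 0, 1 / deg, 0), `*`)
  term <- diag(n)
  acc <- alpha * term
  for (t in seq_len(tmax)) {
    term <- M %*% term
    acc <- acc + alpha * (1 - alpha)^t * term
  }
  acc
}

# Independent WL refinement: iterate until the number of classes is
# stable, building signatures from sorted neighbour classes via split().
oracle_wl_partition <- function(A) {
  n <- nrow(A)
  cls <- rep(1L, n)
  repeat {
    sig <- character(n)
    for (i in seq_len(n)) {
      nb <- cls[A[i, ] != 0]
      sig[i] <- paste(cls[i], paste(sort(nb), collapse = "."), sep = ":")
    }
    new_cls <- as.integer(factor(sig, levels = unique(sig)))
    if (max(new_cls) == max(cls)) break
    cls <- new_cls
  }
  cls
}

# Canonical form of a partition for comparison: class id by first
# appearance.
canon_partition <- function(x) match(x, unique(x))

# Small synthetic world shared by several tests: ~120 pair-nodes with a
# strong planted signal, cheap to train on.
small_world <- function(seed = 11L, separation = 6) {
  spec <- synthetic_spec(n_proteins = 30L, n_pos = 60L, n_neg = 60L,
                         embed_dim = 16L, separation = separation,
                         noise_sd = 1, seed = seed)
  records <- generate_interactions(spec)
  store <- generate_planted_embeddings(records, spec)
  graph <- build_pair_graph(records)
  list(spec = spec, records = records, store = store, graph = graph,
       X = build_node_features(graph, store))
}

# Nearest-class-mean linear classifier: estimate the class-mean
# difference direction on a training half, threshold at the midpoint,
# report held-out accuracy. The reference oracle for planted-signal
# learnability.
linear_oracle_accuracy <- function(X, y, seed = 1L) {
  set.seed(seed)
  n <- nrow(X)
  tr <- sample(n, floor(n / 2))
  te <- setdiff(seq_len(n), tr)
  mu1 <- colMeans(X[tr[y[tr] == 1], , drop = FALSE])
  mu0 <- colMeans(X[tr[y[tr] == 0], , drop = FALSE])
  w <- mu1 - mu0
  thr <- sum(w * (mu1 + mu0) / 2)
  pred <- as.integer(X[te, , drop = FALSE] %*% w > thr)
  mean(pred == y[te])
}
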