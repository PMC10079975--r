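test_that("column-normalized adjacency is column-stochastic off isolates", {
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(column_normalized_adjacency(A2), matrix(c(0, 1, 1, 0), 2, 2))
  # star K_{1,3}: hub 1
  A <- matrix(0L, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1L
  M <- column_normalized_adjacency(A)
  expect_equal(colSums(M), rep(1, 4))
  # isolated node keeps an all-zero column
  A5 <- rbind(cbind(A, 0L), 0L)
  expect_equal(colSums(column_normalized_adjacency(A5)), c(rep(1, 4), 0))
})

test_that("intimacy matrix matches closed forms", {
  # edgeless: S = alpha I
  n <- 5
  S0 <- intimacy_matrix(matrix(0L, n, n), alpha = 0.15)
  expect_equal(S0$S, 0.15 * diag(n), tolerance = 1e-12)
  # two nodes, one edge: hand 2x2 inversion
  a <- 0.15
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  S <- intimacy_matrix(A, a)$S
  den <- 1 - (1 - a)^2
  expect_equal(diag(S), rep(a / den, 2), tolerance = 1e-12)
  expect_equal(S[1, 2], a * (1 - a) / den, tolerance = 1e-12)
  expect_error(intimacy_matrix(A, 0), class = "gb_config")
})

test_that("intimacy matrix equals the truncated power series", {
  for (seed in c(1L, 2L, 3L)) {
    A <- random_adjacency(30, 0.15, seed)
    S <- intimacy_matrix(A, 0.15)
    expect_lt(max(abs(S$S - oracle_intimacy_series(A, 0.15))), 1e-8)
    expect_true(all(S$S >= 0))
    if (all(colSums(A) > 0)) {
      expect_equal(colSums(S$S), rep(1, 30), tolerance = 1e-10)
    }
  }
})

test_that("top_k_context matches the sort oracle and tie rule", {
  set.seed(8)
  n <- 12
  S <- matrix(runif(n * n), n, n)
  for (v in c(1L, 5L, 12L)) {
    for (k in c(1L, 4L, n - 1L, n + 3L)) {
      got <- top_k_context(S, v, k)
      others <- setdiff(seq_len(n), v)
      expected <- others[order(-S[others, v], others)]
      expect_identical(got, expected[seq_len(min(k, n - 1L))])
    }
  }
  # explicit tie case: equal intimacies among nodes 2, 5, 9
  St <- matrix(0, 10, 10)
  St[c(2, 5, 9), 1] <- 0.7
  expect_identical(top_k_context(St, 1L, 2L), c(2L, 5L))
})

test_that("WL codes capture structural roles", {
  # 6-cycle: vertex transitive, one code
  C6 <- matrix(0L, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    C6[i, j] <- C6[j, i] <- 1L
  }
  expect_identical(unique(wl_codes(C6)), 0L)
  # path P4: endpoints one role, interior another
  P4 <- matrix(0L, 4, 4)
  for (i in 1:3) P4[i, i + 1] <- P4[i + 1, i] <- 1L
  codes <- wl_codes(P4)
  expect_identical(codes[1], codes[4])
  expect_identical(codes[2], codes[3])
  expect_false(codes[1] == codes[2])
  expect_identical(sort(unique(codes)), 0:1)
})

test_that("WL partition equals the independent refinement oracle and is stable", {
  for (seed in c(4L, 5L, 6L)) {
    A <- random_adjacency(25, 0.12, seed)
    codes <- wl_codes(A)
    expect_identical(canon_partition(codes + 1L),
                     canon_partition(oracle_wl_partition(A)))
    # one extra refinement round must not split any class
    sig <- vapply(seq_len(nrow(A)), function(i) {
      paste(codes[i], paste(sort(codes[A[i, ] != 0]), collapse = ","),
            sep = "|")
    }, "")
    expect_identical(length(unique(sig)), length(unique(codes)))
  }
})

test_that("sinusoidal position encoding follows the stated formula", {
  d_h <- 16L
  e0 <- position_embed(0L, d_h)
  expect_equal(e0, rep(c(0, 1), d_h / 2))
  for (idx in c(1L, 7L, 50L)) {
    e <- position_embed(idx, d_h)
    expect_true(all(abs(e) <= 1))
    direct <- numeric(d_h)
    for (i in 0:(d_h / 2 - 1)) {
      direct[2 * i + 1] <- sin(idx / 10000^(2 * i / d_h))
      direct[2 * i + 2] <- cos(idx / 10000^(2 * i / d_h))
    }
    expect_equal(e, direct, tolerance = 1e-12)
  }
  expect_error(position_embed(1L, 7L), class = "gb_config")
})

test_that("hop distances agree with an independent BFS (igraph)", {
  for (seed in c(7L, 8L)) {
    recs <- random_records(60, 20, seed)
    g <- build_pair_graph(recs)
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency,
                                              mode = "undirected")
    D <- igraph::distances(ig)
    for (v in c(1L, g$n)) {
      ctx <- setdiff(seq_len(g$n), v)
      got <- hop_distances(g, v, ctx, max_hop = 20L)
      expected <- pmin(D[ctx, v], 20)
      expect_equal(got, unname(expected))
    }
    expect_identical(hop_distances(g, 1L, 1L), 0L)
  }
})

test_that("sampled subgraphs satisfy the ordering invariants", {
  w <- small_world(seed = 31L)
  S <- intimacy_matrix(w$graph$adjacency)
  wl <- wl_codes(w$graph$adjacency)
  for (v in c(1L, 25L, w$graph$n)) {
    sub <- sample_subgraph(w$graph, S, wl, v, k = 7L)
    expect_identical(sub$nodes[1], v)
    expect_identical(sub$pos, 0:(length(sub$nodes) - 1L))
    expect_identical(sub$hop[1], 0L)
    ints <- S$S[sub$nodes[-1], v]
    expect_true(all(diff(ints) <= 1e-12))
  }
})
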