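# Model-level checks: input aggregation, encoder behaviour, fusion,
# classification, determinism and permutation equivariance.

make_params <- function(d_in = 6L, d_h = 8L, ...) {
  init_model_params(d_in, d_h = d_h, k = 3L, n_layers = 2L, heads = 2L,
                    hidden_dropout = 0, attention_dropout = 0, seed = 42L,
                    ...)
}

test_that("node input embedding is the four-term vector sum", {
  p <- make_params()
  # zero projection, all indices 0: the 0-index sinusoid tripled
  p0 <- p
  p0$W_embed <- p0$W_embed * 0
  e <- node_input_embedding(numeric(6), 0L, 0L, 0L, p0)
  expect_equal(e, rep(c(0, 3), 4))
  # random components match the independent four-term addition
  set.seed(1)
  x <- rnorm(6)
  got <- node_input_embedding(x, 3L, 1L, 2L, p)
  expected <- drop(x %*% p$W_embed) + p$b_embed +
    position_embed(3L, 8L) + position_embed(1L, 8L) + position_embed(2L, 8L)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_error(node_input_embedding(rnorm(5), 0L, 0L, 0L, p),
               class = "gb_shape_mismatch")
})

test_that("attention rows sum to one and singleton attention is trivial", {
  p <- make_params()
  set.seed(2)
  # 1-node subgraph: output defined, finite
  H1 <- matrix(rnorm(8), 1, 8)
  X1 <- matrix(rnorm(6), 1, 6)
  out1 <- encoder_forward(H1, X1, p)
  expect_true(all(is.finite(out1)))
  # attention probabilities row-stochastic for a random subgraph
  H <- matrix(rnorm(32), 4, 8)
  Q <- H %*% p$layers[[1]]$Wq
  K <- H %*% p$layers[[1]]$Wk
  for (cols in list(1:4, 5:8)) {
    P <- pairGBERT:::softmax_rows(Q[, cols] %*% t(K[, cols]) / sqrt(4))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
  }
})

test_that("pure-mode encoder equals a straight-line dense recomputation", {
  p <- make_params(pure_eq3 = TRUE)
  set.seed(3)
  m <- 4L
  H0 <- matrix(rnorm(m * 8), m, 8)
  X_sub <- matrix(rnorm(m * 6), m, 6)
  got <- encoder_forward(H0, X_sub, p)
  # independent re-computation, scalar loops only
  GR <- X_sub %*% p$W_res + matrix(p$b_res, m, 8, byrow = TRUE)
  H <- H0
  for (l in 1:2) {
    lw <- p$layers[[l]]
    Q <- H %*% lw$Wq
    K <- H %*% lw$Wk
    V <- H %*% lw$Wv
    Hn <- matrix(0, m, 8)
    for (h in 1:2) {
      cols <- if (h == 1) 1:4 else 5:8
      sc <- matrix(0, m, m)
      for (i in 1:m) for (j in 1:m) {
        sc[i, j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(4)
      }
      P <- matrix(0, m, m)
      for (i in 1:m) P[i, ] <- exp(sc[i, ]) / sum(exp(sc[i, ]))
      Hn[, cols] <- P %*% V[, cols]
    }
    H <- Hn + GR
  }
  expect_equal(got, H, tolerance = 1e-6)
})

test_that("fuse averages rows and classify is a proper softmax", {
  one <- matrix(rnorm(8), 1, 8)
  expect_equal(fuse(one), drop(one))
  r <- rnorm(8)
  expect_equal(fuse(rbind(r, -r)), rep(0, 8))
  set.seed(4)
  M <- matrix(rnorm(40), 5, 8)
  expect_equal(fuse(M), apply(M, 2, mean))

  p <- make_params()
  pz <- p
  pz$W_cls <- pz$W_cls * 0
  expect_equal(classify(rnorm(8), pz), c(0.5, 0.5))
  z <- rnorm(8)
  pr <- classify(z, p)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # exp-normalize oracle with max subtraction
  lg <- drop(z %*% p$W_cls) + p$b_cls
  expect_equal(pr, exp(lg - max(lg)) / sum(exp(lg - max(lg))),
               tolerance = 1e-12)
})

test_that("model_forward outputs probabilities, deterministically in eval mode", {
  w <- small_world(seed = 41L)
  p <- init_model_params(ncol(w$X), d_h = 16L, k = 5L, seed = 13L)
  pr1 <- model_forward(w$graph, w$X, p, nodes = 1:10)
  pr2 <- model_forward(w$graph, w$X, p, nodes = 1:10)
  expect_identical(pr1, pr2)
  expect_equal(rowSums(pr1), rep(1, 10), tolerance = 1e-9)
})

test_that("model_forward commutes with node relabeling (tie-free graphs)", {
  # mean readout makes the check exercise the whole fused representation
  w <- small_world(seed = 43L)
  g <- w$graph
  X <- w$X
  p <- init_model_params(ncol(X), d_h = 16L, k = 5L, readout = "mean",
                         seed = 17L)
  S <- intimacy_matrix(g$adjacency, 0.15)
  # restrict to targets whose intimacy scores are tie-free so context
  # ordering is permutation-invariant
  probe <- which(vapply(seq_len(g$n), function(v) {
    s <- sort(S$S[-v, v], decreasing = TRUE)[1:6]
    all(diff(s) < -1e-9)
  }, logical(1)))[1:5]
  expect_true(all(!is.na(probe)))

  set.seed(44)
  perm <- sample(g$n)          # perm[i]: new position of old node i
  g2 <- g
  inv <- order(perm)
  g2$adjacency <- g$adjacency[inv, inv]
  g2$nodes <- g$nodes[inv, ]
  g2$adj_list <- lapply(seq_len(g$n), function(i) {
    sort(perm[g$adj_list[[inv[i]]]])
  })
  X2 <- X[inv, ]
  pr1 <- model_forward(g, X, p, nodes = probe)
  pr2 <- model_forward(g2, X2, p, nodes = perm[probe])
  expect_equal(pr1, pr2, tolerance = 1e-9)
})

test_that("checkpoints round-trip through JSON", {
  p <- make_params()
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p, path)
  q <- load_checkpoint(path)
  expect_equal(q$W_embed, p$W_embed, tolerance = 1e-15)
  expect_equal(q$layers[[2]]$Wv, p$layers[[2]]$Wv, tolerance = 1e-15)
  expect_identical(q$config[order(names(q$config))],
                   p$config[order(names(p$config))])
  w <- small_world(seed = 47L)
  p2 <- init_model_params(ncol(w$X), d_h = 16L, seed = 3L)
  path2 <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p2, path2)
  q2 <- load_checkpoint(path2)
  expect_equal(model_forward(w$graph, w$X, q2, nodes = 1:5),
               model_forward(w$graph, w$X, p2, nodes = 1:5),
               tolerance = 1e-12)
})
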