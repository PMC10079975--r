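# Graph transformer model: parameter container, node-level forward pass
# and the analytic backward pass used by the trainer.
#
# Per target node the computation is
#   H^0   = Embed(X_sub) + PE(WL) + PE(pos) + PE(hop)      (additive)
#   H^l   = Encoder layer: multi-head softmax(QK'/sqrt(d_k))V
#           + graph residual (projection of X_sub), then the standard
#           transformer sublayers (layer norm + position-wise FFN);
#           a "pure" config drops everything but attention + residual
#   z     = readout of H^D: the target row (default) or the column mean
#           over all subgraph nodes (average fusion)
#   y_hat = softmax(FC(z))

#' Initialize model parameters
#'
#' Glorot-uniform weight initialization; layer-norm gains 1, biases 0.
#' The graph-residual projection is shared across encoder layers and
#' re-injects the subgraph's raw features at every layer, countering the
#' suspended-animation failure mode of deep graph stacks.
#'
#' @param d_in Raw node feature width (2d for a d-dim protein store).
#' @param d_h Hidden width; must be even and divisible by `heads`.
#'   Default 32.
#' @param k Subgraph context size (default 7); the target node sits in
#'   front of the k sampled context nodes.
#' @param n_layers Number of encoder layers D (default 2).
#' @param heads Attention heads (default 2).
#' @param hidden_dropout,attention_dropout Dropout rates applied in
#'   training mode to hidden activations (default 0.5) and attention
#'   probabilities (default 0.3).
#' @param alpha Intimacy restart probability (default 0.15).
#' @param max_hop Hop value assigned to unreachable context nodes.
#' @param pure_eq3 Drop layer norm, output projection and feed-forward
#'   sublayers, leaving attention + graph residual only (oracle testing).
#' @param readout Which representation feeds the classifier: `"target"`
#'   (the target node's final representation, the default — the readout
#'   the reference Graph-BERT node classifier uses) or `"mean"` (the
#'   average over all subgraph nodes; see the vignette for why this
#'   dilutes the target's signal on small graphs).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `gbert_params`.
#' @export
init_model_params <- function(d_in, d_h = 32L, k = 7L, n_layers = 2L,
                              heads = 2L, hidden_dropout = 0.5,
                              attention_dropout = 0.3, alpha = 0.15,
                              max_hop = 20L, pure_eq3 = FALSE,
                              readout = c("target", "mean"), seed = 1L) {
  readout <- match.arg(readout)
  if (d_h %% 2L != 0L) gb_stop("gb_shape_mismatch", "d_h must be even")
  if (d_h %% heads != 0L) {
    gb_stop("gb_shape_mismatch", "heads must divide d_h")
  }
  if (n_layers < 1L) gb_stop("gb_config", "need at least one encoder layer")
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  with_seed(stream_seed(seed, "init"), {
    layers <- lapply(seq_len(n_layers), function(l) {
      list(Wq = glorot(d_h, d_h), Wk = glorot(d_h, d_h),
           Wv = glorot(d_h, d_h), Wo = glorot(d_h, d_h),
           b_o = numeric(d_h),
           ln1_g = rep(1, d_h), ln1_b = numeric(d_h),
           W1 = glorot(d_h, d_h), b1 = numeric(d_h),
           W2 = glorot(d_h, d_h), b2 = numeric(d_h),
           ln2_g = rep(1, d_h), ln2_b = numeric(d_h))
    })
    structure(list(
      W_embed = glorot(d_in, d_h), b_embed = numeric(d_h),
      W_res = glorot(d_in, d_h), b_res = numeric(d_h),
      layers = layers,
      W_cls = glorot(d_h, 2L), b_cls = numeric(2L),
      config = list(d_in = d_in, d_h = d_h, k = as.integer(k),
                    n_layers = as.integer(n_layers),
                    heads = as.integer(heads),
                    hidden_dropout = hidden_dropout,
                    attention_dropout = attention_dropout,
                    alpha = alpha, max_hop = as.integer(max_hop),
                    pure_eq3 = isTRUE(pure_eq3), readout = readout)
    ), class = "gbert_params")
  })
}

#' @export
print.gbert_params <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "gbert_params: d_in=%d d_h=%d k=%d layers=%d heads=%d%s\n",
    cfg$d_in, cfg$d_h, cfg$k, cfg$n_layers, cfg$heads,
    if (cfg$pure_eq3) " (pure attention+residual)" else ""))
  invisible(x)
}

ln_eps <- 1e-12

layer_norm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

#' Aggregate input embedding for one subgraph node
#'
#' The vector sum `e^x + e^r + e^p + e^d`: an affine projection of the raw
#' feature row plus sinusoidal encodings of the WL role code, intimacy
#' rank and hop distance (all three share the same sinusoidal encoder).
#'
#' @param x Raw feature row (length `d_in`).
#' @param wl,pos,hop Non-negative integers for the node.
#' @param params A `gbert_params`.
#' @return Numeric vector of length `d_h`.
#' @export
node_input_embedding <- function(x, wl, pos, hop, params) {
  cfg <- params$config
  if (length(x) != cfg$d_in) {
    gb_stop("gb_shape_mismatch",
            "feature length %d does not match d_in %d", length(x), cfg$d_in)
  }
  drop(x %*% params$W_embed) + params$b_embed +
    position_embed(wl, cfg$d_h) + position_embed(pos, cfg$d_h) +
    position_embed(hop, cfg$d_h)
}

# Forward through one node's subgraph, optionally caching every
# intermediate for the backward pass. X_sub: m x d_in raw features.
gbert_node_forward <- function(params, X_sub, wl, pos, hop,
                               train_mode = FALSE, keep_cache = FALSE) {
  cfg <- params$config
  m <- nrow(X_sub)
  d_h <- cfg$d_h
  PE <- position_embed(wl, d_h) + position_embed(pos, d_h) +
    position_embed(hop, d_h)
  if (m == 1L) PE <- matrix(PE, 1L, d_h)
  E <- X_sub %*% params$W_embed + rep(params$b_embed, each = m)
  H0_pre <- E + PE
  mask0 <- if (train_mode) drop_mask(m, d_h, cfg$hidden_dropout)
  H <- if (is.null(mask0)) H0_pre else H0_pre * mask0
  GR <- X_sub %*% params$W_res + rep(params$b_res, each = m)

  cache <- if (keep_cache) {
    list(X_sub = X_sub, mask0 = mask0, H0 = H, GR = GR, layers = list())
  }
  nh <- cfg$heads
  dk <- d_h / nh
  scale <- 1 / sqrt(dk)
  head_cols <- lapply(seq_len(nh), function(h) ((h - 1L) * dk + 1L):(h * dk))

  for (l in seq_len(cfg$n_layers)) {
    lw <- params$layers[[l]]
    Q <- H %*% lw$Wq
    K <- H %*% lw$Wk
    V <- H %*% lw$Wv
    C <- matrix(0, m, d_h)
    lcache <- list(H_in = H, Q = Q, K = K, V = V, P = vector("list", nh),
                   mask_a = vector("list", nh))
    for (h in seq_len(nh)) {
      cols <- head_cols[[h]]
      P <- softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) * scale)
      lcache$P[[h]] <- P
      Pu <- P
      if (train_mode) {
        ma <- drop_mask(m, m, cfg$attention_dropout)
        if (!is.null(ma)) Pu <- P * ma
        lcache$mask_a[h] <- list(ma)
      }
      lcache$Pu <- c(lcache$Pu, list(Pu))
      C[, cols] <- Pu %*% V[, cols, drop = FALSE]
    }
    lcache$C <- C
    if (cfg$pure_eq3) {
      H <- C + GR
    } else {
      O <- C %*% lw$Wo + rep(lw$b_o, each = m)
      mask_o <- if (train_mode) drop_mask(m, d_h, cfg$hidden_dropout)
      Ou <- if (is.null(mask_o)) O else O * mask_o
      S1 <- H + Ou + GR
      ln1 <- layer_norm_fwd(S1, lw$ln1_g, lw$ln1_b)
      H1 <- ln1$y
      A1 <- H1 %*% lw$W1 + rep(lw$b1, each = m)
      G <- gelu(A1)
      Fo <- G %*% lw$W2 + rep(lw$b2, each = m)
      mask_f <- if (train_mode) drop_mask(m, d_h, cfg$hidden_dropout)
      Fu <- if (is.null(mask_f)) Fo else Fo * mask_f
      S2 <- H1 + Fu
      ln2 <- layer_norm_fwd(S2, lw$ln2_g, lw$ln2_b)
      lcache <- c(lcache, list(mask_o = mask_o, ln1 = ln1, H1 = H1,
                               A1 = A1, G = G, mask_f = mask_f, ln2 = ln2))
      H <- ln2$y
    }
    if (keep_cache) cache$layers[[l]] <- lcache
  }
  z <- if (identical(cfg$readout, "target")) H[1L, ] else colMeans(H)
  logits <- drop(z %*% params$W_cls) + params$b_cls
  e <- exp(logits - max(logits))
  prob <- e / sum(e)
  if (keep_cache) {
    cache$H_final <- H
    cache$z <- z
    cache$prob <- prob
    cache$m <- m
  }
  list(prob = prob, z = z, H = H, cache = cache)
}

zero_grads <- function(params) {
  zl <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  g <- list(W_embed = zl(params$W_embed), b_embed = zl(params$b_embed),
            W_res = zl(params$W_res), b_res = zl(params$b_res),
            W_cls = zl(params$W_cls), b_cls = zl(params$b_cls),
            layers = lapply(params$layers, function(lw) lapply(lw, zl)))
  g
}

# Accumulate into `grads` the gradient of -log prob[y] for one node.
gbert_node_backward <- function(params, cache, y, grads) {
  cfg <- params$config
  m <- cache$m
  d_h <- cfg$d_h
  nh <- cfg$heads
  dk <- d_h / nh
  scale <- 1 / sqrt(dk)
  head_cols <- lapply(seq_len(nh), function(h) ((h - 1L) * dk + 1L):(h * dk))

  dlogits <- cache$prob
  dlogits[y + 1L] <- dlogits[y + 1L] - 1
  grads$W_cls <- grads$W_cls + outer(cache$z, dlogits)
  grads$b_cls <- grads$b_cls + dlogits
  dz <- drop(params$W_cls %*% dlogits)
  if (identical(cfg$readout, "target")) {
    dH <- matrix(0, m, d_h)
    dH[1L, ] <- dz
  } else {
    dH <- matrix(dz / m, m, d_h, byrow = TRUE)
  }
  dGR <- matrix(0, m, d_h)

  for (l in rev(seq_len(cfg$n_layers))) {
    lw <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- grads$layers[[l]]
    if (cfg$pure_eq3) {
      dC <- dH
      dGR <- dGR + dH
      dH_in <- matrix(0, m, d_h)
    } else {
      bn2 <- layer_norm_bwd(dH, lc$ln2, lw$ln2_g)
      gl$ln2_g <- gl$ln2_g + bn2$dg
      gl$ln2_b <- gl$ln2_b + bn2$db
      dS2 <- bn2$dx
      dH1 <- dS2
      dFu <- dS2
      dFo <- if (is.null(lc$mask_f)) dFu else dFu * lc$mask_f
      gl$W2 <- gl$W2 + t(lc$G) %*% dFo
      gl$b2 <- gl$b2 + colSums(dFo)
      dG <- dFo %*% t(lw$W2)
      dA1 <- dG * gelu_grad(lc$A1)
      gl$W1 <- gl$W1 + t(lc$H1) %*% dA1
      gl$b1 <- gl$b1 + colSums(dA1)
      dH1 <- dH1 + dA1 %*% t(lw$W1)
      bn1 <- layer_norm_bwd(dH1, lc$ln1, lw$ln1_g)
      gl$ln1_g <- gl$ln1_g + bn1$dg
      gl$ln1_b <- gl$ln1_b + bn1$db
      dS1 <- bn1$dx
      dH_in <- dS1
      dGR <- dGR + dS1
      dOu <- dS1
      dO <- if (is.null(lc$mask_o)) dOu else dOu * lc$mask_o
      gl$Wo <- gl$Wo + t(lc$C) %*% dO
      gl$b_o <- gl$b_o + colSums(dO)
      dC <- dO %*% t(lw$Wo)
    }
    dQ <- matrix(0, m, d_h)
    dK <- matrix(0, m, d_h)
    dV <- matrix(0, m, d_h)
    for (h in seq_len(nh)) {
      cols <- head_cols[[h]]
      P <- lc$P[[h]]
      Pu <- lc$Pu[[h]]
      dCh <- dC[, cols, drop = FALSE]
      dPu <- dCh %*% t(lc$V[, cols, drop = FALSE])
      dV[, cols] <- t(Pu) %*% dCh
      dP <- if (is.null(lc$mask_a[[h]])) dPu else dPu * lc$mask_a[[h]]
      dSc <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dSc %*% lc$K[, cols, drop = FALSE] * scale
      dK[, cols] <- t(dSc) %*% lc$Q[, cols, drop = FALSE] * scale
    }
    gl$Wq <- gl$Wq + t(lc$H_in) %*% dQ
    gl$Wk <- gl$Wk + t(lc$H_in) %*% dK
    gl$Wv <- gl$Wv + t(lc$H_in) %*% dV
    dH_in <- dH_in + dQ %*% t(lw$Wq) + dK %*% t(lw$Wk) + dV %*% t(lw$Wv)
    grads$layers[[l]] <- gl
    dH <- dH_in
  }

  dH0 <- if (is.null(cache$mask0)) dH else dH * cache$mask0
  grads$W_embed <- grads$W_embed + t(cache$X_sub) %*% dH0
  grads$b_embed <- grads$b_embed + colSums(dH0)
  grads$W_res <- grads$W_res + t(cache$X_sub) %*% dGR
  grads$b_res <- grads$b_res + colSums(dGR)
  grads
}

#' Encoder forward pass over a prepared subgraph representation
#'
#' Applies the D encoder layers to an already-aggregated input matrix
#' `H0`, adding the graph residual computed from the subgraph's raw
#' features at every layer. Dropout is active only in training mode.
#'
#' @param H0 `(k+1) x d_h` aggregated input embeddings.
#' @param X_sub `(k+1) x d_in` raw features of the subgraph nodes.
#' @param params A `gbert_params`.
#' @param train_mode Apply dropout (default FALSE).
#' @return `(k+1) x d_h` encoded representations.
#' @export
encoder_forward <- function(H0, X_sub, params, train_mode = FALSE) {
  cfg <- params$config
  if (ncol(H0) != cfg$d_h || ncol(X_sub) != cfg$d_in ||
      nrow(H0) != nrow(X_sub)) {
    gb_stop("gb_shape_mismatch", "H0/X_sub shapes inconsistent with config")
  }
  m <- nrow(H0)
  GR <- X_sub %*% params$W_res + rep(params$b_res, each = m)
  H <- H0
  nh <- cfg$heads
  dk <- cfg$d_h / nh
  scale <- 1 / sqrt(dk)
  for (l in seq_len(cfg$n_layers)) {
    lw <- params$layers[[l]]
    Q <- H %*% lw$Wq
    K <- H %*% lw$Wk
    V <- H %*% lw$Wv
    C <- matrix(0, m, cfg$d_h)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      P <- softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) * scale)
      if (train_mode) {
        ma <- drop_mask(m, m, cfg$attention_dropout)
        if (!is.null(ma)) P <- P * ma
      }
      C[, cols] <- P %*% V[, cols, drop = FALSE]
    }
    if (cfg$pure_eq3) {
      H <- C + GR
    } else {
      O <- C %*% lw$Wo + rep(lw$b_o, each = m)
      if (train_mode) {
        mo <- drop_mask(m, cfg$d_h, cfg$hidden_dropout)
        if (!is.null(mo)) O <- O * mo
      }
      H1 <- layer_norm_fwd(H + O + GR, lw$ln1_g, lw$ln1_b)$y
      Fo <- gelu(H1 %*% lw$W1 + rep(lw$b1, each = m)) %*% lw$W2 +
        rep(lw$b2, each = m)
      if (train_mode) {
        mf <- drop_mask(m, cfg$d_h, cfg$hidden_dropout)
        if (!is.null(mf)) Fo <- Fo * mf
      }
      H <- layer_norm_fwd(H1 + Fo, lw$ln2_g, lw$ln2_b)$y
    }
  }
  H
}

#' Fuse subgraph representations into the target's vector
#'
#' The average over all subgraph nodes (target included) of the encoder's
#' final representations.
#'
#' @param H_D `(k+1) x d_h` matrix of final representations.
#' @return Numeric vector of length `d_h`.
#' @export
fuse <- function(H_D) {
  if (nrow(H_D) < 1L) gb_stop("gb_shape_mismatch", "need at least one row")
  colMeans(H_D)
}

#' Classify a fused representation
#'
#' Softmax over the affine classifier head; returns the two class
#' probabilities (non-interacting, interacting).
#'
#' @param z Fused representation, length `d_h`.
#' @param params A `gbert_params`.
#' @return Numeric vector of length 2 summing to 1.
#' @export
classify <- function(z, params) {
  logits <- drop(z %*% params$W_cls) + params$b_cls
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Full model forward pass over selected nodes
#'
#' For each requested node: sample the intimacy-ranked linkless subgraph,
#' aggregate the four input embeddings, run the encoder, fuse, classify.
#' Intimacy matrix and WL codes are computed once on the full graph (and
#' may be supplied precomputed). Deterministic in eval mode.
#'
#' @param graph A `pair_graph`.
#' @param X Node feature matrix from [build_node_features()].
#' @param params A `gbert_params`.
#' @param nodes Integer node indices (default all).
#' @param S Optional precomputed `intimacy_matrix`.
#' @param wl Optional precomputed WL codes.
#' @param subgraphs Optional precomputed list of subgraphs (one per graph
#'   node, as from [sample_subgraph()]).
#' @param train_mode Apply dropout (default FALSE).
#' @return `length(nodes) x 2` matrix of class probabilities.
#' @export
model_forward <- function(graph, X, params, nodes = seq_len(graph$n),
                          S = NULL, wl = NULL, subgraphs = NULL,
                          train_mode = FALSE) {
  cfg <- params$config
  if (is.null(subgraphs)) {
    if (is.null(S)) S <- intimacy_matrix(graph$adjacency, cfg$alpha)
    if (is.null(wl)) wl <- wl_codes(graph$adjacency)
  }
  out <- matrix(0, length(nodes), 2L)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    sub <- if (!is.null(subgraphs)) subgraphs[[v]] else {
      sample_subgraph(graph, S, wl, v, cfg$k, max_hop = cfg$max_hop)
    }
    fw <- gbert_node_forward(params, X[sub$nodes, , drop = FALSE],
                             sub$wl, sub$pos, sub$hop,
                             train_mode = train_mode)
    out[i, ] <- fw$prob
  }
  colnames(out) <- c("p0", "p1")
  out
}
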