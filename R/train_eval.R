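# Training and evaluation machinery: stratified splits, k-fold CV,
# confusion-matrix metrics, Welch's t-test, Adam, and the early-stopping
# training loop minimizing binary cross-entropy.

#' Training configuration
#'
#' Defaults follow the published setup: learning rate 0.001, at most 200
#' epochs with early stopping, subgraph size k = 7, two encoder layers,
#' two attention heads, hidden/attention dropout 0.5/0.3, Adam on binary
#' cross-entropy. Early-stopping specifics (validation carve-out 10%,
#' patience 20, best-epoch restore) and batch size 64 are this package's
#' conventions, all overridable here.
#'
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param validation_fraction Stratified fraction of the training split
#'   held out for early stopping, in (0, 1).
#' @param batch_size Subgraphs per gradient step.
#' @param seed Integer seed governing initialization, batching, dropout.
#' @param d_h,k,n_layers,heads,hidden_dropout,attention_dropout,alpha,max_hop,pure_eq3
#'   Model architecture settings; see [init_model_params()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200L,
                         patience = 20L, validation_fraction = 0.1,
                         batch_size = 64L, seed = 1L, d_h = 32L, k = 7L,
                         n_layers = 2L, heads = 2L, hidden_dropout = 0.5,
                         attention_dropout = 0.3, alpha = 0.15,
                         max_hop = 20L, pure_eq3 = FALSE,
                         readout = c("target", "mean")) {
  readout <- match.arg(readout)
  if (learning_rate <= 0) gb_stop("gb_config", "learning_rate must be > 0")
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    gb_stop("gb_config", "validation_fraction must lie in (0, 1)")
  }
  if (patience < 1L) gb_stop("gb_config", "patience must be >= 1")
  structure(as.list(environment()), class = "train_config")
}

#' Stratified train/test split
#'
#' Disjoint index sets covering all nodes, stratified by label and
#' reproducible for a fixed seed.
#'
#' @param n_nodes Number of nodes.
#' @param test_fraction Fraction assigned to the test side, in (0, 1).
#' @param seed Integer seed.
#' @param labels Integer 0/1 labels, length `n_nodes`.
#' @return List with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n_nodes, test_fraction = 0.2, seed = 1L,
                             labels = NULL) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    gb_stop("gb_config", "test_fraction must lie in (0, 1)")
  }
  if (is.null(labels)) labels <- rep(0L, n_nodes)
  if (length(labels) != n_nodes) {
    gb_stop("gb_length_mismatch", "labels length must equal n_nodes")
  }
  test <- integer(0)
  with_seed(stream_seed(seed, "split"), {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_c <- length(idx)
      n_t <- round(test_fraction * n_c)
      if (n_c >= 2L) n_t <- min(max(n_t, 1L), n_c - 1L)
      if (n_c == 1L && length(unique(labels)) > 1L) {
        gb_stop("gb_degenerate_split",
                "class %s has a single member; stratification impossible", cl)
      }
      test <- c(test, sample(idx)[seq_len(n_t)])
    }
  })
  test <- sort(test)
  train <- setdiff(seq_len(n_nodes), test)
  if (length(train) == 0L || length(test) == 0L) {
    gb_stop("gb_degenerate_split", "one side of the split is empty")
  }
  list(train = train, test = test)
}

#' Stratified k-fold cross-validation indices
#'
#' @param n_nodes Number of nodes.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param labels Integer 0/1 labels.
#' @return List of k lists, each with `train` and `test` index vectors;
#'   the test sets partition `1:n_nodes`.
#' @export
kfold_indices <- function(n_nodes, k = 5L, seed = 1L, labels = NULL) {
  if (k < 2L || n_nodes < k) {
    gb_stop("gb_degenerate_split", "need k >= 2 and n_nodes >= k")
  }
  if (is.null(labels)) labels <- rep(0L, n_nodes)
  fold <- integer(n_nodes)
  with_seed(stream_seed(seed, "kfold"), {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity, specificity, precision, F-score and Matthews
#' correlation coefficient from 0/1 truth and prediction vectors, with
#' the confusion counts. Any 0/0 denominator yields 0 and the affected
#' metrics are listed in the `degenerate` field.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors (1 = interacting).
#' @return A list of class `metrics_report`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    gb_stop("gb_length_mismatch", "y_true and y_pred must match, length >= 1")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    gb_stop("gb_invalid_label", "labels must be 0 or 1")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  degenerate <- character(0)
  sdiv <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sens <- sdiv(tp, tp + fn, "sensitivity")
  spec <- sdiv(tn, tn + fp, "specificity")
  prec <- sdiv(tp, tp + fp, "precision")
  f1 <- sdiv(2 * prec * sens, prec + sens, "f_score")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- sdiv(tp * tn - fp * fn, mcc_den, "mcc")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f_score = f1, mcc = mcc,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("metrics: acc %.4f  sens %.4f  spec %.4f  prec %.4f  ",
           "F %.4f  MCC %.4f  (tp %d fp %d tn %d fn %d)\n"),
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f_score,
    x$mcc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided test with Welch-Satterthwaite degrees of freedom, used to
#' judge whether metric differences between method variants are
#' statistically significant.
#'
#' @param sample_a,sample_b Numeric vectors, each of size >= 2 with
#'   nonzero variance.
#' @return List with `t`, `df` and `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L ||
      stats::var(sample_a) == 0 || stats::var(sample_b) == 0) {
    gb_stop("gb_degenerate_sample",
            "both samples need size >= 2 and nonzero variance")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

# ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  zl <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else zl(p)
  }
  flat <- params[c("W_embed", "b_embed", "W_res", "b_res",
                   "W_cls", "b_cls", "layers")]
  list(m = walk(flat), v = walk(flat), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      out_m <- m
      out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p
        out_m[[nm]] <- r$m
        out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in c("W_embed", "b_embed", "W_res", "b_res", "W_cls", "b_cls",
               "layers")) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p
    state$m[[nm]] <- r$m
    state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# ---- Training loop ---------------------------------------------------

node_loss <- function(prob, y) -log(max(prob[y + 1L], 1e-12))

eval_loss <- function(params, X, subgraphs, idx, labels) {
  tot <- 0
  for (v in idx) {
    sub <- subgraphs[[v]]
    fw <- gbert_node_forward(params, X[sub$nodes, , drop = FALSE],
                             sub$wl, sub$pos, sub$hop)
    tot <- tot + node_loss(fw$prob, labels[v])
  }
  tot / length(idx)
}

#' Train the pair-node graph transformer
#'
#' Minimizes mean binary cross-entropy (two-class softmax form) over
#' mini-batches of linkless subgraphs with Adam. A stratified
#' `validation_fraction` of `train_idx` is held out for early stopping on
#' validation loss; the best-epoch weights are restored. Fully
#' reproducible for a fixed config seed. The intimacy matrix, WL codes
#' and subgraphs are precomputed once on the full graph (the model is
#' transductive: node features, not labels, of non-training nodes may
#' appear in training subgraphs).
#'
#' @param graph A `pair_graph`.
#' @param X Node feature matrix.
#' @param train_idx Integer node indices to train on (both classes
#'   required).
#' @param config A [train_config()].
#' @param verbose Print a line every 10 epochs.
#' @return Object of class `gbert_fit`: `params`, `history` (per-epoch
#'   train/validation loss), `best_epoch`, plus the precomputed `S`,
#'   `wl`, `subgraphs` for reuse in evaluation.
#' @export
train <- function(graph, X, train_idx, config = train_config(),
                  verbose = FALSE) {
  labels <- graph$nodes$label
  if (length(unique(labels[train_idx])) < 2L) {
    gb_stop("gb_single_class", "training nodes carry a single class")
  }
  S <- intimacy_matrix(graph$adjacency, config$alpha)
  wl <- wl_codes(graph$adjacency)
  subgraphs <- lapply(seq_len(graph$n), function(v) {
    sample_subgraph(graph, S, wl, v, config$k, max_hop = config$max_hop)
  })

  carve <- split_train_test(length(train_idx),
                            test_fraction = config$validation_fraction,
                            seed = stream_seed(config$seed, "val-carve"),
                            labels = labels[train_idx])
  fit_idx <- train_idx[carve$train]
  val_idx <- train_idx[carve$test]

  params <- init_model_params(
    d_in = ncol(X), d_h = config$d_h, k = config$k,
    n_layers = config$n_layers, heads = config$heads,
    hidden_dropout = config$hidden_dropout,
    attention_dropout = config$attention_dropout, alpha = config$alpha,
    max_hop = config$max_hop, pure_eq3 = config$pure_eq3,
    readout = config$readout, seed = config$seed)
  state <- adam_init(params)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L

  with_seed(stream_seed(config$seed, "sgd"), {
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample(fit_idx)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
      ep_loss <- 0
      for (batch in batches) {
        grads <- zero_grads(params)
        bl <- 0
        for (v in batch) {
          sub <- subgraphs[[v]]
          fw <- gbert_node_forward(params, X[sub$nodes, , drop = FALSE],
                                   sub$wl, sub$pos, sub$hop,
                                   train_mode = TRUE, keep_cache = TRUE)
          bl <- bl + node_loss(fw$prob, labels[v])
          grads <- gbert_node_backward(params, fw$cache, labels[v], grads)
        }
        grads <- rapply(grads, function(g) g / length(batch),
                        how = "replace")
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
        ep_loss <- ep_loss + bl
      }
      tr_loss <- ep_loss / length(fit_idx)
      va_loss <- eval_loss(params, X, subgraphs, val_idx, labels)
      history[epoch, ] <- list(epoch, tr_loss, va_loss)
      if (verbose && epoch %% 10L == 0L) {
        message(sprintf("epoch %3d  train %.4f  val %.4f",
                        epoch, tr_loss, va_loss))
      }
      if (va_loss < best_loss - 1e-8) {
        best_loss <- va_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  structure(list(params = best_params, history = history,
                 best_epoch = best_epoch, S = S, wl = wl,
                 subgraphs = subgraphs, config = config),
            class = "gbert_fit")
}

#' @export
print.gbert_fit <- function(x, ...) {
  cat(sprintf(
    "gbert_fit: %d epochs run, best epoch %d (val loss %.4f)\n",
    nrow(x$history), x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' Evaluate a fitted model on held-out nodes
#'
#' Predictions are the argmax of the eval-mode forward probabilities;
#' the report comes from [compute_metrics()].
#'
#' @param fit A `gbert_fit` (or bare `gbert_params`, in which case the
#'   intimacy matrix and WL codes are recomputed from the graph).
#' @param graph A `pair_graph`.
#' @param X Node feature matrix.
#' @param test_idx Non-empty integer node indices.
#' @return A `metrics_report` with the probability matrix attached as
#'   attribute `"probs"`.
#' @export
evaluate <- function(fit, graph, X, test_idx) {
  if (length(test_idx) == 0L) gb_stop("gb_config", "test_idx is empty")
  if (inherits(fit, "gbert_fit")) {
    probs <- model_forward(graph, X, fit$params, nodes = test_idx,
                           subgraphs = fit$subgraphs)
  } else {
    probs <- model_forward(graph, X, fit, nodes = test_idx)
  }
  pred <- as.integer(probs[, 2L] > probs[, 1L])
  rpt <- compute_metrics(graph$nodes$label[test_idx], pred)
  attr(rpt, "probs") <- probs
  rpt
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Trains and evaluates one model per fold; reports per-fold metrics and
#' their mean and standard deviation. The intimacy matrix and WL codes
#' are precomputed once on the full graph (transductive convention).
#'
#' @param graph A `pair_graph`.
#' @param X Node feature matrix.
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param verbose Passed to [train()].
#' @return List with `folds` (list of `metrics_report`), `mean`, `sd`.
#' @export
cross_validate <- function(graph, X, config = train_config(), k = 5L,
                           verbose = FALSE) {
  folds <- kfold_indices(graph$n, k = k, seed = config$seed,
                         labels = graph$nodes$label)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f_score", "mcc")
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config
    cfg$seed <- stream_seed(config$seed, paste0("fold", f))
    fit <- train(graph, X, folds[[f]]$train, cfg, verbose = verbose)
    reports[[f]] <- evaluate(fit, graph, X, folds[[f]]$test)
  }
  vals <- sapply(reports, function(r) unlist(r[metric_names]))
  list(folds = reports,
       mean = rowMeans(vals),
       sd = apply(vals, 1L, stats::sd))
}
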