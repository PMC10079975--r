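test_that("train/test split is stratified, complete and reproducible", {
  labels <- rep(c(0L, 1L), each = 50)
  sp <- split_train_test(100, 0.2, seed = 3, labels = labels)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(sp$test), 20L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(sp, split_train_test(100, 0.2, seed = 3, labels = labels))
  # per-side class ratio within one sample of 50%
  expect_lte(abs(sum(labels[sp$test] == 1) - 10), 1)
  expect_lte(abs(sum(labels[sp$train] == 1) - 40), 1)
  expect_error(split_train_test(3, 0.2, seed = 1, labels = c(0L, 1L, 1L)),
               class = "gb_degenerate_split")
})

test_that("k-fold indices partition the data with stratified folds", {
  labels <- rep(c(0L, 1L), each = 5L)
  folds <- kfold_indices(10, k = 5, seed = 2, labels = labels)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:10)
  expect_true(all(vapply(tests, length, 1L) == 2L))
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:10)
  }
  # 60/40 labels over 60 samples: per-fold ratio within one sample
  labels2 <- rep(c(1L, 0L), c(36L, 24L))
  folds2 <- kfold_indices(60, k = 5, seed = 7, labels = labels2)
  for (f in folds2) {
    expect_lte(abs(sum(labels2[f$test] == 1) - 0.6 * length(f$test)), 1)
  }
  expect_error(kfold_indices(4, k = 5, seed = 1),
               class = "gb_degenerate_split")
})

test_that("metrics match hand-evaluated formulas and conventions", {
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  for (m in c("accuracy", "sensitivity", "specificity", "precision",
              "f_score", "mcc")) {
    expect_equal(perfect[[m]], 1)
  }
  # tp=3 fn=2 tn=4 fp=1
  y_true <- c(rep(1, 5), rep(0, 5))
  y_pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  r <- compute_metrics(y_true, y_pred)
  expect_identical(c(r$tp, r$fn, r$tn, r$fp), c(3L, 2L, 4L, 1L))
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$sensitivity, 0.6)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$precision, 0.75)
  expect_equal(r$f_score, 2 / 3)
  expect_equal(r$mcc, 10 / sqrt(600))
  # all-one-class predictions: MCC 0 under the 0/0 convention
  r0 <- compute_metrics(y_true, rep(1, 10))
  expect_equal(r0$mcc, 0)
  expect_true("mcc" %in% r0$degenerate)
  expect_error(compute_metrics(c(0, 1), c(1)), class = "gb_length_mismatch")
  expect_error(compute_metrics(c(0, 2), c(1, 1)), class = "gb_invalid_label")
})

test_that("metrics agree with an independent confusion-matrix oracle", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    yt <- rbinom(n, 1, 0.5)
    yp <- rbinom(n, 1, 0.5)
    r <- compute_metrics(yt, yp)
    tp <- sum(yt & yp); tn <- sum(!yt & !yp)
    fp <- sum(!yt & yp); fn <- sum(yt & !yp)
    sdiv <- function(a, b) if (b == 0) 0 else a / b
    expect_equal(r$accuracy, (tp + tn) / n)
    expect_equal(r$sensitivity, sdiv(tp, tp + fn))
    expect_equal(r$specificity, sdiv(tn, tn + fp))
    expect_equal(r$precision, sdiv(tp, tp + fp))
    ff <- if (r$precision + r$sensitivity == 0) 0 else
      2 * r$precision * r$sensitivity / (r$precision + r$sensitivity)
    expect_equal(r$f_score, ff)
    den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    expect_equal(r$mcc, sdiv(tp * tn - fp * fn, den))
  }
})

test_that("MCC is class-swap invariant; sensitivity/specificity swap", {
  set.seed(11)
  yt <- rbinom(40, 1, 0.4)
  yp <- rbinom(40, 1, 0.6)
  a <- compute_metrics(yt, yp)
  b <- compute_metrics(1 - yt, 1 - yp)
  expect_equal(a$mcc, b$mcc)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
})

test_that("Welch's t-test follows the reference formulas", {
  a <- c(1, 2, 3, 4)
  r0 <- welch_t_test(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  r1 <- welch_t_test(a, a + 10)
  expect_gt(abs(r1$t), 10)
  expect_lt(r1$p_value, 0.001)
  # hand formula for the statistic and df
  b <- c(2, 4, 9, 3, 7)
  r2 <- welch_t_test(a, b)
  va <- var(a) / 4; vb <- var(b) / 5
  expect_equal(r2$t, (mean(a) - mean(b)) / sqrt(va + vb))
  expect_equal(r2$df, (va + vb)^2 / (va^2 / 3 + vb^2 / 4))
  # antisymmetry
  r3 <- welch_t_test(b, a)
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p_value, r2$p_value)
  expect_error(welch_t_test(c(1, 1), a), class = "gb_degenerate_sample")
})

test_that("training is reproducible and early stopping obeys patience", {
  w <- small_world(seed = 55L)
  sp <- split_train_test(w$graph$n, 0.2, seed = 5,
                         labels = w$graph$nodes$label)
  cfg <- train_config(max_epochs = 8L, patience = 3L, d_h = 16L,
                      batch_size = 32L, seed = 9L)
  f1 <- train(w$graph, w$X, sp$train, cfg)
  f2 <- train(w$graph, w$X, sp$train, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  m1 <- evaluate(f1, w$graph, w$X, sp$test)
  m2 <- evaluate(f2, w$graph, w$X, sp$test)
  expect_identical(unclass(m1)[1:10], unclass(m2)[1:10])
  expect_error(train(w$graph, w$X,
                     which(w$graph$nodes$label == 1L), cfg),
               class = "gb_single_class")
  # patience: stop within patience epochs of the best epoch
  cfg2 <- train_config(max_epochs = 40L, patience = 2L, d_h = 16L,
                       batch_size = 32L, seed = 9L)
  f3 <- train(w$graph, w$X, sp$train, cfg2)
  expect_lte(nrow(f3$history), f3$best_epoch + 2L)
})

test_that("train loss trends downward on separable synthetic data", {
  w <- small_world(seed = 56L)
  sp <- split_train_test(w$graph$n, 0.2, seed = 6,
                         labels = w$graph$nodes$label)
  cfg <- train_config(max_epochs = 15L, patience = 15L, d_h = 16L,
                      batch_size = 32L, seed = 4L)
  fit <- train(w$graph, w$X, sp$train, cfg)
  h <- fit$history$train_loss
  expect_lt(mean(h[11:15]), mean(h[1:5]))
})
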