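test_that("a zero-weight bias-free network outputs 0.5 everywhere (sigmoid of 0)", {
  model <- structure(list(w_hidden = matrix(0, 8, 8), b_hidden = rep(0, 8),
                          w_out = matrix(0, 8, 4), b_out = rep(0, 4),
                          n_out = 4, use_bias = FALSE,
                          normalisation = rep(1, 8),
                          encoding = gesture_encoding(4)),
                     class = "ann_model")
  q <- predict_ann(model, rep(0.3, 8))
  expect_equal(unname(q), rep(0.5, 4))
  expect_error(predict_ann(model, rep(0.3, 7)), "dimension")
})

test_that("E_MS matches hand-computed values and is order-invariant", {
  expect_equal(ems(matrix(0.5, 1, 4), matrix(0.5, 1, 4)), 0)
  # single trial, M = 4, q - u = (1, 0, 0, 0)
  expect_equal(ems(matrix(c(1, 0, 0, 0), 1), matrix(0, 1, 4)), 0.25)
  # uniform 0.5 outputs against one-hot targets: brute-force sum = 4 * 0.25 / 4
  u <- diag(4)
  q <- matrix(0.5, 4, 4)
  expect_equal(ems(q, u), sum((q - u)^2) / (4 * 4))
  expect_equal(ems(q, u), 0.25)
  p <- sample(4)
  expect_equal(ems(q[p, ], u[p, ]), ems(q, u))
  expect_error(ems(matrix(0, 0, 4), matrix(0, 0, 4)), "empty")
})

test_that("training is deterministic under a fixed seed", {
  pair <- fixture("clean1", function() clean_pair(301))
  ftr <- rms_windows(pair$train)
  fte <- rms_windows(pair$test)
  r1 <- train_ann(ftr, fte, seed = 3, max_epochs = 50, patience = 50)
  r2 <- train_ann(ftr, fte, seed = 3, max_epochs = 50, patience = 50)
  expect_identical(r1$report$train_error_curve, r2$report$train_error_curve)
  expect_identical(r1$model$w_hidden, r2$model$w_hidden)
})

test_that("a linearly separable two-gesture problem is driven to near-zero error", {
  # two disjoint activation patterns; the logistic-regression oracle
  # certifies separability on the same frames
  pair <- fixture("clean1", function() clean_pair(301))
  ftr <- rms_windows(pair$train)
  fte <- rms_windows(pair$test)
  keep_tr <- ftr$labels %in% c("G1", "G2")
  keep_te <- fte$labels %in% c("G1", "G2")
  f2tr <- subset_frames(ftr, keep_tr)
  f2te <- subset_frames(fte, keep_te)
  oracle <- suppressWarnings(
    glm(I(f2tr$labels == "G1") ~ f2tr$V, family = binomial))
  expect_true(mean((fitted(oracle) > 0.5) == (f2tr$labels == "G1")) == 1)
  enc <- gesture_encoding(4)[c("G1", "G2"), ]
  res <- train_ann(f2tr, f2te, encoding = enc, seed = 1,
                   max_epochs = 5000, patience = 5000)
  expect_lt(min(res$report$train_error_curve), 0.01)
})

test_that("trained network recognises held-out basic and compound gestures", {
  accs <- c()
  for (s in 1:2) {
    pair <- fixture(paste0("clean", s), function() clean_pair(300 + s))
    ftr <- rms_windows(pair$train)
    fte <- rms_windows(pair$test)
    res <- train_ann(ftr, fte, seed = s, max_epochs = 3000, patience = 100)
    g1 <- fte$V[fte$labels == "G1", , drop = FALSE]
    q1 <- predict_ann(res$model, g1)
    accs <- c(accs, mean(max.col(q1) == 1))
    # compound left-up: ql and qu are the two largest components
    g6 <- fte$V[fte$labels == "G6", , drop = FALSE]
    q6 <- predict_ann(res$model, g6)
    top2 <- t(apply(q6, 1, order, decreasing = TRUE))[, 1:2]
    expect_gt(mean(apply(top2, 1, function(r) setequal(r, c(1, 3)))), 0.8)
  }
  expect_gt(mean(accs), 0.95)
})

test_that("early stopping halts when the test error stops improving", {
  pair <- fixture("clean1", function() clean_pair(301))
  ftr <- rms_windows(pair$train)
  fte <- rms_windows(pair$test)
  res <- train_ann(ftr, fte, seed = 2, max_epochs = 5000, patience = 10)
  rep <- res$report
  if (rep$stopped_early) {
    expect_equal(rep$epochs_run, rep$best_epoch + 10)
    expect_equal(min(rep$test_error_curve), rep$best_test_error)
  }
  expect_equal(length(rep$train_error_curve), rep$epochs_run)
})

test_that("LDA separates well-separated Gaussian classes perfectly and rejects degenerate input", {
  set.seed(9)
  V <- rbind(matrix(rnorm(240, 0, 0.1), ncol = 8),
             matrix(rnorm(240, 5, 0.1), ncol = 8),
             matrix(rnorm(240, -5, 0.1), ncol = 8),
             matrix(rnorm(240, 10, 0.1), ncol = 8))
  fs <- structure(list(V = V, P = rowMeans(abs(V)),
                       frame_times = seq_len(nrow(V)) / 10,
                       labels = rep(basic_gestures(), each = 30),
                       window_samples = 200, step_samples = 100, rate = 1000),
                  class = "feature_stream")
  fit <- train_lda(fs)
  expect_equal(predict_lda(fit, fs), fs$labels)
  one_class <- subset_frames(fs, fs$labels == "G1")
  expect_error(train_lda(one_class), "two gesture classes")
})

test_that("gesture absent from the encoding raises a labelled error", {
  pair <- fixture("clean1", function() clean_pair(301))
  ftr <- rms_windows(pair$train)
  enc <- gesture_encoding(4)[c("G0", paste0("G", 1:7)), ]   # drop G8
  expect_error(train_ann(ftr, ftr, encoding = enc), "absent from encoding")
})
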