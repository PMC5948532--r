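.sigmoid <- function(u) 1 / (1 + exp(-u))

# forward pass on a [n x 8] normalised input matrix
.ann_forward <- function(model, X) {
  H <- .sigmoid(sweep(X %*% model$w_hidden, 2, model$b_hidden, "+"))
  Q <- .sigmoid(sweep(H %*% model$w_out, 2, model$b_out, "+"))
  list(H = H, Q = Q)
}

.ann_targets <- function(labels, encoding) {
  missing <- setdiff(unique(labels), rownames(encoding))
  if (length(missing)) {
    stop("gesture(s) present in features but absent from encoding: ",
         paste(missing, collapse = ", "))
  }
  encoding[labels, , drop = FALSE]
}

#' Train the gesture classification network
#'
#' A single-hidden-layer perceptron (8 inputs, 8 logistic hidden units,
#' `n_out` logistic outputs) trained by full-batch gradient descent
#' (backpropagation) on the squared output error. Training stops early
#' once the test-set error has not improved for `patience` epochs; the
#' returned model is the one with minimal test error.
#'
#' Inputs are normalised per channel by the maximal training RMS (a
#' per-subject calibration); the constants are stored in the model and
#' applied by [predict_ann()].
#'
#' @param features_train,features_test labelled `feature_stream`s.
#' @param encoding target encoding matrix, see [gesture_encoding()].
#' @param seed integer seed for weight initialisation.
#' @param n_hidden hidden-layer width (8).
#' @param learning_rate gradient-descent step (2; the squared-error/sigmoid
#'   gradients are small, so sub-unit rates under-converge within the epoch
#'   budget).
#' @param max_epochs maximum training epochs (5000).
#' @param patience early-stopping patience on the test-error minimum (50).
#' @param use_bias include bias terms (`TRUE`); `FALSE` reproduces the
#'   bias-free neuron equation literally.
#' @return List with `model` (class `ann_model`) and `report` (class
#'   `train_report`: `epochs_run`, `train_error_curve`,
#'   `test_error_curve`, `stopped_early`).
#' @export
train_ann <- function(features_train, features_test,
                      encoding = gesture_encoding(), seed = 1,
                      n_hidden = 8, learning_rate = 2,
                      max_epochs = 5000, patience = 50, use_bias = TRUE) {
  stopifnot(inherits(features_train, "feature_stream"),
            inherits(features_test, "feature_stream"),
            nrow(features_train$V) > 0, nrow(features_test$V) > 0,
            !is.null(features_train$labels), !is.null(features_test$labels))
  if (ncol(features_train$V) != 8) stop("feature dimension must be 8")
  set.seed(seed)
  norm <- apply(features_train$V, 2, max)
  norm[norm <= 0] <- 1
  Xtr <- sweep(features_train$V, 2, norm, "/")
  Xte <- sweep(features_test$V, 2, norm, "/")
  Utr <- .ann_targets(features_train$labels, encoding)
  Ute <- .ann_targets(features_test$labels, encoding)
  n_out <- ncol(encoding)
  n <- nrow(Xtr)
  model <- structure(list(
    w_hidden = matrix(stats::runif(8 * n_hidden, -0.5, 0.5), 8, n_hidden),
    b_hidden = if (use_bias) stats::runif(n_hidden, -0.5, 0.5) else rep(0, n_hidden),
    w_out = matrix(stats::runif(n_hidden * n_out, -0.5, 0.5), n_hidden, n_out),
    b_out = if (use_bias) stats::runif(n_out, -0.5, 0.5) else rep(0, n_out),
    n_out = n_out, use_bias = use_bias, normalisation = norm,
    encoding = encoding), class = "ann_model")
  train_curve <- test_curve <- numeric(max_epochs)
  best <- list(err = Inf, model = model, epoch = 0L)
  for (epoch in seq_len(max_epochs)) {
    fw <- .ann_forward(model, Xtr)
    err_out <- fw$Q - Utr                       # [n x n_out]
    train_curve[epoch] <- mean(err_out^2)
    # backprop of the mean squared error
    dQ <- 2 * err_out * fw$Q * (1 - fw$Q) / (n * n_out)
    gw_out <- t(fw$H) %*% dQ
    dH <- (dQ %*% t(model$w_out)) * fw$H * (1 - fw$H)
    gw_hidden <- t(Xtr) %*% dH
    model$w_out <- model$w_out - learning_rate * gw_out
    model$w_hidden <- model$w_hidden - learning_rate * gw_hidden
    if (use_bias) {
      model$b_out <- model$b_out - learning_rate * colSums(dQ)
      model$b_hidden <- model$b_hidden - learning_rate * colSums(dH)
    }
    test_curve[epoch] <- mean((.ann_forward(model, Xte)$Q - Ute)^2)
    if (test_curve[epoch] < best$err) {
      best <- list(err = test_curve[epoch], model = model, epoch = epoch)
    }
    if (epoch - best$epoch >= patience) break
  }
  epochs_run <- epoch
  report <- structure(list(epochs_run = epochs_run,
                           train_error_curve = train_curve[seq_len(epochs_run)],
                           test_error_curve = test_curve[seq_len(epochs_run)],
                           stopped_early = epochs_run < max_epochs,
                           best_epoch = best$epoch,
                           best_test_error = best$err),
                      class = "train_report")
  list(model = best$model, report = report)
}

#' Forward pass of the gesture network
#'
#' @param model an `ann_model` from [train_ann()].
#' @param V RMS feature vector of length 8, or a `[n x 8]` matrix /
#'   `feature_stream`.
#' @return Output matrix `[n x n_out]` with components in (0, 1); a
#'   single vector input returns a named numeric vector.
#' @export
predict_ann <- function(model, V) {
  stopifnot(inherits(model, "ann_model"))
  single <- FALSE
  if (inherits(V, "feature_stream")) V <- V$V
  if (is.null(dim(V))) {
    single <- TRUE
    V <- matrix(V, nrow = 1)
  }
  if (ncol(V) != 8) stop("feature dimension must be 8")
  X <- sweep(V, 2, model$normalisation, "/")
  Q <- .ann_forward(model, X)$Q
  colnames(Q) <- colnames(model$encoding)
  if (single) Q[1, ] else Q
}

#' Hard gesture label from network outputs
#'
#' @param model an `ann_model`.
#' @param V features as in [predict_ann()].
#' @param gestures candidate gestures (default the basic four).
#' @return Character vector of gesture ids (argmax over the candidate
#'   gestures' encoded outputs).
#' @export
classify_ann <- function(model, V, gestures = basic_gestures()) {
  Q <- predict_ann(model, V)
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1, dimnames = list(NULL, names(Q)))
  enc <- model$encoding[gestures, , drop = FALSE]
  # nearest encoded target in squared error
  d <- sapply(gestures, function(g) rowSums(sweep(Q, 2, enc[g, ], "-")^2))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, gestures))
  gestures[apply(d, 1, which.min)]
}

#' Mean squared output error of the classifier
#'
#' `E_MS = (1 / (N * M)) * sum ||q_n - u_n||^2` over N trials and M output
#' neurons.
#'
#' @param outputs `[N x M]` matrix (or list) of network outputs.
#' @param targets `[N x M]` matrix (or list) of target vectors.
#' @return Scalar error.
#' @export
ems <- function(outputs, targets) {
  if (is.list(outputs)) outputs <- do.call(rbind, outputs)
  if (is.list(targets)) targets <- do.call(rbind, targets)
  if (length(outputs) == 0 || length(targets) == 0) stop("empty inputs")
  stopifnot(all(dim(outputs) == dim(targets)))
  mean((outputs - targets)^2)
}

#' Evaluate E_MS of a trained network on a labelled feature stream
#'
#' @param model an `ann_model`.
#' @param features labelled `feature_stream`.
#' @return Scalar E_MS against the model's own target encoding.
#' @export
ems_ann <- function(model, features) {
  stopifnot(inherits(features, "feature_stream"), !is.null(features$labels))
  U <- .ann_targets(features$labels, model$encoding)
  ems(predict_ann(model, features), U)
}

#' Linear-discriminant baseline classifier
#'
#' Standard LDA on RMS feature vectors, restricted to the basic gestures
#' G1-G4 (hard labels out).
#'
#' @param features_train labelled `feature_stream`.
#' @param gestures classes to fit (default G1-G4).
#' @return An `lda_model` wrapping [MASS::lda()].
#' @export
train_lda <- function(features_train, gestures = basic_gestures()) {
  stopifnot(inherits(features_train, "feature_stream"),
            !is.null(features_train$labels))
  idx <- features_train$labels %in% gestures
  X <- features_train$V[idx, , drop = FALSE]
  y <- factor(features_train$labels[idx], levels = gestures)
  present <- table(y)
  if (sum(present > 0) < 2) stop("need at least two gesture classes")
  if (any(present[present > 0] <= ncol(X))) {
    stop("too few frames per class for a stable pooled covariance")
  }
  fit <- tryCatch(MASS::lda(X, grouping = droplevels(y)),
                  error = function(e) {
                    stop("singular pooled covariance; add frames or jitter ",
                         "the features (regularisation): ", conditionMessage(e))
                  })
  structure(list(fit = fit, gestures = gestures), class = "lda_model")
}

#' @rdname train_lda
#' @param model an `lda_model`.
#' @param V feature vector, matrix or `feature_stream`.
#' @return `predict_lda()` returns the character vector of gesture ids.
#' @export
predict_lda <- function(model, V) {
  stopifnot(inherits(model, "lda_model"))
  if (inherits(V, "feature_stream")) V <- V$V
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  as.character(stats::predict(model$fit, V)$class)
}
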