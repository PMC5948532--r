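#' Per-gesture confusion counts from hard labels
#'
#' @param predicted,truth character vectors of gesture ids.
#' @param gestures gestures to tabulate (default those present in `truth`).
#' @return data.frame with columns `gesture`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth, gestures = sort(unique(truth))) {
  stopifnot(length(predicted) == length(truth))
  do.call(rbind, lapply(gestures, function(g) {
    data.frame(gesture = g,
               tp = sum(predicted == g & truth == g),
               fp = sum(predicted == g & truth != g),
               fn = sum(predicted != g & truth == g))
  }))
}

#' Precision, recall and F-measure per gesture and pooled
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`. A gesture with
#' `TP+FP = 0` or `TP+FN = 0` has an undefined measure and is reported as
#' `NA`, not 0. (When a classifier is only ever shown known gestures,
#' `FN = 0` and recall is identically 1.) The pooled row is the macro
#' average (mean of the per-gesture F values).
#'
#' @param counts data.frame from [confusion_counts()].
#' @return data.frame with columns `gesture`, `precision`, `recall`,
#'   `f`; the last row (`gesture = "pooled"`) holds macro averages.
#' @export
f_measure <- function(counts) {
  stopifnot(all(c("gesture", "tp", "fp", "fn") %in% names(counts)),
            all(counts$tp >= 0), all(counts$fp >= 0), all(counts$fn >= 0))
  P <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), NA_real_)
  R <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), NA_real_)
  f <- ifelse(!is.na(P) & !is.na(R) & (P + R) > 0, 2 * P * R / (P + R), NA_real_)
  out <- data.frame(gesture = counts$gesture, precision = P, recall = R, f = f)
  rbind(out, data.frame(gesture = "pooled",
                        precision = mean(P, na.rm = TRUE),
                        recall = mean(R, na.rm = TRUE),
                        f = mean(f, na.rm = TRUE)))
}

#' Log-median normalised performance index
#'
#' `Re_i = ln(E_MS_i / median(E_MS))`: the per-subject classifier error on
#' a log scale relative to the cohort median, which brings the skewed
#' error distribution close to Gaussian so parametric statistics apply.
#'
#' @param ems_values positive per-subject mean squared errors (>= 2).
#' @return Numeric vector of the same length; its median is 0 up to ties.
#' @export
performance_index <- function(ems_values) {
  if (length(ems_values) < 2) stop("need at least two subjects")
  if (any(!is.finite(ems_values)) || any(ems_values <= 0)) {
    stop("all E_MS values must be positive and finite")
  }
  log(ems_values / stats::median(ems_values))
}

#' Ordinary least-squares regression of a response on one latent factor
#'
#' @param x per-subject factor values (not constant, n >= 3).
#' @param y per-subject response.
#' @return List with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `p_value` (two-sided test of zero slope), `n`, and the underlying
#'   [stats::lm()] `fit`.
#' @export
factor_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least three subjects")
  if (stats::sd(x) == 0) stop("factor values are constant; slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       slope_se = unname(cf["x", "Std. Error"]),
       intercept_se = unname(cf["(Intercept)", "Std. Error"]),
       p_value = unname(cf["x", "Pr(>|t|)"]),
       n = length(x),
       fit = fit)
}
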