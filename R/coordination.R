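#' Calibration protocol for the muscle-localisation analysis
#'
#' Repeated blocks of the four basic gestures (about one minute of
#' recording with the defaults), giving the decomposition enough
#' independent within-gesture variation to resolve the five muscle
#' sources.
#'
#' @param reps repetitions of each basic gesture (6).
#' @param gesture_s seconds per gesture segment (2).
#' @param rest_s rest gap between segments, seconds (0.5).
#' @return A [gesture_sequence()] data.frame.
#' @export
coordination_sequence <- function(reps = 6, gesture_s = 2, rest_s = 0.5) {
  standard_sequence(rep(basic_gestures(), reps),
                    gesture_s = gesture_s, rest_s = rest_s)
}

#' ICA decomposition of the RMS envelope matrix into muscle sources
#'
#' Models the windowed RMS vectors as a linear mixture of a few muscle
#' sources, `V(t) = sum_k W_k s_k(t)`, and estimates loadings and
#' activations by FastICA (deflation with whitening). Because temporal
#' filtering leaves the mixing matrix of a linear model unchanged, the
#' unmixing is by default estimated on the first-differenced frames
#' ("innovations"), where the gesture on/off structure that all muscles
#' share cancels out and the independent within-gesture fluctuations
#' dominate; the resulting unmixing is then applied to the full centred
#' RMS matrix. Components are ordered by the variance they account for
#' in the RMS matrix; each loading's sign is fixed so its peak entry is
#' positive; a source is localised to the electrode where its loading
#' peaks.
#'
#' @param features a `feature_stream` with 8 channels.
#' @param m number of sources to extract (default 5); `NULL` selects
#'   automatically, retaining components that each account for at least
#'   `min_vaf` of the RMS variance and have a unique peak electrode.
#' @param seed integer seed for the random initial rotation (restarted
#'   with derived seeds on non-convergence).
#' @param min_vaf variance fraction for automatic retention (0.05).
#' @param innovations estimate the unmixing on differenced frames
#'   (default `TRUE`); `FALSE` runs ICA on the raw RMS matrix.
#' @param maxit,tol FastICA iteration controls.
#' @return Object of class `ica_result`: `loadings` (`[channels x m]`),
#'   `activations` (`[frames x m]`), `m`, `localization` (peak channel per
#'   source), `vaf` (variance fraction per source), `center`.
#' @export
decompose_sources <- function(features, m = 5, seed = 1, min_vaf = 0.05,
                              innovations = TRUE, maxit = 400, tol = 1e-6) {
  stopifnot(inherits(features, "feature_stream"))
  X <- features$V
  K <- ncol(X)
  if (K != 8) stop("expected 8 channels")
  auto <- is.null(m)
  nc <- if (auto) K else m
  if (nrow(X) < 10 * nc) stop("too few frames for a stable decomposition")
  Y <- if (innovations) diff(X) else X
  fit <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    R0 <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
    fit <- tryCatch(
      ica::icafast(Y, nc = nc, alg = "def", fun = "logcosh",
                   maxit = maxit, tol = tol, Rmat = R0),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("ICA failed to converge after 5 restarts; try another seed or more frames")
  }
  A <- matrix(fit$M, ncol = nc)    # [channels x nc] mixing (loadings)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  # activations of the undifferenced data under the estimated mixing
  S <- Xc %*% t(MASS::ginv(A))
  # variance of the RMS matrix accounted for by each component
  total_var <- sum(Xc^2)
  vaf <- vapply(seq_len(ncol(A)),
                function(k) sum((S[, k] %*% t(A[, k]))^2) / total_var,
                numeric(1))
  ord <- order(vaf, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  vaf <- vaf[ord]
  peaks <- integer(ncol(A))
  for (k in seq_len(ncol(A))) {
    peaks[k] <- which.max(abs(A[, k]))
    if (A[peaks[k], k] < 0) {
      A[, k] <- -A[, k]
      S[, k] <- -S[, k]
    }
  }
  keep <- seq_len(ncol(A))
  if (auto) {
    keep <- which(vaf >= min_vaf)
    # among retained components sharing a peak electrode, keep the strongest
    keep <- keep[!duplicated(peaks[keep])]
  }
  rownames(A) <- colnames(X)
  structure(list(loadings = A[, keep, drop = FALSE],
                 activations = S[, keep, drop = FALSE],
                 m = length(keep),
                 localization = peaks[keep],
                 vaf = vaf[keep],
                 center = center),
            class = "ica_result")
}

#' Reconstruct the RMS matrix from an ICA decomposition
#'
#' @param ica an `ica_result`.
#' @return `[frames x channels]` matrix `S %*% t(W) + center`.
#' @export
reconstruct_rms <- function(ica) {
  stopifnot(inherits(ica, "ica_result"))
  sweep(ica$activations %*% t(ica$loadings), 2, ica$center, "+")
}

#' Mean RMS vector per gesture
#'
#' With `rest_correct = TRUE` the sensor-noise floor, measured from the
#' rest-state (`G0`) frames, is subtracted in power before averaging:
#' `Vbar_g = sqrt(max(mean(V_g^2) - mean(V_rest^2), 0.1 * floor))` per
#' channel. Because the expected squared RMS is (signal power) + (noise
#' power), this removes the additive noise-floor bias that would
#' otherwise compress synergist/antagonist ratios for low-amplitude
#' (high body-fat) recordings; the corrected power is clipped at 10% of
#' the floor since activity below that is unmeasurable.
#'
#' @param features a labelled `feature_stream`.
#' @param gestures gestures to average (default the basic four, all of
#'   which must be present).
#' @param rest_correct subtract the rest-state noise power (default
#'   `FALSE`; requires `G0` frames).
#' @return `[gesture x channels]` matrix of mean RMS values.
#' @export
mean_rms_per_gesture <- function(features, gestures = basic_gestures(),
                                 rest_correct = FALSE) {
  stopifnot(inherits(features, "feature_stream"), !is.null(features$labels))
  missing <- setdiff(gestures, unique(features$labels))
  if (length(missing)) {
    stop("gesture(s) missing from the feature stream: ",
         paste(missing, collapse = ", "))
  }
  floor_pow <- 0
  if (rest_correct) {
    if (!any(features$labels == "G0")) {
      stop("rest correction requires rest-state (G0) frames")
    }
    floor_pow <- colMeans(features$V[features$labels == "G0", , drop = FALSE]^2)
  }
  vbar <- t(vapply(gestures, function(g) {
    pow <- colMeans(features$V[features$labels == g, , drop = FALSE]^2)
    sqrt(pmax(pow - floor_pow, 0.1 * floor_pow))
  }, numeric(ncol(features$V))))
  rownames(vbar) <- gestures
  vbar
}

#' Synergist-antagonist coefficient (SAC)
#'
#' For each basic gesture the synergist sum `S_k` and antagonist sum `A_k`
#' are formed from the mean RMS at the reference electrodes 2, 4, 6 and 8
#' (see [sac_channel_table()]); the coefficient is
#' `SAC = ln(mean_k S_k / A_k)`. SAC = 0 means synergists and antagonists
#' are equally activated; SAC > 0 indicates prevalence of synergist
#' contraction. Because each ratio cancels any global amplitude gain, SAC
#' is insensitive to signal attenuation (e.g. by body fat).
#'
#' @param vbar `[gesture x 8]` matrix from [mean_rms_per_gesture()]
#'   containing rows G1-G4.
#' @return Object of class `sac_report`: per-gesture `synergist`,
#'   `antagonist`, `ratio`, and the scalar `sac`.
#' @export
sac <- function(vbar) {
  stopifnot(is.matrix(vbar), ncol(vbar) == 8,
            all(basic_gestures() %in% rownames(vbar)))
  tab <- sac_channel_table()
  gestures <- basic_gestures()
  syn <- ant <- numeric(length(gestures))
  names(syn) <- names(ant) <- gestures
  for (g in gestures) {
    syn[g] <- sum(vbar[g, tab[[g]]$synergist])
    ant[g] <- sum(vbar[g, tab[[g]]$antagonist])
  }
  if (any(ant <= 0)) stop("antagonist sum is zero: SAC ratio undefined")
  ratio <- syn / ant
  structure(list(synergist = syn, antagonist = ant, ratio = ratio,
                 sac = log(mean(ratio))),
            class = "sac_report")
}

#' @export
print.sac_report <- function(x, ...) {
  cat("<sac_report>\n")
  print(data.frame(gesture = names(x$ratio), synergist = x$synergist,
                   antagonist = x$antagonist, ratio = x$ratio,
                   row.names = NULL))
  cat(sprintf("SAC = %.4f\n", x$sac))
  invisible(x)
}
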