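#' Write / read an sEMG recording as CSV plus a JSON manifest
#'
#' The CSV holds columns `time_s, ch1..chK, gesture_label`; the sidecar
#' manifest (`<path>.json`) records the sampling rate, subject profile
#' and seed.
#'
#' @param rec an `emg_recording`.
#' @param path CSV file path.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns an `emg_recording` (without the
#'   generating model/envelopes).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(time_s = seq_len(nrow(rec$samples)) / rec$rate,
                   rec$samples, gesture_label = rec$labels)
  names(df) <- c("time_s", paste0("ch", seq_len(ncol(rec$samples))), "gesture_label")
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(rate = rec$rate, seed = rec$seed,
                   profile = unclass(rec$profile)[c("co_activation", "attenuation",
                                                    "bf_index", "reaction_delay",
                                                    "angular_noise_sd")])
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  chans <- grep("^ch[0-9]+$", names(df), value = TRUE)
  manifest_path <- paste0(path, ".json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(rate = 1 / stats::median(diff(df$time_s)))
  structure(list(samples = as.matrix(df[chans]),
                 rate = manifest$rate,
                 labels = df$gesture_label,
                 envelopes = NULL, model = NULL, profile = NULL,
                 seed = manifest$seed),
            class = "emg_recording")
}

#' Write / read a feature stream as CSV
#'
#' Columns: `frame_time, V1..VK, P, label`.
#'
#' @param fs a `feature_stream`.
#' @param path CSV file path.
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "feature_stream"))
  df <- data.frame(frame_time = fs$frame_times, fs$V, P = fs$P,
                   label = if (is.null(fs$labels)) NA else fs$labels)
  names(df) <- c("frame_time", paste0("V", seq_len(ncol(fs$V))), "P", "label")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a game trace as CSV
#'
#' Columns: `time_s, px, py, cx, cy, ql, qr, qu, qd`; the score and seed
#' travel in a sidecar JSON (`<path>.json`), like the recording manifest.
#'
#' @param trace a `game_trace`.
#' @param path CSV file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "game_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(list(score = game_score(trace), seed = attr(trace, "seed")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  manifest_path <- paste0(path, ".json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    attr(df, "score") <- manifest$score
    attr(df, "seed") <- manifest$seed
  }
  class(df) <- c("game_trace", class(df))
  df
}

#' Serialize a trained gesture network to JSON
#'
#' Stores weights, biases, the target encoding, the per-channel
#' normalisation constants and, optionally, a proportional-control
#' calibration, so a trained interface can be reloaded elsewhere.
#'
#' @param model an `ann_model` from [train_ann()].
#' @param path JSON file path.
#' @param control optional `control_state` from [calibrate_control()].
#' @return `path`, invisibly; `read_ann()` returns the `ann_model` (with
#'   a `control` attribute when one was stored).
#' @export
write_ann <- function(model, path, control = NULL) {
  stopifnot(inherits(model, "ann_model"))
  payload <- list(w_hidden = model$w_hidden, b_hidden = model$b_hidden,
                  w_out = model$w_out, b_out = model$b_out,
                  n_out = model$n_out, use_bias = model$use_bias,
                  normalisation = model$normalisation,
                  encoding = model$encoding,
                  encoding_gestures = rownames(model$encoding),
                  encoding_outputs = colnames(model$encoding))
  if (!is.null(control)) {
    stopifnot(inherits(control, "control_state"))
    payload$control <- unclass(control)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- as.matrix(p$encoding)
  dimnames(enc) <- list(p$encoding_gestures, p$encoding_outputs)
  model <- structure(list(w_hidden = as.matrix(p$w_hidden),
                          b_hidden = p$b_hidden,
                          w_out = as.matrix(p$w_out), b_out = p$b_out,
                          n_out = p$n_out, use_bias = p$use_bias,
                          normalisation = p$normalisation,
                          encoding = enc),
                     class = "ann_model")
  if (!is.null(p$control)) {
    attr(model, "control") <- structure(p$control, class = "control_state")
  }
  model
}

#' Serialize coordination results to JSON
#'
#' @param x an `ica_result` or `sac_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_coordination <- function(x, path) {
  payload <- if (inherits(x, "ica_result")) {
    list(type = "ica_result", loadings = x$loadings,
         localization = x$localization, vaf = x$vaf, m = x$m,
         center = x$center)
  } else if (inherits(x, "sac_report")) {
    list(type = "sac_report", synergist = as.list(x$synergist),
         antagonist = as.list(x$antagonist), ratio = as.list(x$ratio),
         sac = x$sac)
  } else {
    stop("expected an ica_result or sac_report")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
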