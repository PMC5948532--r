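#' Forward model of forearm muscles under a circular 8-electrode bracelet
#'
#' Five spatially localised muscle sources are mixed linearly onto eight
#' equally spaced electrodes. The default geometry places the dominant
#' electrode of each source at channels 2, 4, 5, 6 and 8 (1-based),
#' corresponding to flexor carpi radialis (FR, ch 2), extensor carpi
#' radialis longus (ER, ch 4), extensor digitorum (ED, ch 5), extensor
#' carpi ulnaris (EU, ch 6) and flexor carpi ulnaris (FU, ch 8).
#'
#' @param n_channels number of electrodes (8).
#' @param peak_channels dominant electrode of each source, one per source.
#' @param peak_gain loading at the dominant electrode.
#' @param neighbour_gain loading at the two circularly adjacent electrodes.
#' @param far_gain loading elsewhere (volume-conduction floor).
#' @param activation_templates optional `[gesture x source]` matrix of mean
#'   activation levels in `[0, 1]`; default [default_activation_templates()].
#' @return An object of class `muscle_model` with fields `loadings`
#'   (`[channels x sources]`), `peak_channels`, `source_names` and
#'   `activation_templates`.
#' @export
muscle_model <- function(n_channels = 8,
                         peak_channels = c(FR = 2, ER = 4, ED = 5, EU = 6, FU = 8),
                         peak_gain = 1,
                         neighbour_gain = 0.25,
                         far_gain = 0.05,
                         activation_templates = NULL) {
  stopifnot(n_channels >= 1, all(peak_channels >= 1),
            all(peak_channels <= n_channels),
            peak_gain > neighbour_gain, neighbour_gain >= far_gain,
            far_gain >= 0)
  m <- length(peak_channels)
  src <- names(peak_channels)
  if (is.null(src)) src <- paste0("S", seq_len(m))
  W <- matrix(far_gain, nrow = n_channels, ncol = m,
              dimnames = list(paste0("ch", seq_len(n_channels)), src))
  for (k in seq_len(m)) {
    p <- peak_channels[k]
    W[p, k] <- peak_gain
    # circular neighbours on the bracelet
    W[(p %% n_channels) + 1, k] <- neighbour_gain
    W[((p - 2) %% n_channels) + 1, k] <- neighbour_gain
  }
  if (is.null(activation_templates)) {
    activation_templates <- default_activation_templates(src)
  }
  stopifnot(identical(colnames(activation_templates), src),
            all(activation_templates >= 0), all(activation_templates <= 1),
            all(activation_templates["G0", ] == 0))
  structure(list(loadings = W,
                 peak_channels = peak_channels,
                 source_names = src,
                 n_channels = n_channels,
                 n_sources = m,
                 activation_templates = activation_templates),
            class = "muscle_model")
}

#' Default per-gesture synergist activation templates
#'
#' Rows are gestures, columns muscle sources; entries are mean activation
#' levels in `[0, 1]` *before* antagonist co-activation is added. For the
#' four basic gestures the synergist pairs follow wrist biomechanics:
#' flexion (G1) drives FR+FU, extension (G2) drives ER+EU (with strong
#' extensor digitorum involvement), radial deviation (G3) drives FR+ER and
#' ulnar deviation (G4) drives EU+FU. Compound gestures take the scaled sum
#' (factor 1/sqrt(2)) of their parents so that total power stays comparable.
#' Rest is silent.
#'
#' @param source_names names of the five sources.
#' @return `[9 x 5]` numeric matrix.
#' @export
default_activation_templates <- function(source_names = c("FR", "ER", "ED", "EU", "FU")) {
  stopifnot(length(source_names) == 5)
  tpl <- matrix(0, nrow = 9, ncol = 5,
                dimnames = list(gesture_ids(), source_names))
  #              FR   ER   ED   EU   FU
  tpl["G1", ] <- c(1.0, 0.0, 0.1, 0.0, 1.0)
  tpl["G2", ] <- c(0.0, 1.0, 0.9, 1.0, 0.0)
  tpl["G3", ] <- c(1.0, 1.0, 0.5, 0.0, 0.0)
  tpl["G4", ] <- c(0.0, 0.0, 0.5, 1.0, 1.0)
  for (g in compound_gestures()) {
    p <- .compound_parents[[g]]
    tpl[g, ] <- pmin(1, (tpl[p[1], ] + tpl[p[2], ]) / sqrt(2))
  }
  tpl
}

#' Synergist and antagonist electrode indices per basic gesture
#'
#' The coordination coefficient references raw electrode activity at
#' channels 2, 4, 6 and 8 (FR, ER, EU, FU). For each basic gesture two of
#' these muscles act as synergists and the other two as antagonists.
#'
#' @return Named list with `synergist` and `antagonist` channel index
#'   vectors for gestures G1-G4.
#' @export
sac_channel_table <- function() {
  list(
    G1 = list(synergist = c(2, 8), antagonist = c(4, 6)),
    G2 = list(synergist = c(4, 6), antagonist = c(2, 8)),
    G3 = list(synergist = c(2, 4), antagonist = c(6, 8)),
    G4 = list(synergist = c(6, 8), antagonist = c(2, 4))
  )
}

#' Per-gesture source activation for a subject
#'
#' Adds antagonist co-activation to the synergist template: for each basic
#' gesture the antagonist pair (per [sac_channel_table()]) is driven at
#' `co_activation` times the synergist level; compound gestures combine
#' their parents with the 1/sqrt(2) scaling.
#'
#' @param model a [muscle_model()].
#' @param co_activation antagonist activation as a fraction of synergist
#'   activation, in `[0, 1)`.
#' @return `[gesture x source]` activation matrix.
#' @export
subject_activation <- function(model, co_activation) {
  stopifnot(inherits(model, "muscle_model"),
            co_activation >= 0, co_activation < 1)
  tpl <- model$activation_templates
  act <- tpl
  tab <- sac_channel_table()
  for (g in basic_gestures()) {
    syn_src <- which(model$peak_channels %in% tab[[g]]$synergist)
    ant_src <- which(model$peak_channels %in% tab[[g]]$antagonist)
    level <- max(tpl[g, syn_src])
    act[g, ant_src] <- pmin(1, act[g, ant_src] + co_activation * level)
  }
  for (g in compound_gestures()) {
    p <- .compound_parents[[g]]
    act[g, ] <- pmin(1, (act[p[1], ] + act[p[2], ]) / sqrt(2))
  }
  act
}

#' Subject profile of latent factors
#'
#' Bundles the per-subject latent factors of the analysis: antagonist
#' co-activation (drives the synergist-antagonist coefficient down),
#' amplitude attenuation emulating subcutaneous fat (drives the
#' signal-to-noise ratio down at fixed sensor noise), and the pursuit-game
#' user policy (reaction delay, angular noise, per-gesture articulation
#' error rates).
#'
#' @param co_activation fraction in `[0, 1)`.
#' @param attenuation multiplicative signal gain in `(0, 1]`.
#' @param reaction_delay seconds.
#' @param angular_noise_sd radians.
#' @param per_gesture_error_rate named numeric vector of substitution
#'   probabilities; names are gesture ids `G1..G8` or the aliases
#'   `"left"`, `"right"`, `"up"`, `"down"`. Missing gestures default to 0.
#' @return Object of class `subject_profile`; `bf_index` (percent body
#'   fat) is derived from the attenuation by the fixed monotone map
#'   `4 - (36 / ln 10) * ln(attenuation)`: tissue attenuates bioelectric
#'   amplitude roughly exponentially with fat thickness, so body fat is
#'   linear in log-attenuation (attenuation 1 maps to 4%, 0.1 to 40%).
#' @export
subject_profile <- function(co_activation = 0.2,
                            attenuation = 1,
                            reaction_delay = 0.2,
                            angular_noise_sd = 0.2,
                            per_gesture_error_rate = NULL) {
  stopifnot(co_activation >= 0, co_activation < 1,
            attenuation > 0, attenuation <= 1,
            reaction_delay >= 0, angular_noise_sd >= 0)
  err <- stats::setNames(rep(0, 8), paste0("G", 1:8))
  if (!is.null(per_gesture_error_rate)) {
    nm <- names(per_gesture_error_rate)
    stopifnot(!is.null(nm))
    alias <- c(left = "G1", right = "G2", up = "G3", down = "G4")
    nm <- ifelse(nm %in% names(alias), alias[nm], nm)
    stopifnot(all(nm %in% names(err)),
              all(per_gesture_error_rate >= 0),
              all(per_gesture_error_rate <= 1))
    err[nm] <- unname(per_gesture_error_rate)
  }
  structure(list(co_activation = co_activation,
                 attenuation = attenuation,
                 bf_index = 4 - 36 / log(10) * log(attenuation),
                 reaction_delay = reaction_delay,
                 angular_noise_sd = angular_noise_sd,
                 per_gesture_error_rate = err),
            class = "subject_profile")
}
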