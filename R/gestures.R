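#' Gesture vocabulary
#'
#' The interface uses a rest state `G0`, four basic wrist gestures and four
#' compound (diagonal) gestures:
#'
#' * `G1` wrist flexion ("left"), `G2` wrist extension ("right"),
#'   `G3` radial deviation ("up"), `G4` ulnar deviation ("down");
#' * `G5` = G2+G3 (right-up), `G6` = G1+G3 (left-up),
#'   `G7` = G1+G4 (left-down), `G8` = G2+G4 (right-down).
#'
#' @return Character vector of the nine gesture identifiers.
#' @export
gesture_ids <- function() c("G0", paste0("G", 1:8))

#' @rdname gesture_ids
#' @export
basic_gestures <- function() paste0("G", 1:4)

#' @rdname gesture_ids
#' @export
compound_gestures <- function() paste0("G", 5:8)

# parents of each compound gesture
.compound_parents <- list(
  G5 = c("G2", "G3"),
  G6 = c("G1", "G3"),
  G7 = c("G1", "G4"),
  G8 = c("G2", "G4")
)

# direction names for the four basic gestures
.gesture_direction <- c(G1 = "left", G2 = "right", G3 = "up", G4 = "down")

#' Direction unit vector of a gesture on the screen
#'
#' Basic gestures map to the four axis directions, compound gestures to the
#' diagonals (unit length). Rest maps to the zero vector.
#'
#' @param gesture gesture id, e.g. `"G1"`.
#' @return Numeric length-2 vector (x rightward, y upward).
#' @export
gesture_direction <- function(gesture) {
  stopifnot(gesture %in% gesture_ids())
  if (gesture == "G0") return(c(0, 0))
  ax <- c(G1 = -1, G2 = 1, G3 = 0, G4 = 0)
  ay <- c(G1 = 0, G2 = 0, G3 = 1, G4 = -1)
  if (gesture %in% basic_gestures()) {
    return(c(ax[[gesture]], ay[[gesture]]))
  }
  p <- .compound_parents[[gesture]]
  v <- c(ax[[p[1]]] + ax[[p[2]]], ay[[p[1]]] + ay[[p[2]]])
  v / sqrt(sum(v^2))
}

#' Target encoding of gestures for the directional classifier
#'
#' Each basic gesture is one-hot over the four directional outputs
#' (ql, qr, qu, qd); a compound gesture sets the two parent entries to 1/2;
#' rest is all-zero. With `n_out = 7` three further outputs (fist, palm,
#' rest) are appended: fist/palm are one-hot in their own slots and the rest
#' class activates the seventh output.
#'
#' @param n_out number of output neurons, 4 (default) or 7.
#' @return Matrix `[gesture x n_out]` with row names `G0..G8` (plus
#'   `G9`/`G10` in the 7-output mode) and column names
#'   `c("ql","qr","qu","qd", ...)`.
#' @export
gesture_encoding <- function(n_out = 4) {
  stopifnot(n_out %in% c(4, 7))
  dir_cols <- c("ql", "qr", "qu", "qd")
  enc <- matrix(0, nrow = 9, ncol = 4, dimnames = list(gesture_ids(), dir_cols))
  enc["G1", "ql"] <- 1
  enc["G2", "qr"] <- 1
  enc["G3", "qu"] <- 1
  enc["G4", "qd"] <- 1
  for (g in compound_gestures()) {
    for (p in .compound_parents[[g]]) {
      enc[g, ] <- enc[g, ] + enc[p, ] / 2
    }
  }
  if (n_out == 7) {
    extra <- matrix(0, nrow = nrow(enc), ncol = 3,
                    dimnames = list(rownames(enc), c("qfist", "qpalm", "qrest")))
    enc <- cbind(enc, extra)
    enc <- rbind(enc,
                 G9 = c(rep(0, 4), 1, 0, 0),
                 G10 = c(rep(0, 4), 0, 1, 0))
    enc["G0", "qrest"] <- 1
  }
  enc
}
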