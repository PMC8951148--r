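#' Per-lead electrogram correlation
#'
#' Pearson correlation between a measured and a reconstructed electrogram
#' across time, the standard per-electrode accuracy score for ECGi
#' reconstructions. Invariant to positive scaling and offset of either
#' series; negating one series negates the result. If either series is
#' constant the correlation is undefined and `NA` is returned (callers
#' exclude such leads from medians).
#'
#' @param measured,reconstructed Equal-length numeric vectors (>= 2 samples).
#' @return A number in `[-1, 1]`, or `NA_real_` for constant input.
#' @export
cc_time <- function(measured, reconstructed) {
  stopifnot(length(measured) == length(reconstructed), length(measured) >= 2L)
  if (sd(measured) == 0 || sd(reconstructed) == 0) return(NA_real_)
  cor(measured, reconstructed)
}

#' Activation time of one electrogram
#'
#' The local activation time is the instant of steepest potential decline:
#' the sample `t*` maximizing the one-step drop `-(V[t+1] - V[t])` (the
#' divisor `dt` does not change the argmax). Ties break to the earliest
#' sample, so a constant series returns 0 ms. The result is reported at the
#' first sample of the maximal drop, in ms from the start of the cycle, and
#' is invariant to adding a constant or positive rescaling of `V`.
#'
#' @param v Numeric vector of potentials at one lead (>= 2 samples).
#' @param dt Sampling interval in ms. Default 0.5 (2 kHz).
#' @return Activation time in ms.
#' @export
activation_time <- function(v, dt = 0.5) {
  stopifnot(length(v) >= 2L)
  drops <- -diff(v)
  (which.max(drops) - 1L) * dt
}

#' Activation map of a recording
#'
#' Applies [activation_time()] to every lead and identifies the
#' earliest-activating node (ties to the lowest node index), the predicted
#' pacing site.
#'
#' @param rec A heart `potential_recording`, or a lead x time matrix.
#' @param dt Sampling interval in ms; taken from the recording if available.
#' @return A tibble of class `activation_map` with columns `node_id` and
#'   `at_ms`, and attribute `earliest_node` (zero-based).
#' @export
activation_map <- function(rec, dt = NULL) {
  if (inherits(rec, "potential_recording")) {
    if (is.null(dt)) dt <- rec$sampling_interval
    pot <- rec$potentials
  } else {
    if (is.null(dt)) dt <- 0.5
    pot <- as.matrix(rec)
  }
  at <- apply(pot, 1L, activation_time, dt = dt)
  out <- tibble(node_id = seq_len(nrow(pot)) - 1L, at_ms = at)
  class(out) <- c("activation_map", class(out))
  attr(out, "earliest_node") <- out$node_id[which.min(out$at_ms)]
  out
}

#' Earliest-activating node of a map
#'
#' @param map An `activation_map`.
#' @return Zero-based node index.
#' @export
earliest_node <- function(map) {
  attr(map, "earliest_node", exact = TRUE) %||% map$node_id[which.min(map$at_ms)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation between two activation maps
#'
#' Pearson correlation across leads between measured and reconstructed
#' activation times — the accuracy score for the reconstructed activation
#' sequence. `NA` if either map is constant.
#'
#' @param at_measured,at_reconstructed `activation_map`s (or numeric vectors)
#'   over the same leads.
#' @return A number in `[-1, 1]`, or `NA_real_`.
#' @export
cc_activation <- function(at_measured, at_reconstructed) {
  a <- if (is.data.frame(at_measured)) at_measured$at_ms else as.numeric(at_measured)
  b <- if (is.data.frame(at_reconstructed)) at_reconstructed$at_ms else as.numeric(at_reconstructed)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Spatially smooth an activation map
#'
#' Optional inverse-distance-weighted neighbourhood smoothing of activation
#' times: each lead's time is replaced by the weighted mean of times within
#' `radius` mm (itself included), with weights `1 / (d + radius/4)`. With a
#' radius below the minimal inter-lead distance the map is unchanged. The
#' earliest node is recomputed. Off by default in all pipelines.
#'
#' @param map An `activation_map`.
#' @param heart The heart `node_set`.
#' @param radius Neighbourhood radius in mm (> 0).
#' @return A smoothed `activation_map`.
#' @export
smooth_at <- function(map, heart, radius) {
  stopifnot(radius > 0)
  pos <- node_positions(heart)
  d <- as.matrix(stats::dist(pos))
  w <- 1 / (d + radius / 4)
  w[d > radius] <- 0
  at <- unname(as.vector(w %*% map$at_ms) / rowSums(w))
  out <- map
  out$at_ms <- at
  attr(out, "earliest_node") <- out$node_id[which.min(at)]
  out
}

#' Pacing-site localization error
#'
#' Euclidean distance (mm) between the earliest-activating nodes of the
#' measured and reconstructed activation maps. The node derived from the
#' recorded electrograms serves as the ground-truth pacing site.
#'
#' @param at_measured,at_reconstructed `activation_map`s over `heart`.
#' @param heart The heart `node_set`.
#' @return Distance in mm (>= 0).
#' @export
localization_error <- function(at_measured, at_reconstructed, heart) {
  pos <- node_positions(heart)
  p1 <- pos[earliest_node(at_measured) + 1L, ]
  p2 <- pos[earliest_node(at_reconstructed) + 1L, ]
  sqrt(sum((p1 - p2)^2))
}

#' Tidy an activation map
#'
#' @param x An `activation_map`.
#' @param ... Unused.
#' @return A tibble with `node_id`, `at_ms`, and logical `earliest`.
#' @export
tidy.activation_map <- function(x, ...) {
  tibble(node_id = x$node_id, at_ms = x$at_ms,
         earliest = x$node_id == earliest_node(x))
}
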