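#' Synchronized beat averaging
#'
#' Raw paced recordings contain 5-20 repeats of the same beat. Averaging the
#' beats sample-by-sample from their onsets suppresses uncorrelated noise by
#' about `1/sqrt(n_beats)` while leaving the repeating waveform intact. All
#' beats are truncated to the shortest beat length; the output holds one
#' cycle whose value at (lead, t) is the arithmetic mean over beats of that
#' lead's value at offset t from the beat onset. The operation is invariant
#' to beat order and idempotent on identical beats.
#'
#' @param raw A `potential_recording` holding the multi-beat recording.
#' @param beat_onsets Strictly increasing integer vector of 1-based time-step
#'   indices at which each beat starts. Beat i spans `onsets[i]` up to
#'   `onsets[i+1] - 1` (the last beat runs to the end of the recording).
#' @return A one-cycle `potential_recording`.
#' @export
synchronized_average <- function(raw, beat_onsets) {
  if (length(beat_onsets) < 1L) stop_epimap("no-beats", "need at least one beat onset")
  if (is.unsorted(beat_onsets, strictly = TRUE)) {
    stop_epimap("no-beats", "beat onsets must be strictly increasing")
  }
  nt <- ncol(raw$potentials)
  ends <- c(beat_onsets[-1L] - 1L, nt)
  lens <- ends - beat_onsets + 1L
  if (any(lens < 2L)) stop_epimap("no-beats", "each beat needs >= 2 samples")
  len <- min(lens)
  acc <- matrix(0, nrow(raw$potentials), len)
  for (i in seq_along(beat_onsets)) {
    acc <- acc + raw$potentials[, beat_onsets[i]:(beat_onsets[i] + len - 1L), drop = FALSE]
  }
  out <- raw
  out$potentials <- acc / length(beat_onsets)
  out
}

#' Trailing moving mean
#'
#' Smooths each lead with a trailing window: output at time t is the mean of
#' the last `window` samples up to and including t (the window shrinks at
#' the left edge, so the output has the same length and constants are
#' preserved). The default window of 20 samples is 10 ms at 2 kHz. The
#' filter is linear in its input.
#'
#' @param x A numeric vector, a lead x time matrix, or a
#'   `potential_recording` (smoothed per lead).
#' @param window Window length in samples; must be >= 1. Default 20.
#' @return Same shape/class as the input.
#' @export
moving_mean <- function(x, window = 20L) {
  if (window < 1L) stop_epimap("bad-window", "window must be >= 1, got %s", format(window))
  window <- as.integer(window)
  if (inherits(x, "potential_recording")) {
    x$potentials <- moving_mean(x$potentials, window)
    return(x)
  }
  smooth_vec <- function(v) {
    n <- length(v)
    cs <- cumsum(v)
    lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
    denom <- pmin(seq_len(n), window)
    (cs - lag) / denom
  }
  if (is.matrix(x)) t(apply(x, 1L, smooth_vec)) else smooth_vec(x)
}

#' Baseline alignment of one cycle
#'
#' Electrograms are recorded against an arbitrary reference, so the whole
#' recording can sit on a common offset. All leads are shifted synchronously
#' by one scalar — the mean potential over every lead and the first
#' `onset_window` samples — so that the mean at the beginning of the cycle
#' is exactly zero. Applying the shift twice equals applying it once.
#'
#' @param cycle A `potential_recording`.
#' @param onset_window Number of initial samples defining "the beginning of
#'   the cycle". Default 1.
#' @return The shifted `potential_recording`.
#' @export
baseline_align <- function(cycle, onset_window = 1L) {
  if (onset_window < 1L) stop_epimap("bad-window", "onset_window must be >= 1")
  onset_window <- min(as.integer(onset_window), ncol(cycle$potentials))
  s <- mean(cycle$potentials[, seq_len(onset_window), drop = FALSE])
  cycle$potentials <- cycle$potentials - s
  cycle
}

#' Fill bad torso leads by spatial interpolation
#'
#' In experimental vests some 10-20% of leads record poorly; the whole lead
#' (not individual samples) is unusable. Each bad lead's full time series is
#' replaced by barycentric-linear interpolation of the good leads' series at
#' the bad lead's own registered (theta, h) position on the torso cylinder
#' (nearest good lead outside the good-lead hull). Because the
#' interpolation weights form a partition of unity and reproduce affine
#' fields, any potential field linear in (theta, h) is restored exactly at
#' interior bad leads. Filled leads are re-flagged `"interpolated"`.
#'
#' @param rec A torso `potential_recording` with `lead_quality` flags.
#' @param geometry The torso `node_set`.
#' @return The recording with bad leads filled.
#' @export
interpolate_bad_leads <- function(rec, geometry) {
  bad <- rec$lead_quality == "bad"
  if (!any(bad)) return(rec)
  good <- which(!bad)
  if (length(good) < 3L) {
    stop_epimap("insufficient-leads", "need >= 3 good leads, have %d", length(good))
  }
  coords <- cylinder_project(center_nodes(geometry))
  itp <- scattered_interpolator(coords$theta[good], coords$h[good], wrap_x = 360)
  w <- interp_weights(itp, coords$theta[bad], coords$h[bad])
  rec$potentials[bad, ] <- as.matrix(w %*% rec$potentials[good, , drop = FALSE])
  rec$lead_quality[bad] <- "interpolated"
  rec
}

#' Detect beat onsets from the global RMS slope (helper)
#'
#' A convenience for unreviewed data: marks a beat onset wherever the RMS
#' (across leads) of the one-step potential difference crosses `frac` of its
#' maximum from below, enforcing a refractory gap of `min_gap` samples.
#' Experimental beat segmentation is normally reviewed by hand; treat this
#' as a starting point, not a contract.
#'
#' @param raw A `potential_recording`.
#' @param frac Threshold as a fraction of the peak RMS slope. Default 0.5.
#' @param min_gap Minimum samples between onsets. Default 100.
#' @return Integer vector of 1-based onset indices.
#' @export
detect_beats <- function(raw, frac = 0.5, min_gap = 100L) {
  d <- diff(t(raw$potentials)) # (time-1) x leads
  rms <- sqrt(rowMeans(d^2))
  thr <- frac * max(rms)
  above <- rms >= thr
  onsets <- integer(0)
  last <- -Inf
  for (t in seq_along(above)) {
    if (above[t] && (t - last) >= min_gap) {
      onsets <- c(onsets, t)
      last <- t
    }
  }
  onsets
}

#' Full preprocessing of one raw recording
#'
#' Convenience chain in the order used on experimental data: synchronized
#' beat average, trailing moving mean, baseline alignment, and (for torso
#' recordings with a geometry) bad-lead interpolation.
#'
#' @param raw A `potential_recording`.
#' @param beat_onsets Beat onsets (1-based); a single beat spanning the whole
#'   recording if omitted.
#' @param window Moving-mean window (samples). Default 20.
#' @param onset_window Baseline window (samples). Default 1.
#' @param geometry Optional `node_set` for bad-lead interpolation.
#' @return A clean one-cycle `potential_recording`.
#' @export
preprocess_recording <- function(raw, beat_onsets = 1L, window = 20L,
                                 onset_window = 1L, geometry = NULL) {
  out <- synchronized_average(raw, beat_onsets)
  out <- moving_mean(out, window)
  out <- baseline_align(out, onset_window)
  if (!is.null(geometry) && any(out$lead_quality == "bad")) {
    out <- interpolate_bad_leads(out, geometry)
  }
  out
}
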