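#' Simulation configuration
#'
#' Parameters of the synthetic paired torso/heart generator. The generator
#' emulates the structure of an experimental paced-mapping study: per
#' subject, a 239-lead epicardial sock on a quasi-ellipsoidal ventricular
#' shell and a 150-171-lead vest on a quasi-cylindrical torso shell; per
#' recording, one paced beat whose activation spreads from a pacing node at
#' fixed conduction velocity, observed on the torso through a smooth linear
#' forward projection plus optional Gaussian sensor noise. Every draw is a
#' pure function of `(seed, subject, recording)`.
#'
#' @param n_subjects Number of subjects.
#' @param recordings_per_subject Recordings (distinct pacing sites) per
#'   subject; a scalar or one count per subject.
#' @param n_heart Epicardial sock lead count. Default 239.
#' @param torso_leads Torso lead count; `NULL` draws per subject from
#'   150-171, mirroring vest-to-vest variability.
#' @param cv_mm_per_ms Conduction velocity in mm/ms. Default 1.5.
#' @param cycle_ms Cycle length in ms. Default 90 (a compressed cycle: long
#'   enough for full ventricular activation plus the early recovery phase at
#'   desk scale).
#' @param sampling_interval Sampling interval in ms. Default 0.5 (2 kHz).
#' @param noise_sd Torso sensor noise sd in mV. Default 0.05, a residual
#'   noise level typical after beat averaging; set 0 for noiseless studies.
#' @param bad_lead_rate Fraction of torso leads flagged (and corrupted) as
#'   bad per recording. Default 0.15, the middle of the 10-20% seen on
#'   experimental vests.
#' @param waveform Named list of electrogram waveform parameters (mV, ms):
#'   `a_r` R-wave amplitude, `a_q` S-wave depth, `tau_d` downstroke time
#'   constant, `tau_r` upstroke time constant, `delta` R-wave lead time,
#'   `rec_delay`, `tau_rec` recovery timing. The downstroke term dominates
#'   all other slopes, so the steepest decline is at the activation time by
#'   construction.
#' @param seed Master RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1L,
                       recordings_per_subject = 12L,
                       n_heart = 239L,
                       torso_leads = NULL,
                       cv_mm_per_ms = 1.5,
                       cycle_ms = 90,
                       sampling_interval = 0.5,
                       noise_sd = 0.05,
                       bad_lead_rate = 0.15,
                       waveform = list(a_r = 20, a_q = 13, tau_d = 2.5, tau_r = 4,
                                       delta = 6, rec_delay = 30, tau_rec = 12),
                       seed = 1L) {
  stopifnot(n_subjects >= 1L, all(recordings_per_subject >= 1L), n_heart >= 4L,
            cv_mm_per_ms > 0, cycle_ms > 0, sampling_interval > 0,
            noise_sd >= 0, bad_lead_rate >= 0, bad_lead_rate <= 1)
  if (length(recordings_per_subject) == 1L) {
    recordings_per_subject <- rep(as.integer(recordings_per_subject), n_subjects)
  }
  stopifnot(length(recordings_per_subject) == n_subjects)
  structure(
    list(n_subjects = as.integer(n_subjects),
         recordings_per_subject = as.integer(recordings_per_subject),
         n_heart = as.integer(n_heart), torso_leads = torso_leads,
         cv_mm_per_ms = cv_mm_per_ms, cycle_ms = cycle_ms,
         sampling_interval = sampling_interval, noise_sd = noise_sd,
         bad_lead_rate = bad_lead_rate, waveform = waveform,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic quasi-uniform point cloud on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate one subject's paired geometry
#'
#' Heart: `n_heart` sock leads on a quasi-ellipsoidal shell (half-axes about
#' 26 x 26 x 40 mm, jittered per subject, 2% radial roughness), apex-base
#' axis along z, apex electrode labelled, the whole shell offset inside the
#' torso. Torso: the subject's vest leads on rings of a quasi-cylindrical
#' shell (radius about 70 mm — a snugly wrapped electrode vest — height
#' 260 mm) enclosing the heart.
#' Deterministic per `(config$seed, subject)`.
#'
#' @param config A [sim_config()].
#' @param subject 1-based subject index.
#' @return A list with `torso` and `heart` `node_set`s and `apex_node`
#'   (zero-based heart node index).
#' @export
make_geometry <- function(config, subject = 1L) {
  with_seed(derive_seed(config$seed, subject), {
    # heart shell
    n_h <- config$n_heart
    sph <- fibonacci_sphere(n_h)
    ax <- 26 * (1 + runif(1, -0.08, 0.08))
    cz <- 40 * (1 + runif(1, -0.08, 0.08))
    rough <- 1 + 0.02 * rnorm(n_h)
    heart_pos <- sph * rough * rep(c(ax, ax, cz), each = n_h)
    apex_node <- which.min(heart_pos[, 3]) - 1L
    offset <- c(runif(1, -12, 12), runif(1, -12, 12), runif(1, -15, 15))
    heart_pos <- sweep(heart_pos, 2, offset, "+")
    # torso shell
    n_t <- if (is.null(config$torso_leads)) sample(150:171, 1L) else as.integer(config$torso_leads)
    n_rings <- 10L
    per_ring <- diff(round(seq(0, n_t, length.out = n_rings + 1L)))
    radius <- 70 * (1 + runif(1, -0.05, 0.05))
    heights <- seq(-110, 110, length.out = n_rings)
    torso_pos <- do.call(rbind, lapply(seq_len(n_rings), function(k) {
      m <- per_ring[k]
      ang <- (seq_len(m) - 1) / m * 2 * pi + runif(1, 0, 2 * pi / max(m, 1))
      r_k <- radius * (1 + 0.03 * rnorm(m))
      cbind(r_k * sin(ang), r_k * cos(ang),
            heights[k] + rnorm(m, 0, 3))
    }))
    list(
      torso = node_set(torso_pos, "torso"),
      heart = node_set(heart_pos, "epicardium"),
      apex_node = apex_node
    )
  })
}

# Extracellular electrogram template: logistic upstroke (R wave), dominant
# logistic downstroke at the activation time, slow logistic recovery back to
# baseline. The downstroke's peak slope (a_r + a_q)/(4 tau_d) exceeds every
# other term's slope everywhere, so max -dV/dt sits at the activation time.
electrogram_waveform <- function(t, at, wf) {
  a_tot <- wf$a_r + wf$a_q
  wf$a_r * stats::plogis((t - at + wf$delta) / wf$tau_r) -
    a_tot * stats::plogis((t - at) / wf$tau_d) +
    wf$a_q * stats::plogis((t - at - wf$rec_delay) / wf$tau_rec)
}

#' Simulate a paced epicardial recording
#'
#' Activation spreads from the pacing node at the configured conduction
#' velocity; each lead's ground-truth activation time is its Euclidean
#' distance to the pacing node divided by that velocity (a shell-surface
#' simplification), and its electrogram is the template waveform centred on
#' that time, sampled at the configured interval. The returned recording
#' carries the ground-truth map as `$truth_at` (an `activation_map`).
#'
#' @param heart The heart `node_set`.
#' @param pacing_node Zero-based pacing lead index.
#' @param config A [sim_config()].
#' @param subject_id,recording_id Identifiers stored on the recording.
#' @return A heart `potential_recording` with element `truth_at`.
#' @export
simulate_pacing <- function(heart, pacing_node, config,
                            subject_id = "s1", recording_id = "r1") {
  n <- nrow(heart)
  if (is.na(pacing_node) || pacing_node < 0L || pacing_node >= n) {
    stop_epimap("bad-node", "pacing node %s not on the heart (0..%d)",
                format(pacing_node), n - 1L)
  }
  pos <- node_positions(heart)
  d <- sqrt(rowSums(sweep(pos, 2, pos[pacing_node + 1L, ])^2))
  at <- d / config$cv_mm_per_ms
  tgrid <- seq(0, config$cycle_ms, by = config$sampling_interval)
  pot <- t(vapply(at, function(a) electrogram_waveform(tgrid, a, config$waveform),
                  numeric(length(tgrid))))
  rec <- potential_recording(
    pot, subject_id = subject_id, recording_id = recording_id,
    pacing_type = "epicardial", pacing_node = pacing_node,
    sampling_interval = config$sampling_interval
  )
  truth <- tibble(node_id = seq_len(n) - 1L, at_ms = at)
  class(truth) <- c("activation_map", class(truth))
  attr(truth, "earliest_node") <- pacing_node
  rec$truth_at <- truth
  rec
}

#' Forward transfer matrix between heart and torso leads
#'
#' A smooth linear volume-conductor stand-in: entry (i, j) is the
#' inverse-square kernel `1 / d(i,j)^2` between torso lead i and heart lead
#' j, row-normalized so each row sums to 1 (a uniform epicardial potential
#' therefore appears unchanged at every torso lead). This is a fixture for
#' exercising the learning and registration machinery — not a boundary
#' element solution, and not a claim about tissue conductivity.
#'
#' @param torso,heart `node_set`s with disjoint positions.
#' @return A torso x heart matrix with unit row sums.
#' @export
build_transfer <- function(torso, heart) {
  tp <- node_positions(torso); hp <- node_positions(heart)
  d2 <- outer(rowSums(tp^2), rep(1, nrow(hp))) +
    outer(rep(1, nrow(tp)), rowSums(hp^2)) - 2 * tp %*% t(hp)
  d2[d2 < 0] <- 0
  if (any(d2 == 0)) stop_epimap("degenerate-geometry", "coincident torso/heart nodes")
  w <- 1 / d2
  w / rowSums(w)
}

#' Project an epicardial recording to the torso
#'
#' Applies the forward model: torso potentials are the transfer matrix times
#' the epicardial potentials at every time step, plus seeded i.i.d. Gaussian
#' sensor noise.
#'
#' @param heart_rec A heart `potential_recording`.
#' @param A Transfer matrix from [build_transfer()].
#' @param noise_sd Noise sd in mV.
#' @param seed RNG seed for the noise.
#' @return A torso `potential_recording` with matching metadata.
#' @export
forward_project <- function(heart_rec, A, noise_sd = 0, seed = 1L) {
  if (ncol(A) != nrow(heart_rec$potentials)) {
    stop_epimap("shape-mismatch", "transfer matrix has %d heart columns, recording %d leads",
                ncol(A), nrow(heart_rec$potentials))
  }
  pot <- A %*% heart_rec$potentials
  if (noise_sd > 0) {
    pot <- pot + with_seed(seed, matrix(rnorm(length(pot), 0, noise_sd), nrow(pot)))
  }
  potential_recording(
    pot, subject_id = heart_rec$subject_id, recording_id = heart_rec$recording_id,
    pacing_type = heart_rec$pacing_type, pacing_node = heart_rec$pacing_node,
    sampling_interval = heart_rec$sampling_interval
  )
}

# Greedy farthest-point selection of pacing nodes, so sites spread over the
# whole shell the way an experimental pacing protocol would.
spread_pacing_nodes <- function(heart, k, first) {
  pos <- node_positions(heart)
  chosen <- first + 1L
  if (k > 1L) {
    mind <- sqrt(rowSums(sweep(pos, 2, pos[chosen, ])^2))
    for (i in seq_len(k - 1L)) {
      nxt <- which.max(mind)
      chosen <- c(chosen, nxt)
      mind <- pmin(mind, sqrt(rowSums(sweep(pos, 2, pos[nxt, ])^2)))
    }
  }
  chosen - 1L
}

#' Generate a multi-subject synthetic corpus
#'
#' For each subject: one paired geometry and one recording per pacing site,
#' with pacing sites spread over the heart by farthest-point selection from
#' a seeded start. Torso recordings are the forward projection of the
#' simulated epicardial potentials plus sensor noise; a configured fraction
#' of torso leads per recording is corrupted (replaced by baseline noise)
#' and flagged `"bad"`, emulating poorly recording vest leads. Byte-identical
#' output for identical `(config)`.
#'
#' @param config A [sim_config()].
#' @return An [epimap_corpus()].
#' @export
make_corpus <- function(config) {
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    geo <- make_geometry(config, s)
    A <- build_transfer(geo$torso, geo$heart)
    n_rec <- config$recordings_per_subject[s]
    first <- with_seed(derive_seed(config$seed, 7919L + s),
                       sample.int(config$n_heart, 1L) - 1L)
    pacing <- spread_pacing_nodes(geo$heart, n_rec, first)
    sid <- sprintf("subj%02d", s)
    recordings <- lapply(seq_len(n_rec), function(r) {
      rid <- sprintf("rec%02d", r)
      hrec <- simulate_pacing(geo$heart, pacing[r], config,
                              subject_id = sid, recording_id = rid)
      rec_seed <- derive_seed(config$seed, s * 1000L + r)
      trec <- forward_project(hrec, A, config$noise_sd, seed = rec_seed)
      if (config$bad_lead_rate > 0) {
        trec <- with_seed(derive_seed(config$seed, s * 1000L + r + 500000L), {
          n_t <- nrow(trec$potentials)
          n_bad <- round(config$bad_lead_rate * n_t)
          if (n_bad > 0) {
            bad <- sample.int(n_t, n_bad)
            trec$potentials[bad, ] <- matrix(
              rnorm(n_bad * ncol(trec$potentials), 0, 0.5),
              n_bad)
            trec$lead_quality[bad] <- "bad"
          }
          trec
        })
      }
      list(torso = trec, heart = hrec)
    })
    paired_dataset(geo$torso, geo$heart, recordings,
                   subject_id = sid, apex_node = geo$apex_node)
  })
  epimap_corpus(subjects)
}
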