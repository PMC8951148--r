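#' Multichannel potential recordings
#'
#' A `potential_recording` holds one multichannel electrogram: a lead x time
#' matrix of potentials (mV, arbitrary reference) at a fixed sampling
#' interval, plus identifying metadata. After preprocessing a recording holds
#' exactly one cardiac cycle (QRS and T wave). Raw multi-beat recordings use
#' the same container.
#'
#' @param potentials Numeric matrix, leads in rows, time steps in columns.
#' @param subject_id,recording_id Character identifiers.
#' @param pacing_type One of `"sinus"`, `"endocardial"`, `"epicardial"`.
#' @param pacing_node Zero-based epicardial node index of the pacing site, or
#'   `NA` if unknown (e.g. sinus rhythm).
#' @param sampling_interval Sampling interval in ms. Default 0.5 ms (2 kHz).
#' @param lead_quality Character vector, one of `"good"`, `"bad"`,
#'   `"interpolated"` per lead. Defaults to all good.
#'
#' @return An object of class `potential_recording`.
#' @export
potential_recording <- function(potentials,
                                subject_id = "s0",
                                recording_id = "r0",
                                pacing_type = c("epicardial", "endocardial", "sinus"),
                                pacing_node = NA_integer_,
                                sampling_interval = 0.5,
                                lead_quality = NULL) {
  pacing_type <- match.arg(pacing_type)
  pot <- as.matrix(potentials)
  storage.mode(pot) <- "double"
  if (ncol(pot) < 2L) stop_epimap("bad-recording", "need at least 2 time steps")
  if (!all(is.finite(pot))) stop_epimap("bad-recording", "non-finite potentials")
  if (sampling_interval <= 0) stop_epimap("bad-recording", "sampling_interval must be > 0")
  if (is.null(lead_quality)) lead_quality <- rep("good", nrow(pot))
  if (length(lead_quality) != nrow(pot)) {
    stop_epimap("shape-mismatch", "lead_quality length %d != %d leads",
                length(lead_quality), nrow(pot))
  }
  stopifnot(all(lead_quality %in% c("good", "bad", "interpolated")))
  structure(
    list(
      subject_id = as.character(subject_id),
      recording_id = as.character(recording_id),
      pacing_type = pacing_type,
      pacing_node = as.integer(pacing_node),
      sampling_interval = as.double(sampling_interval),
      potentials = pot,
      lead_quality = lead_quality
    ),
    class = "potential_recording"
  )
}

#' @export
print.potential_recording <- function(x, ...) {
  cat(sprintf(
    "<potential_recording %s/%s: %d leads x %d steps @ %.3g ms, pacing %s%s>\n",
    x$subject_id, x$recording_id, nrow(x$potentials), ncol(x$potentials),
    x$sampling_interval, x$pacing_type,
    if (is.na(x$pacing_node)) "" else sprintf(" (node %d)", x$pacing_node)
  ))
  invisible(x)
}

#' @export
dim.potential_recording <- function(x) dim(x$potentials)

#' Tidy a potential recording into long format
#'
#' @param x A `potential_recording`.
#' @param ... Unused.
#' @return A tibble with columns `lead` (zero-based), `time_ms`,
#'   `potential_mv`, and `quality`.
#' @export
tidy.potential_recording <- function(x, ...) {
  nl <- nrow(x$potentials); nt <- ncol(x$potentials)
  tibble(
    lead = rep(seq_len(nl) - 1L, times = nt),
    time_ms = rep((seq_len(nt) - 1) * x$sampling_interval, each = nl),
    potential_mv = as.vector(x$potentials),
    quality = rep(x$lead_quality, times = nt)
  )
}

#' Paired torso/heart dataset for one subject
#'
#' Bundles one subject's torso and epicardial geometries with a list of
#' simultaneously recorded (torso, heart) electrogram pairs. Every pair must
#' share the subject id, sampling interval and time length, and each
#' recording's lead count must match its geometry.
#'
#' @param torso_geometry,heart_geometry `node_set` objects.
#' @param recordings List of `list(torso = , heart = )` pairs of
#'   [potential_recording()] objects.
#' @param subject_id Subject identifier.
#' @param apex_node Zero-based heart node index of the sock's apex electrode
#'   (used by the epicardial registration).
#'
#' @return An object of class `paired_dataset`.
#' @export
paired_dataset <- function(torso_geometry, heart_geometry, recordings = list(),
                           subject_id = "s0", apex_node = 0L) {
  validate_node_set(torso_geometry)
  validate_node_set(heart_geometry)
  nt <- nrow(torso_geometry); nh <- nrow(heart_geometry)
  for (pair in recordings) {
    stopifnot(is.list(pair), !is.null(pair$torso), !is.null(pair$heart))
    if (nrow(pair$torso$potentials) != nt) {
      stop_epimap("shape-mismatch", "torso recording %s has %d leads, geometry has %d",
                  pair$torso$recording_id, nrow(pair$torso$potentials), nt)
    }
    if (nrow(pair$heart$potentials) != nh) {
      stop_epimap("shape-mismatch", "heart recording %s has %d leads, geometry has %d",
                  pair$heart$recording_id, nrow(pair$heart$potentials), nh)
    }
    if (ncol(pair$torso$potentials) != ncol(pair$heart$potentials)) {
      stop_epimap("shape-mismatch", "torso/heart time lengths differ in recording %s",
                  pair$torso$recording_id)
    }
    if (!isTRUE(all.equal(pair$torso$sampling_interval, pair$heart$sampling_interval))) {
      stop_epimap("shape-mismatch", "sampling intervals differ in recording %s",
                  pair$torso$recording_id)
    }
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      torso_geometry = torso_geometry,
      heart_geometry = heart_geometry,
      apex_node = as.integer(apex_node),
      recordings = recordings
    ),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset %s: %d torso + %d heart leads, %d recordings>\n",
              x$subject_id, nrow(x$torso_geometry), nrow(x$heart_geometry),
              length(x$recordings)))
  invisible(x)
}

#' Multi-subject corpus
#'
#' A named list of [paired_dataset()] objects, one per subject, as produced by
#' [make_corpus()] and consumed by the leave-one-subject-out harness.
#'
#' @param subjects Named list of `paired_dataset` objects.
#' @return An object of class `epimap_corpus`.
#' @export
epimap_corpus <- function(subjects) {
  stopifnot(length(subjects) >= 1L)
  if (is.null(names(subjects)) || anyDuplicated(names(subjects))) {
    names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  }
  stopifnot(!anyDuplicated(names(subjects)))
  structure(subjects, class = "epimap_corpus")
}

#' @export
print.epimap_corpus <- function(x, ...) {
  cat(sprintf("<epimap_corpus: %d subjects, %d recordings>\n",
              length(x), sum(vapply(x, function(s) length(s$recordings), integer(1)))))
  invisible(x)
}

#' Summarize a corpus as a tibble
#'
#' @param x An `epimap_corpus`.
#' @param ... Unused.
#' @return A tibble with one row per recording: subject, recording id,
#'   pacing type/node, lead counts, time steps.
#' @export
tidy.epimap_corpus <- function(x, ...) {
  purrr::map_dfr(unname(x), function(s) {
    purrr::map_dfr(s$recordings, function(pair) {
      tibble(
        subject_id = s$subject_id,
        recording_id = pair$heart$recording_id,
        pacing_type = pair$heart$pacing_type,
        pacing_node = pair$heart$pacing_node,
        torso_leads = nrow(pair$torso$potentials),
        heart_leads = nrow(pair$heart$potentials),
        n_steps = ncol(pair$heart$potentials)
      )
    })
  })
}
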