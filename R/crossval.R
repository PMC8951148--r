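# Cross-validation harnesses and fold scoring.

#' Score one reconstructed recording against the measurement
#'
#' Computes the full per-recording scorecard: per-lead electrogram
#' correlations across time, their median (constant leads excluded),
#' the correlation between measured and reconstructed activation maps,
#' and the pacing-site localization error.
#'
#' Reconstructed activation maps can be spatially smoothed ([smooth_at()])
#' before the map correlation and earliest-node search: a learned
#' reconstruction recovers the activation sequence at the scale of a few
#' electrodes but not the single-node argmin, so the experimental practice
#' of smoothing activation fields before locating the pacing site is
#' followed by the cross-validation harnesses (`smooth_radius = "auto"`,
#' i.e. three times the sock's mean inter-lead spacing). The measured map —
#' the ground-truth side — is never smoothed.
#'
#' @param measured A heart `potential_recording` (ground truth).
#' @param reconstructed Lead x time matrix of reconstructed potentials.
#' @param heart The heart `node_set`.
#' @param smooth_radius `NULL` for no smoothing (the default), `"auto"` for
#'   3x the mean inter-lead spacing, or a radius in mm.
#' @return A list: `lead_cc` (one per lead, `NA` where undefined),
#'   `median_cc`, `at_cc`, `loc_error_mm`, `at_measured`, `at_reconstructed`.
#' @export
score_reconstruction <- function(measured, reconstructed, heart,
                                 smooth_radius = NULL) {
  truth <- measured$potentials
  recon <- as.matrix(reconstructed)
  if (!all(dim(truth) == dim(recon))) {
    stop_epimap("shape-mismatch", "reconstruction is %dx%d, measurement %dx%d",
                nrow(recon), ncol(recon), nrow(truth), ncol(truth))
  }
  lead_cc <- vapply(seq_len(nrow(truth)),
                    function(k) cc_time(truth[k, ], recon[k, ]), numeric(1))
  at_m <- activation_map(measured)
  at_r <- activation_map(recon, dt = measured$sampling_interval)
  if (!is.null(smooth_radius)) {
    r <- if (identical(smooth_radius, "auto")) 3 * node_spacing(heart) else smooth_radius
    at_r <- smooth_at(at_r, heart, r)
  }
  list(
    lead_cc = lead_cc,
    median_cc = median(lead_cc, na.rm = TRUE),
    at_cc = cc_activation(at_m, at_r),
    loc_error_mm = localization_error(at_m, at_r, heart),
    at_measured = at_m,
    at_reconstructed = at_r
  )
}

#' Leave-one-recording-out folds
#'
#' The Part I design: each recording of one subject is held out in turn
#' while the rest train, so K recordings yield K folds and K trained
#' models. `loocv_folds()` returns the fold plan; [loocv_recordings()]
#' executes it.
#'
#' @param n_recordings Number of recordings (>= 2).
#' @return A tibble with columns `fold`, `validation` (held-out recording
#'   index) and list-column `train` (training indices).
#' @export
loocv_folds <- function(n_recordings) {
  if (n_recordings < 2L) stop_epimap("insufficient-data", "need >= 2 recordings")
  tibble(
    fold = seq_len(n_recordings),
    validation = seq_len(n_recordings),
    train = lapply(seq_len(n_recordings), function(i) setdiff(seq_len(n_recordings), i))
  )
}

# Clean torso matrix: bad leads spatially interpolated before any model
# sees the data.
clean_torso <- function(rec, geometry) {
  if (any(rec$lead_quality == "bad")) interpolate_bad_leads(rec, geometry) else rec
}

#' Leave-one-recording-out cross-validation (Part I)
#'
#' Runs the within-subject design on one subject's paired dataset: for each
#' fold an FCN (per-time-step) or LSTM (per-sequence) inverse solver is
#' trained on all other recordings and evaluated on the held-out recording.
#' Bad torso leads are interpolated before training and prediction.
#'
#' @param dataset A [paired_dataset()] with >= 2 recordings.
#' @param kind `"fcn"` or `"lstm"`.
#' @param spec Optional [model_spec()]; a default is built from the data
#'   shapes (and `...` is passed to [model_spec()]) if omitted.
#' @param smooth_radius Activation-map smoothing for scoring; see
#'   [score_reconstruction()]. Default `"auto"`.
#' @param ... Passed to [model_spec()] when `spec` is `NULL`.
#' @return An `epimap_cv` tibble: one row per fold with `fold`,
#'   `subject_id`, `recording_id`, `median_cc`, `at_cc`, `loc_error_mm`,
#'   `n_cc_defined`, and list-column `lead_cc`.
#' @export
loocv_recordings <- function(dataset, kind = c("fcn", "lstm"), spec = NULL,
                             smooth_radius = "auto", ...) {
  kind <- match.arg(kind)
  n <- length(dataset$recordings)
  plan <- loocv_folds(n)
  torso_mats <- lapply(dataset$recordings, function(p) {
    t(clean_torso(p$torso, dataset$torso_geometry)$potentials)
  })
  heart_mats <- lapply(dataset$recordings, function(p) t(p$heart$potentials))
  if (is.null(spec)) {
    spec <- model_spec(kind, ncol(torso_mats[[1]]), ncol(heart_mats[[1]]), ...)
  }
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    tr <- plan$train[[i]]
    model <- if (kind == "fcn") {
      train_fcn(do.call(rbind, torso_mats[tr]), do.call(rbind, heart_mats[tr]), spec)
    } else {
      train_lstm(torso_mats[tr], heart_mats[tr], spec)
    }
    recon <- t(predict(model, torso_mats[[i]]))
    sc <- score_reconstruction(dataset$recordings[[i]]$heart, recon,
                               dataset$heart_geometry,
                               smooth_radius = smooth_radius)
    tibble(
      fold = i, subject_id = dataset$subject_id,
      recording_id = dataset$recordings[[i]]$heart$recording_id,
      median_cc = sc$median_cc, at_cc = sc$at_cc,
      loc_error_mm = sc$loc_error_mm,
      n_cc_defined = sum(!is.na(sc$lead_cc)),
      lead_cc = list(sc$lead_cc)
    )
  })
  new_epimap_cv(rows, design = "loo-recording", kind = kind)
}

#' Register one subject for the cross-subject model
#'
#' Applies both registration stages to every recording of a subject: bad
#' torso leads interpolated, torso potentials rasterized to images over the
#' unrolled cylinder, epicardial potentials resampled at the fixed template
#' through the normalized disk projection.
#'
#' @param subject A [paired_dataset()].
#' @param template An [build_template()].
#' @param image_dim `c(rows, cols)` of the torso raster. Default `c(30, 90)`.
#' @param arc_deg Segment arc for [normalize_segments()]. Default 30.
#' @return A list: `frames` (rows x cols x total time steps), `targets`
#'   (total time steps x template nodes), `rec_index` (recording of each
#'   frame), `disk` (normalized disk coords), recording list and geometry
#'   passthroughs.
#' @export
register_subject <- function(subject, template = build_template(),
                             image_dim = c(30L, 90L), arc_deg = 30) {
  coords <- cylinder_project(center_nodes(subject$torso_geometry))
  disk <- normalize_segments(
    project_to_disk(subject$heart_geometry, apex_node = subject$apex_node),
    arc_deg = arc_deg
  )
  frames_list <- list(); targets_list <- list(); rec_index <- integer(0)
  for (i in seq_along(subject$recordings)) {
    pair <- subject$recordings[[i]]
    torso <- clean_torso(pair$torso, subject$torso_geometry)
    imgs <- rasterize_torso(coords, torso$potentials,
                            nrow = image_dim[1], ncol = image_dim[2])
    tseq <- sample_to_template(disk, pair$heart$potentials, template)
    frames_list[[i]] <- unclass(imgs)
    targets_list[[i]] <- t(tseq)
    rec_index <- c(rec_index, rep(i, dim(imgs)[3]))
  }
  frames <- array(unlist(frames_list, use.names = FALSE),
                  c(image_dim[1], image_dim[2], length(rec_index)))
  list(frames = frames, targets = do.call(rbind, targets_list),
       rec_index = rec_index, disk = disk, template = template,
       subject = subject)
}

#' Leave-one-subject-out folds
#'
#' The Part II design: each subject's recordings are held out as a unit
#' while all other subjects' recordings train, so S subjects yield S folds
#' and S trained models.
#'
#' @param corpus An [epimap_corpus()] with >= 2 subjects.
#' @return A tibble with `fold`, `validation_subject`, `n_train_recordings`,
#'   `n_validation_recordings`, and list-column `train_subjects`.
#' @export
loso_folds <- function(corpus) {
  if (length(corpus) < 2L) stop_epimap("insufficient-data", "need >= 2 subjects")
  nms <- names(corpus)
  counts <- unname(vapply(corpus, function(s) length(s$recordings), integer(1)))
  tibble(
    fold = seq_along(nms),
    validation_subject = nms,
    n_train_recordings = sum(counts) - counts,
    n_validation_recordings = counts,
    train_subjects = lapply(seq_along(nms), function(i) nms[-i])
  )
}

#' Leave-one-subject-out cross-validation (Part II)
#'
#' Runs the cross-subject design: all subjects are registered into the
#' common representation (torso images, template sequences), then for each
#' fold one CNN is trained on every frame of the other subjects and
#' evaluated on every recording of the held-out subject. Predictions are
#' resampled from the template back to the held-out subject's own sock
#' leads before scoring, so the score is computed in the subject's native
#' lead space. Optionally scores a predict-the-training-mean baseline (the
#' per-time-step mean template sequence over the training recordings,
#' resampled the same way).
#'
#' @param corpus An [epimap_corpus()] with >= 2 subjects.
#' @param spec Optional [model_spec()] (`kind = "cnn"`); built via `...`
#'   if omitted.
#' @param template,image_dim,arc_deg Registration settings as in
#'   [register_subject()].
#' @param train_stride Keep every `train_stride`-th training frame (the
#'   registered frames are heavily redundant in time); validation uses all
#'   frames. Default 1.
#' @param baseline Also score the training-mean baseline. Default TRUE.
#' @param smooth_radius Activation-map smoothing for scoring; see
#'   [score_reconstruction()]. Default `"auto"`.
#' @param ... Passed to [model_spec()] when `spec` is `NULL`.
#' @return An `epimap_cv` tibble, one row per held-out recording, with
#'   `baseline_median_cc` when `baseline` is set.
#' @export
leave_one_subject_out <- function(corpus, spec = NULL,
                                  template = build_template(),
                                  image_dim = c(30L, 90L), arc_deg = 30,
                                  train_stride = 1L, baseline = TRUE,
                                  smooth_radius = "auto", ...) {
  plan <- loso_folds(corpus)
  reg <- lapply(corpus, register_subject, template = template,
                image_dim = image_dim, arc_deg = arc_deg)
  if (is.null(spec)) {
    spec <- model_spec("cnn", image_dim, nrow(template), ...)
  }
  rows <- purrr::map_dfr(plan$fold, function(f) {
    val_nm <- plan$validation_subject[f]
    tr_nms <- plan$train_subjects[[f]]
    tr_frames <- do.call(function(...) abind3(...), lapply(reg[tr_nms], `[[`, "frames"))
    tr_targets <- do.call(rbind, lapply(reg[tr_nms], `[[`, "targets"))
    keep <- seq(1L, dim(tr_frames)[3], by = as.integer(train_stride))
    model <- train_cnn(tr_frames[, , keep, drop = FALSE],
                       tr_targets[keep, , drop = FALSE], spec)
    rv <- reg[[val_nm]]
    pred_templ <- predict(model, rv$frames) # frames x template nodes
    base_templ <- if (baseline) {
      # per-time-step mean over training recordings (truncated to the
      # shortest recording)
      mean_template_sequence(reg[tr_nms])
    } else NULL
    subj <- rv$subject
    purrr::map_dfr(seq_along(subj$recordings), function(i) {
      sel <- rv$rec_index == i
      recon_sock <- sample_from_template(t(pred_templ[sel, , drop = FALSE]),
                                         template, rv$disk)
      sc <- score_reconstruction(subj$recordings[[i]]$heart, recon_sock,
                                 subj$heart_geometry,
                                 smooth_radius = smooth_radius)
      row <- tibble(
        fold = f, subject_id = subj$subject_id,
        recording_id = subj$recordings[[i]]$heart$recording_id,
        median_cc = sc$median_cc, at_cc = sc$at_cc,
        loc_error_mm = sc$loc_error_mm,
        n_cc_defined = sum(!is.na(sc$lead_cc)),
        lead_cc = list(sc$lead_cc)
      )
      if (!is.null(base_templ)) {
        nt <- sum(sel)
        bt <- base_templ[, rep_len(seq_len(ncol(base_templ)), nt), drop = FALSE]
        base_sock <- sample_from_template(bt, template, rv$disk)
        scb <- score_reconstruction(subj$recordings[[i]]$heart, base_sock,
                                    subj$heart_geometry,
                                    smooth_radius = smooth_radius)
        row$baseline_median_cc <- scb$median_cc
      }
      row
    })
  })
  new_epimap_cv(rows, design = "loo-subject", kind = "cnn")
}

# Stack 3D arrays along the third dimension.
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], numeric(1)))))
}

# Mean template sequence (template nodes x time) over all training
# recordings, truncated to the shortest.
mean_template_sequence <- function(regs) {
  seqs <- list()
  for (r in regs) {
    for (i in unique(r$rec_index)) {
      seqs[[length(seqs) + 1L]] <- t(r$targets[r$rec_index == i, , drop = FALSE])
    }
  }
  len <- min(vapply(seqs, ncol, integer(1)))
  Reduce(`+`, lapply(seqs, function(s) s[, seq_len(len), drop = FALSE])) / length(seqs)
}

new_epimap_cv <- function(rows, design, kind) {
  class(rows) <- c("epimap_cv", class(rows))
  attr(rows, "design") <- design
  attr(rows, "kind") <- kind
  rows
}

#' Summaries of cross-validation results
#'
#' `summarize_folds()` pools per-recording scores: the overall median and
#' first/third quartiles (linear interpolation of order statistics) of the
#' per-recording median electrogram CC, activation-map CC and localization
#' error, plus the same breakdown per subject. `glance()` returns the
#' overall row only; `tidy()` unnests the per-lead correlations.
#'
#' @param results An `epimap_cv` (or any tibble with `median_cc`, `at_cc`,
#'   `loc_error_mm`, `subject_id`).
#' @return A tibble, one row overall plus one per subject.
#' @export
summarize_folds <- function(results) {
  stopifnot(nrow(results) >= 1L)
  one <- function(df, label) {
    q <- function(v, p) unname(quantile(v, p, na.rm = TRUE, type = 7))
    tibble(
      group = label, n_recordings = nrow(df),
      cc_median = q(df$median_cc, 0.5), cc_q1 = q(df$median_cc, 0.25),
      cc_q3 = q(df$median_cc, 0.75),
      at_cc_median = q(df$at_cc, 0.5), at_cc_q1 = q(df$at_cc, 0.25),
      at_cc_q3 = q(df$at_cc, 0.75),
      loc_error_median_mm = q(df$loc_error_mm, 0.5),
      loc_error_q1_mm = q(df$loc_error_mm, 0.25),
      loc_error_q3_mm = q(df$loc_error_mm, 0.75)
    )
  }
  per_subject <- purrr::map_dfr(split(results, results$subject_id),
                                function(df) one(df, df$subject_id[1]))
  dplyr::bind_rows(one(results, "overall"), per_subject)
}

#' @rdname summarize_folds
#' @param x An `epimap_cv`.
#' @param ... Unused.
#' @export
glance.epimap_cv <- function(x, ...) summarize_folds(x)[1, ]

#' @rdname summarize_folds
#' @export
tidy.epimap_cv <- function(x, ...) {
  out <- as_tibble(x)[, c("fold", "subject_id", "recording_id", "lead_cc")]
  out$lead_cc <- lapply(out$lead_cc, function(v) {
    tibble(node_id = seq_along(v) - 1L, cc = v)
  })
  tidyr::unnest(out, "lead_cc")
}
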