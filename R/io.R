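#' Read and write paired datasets
#'
#' The on-disk container is a plain tabular directory: per subject a
#' directory holding `geometry_torso.csv` / `geometry_heart.csv`
#' (`node_id,x,y,z`), a `subject.json` with metadata, and per recording a
#' `rec_<id>_torso.csv` / `rec_<id>_heart.csv` potential matrix (leads in
#' rows, time in columns) plus `rec_<id>_meta.json`. A multi-subject corpus
#' is a directory of such subject directories with a top-level `corpus.json`.
#' Floats are written as `%.17g`, which round-trips IEEE doubles exactly, so
#' write-then-read is bit-identical.
#'
#' @param dataset A [paired_dataset()] or [epimap_corpus()].
#' @param path Directory to create (write) or read.
#' @param format Container dialect. Only `"dir"` (tabular directory) is
#'   supported.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `paired_dataset` or `epimap_corpus` matching what was written.
#' @examples
#' \donttest{
#' corpus <- make_corpus(sim_config(n_subjects = 1, recordings_per_subject = 2,
#'                                  n_heart = 40, torso_leads = 20, seed = 1))
#' p <- file.path(tempdir(), "corpus_demo")
#' write_dataset(corpus, p)
#' corpus2 <- read_dataset(p)
#' }
#' @export
write_dataset <- function(dataset, path, format = "dir") {
  check_format(format)
  if (inherits(dataset, "epimap_corpus")) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(kind = "corpus", subjects = as.list(names(dataset))),
      file.path(path, "corpus.json"), auto_unbox = TRUE
    )
    for (nm in names(dataset)) {
      write_subject(dataset[[nm]], file.path(path, nm))
    }
  } else if (inherits(dataset, "paired_dataset")) {
    write_subject(dataset, path)
  } else {
    stop_epimap("bad-dataset", "expected a paired_dataset or epimap_corpus")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, format = "dir") {
  check_format(format)
  if (!dir.exists(path)) stop_epimap("geometry-missing", "path %s does not exist", path)
  if (file.exists(file.path(path, "corpus.json"))) {
    meta <- jsonlite::read_json(file.path(path, "corpus.json"), simplifyVector = TRUE)
    subjects <- lapply(meta$subjects, function(nm) read_subject(file.path(path, nm)))
    names(subjects) <- meta$subjects
    epimap_corpus(subjects)
  } else {
    read_subject(path)
  }
}

check_format <- function(format) {
  if (!identical(format, "dir")) {
    stop_epimap("unsupported-format",
                "only the tabular-directory container ('dir') is supported, got '%s'", format)
  }
}

# %.17g round-trips doubles exactly through text.
fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, file) {
  ch <- matrix(fmt_num(m), nrow = nrow(m))
  utils::write.table(ch, file, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_csv <- function(file) {
  m <- as.matrix(utils::read.csv(file, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

write_geometry_csv <- function(nodes, file) {
  df <- data.frame(
    node_id = nodes$node_id,
    x = fmt_num(nodes$x), y = fmt_num(nodes$y), z = fmt_num(nodes$z),
    surface = nodes$surface
  )
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
}

read_geometry_csv <- function(file) {
  if (!file.exists(file)) stop_epimap("geometry-missing", "missing geometry file %s", file)
  df <- utils::read.csv(file, colClasses = c("integer", "numeric", "numeric",
                                             "numeric", "character"))
  node_set(df[, c("x", "y", "z")], surface = df$surface[1], node_id = df$node_id)
}

write_subject <- function(ds, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(kind = "subject", subject_id = ds$subject_id, apex_node = ds$apex_node,
         recordings = lapply(ds$recordings, function(p) p$heart$recording_id)),
    file.path(path, "subject.json"), auto_unbox = TRUE
  )
  write_geometry_csv(ds$torso_geometry, file.path(path, "geometry_torso.csv"))
  write_geometry_csv(ds$heart_geometry, file.path(path, "geometry_heart.csv"))
  for (pair in ds$recordings) {
    id <- pair$heart$recording_id
    write_matrix_csv(pair$torso$potentials, file.path(path, sprintf("rec_%s_torso.csv", id)))
    write_matrix_csv(pair$heart$potentials, file.path(path, sprintf("rec_%s_heart.csv", id)))
    jsonlite::write_json(
      list(
        recording_id = id,
        pacing_type = pair$heart$pacing_type,
        pacing_node = if (is.na(pair$heart$pacing_node)) NULL else pair$heart$pacing_node,
        sampling_interval = pair$heart$sampling_interval,
        torso_lead_quality = pair$torso$lead_quality,
        heart_lead_quality = pair$heart$lead_quality
      ),
      file.path(path, sprintf("rec_%s_meta.json", id)), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

read_subject <- function(path) {
  meta_file <- file.path(path, "subject.json")
  if (!file.exists(meta_file)) stop_epimap("geometry-missing", "missing subject.json in %s", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  torso_geo <- read_geometry_csv(file.path(path, "geometry_torso.csv"))
  heart_geo <- read_geometry_csv(file.path(path, "geometry_heart.csv"))
  recordings <- lapply(meta$recordings, function(id) {
    rmeta <- jsonlite::read_json(file.path(path, sprintf("rec_%s_meta.json", id)),
                                 simplifyVector = TRUE)
    tfile <- file.path(path, sprintf("rec_%s_torso.csv", id))
    hfile <- file.path(path, sprintf("rec_%s_heart.csv", id))
    if (!file.exists(hfile)) stop_epimap("shape-mismatch", "missing heart potentials for %s", id)
    if (!file.exists(tfile)) stop_epimap("shape-mismatch", "missing torso potentials for %s", id)
    pacing_node <- if (is.null(rmeta$pacing_node)) NA_integer_ else rmeta$pacing_node
    list(
      torso = potential_recording(
        read_matrix_csv(tfile), subject_id = meta$subject_id, recording_id = id,
        pacing_type = rmeta$pacing_type, pacing_node = pacing_node,
        sampling_interval = rmeta$sampling_interval,
        lead_quality = rmeta$torso_lead_quality
      ),
      heart = potential_recording(
        read_matrix_csv(hfile), subject_id = meta$subject_id, recording_id = id,
        pacing_type = rmeta$pacing_type, pacing_node = pacing_node,
        sampling_interval = rmeta$sampling_interval,
        lead_quality = rmeta$heart_lead_quality
      )
    )
  })
  paired_dataset(torso_geo, heart_geo, recordings,
                 subject_id = meta$subject_id, apex_node = meta$apex_node)
}
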