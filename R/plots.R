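# ggplot2 views of the main result types.

#' Plot one torso potential image
#'
#' @param object A `torso_images` stack from [rasterize_torso()].
#' @param time_step 1-based frame index. Default 1.
#' @param ... Unused.
#' @return A ggplot raster of the frame over (theta, h).
#' @export
autoplot.torso_images <- function(object, time_step = 1L, ...) {
  theta <- attr(object, "theta"); h <- attr(object, "h")
  frame <- unclass(object)[, , time_step]
  theta_col <- rep(theta, each = length(h))
  h_col <- rep(h, times = length(theta))
  df <- tibble(theta = theta_col, h = h_col, mv = as.vector(frame))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$h, fill = .data$mv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "mV") +
    ggplot2::labs(x = "theta (deg from +y, clockwise)", y = "h (mm)",
                  title = sprintf("Torso potential image, frame %d", time_step)) +
    ggplot2::coord_cartesian(expand = FALSE)
}

#' Plot an activation map on the registered disk
#'
#' @param object An `activation_map`.
#' @param coords Normalized `disk_coords` of the same leads (from
#'   [project_to_disk()] + [normalize_segments()]).
#' @param ... Unused.
#' @return A ggplot scatter of activation time over the disk, the earliest
#'   node highlighted.
#' @export
autoplot.activation_map <- function(object, coords, ...) {
  df <- dplyr::left_join(tidy(object), as_tibble(coords), by = "node_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$at_ms)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = df[df$earliest, ], shape = 1, size = 5,
                        colour = "red") +
    ggplot2::scale_colour_viridis_c(name = "AT (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u", y = "v", title = "Activation map (earliest node circled)")
}

#' Plot cross-validation scores
#'
#' @param object An `epimap_cv`.
#' @param ... Unused.
#' @return A ggplot of per-recording median correlations by subject.
#' @export
autoplot.epimap_cv <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$median_cc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::ylim(NA, 1) +
    ggplot2::labs(x = NULL, y = "median per-lead CC",
                  title = sprintf("Cross-validation (%s, %s)",
                                  attr(object, "design"), attr(object, "kind")))
}

#' Compare measured and reconstructed electrograms at selected leads
#'
#' @param measured A heart `potential_recording`.
#' @param reconstructed Lead x time matrix of reconstructed potentials.
#' @param leads Zero-based lead indices to show. Default first 4.
#' @return A faceted ggplot of the two traces per lead.
#' @export
plot_electrograms <- function(measured, reconstructed, leads = 0:3) {
  dt <- measured$sampling_interval
  nt <- ncol(measured$potentials)
  df <- purrr::map_dfr(leads, function(k) {
    tibble(
      lead = sprintf("lead %d", k),
      time_ms = rep((seq_len(nt) - 1) * dt, 2),
      mv = c(measured$potentials[k + 1L, ], as.matrix(reconstructed)[k + 1L, ]),
      series = rep(c("measured", "reconstructed"), each = nt)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$mv,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~lead, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "potential (mV)", colour = NULL)
}
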