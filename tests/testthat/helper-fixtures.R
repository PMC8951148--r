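# Shared fixtures, all built in code.

# A well-spread torso lead cloud whose cylinder unwrapping covers the full
# (theta, h) raster, so interior-exactness checks are not confounded by
# convex-hull fallback at the image edges.
covering_torso_coords <- function(seed = 1) {
  withr::with_seed(seed, {
    # dense rings at the height extremes keep every boundary pixel of the
    # raster next to a lead at that same height
    th <- c(rep(seq(0, 352.5, by = 7.5), 2), runif(120, 0, 360))
    hh <- c(rep(c(-120, 120), each = 48), runif(120, -110, 110))
    pos <- cbind(110 * sin(th * pi / 180), 110 * cos(th * pi / 180), hh)
    cylinder_project(node_set(pos, "torso"))
  })
}

# Normalized disk coordinates for a generic 239-lead sock.
random_disk_coords <- function(seed = 1, n = 239) {
  withr::with_seed(seed, {
    r <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
    out <- tibble::tibble(node_id = seq_len(n) - 1L,
                          u = r * cos(a), v = r * sin(a))
    class(out) <- c("disk_coords", class(out))
    normalize_segments(out)
  })
}

# Small noiseless corpus for pipeline tests.
tiny_config <- function(...) {
  sim_config(n_subjects = 1, recordings_per_subject = 3, n_heart = 60,
             torso_leads = 40, cycle_ms = 40, noise_sd = 0,
             bad_lead_rate = 0, seed = 7, ...)
}
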