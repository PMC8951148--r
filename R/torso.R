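#' Torso electrode registration onto a cylinder
#'
#' Different subjects wear different vests: lead counts (about 150-171) and
#' positions vary, so raw torso vectors are not comparable across subjects.
#' The registration maps every torso lead cloud onto the surface of a
#' cylinder around the torso, giving each lead a subject-independent pair of
#' coordinates: the azimuth `theta` (degrees from the +y axis, increasing
#' toward +x, i.e. clockwise viewed from above, wrapped to [0, 360)) and the
#' height `h` (the raw z coordinate in mm, signed distance to the x-y
#' plane). `center_nodes()` must be applied first so the cylinder axis passes
#' through the cloud's centroid.
#'
#' @param nodes A `node_set`.
#' @return `center_nodes()`: a `node_set` with the centroid subtracted.
#'   `cylinder_project()`: a tibble of class `cylinder_coords` with columns
#'   `node_id`, `theta` (degrees) and `h` (mm), one row per lead.
#' @export
center_nodes <- function(nodes) {
  pos <- node_positions(nodes)
  centered <- sweep(pos, 2, colMeans(pos))
  out <- nodes[order(nodes$node_id), ]
  out$x <- centered[, 1]; out$y <- centered[, 2]; out$z <- centered[, 3]
  out
}

#' @rdname center_nodes
#' @export
cylinder_project <- function(nodes) {
  pos <- node_positions(nodes)
  r2 <- pos[, 1]^2 + pos[, 2]^2
  if (any(r2 == 0)) {
    stop_epimap("degenerate-node", "node(s) on the cylinder axis: %s",
                paste(which(r2 == 0) - 1L, collapse = ", "))
  }
  theta <- (atan2(pos[, 1], pos[, 2]) * 180 / pi) %% 360
  out <- tibble(node_id = sort(nodes$node_id), theta = theta, h = pos[, 3])
  class(out) <- c("cylinder_coords", class(out))
  out
}

#' Rasterize torso potentials into fixed-size images
#'
#' Interpolates per-lead torso potentials onto a fixed pixel grid over the
#' unrolled cylinder, one image per time step, so that subjects with
#' different vests all produce images of the same shape. Interpolation is
#' barycentric-linear on a Delaunay triangulation of the (theta, h) lead
#' locations, with the point set replicated at theta +/- 360 degrees so the
#' image is seamless across the wrap; pixels outside the convex hull take
#' the nearest lead's value.
#'
#' Column pixel centers sit at `theta_j = (j + 0.5) * 360/ncol` degrees;
#' row centers span the subject's lead height range `[h_min, h_max]`
#' uniformly, row 1 at the top (largest h).
#'
#' @param coords A `cylinder_coords` tibble from [cylinder_project()].
#' @param potentials Lead x time matrix (mV), rows ordered by `node_id`.
#' @param nrow,ncol Image size; default 30 x 90.
#' @return A `torso_images` object: array of dim `(nrow, ncol, time)` with
#'   attributes `theta` (column centers) and `h` (row centers).
#' @export
rasterize_torso <- function(coords, potentials, nrow = 30L, ncol = 90L) {
  stopifnot(inherits(coords, "cylinder_coords"))
  pot <- as.matrix(potentials)
  if (base::nrow(pot) != base::nrow(coords)) {
    stop_epimap("shape-mismatch", "potentials have %d rows, coords %d leads",
                base::nrow(pot), base::nrow(coords))
  }
  itp <- torso_interpolant(coords)
  theta_px <- (seq_len(ncol) - 0.5) * 360 / ncol
  h_px <- seq(max(coords$h), min(coords$h), length.out = nrow)
  grid <- expand.grid(h = h_px, theta = theta_px) # column-major: rows vary fastest
  w <- interp_weights(itp, grid$theta, grid$h)
  img <- as.matrix(w %*% pot) # (nrow*ncol) x time
  out <- array(img, dim = c(nrow, ncol, base::ncol(pot)))
  structure(out, theta = theta_px, h = h_px, class = "torso_images")
}

#' Interpolant over the unrolled torso cylinder
#'
#' The periodic (period 360) scattered interpolant used by
#' [rasterize_torso()], exposed so callers can evaluate torso potentials at
#' arbitrary (theta, h) locations — e.g. to check seamlessness at the
#' 0/360 boundary, or to fill bad leads at their own registered positions.
#'
#' @param coords A `cylinder_coords` tibble.
#' @return A [scattered_interpolator()] with `wrap_x = 360`.
#' @export
torso_interpolant <- function(coords) {
  scattered_interpolator(coords$theta, coords$h, wrap_x = 360)
}

#' @export
print.torso_images <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<torso_images: %d x %d pixels x %d time steps>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.torso_images <- function(x) dim(unclass(x))
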