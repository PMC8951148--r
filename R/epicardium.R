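#' Project epicardial sock nodes onto a 2D disk
#'
#' The sock electrodes wrap a roughly ellipsoidal surface; projecting them
#' straight down onto the x-y plane would stack nodes from the sides of the
#' ventricles on top of each other. Instead each node is projected radially:
#' with the apex electrode at the origin and the apex-base axis along z, a
#' node at 3D position `p` maps to the planar direction of `(p_x, p_y)`
#' stretched out to the node's full 3D distance from the apex,
#' `r = ||p||`. The planar angle then encodes the node's orientation around
#' the heart and the planar radius its distance from the apex, and the map
#' preserves `||output|| = r` for every off-axis node. The apex maps to
#' (0, 0); a non-apex node lying exactly on the z axis has no defined
#' orientation and is mapped to (0, 0) with an `axial-node` warning.
#'
#' If `apex_node` is given, the geometry is first translated and rotated by
#' [align_apex()] so the apex is at the origin with the apex-to-centroid
#' direction along +z; otherwise the geometry is assumed pre-aligned.
#'
#' @param heart A `node_set` of epicardial leads.
#' @param apex_node Zero-based index of the apex electrode, or `NULL` if the
#'   geometry is already apex-aligned.
#' @return A tibble of class `disk_coords` with columns `node_id`, `u`, `v`
#'   (mm, pre-normalization).
#' @export
project_to_disk <- function(heart, apex_node = NULL) {
  pos <- node_positions(heart)
  if (!is.null(apex_node)) pos <- align_apex(pos, apex_node)
  r <- sqrt(rowSums(pos^2))
  rp <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  axial <- rp == 0 & r > 0
  if (any(axial)) {
    warn_epimap("axial-node", "%d non-apex node(s) on the z axis mapped to (0,0)",
                sum(axial))
  }
  scale <- ifelse(rp > 0, r / rp, 0)
  out <- tibble(node_id = sort(heart$node_id),
                u = pos[, 1] * scale, v = pos[, 2] * scale)
  class(out) <- c("disk_coords", class(out))
  out
}

# Translate apex to the origin and rotate so the apex->centroid direction is
# +z (Rodrigues rotation). The registration deliberately ignores where the
# heart sits in the body; only this internal axis matters.
align_apex <- function(pos, apex_node) {
  apex <- pos[apex_node + 1L, ]
  pos <- sweep(pos, 2, apex)
  axis <- colMeans(pos)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) return(pos)
  a <- axis / nrm
  ez <- c(0, 0, 1)
  v <- c(a[2] * ez[3] - a[3] * ez[2], a[3] * ez[1] - a[1] * ez[3],
         a[1] * ez[2] - a[2] * ez[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * ez)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  pos %*% t(R)
}

#' Normalize disk coordinates segment-wise
#'
#' Hearts differ in shape, so the projected scatter is oval rather than
#' circular and its extent differs between subjects. The disk is cut into
#' `360 / arc_deg` angular segments; within each segment the most distant
#' node defines the segment radius `L`, and every node in the segment is
#' shrunk concentrically by the factor `R / L` (angles unchanged), so after
#' normalization every non-empty segment's furthest node sits exactly at
#' radius `R` and all nodes lie within the radius-`R` disk. With the default
#' 30 degree arc the disk is divided into 12 segments. Empty segments are
#' skipped with an `empty-segment` warning. The operation is idempotent:
#' after one pass each segment's `L` equals `R`.
#'
#' @param coords A `disk_coords` tibble.
#' @param arc_deg Segment arc in degrees; must divide 360. Default 30.
#' @param R Target disk radius (dimensionless). Default 1.
#' @return A `disk_coords` tibble with normalized `u`, `v` and an attribute
#'   `n_segments`.
#' @export
normalize_segments <- function(coords, arc_deg = 30, R = 1) {
  if (360 %% arc_deg != 0) {
    stop_epimap("bad-arc", "arc_deg (%s) must divide 360", format(arc_deg))
  }
  n_seg <- as.integer(360 / arc_deg)
  r <- sqrt(coords$u^2 + coords$v^2)
  ang <- (atan2(coords$v, coords$u) * 180 / pi) %% 360
  seg <- pmin(floor(ang / arc_deg), n_seg - 1L) # guard 360-eps rounding
  seg[r == 0] <- 0L # center node: segment irrelevant, scale cancels at r=0
  scale <- rep(NA_real_, nrow(coords))
  empty <- 0L
  for (s in seq_len(n_seg) - 1L) {
    in_seg <- seg == s
    if (!any(in_seg)) { empty <- empty + 1L; next }
    L <- max(r[in_seg])
    scale[in_seg] <- if (L > 0) R / L else 1
  }
  if (empty > 0L) warn_epimap("empty-segment", "%d empty segment(s) skipped", empty)
  out <- coords
  out$u <- coords$u * scale
  out$v <- coords$v * scale
  attr(out, "n_segments") <- n_seg
  out
}

#' Build the fixed epicardial sampling template
#'
#' The template is the fixed set of sampling points on the unit disk that
#' gives every subject's epicardial data a common length and geometric
#' ordering: point 0 at the center, then `layers` concentric rings from
#' inner to outer, each traversed clockwise starting at angle 0 (the +u
#' direction). Ring `k` sits at radius `k * R / layers` and holds a number
#' of points proportional to `k` (area-uniform), rounded with a
#' largest-remainder correction so the total is exact. The defaults (7
#' rings, 165 points) give ring counts 6, 12, 18, 23, 29, 35, 41. The
#' layout is a pure function of its arguments: two builds are identical.
#'
#' @param layers Number of rings. Default 7.
#' @param total Total number of template points including the center.
#'   Default 165.
#' @param R Disk radius. Default 1.
#' @return A tibble of class `epi_template` with columns `node_id` (0-based),
#'   `ring`, `u`, `v`, `radius`, `angle_deg`.
#' @export
build_template <- function(layers = 7L, total = 165L, R = 1) {
  layers <- as.integer(layers); total <- as.integer(total)
  if (total < layers + 1L || layers < 1L) {
    stop_epimap("bad-template-spec", "need total >= layers + 1 (got %d, %d)", total, layers)
  }
  k <- seq_len(layers)
  target <- (total - 1L) * k / sum(k)
  counts <- round(target)
  # largest-remainder correction to hit total - 1 exactly
  excess <- sum(counts) - (total - 1L)
  if (excess != 0L) {
    resid <- target - counts
    ord <- order(if (excess > 0L) resid else -resid)
    for (i in seq_len(abs(excess))) {
      j <- ord[i]
      counts[j] <- counts[j] - sign(excess)
    }
  }
  if (any(counts < 1L)) stop_epimap("bad-template-spec", "a ring would be empty")
  rows <- purrr::map_dfr(k, function(kk) {
    n_k <- counts[kk]
    ang <- -(seq_len(n_k) - 1L) * 360 / n_k # clockwise from angle 0
    tibble(ring = kk, radius = kk * R / layers, angle_deg = ang %% 360,
           u = kk * R / layers * cos(ang * pi / 180),
           v = kk * R / layers * sin(ang * pi / 180))
  })
  out <- dplyr::bind_rows(
    tibble(ring = 0L, radius = 0, angle_deg = 0, u = 0, v = 0),
    rows
  )
  out <- dplyr::bind_cols(tibble(node_id = seq_len(nrow(out)) - 1L), out)
  class(out) <- c("epi_template", class(out))
  out
}

#' Resample potentials between sock leads and the template
#'
#' `sample_to_template()` interpolates per-lead epicardial potentials at the
#' template points (barycentric-linear on the registered disk coordinates,
#' nearest-lead fallback outside the lead hull), producing the fixed-length
#' representation models are trained on. `sample_from_template()` is the
#' reverse map used at prediction time: template-node values are
#' interpolated back at each lead's registered disk location. Both maps are
#' linear in the potentials and exact on affine fields at interior points.
#'
#' @param coords Normalized `disk_coords` of the sock leads.
#' @param potentials Lead x time matrix (mV), rows ordered by `node_id`.
#' @param template An [build_template()] tibble.
#' @param seq Template x time matrix (165 rows with the default template).
#' @return `sample_to_template()`: a template x time matrix.
#'   `sample_from_template()`: a lead x time matrix.
#' @export
sample_to_template <- function(coords, potentials, template = build_template()) {
  pot <- as.matrix(potentials)
  if (nrow(pot) != nrow(coords)) {
    stop_epimap("shape-mismatch", "potentials have %d rows, coords %d leads",
                nrow(pot), nrow(coords))
  }
  itp <- scattered_interpolator(coords$u, coords$v)
  w <- interp_weights(itp, template$u, template$v)
  as.matrix(w %*% pot)
}

#' @rdname sample_to_template
#' @export
sample_from_template <- function(seq, template, coords) {
  seq <- as.matrix(seq)
  if (nrow(seq) != nrow(template)) {
    stop_epimap("shape-mismatch", "sequence has %d rows, template %d points",
                nrow(seq), nrow(template))
  }
  itp <- scattered_interpolator(template$u, template$v)
  w <- interp_weights(itp, coords$u, coords$v)
  as.matrix(w %*% seq)
}
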