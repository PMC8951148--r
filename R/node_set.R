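#' Electrode node sets
#'
#' A `node_set` is a tibble of electrode positions for one recording surface:
#' one row per lead with a dense zero-based `node_id`, Cartesian coordinates
#' `x`, `y`, `z` in millimetres, and a `surface` label (`"torso"` or
#' `"epicardium"`). It is the geometric half of every dataset: the 2D
#' registration stages (cylinder unwrapping for the torso, disk projection for
#' the epicardial sock) consume node sets and nothing else — the pipeline
#' never needs a surface mesh, only point locations.
#'
#' @param positions A numeric matrix or data frame with three columns
#'   (x, y, z) in mm, one row per lead.
#' @param surface `"torso"` or `"epicardium"`.
#' @param node_id Optional integer ids; defaults to `0:(n-1)`.
#'
#' @return A tibble of class `node_set` with columns `node_id`, `x`, `y`,
#'   `z`, `surface`.
#' @examples
#' geom <- node_set(cbind(x = rnorm(8), y = rnorm(8), z = rnorm(8)), "torso")
#' @export
node_set <- function(positions, surface = c("torso", "epicardium"),
                     node_id = NULL) {
  surface <- match.arg(surface)
  pos <- as.matrix(positions)
  if (ncol(pos) != 3L) {
    stop_epimap("shape-mismatch", "positions must have 3 columns, got %d", ncol(pos))
  }
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  if (is.null(node_id)) node_id <- seq_len(n) - 1L
  out <- tibble(
    node_id = as.integer(node_id),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    surface = surface
  )
  class(out) <- c("node_set", class(out))
  validate_node_set(out)
  out
}

#' Validate a node set
#'
#' Checks the `node_set` invariants: unique dense zero-based ids, finite
#' coordinates, and (for sets of 4 or more nodes) non-coplanarity, which the
#' downstream projections require.
#'
#' @param nodes A `node_set`.
#' @return `nodes`, invisibly, if valid; otherwise an error.
#' @export
validate_node_set <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  n <- nrow(nodes)
  if (n < 1L) stop_epimap("empty-geometry", "node set has no nodes")
  if (!identical(sort(nodes$node_id), seq_len(n) - 1L)) {
    stop_epimap("bad-node-ids", "node_ids must be dense 0..%d", n - 1L)
  }
  pos <- node_positions(nodes)
  if (!all(is.finite(pos))) stop_epimap("bad-geometry", "non-finite coordinates")
  if (n >= 4L) {
    centered <- sweep(pos, 2, colMeans(pos))
    if (qr(centered)$rank < 3L) {
      stop_epimap("bad-geometry", "nodes are coplanar; need at least 4 non-coplanar nodes")
    }
  }
  invisible(nodes)
}

#' Extract the coordinate matrix of a node set
#'
#' @param nodes A `node_set`.
#' @return An n x 3 numeric matrix (mm), rows ordered by `node_id`.
#' @export
node_positions <- function(nodes) {
  nodes <- nodes[order(nodes$node_id), ]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  pos
}

#' Mean nearest-neighbour spacing of a node set
#'
#' The average distance from each node to its closest neighbour, in mm. Used
#' as the natural length scale of an electrode array, e.g. to judge
#' pacing-site localization errors against the sock's own resolution.
#'
#' @param nodes A `node_set`.
#' @return A single number (mm).
#' @export
node_spacing <- function(nodes) {
  pos <- node_positions(nodes)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}
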