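# Scattered linear interpolation shared by both registration stages.
#
# "Bilinear interpolation" from scattered electrode locations is realized as
# barycentric-linear interpolation on a Delaunay triangulation of the 2D
# registered points (bilinear is undefined off a regular grid); query points
# outside the convex hull fall back to the nearest source point. Weights are
# assembled once into a sparse (queries x sources) matrix so interpolating a
# whole recording is a single sparse matmul — which also makes linearity in
# the potentials exact by construction, and exactness on affine fields an
# inherited property of barycentric coordinates.

#' Build a scattered-data linear interpolator
#'
#' Triangulates source points in a 2D plane (Delaunay) for barycentric-linear
#' interpolation. If `wrap_x` is given, the x coordinate is treated as
#' periodic with that period (used for the cylindrical torso angle, period
#' 360 degrees): the point set is replicated at x +/- `wrap_x` before
#' triangulation, so the interpolant is seamless across the wrap and
#' evaluating at x and x + `wrap_x` gives identical values.
#'
#' @param x,y Source point coordinates (one pair per lead).
#' @param wrap_x Optional period of the x axis.
#' @return An object of class `scattered_interp`.
#' @export
scattered_interpolator <- function(x, y, wrap_x = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop_epimap("degenerate-layout", "need at least 3 points, got %d", n)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_epimap("degenerate-layout", "non-finite registered coordinates")
  }
  if (is.null(wrap_x)) {
    xs <- x; ys <- y; src <- seq_len(n)
  } else {
    xs <- c(x, x - wrap_x, x + wrap_x)
    ys <- c(y, y, y)
    src <- rep(seq_len(n), 3L)
  }
  tm <- tryCatch(
    interp::tri.mesh(xs, ys),
    error = function(e) stop_epimap("degenerate-layout",
                                    "triangulation failed: %s", conditionMessage(e))
  )
  structure(
    list(tm = tm, x = x, y = y, n = n, src = src, wrap_x = wrap_x),
    class = "scattered_interp"
  )
}

#' Interpolation weight matrix at query points
#'
#' Returns the sparse matrix `W` (queries x sources) such that `W %*% v`
#' linearly interpolates per-source values `v` at the query locations. Rows
#' for queries inside the convex hull hold the three barycentric weights of
#' the enclosing Delaunay triangle (summing to 1); rows for outside queries
#' hold a single 1 at the nearest source point.
#'
#' @param itp A [scattered_interpolator()].
#' @param xq,yq Query coordinates.
#' @return A sparse `dgCMatrix` with `length(xq)` rows, rows summing to 1.
#' @export
interp_weights <- function(itp, xq, yq) {
  stopifnot(inherits(itp, "scattered_interp"), length(xq) == length(yq))
  q <- length(xq)
  if (!is.null(itp$wrap_x)) xq <- xq %% itp$wrap_x
  tf <- interp::tri.find(itp$tm, xq, yq)
  # trust the returned vertices whenever they define valid, essentially
  # non-negative barycentric coordinates: the walk can report tr = 0 for
  # points numerically on a hull edge while still returning the enclosing
  # triangle
  bc_min <- apply(tf$bc, 1, min)
  inside <- tf$i1 > 0 & tf$i2 > 0 & tf$i3 > 0 & bc_min > -1e-9
  rows <- integer(0); cols <- integer(0); vals <- double(0)
  if (any(inside)) {
    iv <- cbind(tf$i1[inside], tf$i2[inside], tf$i3[inside])
    bc <- tf$bc[inside, , drop = FALSE]
    # clip tiny negative weights from points numerically on an edge
    bc[bc < 0 & bc > -1e-9] <- 0
    bc <- bc / rowSums(bc)
    rows <- rep(which(inside), 3L)
    cols <- itp$src[as.vector(iv)]
    vals <- as.vector(bc)
  }
  if (any(!inside)) {
    out_idx <- which(!inside)
    nearest <- nearest_source(itp, xq[out_idx], yq[out_idx])
    rows <- c(rows, out_idx)
    cols <- c(cols, nearest)
    vals <- c(vals, rep(1, length(out_idx)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(q, itp$n))
}

nearest_source <- function(itp, xq, yq) {
  if (is.null(itp$wrap_x)) {
    dx <- outer(xq, itp$x, "-")
  } else {
    dx <- abs(outer(xq, itp$x, "-"))
    dx <- pmin(dx, itp$wrap_x - dx)
  }
  dy <- outer(yq, itp$y, "-")
  max.col(-(dx^2 + dy^2), ties.method = "first")
}

#' Evaluate a scattered interpolant
#'
#' Convenience wrapper around [interp_weights()]: interpolates one or more
#' value columns at query points.
#'
#' @param itp A [scattered_interpolator()].
#' @param values Numeric vector (one per source) or matrix (sources x k).
#' @param xq,yq Query coordinates.
#' @return A vector or matrix of interpolated values, `length(xq)` rows.
#' @export
interp_eval <- function(itp, values, xq, yq) {
  w <- interp_weights(itp, xq, yq)
  out <- as.matrix(w %*% as.matrix(values))
  if (is.null(dim(values)) || ncol(as.matrix(values)) == 1L) drop(out) else out
}
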