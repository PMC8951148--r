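# Convolutional inverse solver (Part II).
#
# Maps one registered 30 x 90 torso image to the 165-node epicardial
# template vector. Architecture: three blocks of [3x3 convolution, output
# depth `filters`, tanh, 2x2 average pooling], then a linear readout.
# Because image column 0 and column 89 are physically adjacent on the torso
# cylinder, convolutions pad circularly along the width (zero padding along
# the height).
#
# Layout: activations are (H*W*B) x C matrices, rows pixel-fastest then
# image — the column-major flattening of an (H, W, B) array — so im2col
# needs no transposes. The gather/scatter hot loops live in src/conv.cpp;
# everything else is BLAS.

# Per-offset gather table for one layer at input size (H, W): spix[p, o]
# is the 1-based source pixel read by kernel offset o at output pixel p
# (0 = zero pad). Circular width padding is resolved here once.
conv_geom <- function(H, W, circular) {
  i <- rep(seq_len(H), times = W); j <- rep(seq_len(W), each = H)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  spix <- matrix(0L, H * W, 9L)
  for (o in seq_len(9L)) {
    sr <- i + offs$di[o]; sc <- j + offs$dj[o]
    if (circular) sc <- ((sc - 1L) %% W) + 1L
    ok <- sr >= 1L & sr <= H & sc >= 1L & sc <= W
    spix[ok, o] <- sr[ok] + (sc[ok] - 1L) * H
  }
  list(H = H, W = W, spix = spix)
}

# 2x2 average pooling, stride 2, floor (trailing odd row/col dropped).
pool_geom <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo); jo <- rep(seq_len(Wo), each = Ho)
  i1 <- 2L * io - 1L; j1 <- 2L * jo - 1L
  list(Ho = Ho, Wo = Wo,
       idx = cbind(i1 + (j1 - 1L) * H, i1 + 1L + (j1 - 1L) * H,
                   i1 + j1 * H, i1 + 1L + j1 * H))
}

pool_batch_idx <- function(pg, HW, B) {
  boff <- rep(seq_len(B) - 1L, each = pg$Ho * pg$Wo) * HW
  lapply(1:4, function(k) rep.int(pg$idx[, k], B) + boff)
}

pool_forward <- function(A, pg, HW, B) {
  gi <- pool_batch_idx(pg, HW, B)
  (A[gi[[1]], , drop = FALSE] + A[gi[[2]], , drop = FALSE] +
     A[gi[[3]], , drop = FALSE] + A[gi[[4]], , drop = FALSE]) / 4
}

pool_backward <- function(dP, pg, HW, B) {
  dA <- matrix(0, HW * B, ncol(dP))
  gi <- pool_batch_idx(pg, HW, B)
  g <- dP / 4
  for (k in 1:4) dA[gi[[k]], ] <- g
  dA
}

cnn_geoms <- function(spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  out <- vector("list", 3L)
  for (l in 1:3) {
    cg <- conv_geom(H, W, spec$circular)
    pg <- pool_geom(H, W)
    out[[l]] <- list(conv = cg, pool = pg, C_in = if (l == 1L) 1L else spec$filters)
    H <- pg$Ho; W <- pg$Wo
  }
  attr(out, "flat") <- H * W * spec$filters
  attr(out, "final_hw") <- c(H, W)
  out
}

cnn_init <- function(spec, geoms) {
  params <- list()
  for (l in 1:3) {
    C_in <- geoms[[l]]$C_in
    params[[paste0("K", l)]] <- glorot(9L * C_in, spec$filters,
                                       c(9L * C_in, spec$filters))
    params[[paste0("bk", l)]] <- rep(0, spec$filters)
  }
  params$Wd <- glorot(attr(geoms, "flat"), spec$output_shape)
  params$bd <- rep(0, spec$output_shape)
  params
}

# X: (H, W, B) array. Returns B x out predictions; with keep_cache also the
# intermediates for backprop, including each layer's pre-pooling
# convolution output `conv` as an (H*W*B) x F matrix.
cnn_forward <- function(params, X, spec, geoms = NULL, keep_cache = FALSE) {
  if (is.null(geoms)) geoms <- cnn_geoms(spec)
  d <- dim(X)
  B <- d[3]
  A <- matrix(X, d[1] * d[2] * B, 1L)
  cache <- if (keep_cache) list(inputs = list(), act = list(), conv = list()) else NULL
  for (l in 1:3) {
    g <- geoms[[l]]
    Z <- conv_fwd_cpp(A, g$conv$spix, B, params[[paste0("K", l)]],
                      params[[paste0("bk", l)]])
    act <- tanh(Z)
    if (keep_cache) {
      cache$inputs[[l]] <- A; cache$conv[[l]] <- Z; cache$act[[l]] <- act
    }
    A <- pool_forward(act, g$pool, g$conv$H * g$conv$W, B)
  }
  # dense readout: per-image flatten in (pixel, channel) order
  fhw <- attr(geoms, "final_hw"); npix <- prod(fhw)
  flat <- matrix(aperm(array(A, c(npix, B, spec$filters)), c(1L, 3L, 2L)),
                 npix * spec$filters, B)
  Y <- sweep(crossprod(flat, params$Wd), 2, params$bd, "+")
  if (keep_cache) {
    cache$flat <- flat; cache$B <- B; cache$geoms <- geoms
    list(Y = Y, cache = cache)
  } else {
    list(Y = Y)
  }
}

cnn_backward <- function(params, fw, dY, spec) {
  cache <- fw$cache
  geoms <- cache$geoms
  B <- cache$B
  grads <- list()
  grads$Wd <- cache$flat %*% dY
  grads$bd <- colSums(dY)
  dFlat <- params$Wd %*% t(dY) # (npix*filters) x B
  fhw <- attr(geoms, "final_hw"); npix <- prod(fhw)
  dPool <- matrix(aperm(array(dFlat, c(npix, spec$filters, B)), c(1L, 3L, 2L)),
                  npix * B, spec$filters)
  for (l in 3:1) {
    g <- geoms[[l]]
    HW <- g$conv$H * g$conv$W
    dAct <- pool_backward(dPool, g$pool, HW, B)
    dZ <- dAct * (1 - cache$act[[l]]^2)
    cb <- conv_bwd_cpp(dZ, cache$inputs[[l]], params[[paste0("K", l)]],
                       g$conv$spix, B)
    grads[[paste0("K", l)]] <- cb$dK
    grads[[paste0("bk", l)]] <- as.vector(cb$db)
    if (l > 1L) dPool <- cb$dA
  }
  grads
}

#' Train the convolutional inverse solver
#'
#' Learns the map from one registered torso image (30 x 90 by default) to
#' the 165-node epicardial template vector at the same time step. Training
#' frames from all training recordings are pooled and consumed in seeded
#' random minibatches.
#'
#' @param frames Array `(height, width, n_frames)` of torso images (mV).
#' @param targets Matrix `n_frames x output` of template potentials (mV).
#' @param spec A [model_spec()] with `kind = "cnn"`; built from the data
#'   shapes if omitted.
#' @return An `epimap_model`.
#' @export
train_cnn <- function(frames, targets, spec = NULL) {
  d <- dim(frames)
  stopifnot(length(d) == 3L)
  targets <- as.matrix(targets)
  if (d[3] != nrow(targets)) stop_epimap("shape-mismatch", "frame/target counts differ")
  if (is.null(spec)) spec <- model_spec("cnn", d[1:2], ncol(targets))
  if (!identical(as.integer(d[1:2]), spec$input_shape)) {
    stop_epimap("shape-mismatch", "frames are %dx%d, spec expects %s",
                d[1], d[2], paste(spec$input_shape, collapse = "x"))
  }
  if (ncol(targets) != spec$output_shape) {
    stop_epimap("shape-mismatch", "targets have %d nodes, spec expects %d",
                ncol(targets), spec$output_shape)
  }
  # frames share one physical unit -> one global scale; targets per node
  x_sc <- if (spec$standardize) {
    list(mu = mean(frames), sd = max(sd(frames), 1e-8))
  } else list(mu = 0, sd = 1)
  y_sc <- if (spec$standardize) make_scaler(targets) else identity_scaler(ncol(targets))
  Xs <- (frames - x_sc$mu) / x_sc$sd
  Ys <- scale_apply(targets, y_sc)
  bs <- spec$batch_size %||% 32L
  n <- d[3]
  geoms <- cnn_geoms(spec)
  with_seed(spec$seed, {
    params <- cnn_init(spec, geoms)
    opt <- adam_init(params)
    history <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      total <- 0
      for (s in seq(1L, n, by = bs)) {
        idx <- perm[s:min(s + bs - 1L, n)]
        fw <- cnn_forward(params, Xs[, , idx, drop = FALSE], spec, geoms,
                          keep_cache = TRUE)
        resid <- fw$Y - Ys[idx, , drop = FALSE]
        total <- total + sum(resid^2)
        grads <- cnn_backward(params, fw, 2 * resid / length(resid), spec)
        st <- adam_step(opt, params, grads, spec$lr, spec$weight_decay)
        opt <- st$state; params <- st$params
      }
      history[ep] <- total / (n * spec$output_shape)
    }
    new_epimap_model(spec, params, list(x = x_sc, y = y_sc), history)
  })
}

predict_cnn <- function(model, frames, chunk = 64L) {
  d <- dim(frames)
  if (length(d) == 2L) { frames <- array(frames, c(d, 1L)); d <- dim(frames) }
  if (!identical(as.integer(d[1:2]), model$spec$input_shape)) {
    stop_epimap("shape-mismatch", "frames are %dx%d, model expects %s",
                d[1], d[2], paste(model$spec$input_shape, collapse = "x"))
  }
  geoms <- cnn_geoms(model$spec)
  Xs <- (frames - model$scalers$x$mu) / model$scalers$x$sd
  out <- matrix(0, d[3], model$spec$output_shape)
  for (s in seq(1L, d[3], by = chunk)) {
    idx <- s:min(s + chunk - 1L, d[3])
    out[idx, ] <- cnn_forward(model$params, Xs[, , idx, drop = FALSE],
                              model$spec, geoms)$Y
  }
  scale_invert(out, model$scalers$y)
}

# Reshape one cached pre-pooling convolution output back to (H, W, F, B),
# for inspection (e.g. the circular shift-equivariance contract).
conv_feature_array <- function(convmat, geom, B) {
  F_out <- ncol(convmat)
  aperm(array(convmat, c(geom$H, geom$W, B, F_out)), c(1L, 2L, 4L, 3L))
}
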