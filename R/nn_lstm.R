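# LSTM inverse solver (Part I, sequence variant).
#
# Consumes a whole electrogram cycle as a sequence: at each time step the
# recurrent state integrates the torso potentials seen so far and a linear
# readout emits the epicardial vector. State carries across time steps
# within a recording and resets between recordings. Standard LSTM cell
# (gates i, f, o, candidate g), trained by backpropagation through time
# with one Adam step per recording per epoch.

lstm_init <- function(p, h, q) {
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1 # forget-gate bias: remember by default
  list(
    Wx = glorot(p, 4 * h, c(p, 4 * h)),
    Wh = glorot(h, 4 * h, c(h, 4 * h)),
    b = b,
    Wy = glorot(h, q, c(h, q)),
    by = rep(0, q)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: T x p. Returns caches needed for BPTT.
lstm_forward <- function(params, x) {
  h_dim <- nrow(params$Wh)
  Tn <- nrow(x)
  Xz <- x %*% params$Wx
  H <- matrix(0, Tn, h_dim); C <- matrix(0, Tn, h_dim)
  G <- array(0, c(Tn, h_dim, 4L)) # i, f, o, g
  h_prev <- rep(0, h_dim); c_prev <- rep(0, h_dim)
  idx <- list(1:h_dim, (h_dim + 1):(2 * h_dim), (2 * h_dim + 1):(3 * h_dim),
              (3 * h_dim + 1):(4 * h_dim))
  for (t in seq_len(Tn)) {
    z <- Xz[t, ] + as.vector(h_prev %*% params$Wh) + params$b
    i <- sigmoid(z[idx[[1]]]); f <- sigmoid(z[idx[[2]]])
    o <- sigmoid(z[idx[[3]]]); g <- tanh(z[idx[[4]]])
    c_t <- f * c_prev + i * g
    h_t <- o * tanh(c_t)
    G[t, , 1] <- i; G[t, , 2] <- f; G[t, , 3] <- o; G[t, , 4] <- g
    C[t, ] <- c_t; H[t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  Y <- sweep(H %*% params$Wy, 2, params$by, "+")
  list(Y = Y, H = H, C = C, G = G, x = x)
}

lstm_backward <- function(params, cache, dY) {
  h_dim <- nrow(params$Wh)
  Tn <- nrow(cache$x)
  grads <- lapply(params, function(p) p * 0)
  grads$Wy <- crossprod(cache$H, dY)
  grads$by <- colSums(dY)
  dH_out <- dY %*% t(params$Wy)
  dh_next <- rep(0, h_dim); dc_next <- rep(0, h_dim)
  for (t in rev(seq_len(Tn))) {
    i <- cache$G[t, , 1]; f <- cache$G[t, , 2]
    o <- cache$G[t, , 3]; g <- cache$G[t, , 4]
    c_t <- cache$C[t, ]
    c_prev <- if (t > 1L) cache$C[t - 1L, ] else rep(0, h_dim)
    h_prev <- if (t > 1L) cache$H[t - 1L, ] else rep(0, h_dim)
    dh <- dH_out[t, ] + dh_next
    tc <- tanh(c_t)
    do <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; df <- dc * c_prev; dg <- dc * i
    dc_next <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f), do * o * (1 - o), dg * (1 - g^2))
    grads$Wx <- grads$Wx + outer(cache$x[t, ], dz)
    grads$Wh <- grads$Wh + outer(h_prev, dz)
    grads$b <- grads$b + dz
    dh_next <- as.vector(params$Wh %*% dz)
  }
  grads
}

#' Train the LSTM inverse solver
#'
#' @param x_seqs List of torso sequences, each a time x torso-leads matrix
#'   (one per training recording).
#' @param y_seqs List of matching heart sequences (time x heart-leads).
#' @param spec A [model_spec()] with `kind = "lstm"`; built from the data
#'   shapes if omitted. Sequences may differ in length; each recording is
#'   its own batch.
#' @return An `epimap_model`.
#' @export
train_lstm <- function(x_seqs, y_seqs, spec = NULL) {
  stopifnot(is.list(x_seqs), is.list(y_seqs), length(x_seqs) == length(y_seqs),
            length(x_seqs) >= 1L)
  x_seqs <- lapply(x_seqs, as.matrix)
  y_seqs <- lapply(y_seqs, as.matrix)
  p <- ncol(x_seqs[[1]]); q <- ncol(y_seqs[[1]])
  if (any(vapply(x_seqs, ncol, integer(1)) != p) ||
      any(vapply(y_seqs, ncol, integer(1)) != q)) {
    stop_epimap("shape-mismatch", "inconsistent lead counts across recordings")
  }
  if (is.null(spec)) spec <- model_spec("lstm", p, q)
  if (p != spec$input_shape || q != spec$output_shape) {
    stop_epimap("shape-mismatch", "sequences are %d -> %d, spec expects %d -> %d",
                p, q, spec$input_shape, spec$output_shape)
  }
  scalers <- if (spec$standardize) {
    list(x = make_scaler(do.call(rbind, x_seqs)), y = make_scaler(do.call(rbind, y_seqs)))
  } else {
    list(x = identity_scaler(p), y = identity_scaler(q))
  }
  xs <- lapply(x_seqs, scale_apply, sc = scalers$x)
  ys <- lapply(y_seqs, scale_apply, sc = scalers$y)
  with_seed(spec$seed, {
    params <- lstm_init(p, spec$lstm_units, q)
    opt <- adam_init(params)
    history <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      total <- 0; n_obs <- 0
      for (r in seq_along(xs)) {
        cache <- lstm_forward(params, xs[[r]])
        resid <- cache$Y - ys[[r]]
        total <- total + sum(resid^2); n_obs <- n_obs + length(resid)
        grads <- lstm_backward(params, cache, 2 * resid / length(resid))
        st <- adam_step(opt, params, grads, spec$lr, spec$weight_decay)
        opt <- st$state; params <- st$params
      }
      history[ep] <- total / n_obs
    }
    new_epimap_model(spec, params, scalers, history)
  })
}

predict_lstm <- function(model, x_seq) {
  x_seq <- as.matrix(x_seq)
  if (ncol(x_seq) != model$spec$input_shape) {
    stop_epimap("shape-mismatch", "sequence has %d leads, model expects %d",
                ncol(x_seq), model$spec$input_shape)
  }
  xs <- scale_apply(x_seq, model$scalers$x)
  cache <- lstm_forward(model$params, xs)
  scale_invert(cache$Y, model$scalers$y)
}
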