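# Fully connected inverse solver (Part I).
#
# One time step of body-surface potentials in, one vector of epicardial
# potentials out: hidden tanh layers, linear readout, full-batch Adam on
# MSE. The per-time-step framing treats each sample of each training
# recording as one observation.

mlp_init <- function(sizes) {
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- glorot(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, x) {
  n_layers <- length(params) / 2L
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params[[paste0("W", l)]]
    z <- sweep(z, 2, params[[paste0("b", l)]], "+")
    acts[[l + 1L]] <- if (l < n_layers) tanh(z) else z
  }
  acts
}

mlp_backward <- function(params, acts, dy) {
  n_layers <- length(params) / 2L
  grads <- list()
  delta <- dy
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (1 - acts[[l]]^2)
    }
  }
  grads
}

#' Train the fully connected inverse solver
#'
#' Learns a map from one time step of torso potentials (a vector over that
#' subject's vest leads) to the simultaneous 239-lead epicardial potential
#' vector. Rows of `x` and `y` are paired time steps pooled over the
#' training recordings.
#'
#' @param x Samples x torso-leads matrix (mV).
#' @param y Samples x heart-leads matrix (mV).
#' @param spec A [model_spec()] with `kind = "fcn"`; a default is built from
#'   the data shapes if omitted.
#' @return An `epimap_model`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x %*% matrix(rnorm(12), 4, 3)
#' m <- train_fcn(x, y, model_spec("fcn", 4, 3, hidden = 8, epochs = 50))
#' @export
train_fcn <- function(x, y, spec = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_epimap("shape-mismatch", "x and y row counts differ")
  if (is.null(spec)) spec <- model_spec("fcn", ncol(x), ncol(y))
  if (ncol(x) != spec$input_shape) {
    stop_epimap("shape-mismatch", "input has %d leads, spec expects %d",
                ncol(x), spec$input_shape)
  }
  if (ncol(y) != spec$output_shape) {
    stop_epimap("shape-mismatch", "target has %d leads, spec expects %d",
                ncol(y), spec$output_shape)
  }
  scalers <- if (spec$standardize) {
    list(x = make_scaler(x), y = make_scaler(y))
  } else {
    list(x = identity_scaler(ncol(x)), y = identity_scaler(ncol(y)))
  }
  xs <- scale_apply(x, scalers$x)
  ys <- scale_apply(y, scalers$y)
  sizes <- c(spec$input_shape, spec$hidden, spec$output_shape)
  n <- nrow(xs)
  bs <- min(spec$batch_size %||% n, n)
  with_seed(spec$seed, {
    params <- mlp_init(sizes)
    opt <- adam_init(params)
    history <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      # step decay: drop the learning rate late in training so the last
      # epochs refine rather than oscillate
      lr <- spec$lr * if (ep > 0.85 * spec$epochs) 0.1 else
        if (ep > 0.6 * spec$epochs) 0.3 else 1
      perm <- if (bs < n) sample.int(n) else seq_len(n)
      total <- 0
      for (s in seq(1L, n, by = bs)) {
        idx <- perm[s:min(s + bs - 1L, n)]
        acts <- mlp_forward(params, xs[idx, , drop = FALSE])
        resid <- acts[[length(acts)]] - ys[idx, , drop = FALSE]
        total <- total + sum(resid^2)
        grads <- mlp_backward(params, acts, 2 * resid / length(resid))
        st <- adam_step(opt, params, grads, lr, spec$weight_decay)
        opt <- st$state; params <- st$params
      }
      history[ep] <- total / (n * spec$output_shape)
    }
    new_epimap_model(spec, params, scalers, history)
  })
}

predict_fcn <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$spec$input_shape) {
    stop_epimap("shape-mismatch", "input has %d leads, model expects %d",
                ncol(x), model$spec$input_shape)
  }
  xs <- scale_apply(x, model$scalers$x)
  acts <- mlp_forward(model$params, xs)
  scale_invert(acts[[length(acts)]], model$scalers$y)
}
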