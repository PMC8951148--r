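# Native neural-network engine.
#
# The inverse solvers are small networks trained with Adam on mean squared
# error. They are implemented directly with dense matrix algebra — the
# architectures are small enough (a few hundred units, depth-32 feature
# maps) that BLAS-backed R is entirely adequate, and a native implementation
# keeps training bit-reproducible from a seed.

#' Model specification
#'
#' Declares one inverse solver's architecture and training hyperparameters.
#' Fixed architectural commitments: hyperbolic-tangent activations
#' throughout; the CNN has three convolution layers of output depth
#' `filters` with average pooling after each; the readout layers are linear.
#' Layer widths, epochs, and learning rate are tunable.
#'
#' @param kind `"fcn"`, `"lstm"` or `"cnn"`.
#' @param input_shape Input size: lead count (fcn/lstm) or `c(30, 90)`
#'   image shape (cnn).
#' @param output_shape Output vector length (239 sock leads for Part I,
#'   165 template nodes for Part II).
#' @param hidden Hidden-layer widths of the FCN. Default `c(256, 256)`.
#' @param lstm_units Recurrent state width. Default 128.
#' @param filters CNN feature depth per convolution layer. Default 32.
#' @param kernel Convolution kernel size. Default 3.
#' @param epochs Training epochs. Default 500.
#' @param lr Adam learning rate. Default 1e-3.
#' @param weight_decay Decoupled L2 weight decay applied to weight
#'   matrices (not biases). Regularizes the inverse map the way ridge
#'   regression does its linear analogue. Default 0.
#' @param batch_size Minibatch size for the CNN (frames); `NULL` = 32. FCN
#'   trains full-batch, the LSTM per recording.
#' @param circular Circularly pad the CNN along the image width (the torso
#'   angle axis, where column 0 and column 89 are physically adjacent).
#'   Default TRUE.
#' @param standardize Standardize inputs and targets to zero mean / unit
#'   variance over the training set (inverted at prediction). Needed to keep
#'   tanh units out of saturation. Default TRUE.
#' @param seed RNG seed for initialization and batch order.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("fcn", "lstm", "cnn"),
                       input_shape, output_shape,
                       hidden = c(256L, 256L), lstm_units = 128L,
                       filters = 32L, kernel = 3L,
                       epochs = 500L, lr = 1e-3, weight_decay = 0,
                       batch_size = NULL,
                       circular = TRUE, standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, input_shape = as.integer(input_shape),
         output_shape = as.integer(output_shape),
         hidden = as.integer(hidden), lstm_units = as.integer(lstm_units),
         filters = as.integer(filters), kernel = as.integer(kernel),
         epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
         batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
         circular = isTRUE(circular), standardize = isTRUE(standardize),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -s, s), dim = dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    step <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    # decoupled weight decay on weight matrices only (not bias vectors)
    if (weight_decay > 0 && is.matrix(params[[k]])) {
      step <- step + weight_decay * params[[k]]
    }
    params[[k]] <- params[[k]] - lr * step
  }
  list(state = state, params = params)
}

# Column-wise standardizer with a variance floor for constant channels.
make_scaler <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s < 1e-8] <- 1
  list(mu = mu, sd = s)
}

scale_apply <- function(m, sc) sweep(sweep(m, 2, sc$mu), 2, sc$sd, "/")
scale_invert <- function(m, sc) sweep(sweep(m, 2, sc$sd, "*"), 2, sc$mu, "+")

identity_scaler <- function(k) list(mu = rep(0, k), sd = rep(1, k))

new_epimap_model <- function(spec, params, scalers, history) {
  structure(
    list(spec = spec, params = params, scalers = scalers,
         history = tibble(epoch = seq_along(history), loss = history)),
    class = c(paste0("epimap_", spec$kind), "epimap_model")
  )
}

#' @export
print.epimap_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<epimap_model %s: %s -> %d, %d parameters, %d epochs, final loss %.3g>\n",
              x$spec$kind, paste(x$spec$input_shape, collapse = "x"),
              x$spec$output_shape, n_par, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Tidy and glance methods for trained models
#'
#' `tidy()` returns the per-epoch training loss (MSE in standardized units);
#' `glance()` a one-row summary.
#'
#' @param x An `epimap_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.epimap_model <- function(x, ...) x$history

#' @rdname tidy.epimap_model
#' @export
glance.epimap_model <- function(x, ...) {
  tibble(kind = x$spec$kind,
         n_parameters = sum(vapply(x$params, length, integer(1))),
         epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         lr = x$spec$lr, seed = x$spec$seed)
}
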