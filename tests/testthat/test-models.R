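test_that("the FCN learns an exact linear map to held-out CC >= 0.99", {
  withr::with_seed(1, {
    X <- matrix(rnorm(300 * 6), 300, 6)
    B <- matrix(rnorm(24), 6, 4)
    Y <- X %*% B
    spec <- model_spec("fcn", 6, 4, hidden = c(32, 32), epochs = 600,
                       lr = 3e-3, seed = 2)
    m <- train_fcn(X[1:250, ], Y[1:250, ], spec)
    P <- predict(m, X[251:300, ])
    ccs <- vapply(1:4, function(j) cor(P[, j], Y[251:300, j]), numeric(1))
    expect_gte(median(ccs), 0.99)
    # training loss fell below 1% of (unit) target variance
    expect_lt(tail(m$history$loss, 1), 0.01)
  })
})

test_that("the FCN memorizes a single repeated pair", {
  x <- matrix(rep(c(1, 2, 3), 40), 40, 3, byrow = TRUE)
  y <- matrix(rep(c(5, -1), 40), 40, 2, byrow = TRUE)
  m <- train_fcn(x, y, model_spec("fcn", 3, 2, hidden = 8, epochs = 200, seed = 1))
  expect_lt(max(abs(predict(m, x[1:2, ]) -
                      matrix(c(5, -1), 2, 2, byrow = TRUE))), 0.05)
})

test_that("model training validates lead counts", {
  x <- matrix(rnorm(40), 10, 4); y <- matrix(rnorm(30), 10, 3)
  spec <- model_spec("fcn", 5, 3, epochs = 1)
  expect_error(train_fcn(x, y, spec), class = "epimap_shape_mismatch")
  m <- train_fcn(x, y, model_spec("fcn", 4, 3, hidden = 4, epochs = 2))
  expect_error(predict(m, x[, 1:3]), class = "epimap_shape_mismatch")
  expect_error(train_lstm(list(x), list(y), model_spec("lstm", 9, 3, epochs = 1)),
               class = "epimap_shape_mismatch")
  expect_error(
    train_lstm(list(x, x[, 1:3]), list(y, y), model_spec("lstm", 4, 3, epochs = 1)),
    class = "epimap_shape_mismatch"
  )
})

test_that("the LSTM learns a per-step linear map on sequences", {
  withr::with_seed(2, {
    xs <- lapply(1:5, function(i) matrix(rnorm(40 * 5), 40, 5))
    B <- matrix(rnorm(15), 5, 3)
    ys <- lapply(xs, function(x) x %*% B)
    spec <- model_spec("lstm", 5, 3, lstm_units = 16, epochs = 300, seed = 3)
    m <- train_lstm(xs[1:4], ys[1:4], spec)
    P <- predict(m, xs[[5]])
    ccs <- vapply(1:3, function(j) cor(P[, j], ys[[5]][, j]), numeric(1))
    expect_gte(median(ccs), 0.99)
  })
})

test_that("the LSTM handles degenerate and mixed-length sequences", {
  withr::with_seed(3, {
    xs <- list(matrix(rnorm(10), 2, 5), matrix(rnorm(35), 7, 5))
    ys <- lapply(xs, function(x) x[, 1:2])
    m <- train_lstm(xs, ys, model_spec("lstm", 5, 2, lstm_units = 4, epochs = 2))
    # a length-1 sequence degenerates to a feed-forward map
    p1 <- predict(m, matrix(rnorm(5), 1, 5))
    expect_equal(dim(p1), c(1L, 2L))
    expect_true(all(is.finite(p1)))
  })
})

test_that("the CNN maps frames to template vectors and checks shapes", {
  withr::with_seed(4, {
    n <- 30
    X <- array(rnorm(12 * 16 * n), c(12, 16, n))
    Y <- matrix(rnorm(n * 7), n, 7)
    spec <- model_spec("cnn", c(12, 16), 7, filters = 4, epochs = 3, seed = 1)
    m <- train_cnn(X, Y, spec)
    P <- predict(m, X)
    expect_equal(dim(P), c(n, 7L))
    expect_error(predict(m, array(0, c(10, 16, 2))), class = "epimap_shape_mismatch")
    expect_error(train_cnn(X, Y[1:5, ], spec), class = "epimap_shape_mismatch")
    expect_error(train_cnn(X, cbind(Y, 1), spec), class = "epimap_shape_mismatch")
  })
})

test_that("all-zero frames and targets train to near-zero output", {
  X <- array(0, c(12, 16, 8))
  Y <- matrix(0, 8, 3)
  spec <- model_spec("cnn", c(12, 16), 3, filters = 2, epochs = 1, seed = 2,
                     standardize = FALSE)
  m <- train_cnn(X, Y, spec)
  expect_lt(max(abs(predict(m, X))), 1e-3)
})

test_that("CNN convolutions are equivariant to cyclic width shifts", {
  withr::with_seed(5, {
    spec <- model_spec("cnn", c(12, 16), 5, filters = 3, standardize = FALSE)
    geoms <- epimap:::cnn_geoms(spec)
    params <- epimap:::cnn_init(spec, geoms)
    X1 <- array(rnorm(12 * 16), c(12, 16, 1))
    for (k in c(1, 5, 9)) {
      X2 <- array(X1[, c((k + 1):16, 1:k), , drop = FALSE], c(12, 16, 1))
      f1 <- epimap:::cnn_forward(params, X1, spec, geoms, keep_cache = TRUE)$cache$conv[[1]]
      f2 <- epimap:::cnn_forward(params, X2, spec, geoms, keep_cache = TRUE)$cache$conv[[1]]
      a1 <- epimap:::conv_feature_array(f1, geoms[[1]]$conv, 1)
      a2 <- epimap:::conv_feature_array(f2, geoms[[1]]$conv, 1)
      expect_equal(a1[, c((k + 1):16, 1:k), , , drop = FALSE], a2,
                   tolerance = 1e-12)
    }
  })
})

test_that("CNN gradients match finite differences", {
  withr::with_seed(6, {
    spec <- model_spec("cnn", c(10, 12), 4, filters = 3, standardize = FALSE)
    geoms <- epimap:::cnn_geoms(spec)
    params <- epimap:::cnn_init(spec, geoms)
    X <- array(rnorm(10 * 12 * 2), c(10, 12, 2))
    Y <- matrix(rnorm(8), 2, 4)
    loss <- function(p) mean((epimap:::cnn_forward(p, X, spec, geoms)$Y - Y)^2)
    fw <- epimap:::cnn_forward(params, X, spec, geoms, keep_cache = TRUE)
    grads <- epimap:::cnn_backward(params, fw, 2 * (fw$Y - Y) / length(Y), spec)
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        eps <- 1e-6
        p <- params
        p[[nm]][i] <- params[[nm]][i] + eps; up <- loss(p)
        p[[nm]][i] <- params[[nm]][i] - eps; dn <- loss(p)
        num <- (up - dn) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("prediction is pure and batches equal stacked single calls", {
  withr::with_seed(7, {
    x <- matrix(rnorm(60), 15, 4)
    y <- x %*% matrix(rnorm(8), 4, 2)
    m <- train_fcn(x, y, model_spec("fcn", 4, 2, hidden = 8, epochs = 20, seed = 1))
    expect_identical(predict(m, x), predict(m, x))
    stacked <- do.call(rbind, lapply(seq_len(5), function(i) predict(m, x[i, , drop = FALSE])))
    expect_equal(stacked, predict(m, x[1:5, ]), tolerance = 1e-12)

    X <- array(rnorm(12 * 16 * 4), c(12, 16, 4))
    mc <- train_cnn(X, matrix(rnorm(12), 4, 3),
                    model_spec("cnn", c(12, 16), 3, filters = 2, epochs = 2, seed = 1))
    per <- do.call(rbind, lapply(1:4, function(i) predict(mc, X[, , i])))
    expect_equal(per, predict(mc, X), tolerance = 1e-12)
  })
})

test_that("training is bit-reproducible from the seed", {
  withr::with_seed(8, {
    x <- matrix(rnorm(200), 50, 4)
    y <- x %*% matrix(rnorm(12), 4, 3)
  })
  spec <- model_spec("fcn", 4, 3, hidden = 8, epochs = 30, batch_size = 16, seed = 7)
  m1 <- train_fcn(x, y, spec)
  m2 <- train_fcn(x, y, spec)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)

  X <- array(rnorm(12 * 16 * 6), c(12, 16, 6))
  Y <- matrix(rnorm(18), 6, 3)
  cspec <- model_spec("cnn", c(12, 16), 3, filters = 2, epochs = 3, seed = 5)
  expect_identical(train_cnn(X, Y, cspec)$history$loss,
                   train_cnn(X, Y, cspec)$history$loss)
})

test_that("tidy and glance expose the training history", {
  x <- matrix(rnorm(40), 10, 4); y <- matrix(rnorm(20), 10, 2)
  m <- train_fcn(x, y, model_spec("fcn", 4, 2, hidden = 4, epochs = 5, seed = 1))
  tt <- tidy(m)
  expect_equal(nrow(tt), 5L)
  expect_named(tt, c("epoch", "loss"))
  g <- glance(m)
  expect_equal(g$epochs, 5L)
  expect_equal(g$final_loss, tt$loss[5])
})
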