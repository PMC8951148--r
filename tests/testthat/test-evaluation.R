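test_that("electrogram correlation has the Pearson identities", {
  withr::with_seed(1, {
    v <- rnorm(50)
    expect_equal(cc_time(v, v), 1)
    expect_equal(cc_time(v, -v), -1)
    expect_equal(cc_time(v, 2 * v + 3), 1)
    expect_true(is.na(cc_time(v, rep(1, 50))))
    expect_true(is.na(cc_time(rep(0, 50), v)))
  })
})

test_that("activation_time finds the steepest one-step drop", {
  # single-step drop between samples 1 and 2 (zero-based), reported at t = 1
  expect_equal(activation_time(c(1, 1, 0, 0), dt = 0.5), 0.5)
  # constant series: all drops tie at 0, earliest index wins
  expect_equal(activation_time(rep(2, 10), dt = 0.5), 0)
  # monotone increasing: least-negative drop at the flattest step (t = 1)
  expect_equal(activation_time(c(0, 3, 3.1, 10), dt = 0.5), 0.5)
  # invariance to offset and positive scale
  withr::with_seed(2, {
    v <- cumsum(rnorm(40))
    expect_equal(activation_time(v), activation_time(5 * v + 11))
  })
  # brute-force scan oracle on a smooth downstroke waveform
  tgrid <- seq(0, 60, by = 0.5)
  wf <- list(a_r = 20, a_q = 13, tau_d = 2.5, tau_r = 4, delta = 6,
             rec_delay = 30, tau_rec = 12)
  v <- epimap:::electrogram_waveform(tgrid, 23.2, wf)
  drops <- -(v[-1] - v[-length(v)])
  expect_equal(activation_time(v, dt = 0.5), (which.max(drops) - 1) * 0.5)
})

test_that("activation_map flags the earliest node with low-index ties", {
  pot <- rbind(c(5, 5, 5, 0, 0), # drop at t=2
               c(5, 0, 0, 0, 0), # drop at t=0
               c(5, 5, 0, 0, 0), # drop at t=1
               c(5, 0, 0, 0, 0)) # tie with lead 1 -> lead 1 wins
  m <- activation_map(pot, dt = 0.5)
  expect_equal(m$at_ms, c(1, 0, 0.5, 0))
  expect_identical(earliest_node(m), 1L)
})

test_that("activation-map correlation matches a direct computation", {
  withr::with_seed(3, {
    a <- runif(30, 0, 50); b <- a + rnorm(30, 0, 5)
    ma <- tibble::tibble(node_id = 0:29, at_ms = a)
    mb <- tibble::tibble(node_id = 0:29, at_ms = b)
    class(ma) <- c("activation_map", class(ma))
    class(mb) <- c("activation_map", class(mb))
    # brute-force Pearson from sums
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cc_activation(ma, mb), num / den)
    expect_equal(cc_activation(ma, ma), 1)
    expect_equal(cc_activation(ma, tibble::tibble(at_ms = 2 * a + 1)), 1)
    expect_true(is.na(cc_activation(ma, tibble::tibble(at_ms = rep(1, 30)))))
  })
})

test_that("localization_error is the distance between earliest nodes", {
  geom <- node_set(rbind(c(0, 0, 0), c(3, 4, 0), c(10, 10, 10), c(0, 5, 2)),
                   "epicardium")
  m1 <- activation_map(rbind(c(5, 0, 0), c(5, 5, 0), c(5, 5, 5), c(5, 5, 0)))
  m2 <- activation_map(rbind(c(5, 5, 0), c(5, 0, 0), c(5, 5, 5), c(5, 5, 0)))
  expect_equal(earliest_node(m1), 0L)
  expect_equal(earliest_node(m2), 1L)
  expect_equal(localization_error(m1, m2, geom), 5) # 3-4-5 triangle
  expect_equal(localization_error(m1, m1, geom), 0)
  # symmetric
  expect_equal(localization_error(m2, m1, geom), 5)
})

test_that("smooth_at is inert below the lead spacing and pulls outliers", {
  withr::with_seed(4, {
    geo <- make_geometry(tiny_config(), 1)$heart
    at <- tibble::tibble(node_id = geo$node_id,
                         at_ms = 0.5 * node_positions(geo)[, 3] + 20)
    class(at) <- c("activation_map", class(at))
    # radius below min spacing: identity
    dmin <- min(as.matrix(stats::dist(node_positions(geo)))[
      upper.tri(diag(nrow(geo)))])
    same <- smooth_at(at, geo, radius = dmin * 0.9)
    expect_equal(same$at_ms, at$at_ms)
    # uniform map unchanged at any radius
    flat <- at; flat$at_ms <- rep(7, nrow(at))
    expect_equal(smooth_at(flat, geo, 25)$at_ms, flat$at_ms)
    # an outlier is pulled toward its neighbourhood
    spike <- at
    spike$at_ms[10] <- spike$at_ms[10] + 30
    sm <- smooth_at(spike, geo, radius = 20)
    expect_lt(sm$at_ms[10], spike$at_ms[10])
    expect_gt(abs(sm$at_ms[10] - spike$at_ms[10]), 0)
  })
})

test_that("cross-validation plans partition the data", {
  plan <- loocv_folds(13)
  expect_equal(nrow(plan), 13L)
  for (i in seq_len(13)) {
    expect_equal(sort(c(plan$validation[i], plan$train[[i]])), 1:13)
  }
  expect_equal(nrow(loocv_folds(2)), 2L)
  expect_error(loocv_folds(1), class = "epimap_insufficient_data")
})

test_that("summarize_folds matches a sorting-based quantile oracle", {
  one <- tibble::tibble(fold = 1, subject_id = "a", recording_id = "r",
                        median_cc = 0.74, at_cc = 0.8, loc_error_mm = 5)
  s1 <- summarize_folds(one)
  expect_equal(s1$cc_median[1], 0.74)
  expect_equal(s1$cc_q1[1], 0.74)
  expect_equal(s1$cc_q3[1], 0.74)

  three <- tibble::tibble(fold = 1:3, subject_id = "a", recording_id = c("x", "y", "z"),
                          median_cc = c(0.2, 0.74, 0.9), at_cc = c(0.1, 0.2, 0.3),
                          loc_error_mm = c(1, 2, 3))
  expect_equal(summarize_folds(three)$cc_median[1], 0.74)

  withr::with_seed(5, {
    vals <- runif(100)
    df <- tibble::tibble(fold = 1:100, subject_id = rep(c("a", "b"), 50),
                         recording_id = as.character(1:100),
                         median_cc = vals, at_cc = runif(100),
                         loc_error_mm = runif(100, 0, 30))
    s <- summarize_folds(df)
    # brute-force linear interpolation of order statistics
    qs <- function(v, p) {
      v <- sort(v); h <- (length(v) - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      v[lo] + (h - lo) * (v[hi] - v[lo])
    }
    expect_equal(s$cc_median[1], qs(vals, 0.5))
    expect_equal(s$cc_q1[1], qs(vals, 0.25))
    expect_equal(s$cc_q3[1], qs(vals, 0.75))
    # per-subject breakdown present
    expect_setequal(s$group, c("overall", "a", "b"))
  })
})
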