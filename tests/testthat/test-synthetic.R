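test_that("geometries are deterministic, complete, and nested", {
  cfg <- sim_config(seed = 3)
  g1 <- make_geometry(cfg, 1)
  g2 <- make_geometry(cfg, 1)
  expect_identical(node_positions(g1$heart), node_positions(g2$heart))
  expect_identical(node_positions(g1$torso), node_positions(g2$torso))
  expect_equal(nrow(g1$heart), 239L)
  expect_true(nrow(g1$torso) >= 150 && nrow(g1$torso) <= 171)
  # different subjects differ
  g3 <- make_geometry(cfg, 2)
  expect_false(identical(node_positions(g1$heart), node_positions(g3$heart)))

  # every heart node inside the torso hull: for sampled directions u, some
  # torso node lies beyond the heart node's projection (a Monte Carlo
  # certificate of hull membership)
  withr::with_seed(1, {
    tp <- node_positions(g1$torso); hp <- node_positions(g1$heart)
    for (k in 1:200) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      expect_gte(max(tp %*% u), max(hp %*% u))
    }
  })
})

test_that("simulated pacing obeys the activation-time oracle", {
  cfg <- sim_config(noise_sd = 0, bad_lead_rate = 0, seed = 5)
  geo <- make_geometry(cfg, 1)
  rec <- simulate_pacing(geo$heart, 57L, cfg)

  # AT at the pacing node is zero
  expect_equal(rec$truth_at$at_ms[58], 0)
  expect_identical(earliest_node(rec$truth_at), 57L)

  # max -dV/dt recovers ground truth within one sample at every lead
  amap <- activation_map(rec)
  expect_lt(max(abs(amap$at_ms - rec$truth_at$at_ms)), 0.5 + 1e-12)
  # and the earliest node is the pacing site -> zero localization error
  expect_identical(earliest_node(amap), 57L)
  expect_equal(localization_error(rec$truth_at, amap, geo$heart), 0)

  expect_error(simulate_pacing(geo$heart, 9999L, cfg), class = "epimap_bad_node")
})

test_that("the transfer matrix is a row-stochastic smoother", {
  cfg <- tiny_config()
  geo <- make_geometry(cfg, 1)
  A <- build_transfer(geo$torso, geo$heart)
  expect_equal(dim(A), c(nrow(geo$torso), nrow(geo$heart)))
  expect_lt(max(abs(rowSums(A) - 1)), 1e-12)

  # uniform heart potential passes through unchanged
  rec <- simulate_pacing(geo$heart, 0L, cfg)
  rec$potentials[] <- 3
  out <- forward_project(rec, A)
  expect_true(all(abs(out$potentials - 3) < 1e-12))

  # coincident nodes rejected
  clash <- geo$heart
  clash[1, c("x", "y", "z")] <- geo$torso[1, c("x", "y", "z")]
  expect_error(build_transfer(geo$torso, clash), class = "epimap_degenerate_geometry")
})

test_that("forward projection is linear and its noise is calibrated", {
  cfg <- tiny_config()
  geo <- make_geometry(cfg, 1)
  A <- build_transfer(geo$torso, geo$heart)
  r1 <- simulate_pacing(geo$heart, 3L, cfg)
  r2 <- simulate_pacing(geo$heart, 40L, cfg)
  mix <- r1; mix$potentials <- 2 * r1$potentials - 0.5 * r2$potentials
  expect_equal(forward_project(mix, A)$potentials,
               2 * forward_project(r1, A)$potentials -
                 0.5 * forward_project(r2, A)$potentials,
               tolerance = 1e-12)
  # zero in, zero out
  z <- r1; z$potentials[] <- 0
  expect_true(all(forward_project(z, A)$potentials == 0))

  # empirical residual sd within [0.095, 0.105] at sd 0.1 over >= 1e5 draws
  bigcfg <- sim_config(seed = 2, torso_leads = 160, cycle_ms = 400)
  biggeo <- make_geometry(bigcfg, 1)
  big <- simulate_pacing(biggeo$heart, 0L, bigcfg)
  Abig <- build_transfer(biggeo$torso, biggeo$heart)
  noisy <- forward_project(big, Abig, noise_sd = 0.1, seed = 99)
  resid <- noisy$potentials - Abig %*% big$potentials
  expect_gt(length(resid), 1e5)
  expect_gt(sd(resid), 0.095)
  expect_lt(sd(resid), 0.105)
  # deterministic per seed
  noisy2 <- forward_project(big, Abig, noise_sd = 0.1, seed = 99)
  expect_identical(noisy$potentials, noisy2$potentials)

  expect_error(forward_project(big, Abig[, 1:10]), class = "epimap_shape_mismatch")
})

test_that("make_corpus mirrors the requested study structure", {
  cfg <- sim_config(n_subjects = 5, recordings_per_subject = c(13, 24, 5, 13, 11),
                    n_heart = 30, torso_leads = 20, cycle_ms = 10,
                    noise_sd = 0, bad_lead_rate = 0, seed = 21)
  corpus <- make_corpus(cfg)
  counts <- vapply(corpus, function(s) length(s$recordings), integer(1))
  expect_equal(unname(counts), c(13, 24, 5, 13, 11))
  # all flags good at bad-lead rate 0
  flags <- unlist(lapply(corpus, function(s) {
    lapply(s$recordings, function(p) p$torso$lead_quality)
  }))
  expect_true(all(flags == "good"))
  # pacing nodes recorded and within range
  tt <- tidy(corpus)
  expect_true(all(tt$pacing_node >= 0 & tt$pacing_node < 30))

  # reproducibility: identical corpus and identical files from the same seed
  corpus2 <- make_corpus(cfg)
  expect_identical(corpus[[2]]$recordings[[3]]$torso$potentials,
                   corpus2[[2]]$recordings[[3]]$torso$potentials)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_dataset(corpus, d1); write_dataset(corpus2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("bad leads are injected at the configured rate and interpolable", {
  cfg <- sim_config(n_subjects = 1, recordings_per_subject = 2, n_heart = 40,
                    torso_leads = 100, cycle_ms = 20, noise_sd = 0,
                    bad_lead_rate = 0.15, seed = 8)
  corpus <- make_corpus(cfg)
  rec <- corpus[[1]]$recordings[[1]]$torso
  expect_equal(sum(rec$lead_quality == "bad"), round(0.15 * 100))
  fixed <- interpolate_bad_leads(rec, corpus[[1]]$torso_geometry)
  expect_true(all(fixed$lead_quality %in% c("good", "interpolated")))
})
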