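test_that("project_to_disk preserves apex distance and orientation", {
  # pre-aligned geometry: apex at origin
  h <- node_set(rbind(c(0, 0, 0), c(3, 4, 12), c(3, 4, 0), c(-1, 2, 5)),
                "epicardium")
  dk <- project_to_disk(h)
  # apex maps to the center
  expect_equal(c(dk$u[1], dk$v[1]), c(0, 0))
  # r = 13, direction (0.6, 0.8) -> (7.8, 10.4)
  expect_equal(c(dk$u[2], dk$v[2]), c(7.8, 10.4))
  # in-plane nodes are fixed points
  expect_equal(c(dk$u[3], dk$v[3]), c(3, 4))
  # planar radius equals 3D distance from the apex for all off-axis nodes
  pos <- node_positions(h)
  expect_equal(sqrt(dk$u^2 + dk$v^2), sqrt(rowSums(pos^2)), tolerance = 1e-12)
})

test_that("non-apex nodes on the axis map to the center with a warning", {
  h <- node_set(rbind(c(0, 0, 0), c(0, 0, 4), c(1, 0, 1), c(0, 1, 2)),
                "epicardium")
  expect_warning(dk <- project_to_disk(h), class = "epimap_axial_node")
  expect_equal(c(dk$u[2], dk$v[2]), c(0, 0))
})

test_that("project_to_disk aligns the apex frame when asked", {
  withr::with_seed(6, {
    cfg <- tiny_config()
    geo <- make_geometry(cfg, 1)
    dk <- project_to_disk(geo$heart, apex_node = geo$apex_node)
    # apex at the center; radii equal 3D distances to the apex
    expect_equal(c(dk$u[geo$apex_node + 1], dk$v[geo$apex_node + 1]), c(0, 0))
    pos <- node_positions(geo$heart)
    d3 <- sqrt(rowSums(sweep(pos, 2, pos[geo$apex_node + 1, ])^2))
    expect_equal(sqrt(dk$u^2 + dk$v^2), d3, tolerance = 1e-9)
  })
})

test_that("normalize_segments scales each segment's furthest node onto R", {
  # 30 degree arc -> 12 segments
  dk <- random_disk_coords(seed = 8)
  expect_identical(attr(dk, "n_segments"), 12L)

  # two nodes in one segment at radii 2 and 1 -> radii 1 and 0.5
  two <- tibble::tibble(node_id = 0:1, u = c(2, cos(0.3)), v = c(0, sin(0.3)))
  class(two) <- c("disk_coords", class(two))
  suppressWarnings(norm2 <- normalize_segments(two))
  expect_equal(sqrt(norm2$u^2 + norm2$v^2), c(1, 0.5))
  # angles unchanged
  expect_equal(atan2(norm2$v, norm2$u), atan2(two$v, two$u))

  # empty segments warn and are skipped
  expect_warning(normalize_segments(two), class = "epimap_empty_segment")
  # arc must divide 360
  expect_error(normalize_segments(two, arc_deg = 50), class = "epimap_bad_arc")
})

test_that("normalize_segments is idempotent and bounded by R", {
  withr::with_seed(10, {
    n <- 120
    r <- runif(n, 0.2, 3); a <- runif(n, 0, 2 * pi)
    dk <- tibble::tibble(node_id = seq_len(n) - 1L, u = r * cos(a), v = r * sin(a))
    class(dk) <- c("disk_coords", class(dk))
    once <- normalize_segments(dk)
    expect_lte(max(sqrt(once$u^2 + once$v^2)), 1 + 1e-12)
    twice <- normalize_segments(once)
    expect_equal(twice$u, once$u, tolerance = 1e-12)
    expect_equal(twice$v, once$v, tolerance = 1e-12)
    # every non-empty segment touches R exactly
    ang <- (atan2(once$v, once$u) * 180 / pi) %% 360
    seg <- floor(ang / 30)
    seg_max <- tapply(sqrt(once$u^2 + once$v^2), seg, max)
    expect_equal(as.vector(seg_max), rep(1, length(seg_max)))
  })
})

test_that("build_template freezes the documented 165-node layout", {
  tpl <- build_template()
  expect_equal(nrow(tpl), 165L)
  expect_equal(as.vector(table(tpl$ring))[-1], c(6, 12, 18, 23, 29, 35, 41))
  expect_equal(c(tpl$u[1], tpl$v[1]), c(0, 0))
  expect_true(all(tpl$radius <= 1 + 1e-12))
  # ring radii are k/7
  expect_equal(sort(unique(round(tpl$radius, 10))), round((0:7) / 7, 10))
  # deterministic: two builds identical
  expect_identical(build_template(), tpl)
  # within-ring ordering is clockwise from angle 0
  r1 <- tpl[tpl$ring == 1, ]
  expect_equal(r1$angle_deg, c(0, 300, 240, 180, 120, 60))

  expect_error(build_template(layers = 7, total = 5), class = "epimap_bad_template_spec")
})

test_that("template resampling is exact on affine fields and linear", {
  dk <- random_disk_coords(seed = 12)
  tpl <- build_template()
  aff <- 1.5 * dk$u - 0.7 * dk$v + 0.2
  tv <- sample_to_template(dk, cbind(aff, 2 * aff), tpl)
  interior <- tpl$radius < 0.75
  truth <- 1.5 * tpl$u - 0.7 * tpl$v + 0.2
  expect_lt(max(abs(tv[interior, 1] - truth[interior])), 1e-9)
  # linearity across columns
  expect_equal(tv[, 2], 2 * tv[, 1], tolerance = 1e-12)
  # constant field: exact everywhere including outside the hull
  cv <- sample_to_template(dk, matrix(4, nrow(dk), 1), tpl)
  expect_true(all(abs(cv - 4) < 1e-12))
})

test_that("template round trip preserves affine fields at interior leads", {
  dk <- random_disk_coords(seed = 13)
  tpl <- build_template()
  aff <- dk$u + 2 * dk$v
  back <- sample_from_template(sample_to_template(dk, cbind(aff), tpl), tpl, dk)
  rl <- sqrt(dk$u^2 + dk$v^2)
  interior <- rl < 0.6
  expect_lt(max(abs(back[interior, 1] - aff[interior])) / max(abs(aff)), 1e-6)
})

test_that("template round trip keeps smooth fields within 5% relative RMSE", {
  dk <- random_disk_coords(seed = 14)
  tpl <- build_template()
  bump <- exp(-((dk$u - 0.2)^2 + (dk$v + 0.1)^2) / (2 * 0.5^2))
  back <- sample_from_template(sample_to_template(dk, cbind(bump), tpl), tpl, dk)
  rl <- sqrt(dk$u^2 + dk$v^2)
  interior <- rl < 0.8
  rel_rmse <- sqrt(mean((back[interior, 1] - bump[interior])^2)) /
    sqrt(mean(bump[interior]^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("resampling validates shapes", {
  dk <- suppressWarnings(random_disk_coords(seed = 15, n = 50))
  tpl <- build_template()
  expect_error(sample_to_template(dk, matrix(0, 10, 2), tpl),
               class = "epimap_shape_mismatch")
  expect_error(sample_from_template(matrix(0, 10, 2), tpl, dk),
               class = "epimap_shape_mismatch")
})
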