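mk_areas <- function(nd, nt, val = 100) matrix(val, nd, nt)

test_that("binning: constant field, distance-valued field, empty bins", {
  de <- seq(0, 50, 10); te <- seq(0, 20, 4)
  areas <- mk_areas(5, 5)
  set.seed(2)
  d <- runif(500, 0, 50); tm <- runif(500, 0, 20)
  h <- bin_behaviour(d, tm, rep(0.7, 500), de, te, areas, kind = "velocity")
  expect_equal(h$values[h$counts > 0], rep(0.7, sum(h$counts > 0)),
               tolerance = 1e-12)
  expect_true(all(is.na(h$values[h$counts == 0])))

  # values equal to distance: bin means within one band width of midpoints,
  # and equal to the brute-force per-bin mean exactly
  h2 <- bin_behaviour(d, tm, d, de, te, areas, kind = "velocity")
  db <- findInterval(d, de); tb <- findInterval(tm, te, rightmost.closed = TRUE)
  for (i in 1:5) for (j in 1:5) {
    sel <- db == i & tb == j
    if (any(sel)) {
      expect_equal(h2$values[i, j], mean(d[sel]), tolerance = 1e-12)
      expect_lt(abs(h2$values[i, j] - (de[i] + 5)), 10)
    }
  }
  # empty bin keeps its weight
  h3 <- bin_behaviour(5, 2, 1, de, te, areas, kind = "velocity")
  expect_true(is.na(h3$values[2, 1]))
  expect_equal(h3$weights[2, 1], 100)
  # overflow tally
  h4 <- bin_behaviour(c(5, 200), c(2, 2), c(1, 1), de, te, areas, "velocity")
  expect_equal(h4$metadata$overflow, 1)
})

test_that("division density: hand counts, conservation, invalid bins", {
  # trivial one-frame model: all tissue, no wound
  n <- 100; ps <- 1
  tm <- list(matrix(1L, n, n))
  wm <- list(matrix(0L, n, n))
  cfg <- analysis_config(pixel_size_um = ps, frame_interval_min = 2)
  vel <- data.frame(track_id = 1, frame = 0, x_um = 1, y_um = 1, vx = 0, vy = 0)
  model <- virtual_wound(tm, vel, cfg)

  ev0 <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric())
  h0 <- division_density_map(ev0, model, seq(0, 40, 10), c(0, 4))
  expect_true(all(h0$values[h0$weights > 0] == 0))

  # 12 events in the 10-20 band; value = 12 / band area
  set.seed(9)
  th <- runif(12, 0, 2 * pi); r <- runif(12, 12, 18)
  ev <- data.frame(frame = 0, x_um = 49.5 + r * cos(th), y_um = 49.5 + r * sin(th))
  h <- division_density_map(ev, model, seq(0, 40, 10), c(0, 4))
  expect_equal(h$counts[2, 1], 12)
  expect_equal(h$values[2, 1], 12 / h$weights[2, 1])

  # exact count conservation incl. overflow: sum(values*weights) + overflow
  ev2 <- rbind(ev, data.frame(frame = 0, x_um = 1, y_um = 1))  # far corner
  h2 <- division_density_map(ev2, model, seq(0, 40, 10), c(0, 4))
  expect_equal(sum(h2$counts) + h2$metadata$overflow, nrow(ev2))
  expect_equal(sum(h2$values * h2$weights, na.rm = TRUE) + h2$metadata$overflow,
               nrow(ev2), tolerance = 1e-12)
})

test_that("combining videos: identity, weighted mean, zero-weight exclusion", {
  de <- c(0, 10); te <- c(0, 4)
  mk <- function(v, w, kind = "velocity")
    st_heatmap(matrix(v), matrix(w), matrix(1), de, te, kind)
  m1 <- mk(1, 1); m3 <- mk(3, 3)
  expect_equal(combine_videos(list(m1))$values, m1$values)
  expect_equal(combine_videos(list(m1, m3))$values[1, 1], 2.5)
  m0 <- mk(NA, 0)
  expect_equal(combine_videos(list(m1, m0))$values[1, 1], 1)
  # identical copies reproduce the map exactly
  set.seed(4)
  de2 <- seq(0, 30, 10); te2 <- seq(0, 8, 4)
  vals <- matrix(rnorm(6), 3, 2)
  m <- st_heatmap(vals, matrix(runif(6), 3, 2), matrix(1, 3, 2), de2, te2, "shape")
  cc <- combine_videos(list(m, m, m))
  expect_equal(cc$values, m$values, tolerance = 1e-12)
  # mismatched grids refused
  expect_error(combine_videos(list(m1, st_heatmap(matrix(1), matrix(1),
    matrix(1), c(0, 20), te, "velocity"))), "grids differ")
})

test_that("grid refinement re-aggregates to the coarse density map", {
  # density maps: pooled counts / pooled areas == area-weighted aggregation
  n <- 200; ps <- 1
  tm <- list(matrix(1L, n, n))
  cfg <- analysis_config(pixel_size_um = ps, frame_interval_min = 2)
  vel <- data.frame(track_id = 1, frame = 0, x_um = 1, y_um = 1, vx = 0, vy = 0)
  model <- virtual_wound(tm, vel, cfg)
  set.seed(14)
  th <- runif(300, 0, 2 * pi); r <- sqrt(runif(300)) * 60
  ev <- data.frame(frame = 0, x_um = 99.5 + r * cos(th), y_um = 99.5 + r * sin(th))
  fine <- division_density_map(ev, model, seq(0, 60, 5), c(0, 4))
  coarse <- division_density_map(ev, model, seq(0, 60, 10), c(0, 4))
  for (i in 1:6) {
    w <- fine$weights[2 * i - 1:0, 1]
    v <- fine$values[2 * i - 1:0, 1]
    expect_equal(sum(w * v) / sum(w), coarse$values[i, 1], tolerance = 1e-9)
  }
})

test_that("shape-map normalisation: robust maximum, scale invariance", {
  de <- seq(0, 30, 10); te <- seq(0, 8, 4)
  set.seed(6)
  vals <- matrix(rnorm(6, 0, 0.02), 3, 2)
  m <- st_heatmap(vals, mk_areas(3, 2), matrix(5, 3, 2), de, te, "shape")
  ms <- normalise_shape_map(m, m, 95)
  k <- quantile(abs(vals), 0.95, names = FALSE)
  expect_equal(ms$metadata$normalisation_constant, k)
  expect_equal(max(abs(ms$values)), max(abs(vals)) / k)
  # doubling inputs leaves the self-normalised map unchanged
  m2 <- m; m2$values <- m$values * 2
  expect_equal(normalise_shape_map(m2, m2, 95)$values, ms$values)
  # known reference constant
  ref <- m; ref$values <- matrix(c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05), 3, 2)
  mm <- m; mm$values[] <- 0.025
  expect_equal(normalise_shape_map(mm, ref, 95)$values[1, 1], 0.5)
  zero <- m; zero$values[] <- 0
  expect_error(normalise_shape_map(m, zero), "zero")
})

test_that("signal-to-noise across videos", {
  de <- c(0, 10); te <- c(0, 4)
  mk <- function(v) st_heatmap(matrix(v), matrix(1), matrix(1), de, te, "velocity")
  s <- snr_map(list(mk(3), mk(1)))
  expect_equal(s$values[1, 1], 2 / sqrt(2), tolerance = 1e-12)
  # identical videos: zero variance flagged missing
  s0 <- snr_map(list(mk(2), mk(2), mk(2)))
  expect_true(is.na(s0$values[1, 1]))
  # simulated replicates: SNR ~ mu/sigma within sampling error
  set.seed(8)
  mu <- 0.4; sigma <- 0.1
  reps <- 1000
  est <- replicate(50, {
    maps <- lapply(rnorm(8, mu, sigma), mk)
    snr_map(maps)$values[1, 1]
  })
  expect_equal(median(est), mu / sigma, tolerance = 0.25)
})

test_that("moving average shrinks its window at the ends", {
  expect_equal(moving_average(c(1, 2, 3))[2], 2)
  expect_equal(moving_average(rep(4, 6)), rep(4, 6))
  expect_equal(moving_average(c(0, 3, 0, 3, 0)), c(1.5, 1, 2, 1, 1.5))
  expect_error(moving_average(numeric(0)), "empty")
})

test_that("baseline correction of division maps", {
  de <- seq(0, 20, 10); te <- seq(0, 12, 4)
  vals <- matrix(c(1, 1, 2, 2, 3, 3) * 1e-3, 2, 3)
  m <- st_heatmap(vals, mk_areas(2, 3), matrix(1, 2, 3), de, te, "division_density")
  base <- c(1, 2, 3) * 1e-3
  z <- baseline_correct_divisions(m, base)
  expect_true(all(z$values == 0))
  ident <- baseline_correct_divisions(m, rep(0, 3))
  expect_equal(ident$values, vals)
  # data.frame interface matched on midpoints; gaps are errors
  bdf <- data.frame(time_mid_min = c(2, 6, 10), density = base)
  expect_equal(baseline_correct_divisions(m, bdf)$values, vals * 0)
  expect_error(baseline_correct_divisions(m,
    data.frame(time_mid_min = c(2, 6), density = base[1:2])), "cover")
})

test_that("difference maps subtract bin-wise and propagate missingness", {
  de <- seq(0, 20, 10); te <- seq(0, 8, 4)
  a <- st_heatmap(matrix(c(0.1, 0.2, NA, 0.4), 2, 2), mk_areas(2, 2),
                  matrix(1, 2, 2), de, te, "velocity")
  b <- st_heatmap(matrix(c(0.3, 0.2, 0.1, 0.1), 2, 2), mk_areas(2, 2),
                  matrix(1, 2, 2), de, te, "velocity")
  d <- difference_map(a, b)
  expect_equal(d$values[1, 1], -0.2)
  expect_equal(d$values[2, 1], 0)
  expect_true(is.na(d$values[1, 2]))
  expect_equal(d$kind, "difference")
  expect_true(all(difference_map(a, a)$values %in% c(0, NA)))
  b2 <- b; b2$kind <- "shape"
  expect_error(difference_map(a, b2), "kinds differ")
})
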