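test_that("parameter validation enforces the documented invariants", {
  expect_error(sim_params(wound_initial_area_um2 = 8000), "margin")
  expect_error(sim_params(frame_interval_min = -1))
  expect_error(sim_params(closure_floor_fraction = 1.2))
  expect_error(sim_params(elong0 = 0.6))
  expect_error(sim_params(burst_annulus_um = c(70, 20)))
  # burst_amplitude = 0 is the documented off value
  expect_silent(sim_params(burst_amplitude = 0))
  expect_error(simulate_epithelium(sim_params(n_frames = 0)), "empty movie")
})

test_that("identical parameters and seed give bit-identical movies", {
  p <- sim_params(field_size_px = 256, n_frames = 4, n_cells_initial = 100,
                  wound_initial_area_um2 = 200, div_rate_base = 3e-4,
                  rng_seed = 9)
  a <- simulate_epithelium(p)
  b <- simulate_epithelium(p)
  expect_identical(a$labels, b$labels)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$divisions, b$divisions)
  expect_identical(a$truth$wound_radius_by_frame_um, b$truth$wound_radius_by_frame_um)
})

test_that("emitted wound masks follow the closure law and shrink monotonically", {
  p <- sim_params(rng_seed = 3, closure_timescale_min = 20,
                  closure_floor_fraction = 0.05, n_frames = 21,
                  div_rate_base = 0)
  mv <- simulate_epithelium(p)
  ps <- p$pixel_size_um
  areas <- wound_area_series(mv$wound_masks, ps)
  A0 <- p$wound_initial_area_um2
  for (f in c(0, 5, 10, 20)) {
    t <- f * p$frame_interval_min
    expected <- A0 * (0.95 * exp(-t / 20) + 0.05)
    R <- sqrt(expected / pi)
    expect_lt(abs(areas[f + 1] - expected), 2 * pi * R * ps + 4 * ps^2)
  }
  # closed form at t = 20 min: A0 (0.95 e^-1 + 0.05)
  expect_equal(areas[11], A0 * (0.95 * exp(-1) + 0.05),
               tolerance = (2 * pi * sqrt(A0 / pi) * ps) / A0)
  # monotone within a one-pixel perimeter band
  slack <- 2 * pi * sqrt(A0 / pi) * ps
  expect_true(all(diff(areas) <= slack * 0.5))
})

test_that("with all wound responses off, cells are static and divisions Poisson", {
  p <- sim_params(field_size_px = 256, n_frames = 30, n_cells_initial = 150,
                  wound_initial_area_um2 = 0, v0_um_per_min = 0, elong0 = 0,
                  div_suppression_depth = 0, burst_amplitude = 0,
                  div_rate_base = 3e-4, detection_jitter_um = 0.05,
                  rng_seed = 17)
  mv <- simulate_epithelium(p)
  tr <- mv$truth$seed_trajectories
  # undivided cells never move
  first <- tr[tr$frame == 0, ]
  last <- tr[tr$frame == max(tr$frame), ]
  shared <- intersect(first$cell_id, last$cell_id)
  i1 <- match(shared, first$cell_id); i2 <- match(shared, last$cell_id)
  expect_lt(max(abs(first$x_um[i1] - last$x_um[i2])), 1e-12)
  # total division count consistent with the homogeneous rate (4 sigma)
  L <- p$field_size_px * p$pixel_size_um
  lam <- p$div_rate_base * L^2 * p$frame_interval_min * (p$n_frames - 1)
  expect_lt(abs(nrow(mv$divisions) - lam), 4 * sqrt(lam))
})

test_that("per-frame division counts pass a Poisson dispersion test", {
  p <- sim_params(field_size_px = 128, n_frames = 200, n_cells_initial = 120,
                  wound_initial_area_um2 = 0, v0_um_per_min = 0, elong0 = 0,
                  div_suppression_depth = 0, burst_amplitude = 0,
                  div_rate_base = 1.2e-3, rng_seed = 23)
  mv <- simulate_epithelium(p)
  counts <- tabulate(mv$divisions$frame, nbins = p$n_frames - 1)
  chi2 <- sum((counts - mean(counts))^2) / mean(counts)
  pval <- pchisq(chi2, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("label conservation: one new cell per division, reveals only near wounds", {
  # unwounded: distinct labels grow exactly by the division count
  p <- sim_params(field_size_px = 128, n_frames = 12, n_cells_initial = 70,
                  wound_initial_area_um2 = 0, v0_um_per_min = 0, elong0 = 0,
                  div_suppression_depth = 0, burst_amplitude = 0,
                  div_rate_base = 1e-3, rng_seed = 31)
  mv <- simulate_epithelium(p)
  expect_gt(nrow(mv$divisions), 0)
  nlab <- vapply(mv$labels, function(m) length(unique(m[m > 0])), numeric(1))
  ndiv <- tabulate(mv$divisions$frame + 1L, nbins = p$n_frames)
  expect_equal(diff(nlab), ndiv[-1])

  # wounded: growth = divisions + cells revealed by the shrinking disc (>= 0)
  p2 <- sim_params(rng_seed = 5, n_frames = 30, div_rate_base = 1e-4)
  mv2 <- simulate_epithelium(p2)
  nlab2 <- vapply(mv2$labels, function(m) length(unique(m[m > 0])), numeric(1))
  ndiv2 <- tabulate(mv2$divisions$frame + 1L, nbins = p2$n_frames)
  expect_true(all(diff(nlab2) - ndiv2[-1] >= 0))
})

test_that("true displacements follow the imposed velocity field (no jitter)", {
  p <- sim_params(rng_seed = 13, detection_jitter_um = 0, div_rate_base = 0,
                  n_frames = 20)
  mv <- simulate_epithelium(p)
  tr <- mv$truth$seed_trajectories
  ctr <- p$wound_centre_px * p$pixel_size_um
  R <- mv$truth$wound_radius_by_frame_um
  o <- order(tr$cell_id, tr$frame)
  tr <- tr[o, ]
  n <- nrow(tr)
  same <- tr$cell_id[-n] == tr$cell_id[-1]
  obs <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[same]
  rn <- sqrt((tr$x_um - ctr[1])^2 + (tr$y_um - ctr[2])^2)
  d <- pmax(0, rn - R[tr$frame + 1L])
  pred <- (mv$truth$v(d, tr$frame * p$frame_interval_min) *
             p$frame_interval_min)[c(same, FALSE)]
  keep <- d[c(same, FALSE)] > 5   # exclude the wound-edge stall zone
  slope <- sum(obs[keep] * pred[keep]) / sum(pred[keep]^2)
  expect_lt(abs(slope - 1), 0.05)
})

test_that("rendered cell elongation tracks the imposed field", {
  # static uniform elongation: measured q_rr ~ e / (1 + e^2)
  p <- sim_params(rng_seed = 19, wound_initial_area_um2 = 0,
                  v0_um_per_min = 0, div_rate_base = 0, n_frames = 1,
                  elong0 = 0.1, elong_decay_length_um = 1e6,
                  elong_relax_time_min = 1e6)
  mv <- simulate_epithelium(p)
  ps <- p$pixel_size_um
  ctr <- p$wound_centre_px * ps
  cf <- cells_from_labels(mv$labels[[1]], ps)
  cf <- cf[!cf$border_flag, ]
  rx <- cf$centroid_x_um - ctr[1]; ry <- cf$centroid_y_um - ctr[2]
  rn2 <- rx^2 + ry^2
  qrr <- cf$qxx * (rx^2 - ry^2) / rn2 + cf$qxy * 2 * rx * ry / rn2
  expect_equal(mean(qrr), 0.1 / 1.01,
               tolerance = 3 * sd(qrr) / sqrt(nrow(cf)) / 0.099)
})

test_that("fixtures round-trip through the manifest with stable hashes", {
  mv <- quick_movie(rng_seed = 8)
  dir <- withr::local_tempdir()
  man <- write_fixture(mv, dir)
  expect_setequal(man$file,
    c("labels.tif", "wound_mask.tif", "tissue_mask.tif", "nuclei.tsv",
      "divisions.tsv", "metadata.json", "ground_truth.json"))
  expect_true(all(file.exists(file.path(dir, man$file))))
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture(mv, dir2)
  expect_equal(man$md5, man2$md5)
  # degenerate movie refused
  broken <- mv; broken$labels <- list()
  expect_error(write_fixture(broken, withr::local_tempdir()), "empty")
})
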