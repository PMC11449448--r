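test_that("closed forms: disc, 2:1 ellipse, rotated ellipse", {
  disc <- rasterise_ellipse(30, 30)
  q <- shape_tensor_pixels(disc$x, disc$y)
  expect_lt(abs(q$qxx), 0.005)
  expect_lt(abs(q$qxy), 0.005)

  ell <- rasterise_ellipse(20, 10)
  q <- shape_tensor_pixels(ell$x, ell$y)
  expect_equal(q$qxx, (20^2 - 10^2) / (2 * (20^2 + 10^2)), tolerance = 0.01 / 0.3)
  expect_lt(abs(q$qxy), 0.01)

  ell45 <- rasterise_ellipse(20, 10, pi / 4)
  q45 <- shape_tensor_pixels(ell45$x, ell45$y)
  expect_lt(abs(q45$qxx), 0.01)
  expect_equal(q45$qxy, 0.300, tolerance = 0.01 / 0.3)

  # exact polygon path on the analytic ellipse boundary
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  qp <- shape_tensor_polygon(cbind(20 * cos(th), 10 * sin(th)))
  expect_equal(qp$qxx, 0.3, tolerance = 1e-4)
  expect_equal(qp$qxy, 0, tolerance = 1e-8)
})

test_that("polygon integration agrees with brute-force pixel summation", {
  set.seed(11)
  worst <- 0
  for (i in 1:200) {
    poly <- random_polygon(mean_radius = runif(1, 10, 30))
    px <- rasterise_star(poly)
    expect_gte(nrow(px), 100)
    qa <- shape_tensor_polygon(poly)
    qb <- pixel_q_oracle(px$x, px$y)
    worst <- max(worst, abs(qa$qxx - qb[["qxx"]]), abs(qa$qxy - qb[["qxy"]]))
  }
  expect_lt(worst, 0.01)
})

test_that("rotation equivariance, scale and translation invariance", {
  set.seed(12)
  for (i in 1:25) {
    poly <- random_polygon()
    q0 <- shape_tensor_polygon(poly)
    th <- runif(1, 0, pi)
    R <- rotmat(th)
    qr <- shape_tensor_polygon(poly %*% t(R))
    Q0 <- matrix(c(q0$qxx, q0$qxy, q0$qxy, -q0$qxx), 2, 2)
    Qe <- R %*% Q0 %*% t(R)
    expect_equal(qr$qxx, Qe[1, 1], tolerance = 1e-9)
    expect_equal(qr$qxy, Qe[1, 2], tolerance = 1e-9)
    k <- runif(1, 0.5, 5); shift <- runif(2, -100, 100)
    qs <- shape_tensor_polygon(sweep(poly * k, 2, shift, "+"))
    expect_equal(qs$qxx, q0$qxx, tolerance = 1e-9)
    expect_equal(qs$qxy, q0$qxy, tolerance = 1e-9)
  }
  # rasterised path: equivariance within rasterisation tolerance
  set.seed(13)
  for (i in 1:10) {
    poly <- random_polygon(mean_radius = 25)
    th <- runif(1, 0, pi)
    pa <- rasterise_star(poly)
    pb <- rasterise_star(poly %*% t(rotmat(th)))
    qa <- shape_tensor_pixels(pa$x, pa$y)
    qb <- shape_tensor_pixels(pb$x, pb$y)
    Q0 <- matrix(c(qa$qxx, qa$qxy, qa$qxy, -qa$qxx), 2, 2)
    Qe <- rotmat(th) %*% Q0 %*% t(rotmat(th))
    expect_lt(abs(qb$qxx - Qe[1, 1]), 0.015)
    expect_lt(abs(qb$qxy - Qe[1, 2]), 0.015)
  }
})

test_that("degenerate regions are rejected with the cell named", {
  expect_error(shape_tensor_pixels(numeric(0), numeric(0), cell = "c7"), "c7")
  expect_error(shape_tensor_polygon(cbind(c(0, 1, 2), c(0, 0, 0)), cell = "c9"), "c9")
})

test_that("tissue mean and deviations: zero-mean by construction", {
  cells <- data.frame(qxx = c(0.1, -0.1), qxy = c(0, 0),
                      border_flag = c(FALSE, FALSE))
  s <- tissue_shape_summary(cells)
  expect_equal(unname(s$Q), c(0, 0))
  expect_equal(s$cells$dqxx, cells$qxx)

  # identical cells -> zero deviations
  cells <- data.frame(qxx = rep(0.07, 5), qxy = rep(-0.02, 5),
                      border_flag = rep(FALSE, 5))
  s <- tissue_shape_summary(cells)
  expect_equal(s$cells$dqxx, rep(0, 5))
  expect_equal(s$cells$dqxy, rep(0, 5))

  # random population about a known mean, recovered within standard error
  set.seed(21)
  n <- 400
  cells <- data.frame(qxx = rnorm(n, 0.05, 0.04), qxy = rnorm(n, -0.03, 0.04),
                      border_flag = rep(FALSE, n))
  s <- tissue_shape_summary(cells)
  expect_lt(abs(s$Q[["qxx"]] - 0.05), 3 * 0.04 / sqrt(n))
  expect_lt(abs(s$Q[["qxy"]] + 0.03), 3 * 0.04 / sqrt(n))
  expect_lt(abs(mean(s$cells$dqxx)), 1e-12)
  expect_lt(abs(mean(s$cells$dqxy)), 1e-12)
  expect_error(tissue_shape_summary(cells[0, ]), "no included cells")
})

test_that("radial elongation dQ1: definition, tracelessness, two-path oracle", {
  e <- 0.17
  expect_equal(radial_elongation(e, 0, 1, 0, c(0, 0)), e, ignore_attr = TRUE)
  expect_equal(radial_elongation(e, 0, 0, 1, c(0, 0)), -e, ignore_attr = TRUE)
  expect_equal(radial_elongation(e, 0, 1, 1, c(0, 0)), 0, ignore_attr = TRUE)

  # explicit rotation-matrix path agrees with r^T dq r to 1e-12
  set.seed(31)
  for (i in 1:50) {
    dq <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    pos <- runif(2, -40, 40)
    got <- radial_elongation(dq[1], dq[2], pos[1], pos[2], c(0, 0))
    th <- atan2(pos[2], pos[1])
    R <- rotmat(-th)
    M <- R %*% matrix(c(dq[1], dq[2], dq[2], -dq[1]), 2, 2) %*% t(R)
    expect_equal(as.numeric(got), M[1, 1], tolerance = 1e-12)
  }
  expect_warning(radial_elongation(0.1, 0, 0, 0, c(0, 0)), "coincident")
})

test_that("global mean elongation magnitude", {
  expect_equal(global_mean_elongation(rep(0, 5), rep(0, 5)), 0)
  expect_equal(global_mean_elongation(rep(0.3, 4), rep(0, 4)), 0.3)
  set.seed(41)
  qxx <- runif(30, -0.2, 0.2); qxy <- runif(30, -0.2, 0.2)
  expect_equal(global_mean_elongation(qxx, qxy),
               mean(sqrt(qxx^2 + qxy^2)), tolerance = 1e-12)
  expect_error(global_mean_elongation(numeric(0), numeric(0)), "no cells")
})

test_that("orientation angle lies in [0, pi) and matches the tensor axis", {
  expect_equal(cell_orientation(0.1, 0), 0)
  expect_equal(cell_orientation(-0.1, 0), pi / 2)
  expect_equal(cell_orientation(0, 0.1), pi / 4)
  th <- cell_orientation(runif(20, -1, 1), runif(20, -1, 1))
  expect_true(all(th >= 0 & th < pi))
})

test_that("label-image region analysis matches closed forms and flags borders", {
  ps <- 0.25
  lab <- matrix(0L, 100, 100)
  lab[11:30, 11:50] <- 1L           # rectangle 40 wide (x), 20 tall (y)
  lab[61:90, 61:90] <- 2L           # square
  lab[1:5, 70:90] <- 3L             # touches the border
  cf <- cells_from_labels(lab, ps, frame = 3L, min_area_px = 9)
  expect_equal(nrow(cf), 3)
  r1 <- cf[cf$cell_id == 1, ]
  expect_equal(r1$area_um2, 800 * ps^2)
  # x extent 40 px, y extent 20 px -> qxx = (40^2-20^2)/(2(40^2+20^2))
  expect_equal(r1$qxx, (40^2 - 20^2) / (2 * (40^2 + 20^2)), tolerance = 0.01)
  expect_equal(r1$qxy, 0, tolerance = 1e-9)
  expect_equal(r1$centroid_x_um, mean(10:49) * ps, tolerance = 1e-9)
  expect_equal(r1$centroid_y_um, mean(10:29) * ps, tolerance = 1e-9)
  expect_false(r1$border_flag)
  expect_lt(abs(cf$qxx[cf$cell_id == 2]), 1e-9)
  expect_true(cf$border_flag[cf$cell_id == 3])
  expect_equal(cf$frame, rep(3L, 3))

  # min-area dropping is counted
  lab[50, 50] <- 4L
  cf2 <- cells_from_labels(lab, ps, min_area_px = 9)
  expect_equal(nrow(cf2), 3)
  expect_equal(attr(cf2, "n_dropped"), 1L)
})
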