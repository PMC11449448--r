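# Shared fixtures, built once per test run and memoised. The "large",
# "unwounded" and "halved_burst" sets are the study-condition fixtures
# (5 replicate videos each, 91 frames, ~400 cells); small ad-hoc movies for
# unit tests are built inline in the test files.

fixture_env <- new.env(parent = emptyenv())

unwounded_params <- function(rng_seed) {
  sim_params(rng_seed = rng_seed, wound_initial_area_um2 = 0,
             v0_um_per_min = 0, elong0 = 0,
             div_suppression_depth = 0, burst_amplitude = 0)
}

quantify_with_truth <- function(p, virtual = FALSE) {
  mv <- simulate_epithelium(p)
  q <- run_quantify(mv, virtual_wound = virtual)
  res <- list(q = q, truth = mv$truth, divisions = mv$divisions,
              nuclei = mv$nuclei)
  rm(mv); gc(FALSE)
  res
}

wq_fixture <- function(name) {
  if (!is.null(fixture_env[[name]])) return(fixture_env[[name]])
  val <- switch(name,
    large = lapply(1:5, function(i)
      quantify_with_truth(sim_params(rng_seed = 100 + i))),
    unwounded = lapply(1:5, function(i)
      quantify_with_truth(unwounded_params(200 + i), virtual = TRUE)),
    halved_burst = lapply(1:5, function(i)
      quantify_with_truth(sim_params(rng_seed = 300 + i, burst_amplitude = 2))),
    stop("unknown fixture ", name))
  fixture_env[[name]] <- val
  val
}

# a quick small movie for unit tests (128 px, 10 frames, no wound responses)
quick_movie <- function(rng_seed = 42, ...) {
  simulate_epithelium(sim_params(
    field_size_px = 128, n_frames = 10, n_cells_initial = 60,
    wound_initial_area_um2 = 0, v0_um_per_min = 0, elong0 = 0,
    div_rate_base = 0, div_suppression_depth = 0, burst_amplitude = 0,
    rng_seed = rng_seed, ...))
}

# --- independent test-side oracles -----------------------------------------

# star-shaped random polygon around the origin (simple by construction)
random_polygon <- function(mean_radius = 25, irregularity = 0.35, n_vert = 48) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-1]
  harm <- sapply(1:3, function(k)
    runif(1, -1, 1) * cos(k * th) + runif(1, -1, 1) * sin(k * th))
  r <- mean_radius * (1 + irregularity * rowSums(harm) / 3)
  r <- pmax(r, 0.3 * mean_radius)
  cbind(r * cos(th), r * sin(th))
}

# rasterise a simple polygon: pixel centres inside by even-odd ray casting
rasterise_star <- function(verts) {
  lim <- ceiling(max(abs(verts))) + 1
  g <- expand.grid(x = -lim:lim, y = -lim:lim)
  n <- nrow(verts)
  x1 <- verts[, 1]; y1 <- verts[, 2]
  x2 <- verts[c(2:n, 1), 1]; y2 <- verts[c(2:n, 1), 2]
  inside <- rep(FALSE, nrow(g))
  for (i in 1:n) {
    crosses <- (y1[i] > g$y) != (y2[i] > g$y)
    if (any(crosses)) {
      xint <- x1[i] + (g$y - y1[i]) / (y2[i] - y1[i]) * (x2[i] - x1[i])
      inside <- xor(inside, crosses & g$x < xint)
    }
  }
  g[inside, , drop = FALSE]
}

# brute-force pixel-summation shape tensor (plain second moments of pixel
# centres; deliberately independent of the package implementation)
pixel_q_oracle <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  sxx <- mean((x - cx)^2); syy <- mean((y - cy)^2)
  sxy <- mean((x - cx) * (y - cy))
  tr <- sxx + syy
  c(qxx = sxx / tr - 0.5, qxy = sxy / tr)
}

# rasterised axis-aligned ellipse (pixel centres)
rasterise_ellipse <- function(a, b, angle = 0) {
  lim <- ceiling(max(a, b)) + 1
  g <- expand.grid(x = -lim:lim, y = -lim:lim)
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * g$x + sa * g$y
  v <- -sa * g$x + ca * g$y
  g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

# 2x2 rotation matrix
rotmat <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# linker accuracy: fraction of true consecutive-frame pairs joined
link_accuracy <- function(nuclei_truth, tracks, pixel_size_um) {
  det <- data.frame(frame = nuclei_truth$frame,
                    x_um = nuclei_truth$x_px * pixel_size_um,
                    y_um = nuclei_truth$y_px * pixel_size_um)
  stopifnot(nrow(det) == nrow(tracks) ||
            nrow(tracks) == nrow(det))  # same detections, relinked
  # match linked rows back to truth rows by (frame, x, y)
  key <- function(f, x, y) paste(f, round(x, 6), round(y, 6))
  truth_key <- key(det$frame, det$x_um, det$y_um)
  track_key <- key(tracks$frame, tracks$x_um, tracks$y_um)
  tid <- tracks$track_id[match(truth_key, track_key)]
  ok <- 0L; tot <- 0L
  o <- order(nuclei_truth$truth_id, nuclei_truth$frame)
  id <- nuclei_truth$truth_id[o]; fr <- nuclei_truth$frame[o]; lid <- tid[o]
  n <- length(id)
  same <- id[-n] == id[-1] & fr[-1] == fr[-n] + 1L
  tot <- sum(same)
  ok <- sum(same & lid[-n] == lid[-1], na.rm = TRUE)
  ok / tot
}
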