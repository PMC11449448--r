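#' Parameters of the synthetic wound-healing epithelium
#'
#' Defines the conditions a simulated movie emulates: acquisition geometry
#' (field, pixel size, frame interval), a circular wound whose area decays
#' exponentially to a floor, an inward radial velocity field decaying in
#' space and time, wound-oriented cell elongation that relaxes over time,
#' and division events from an inhomogeneous Poisson intensity with early
#' suppression near the wound and a late burst in an annulus.
#'
#' Defaults describe a large wound in a 123.26 x 123.26 um field imaged at
#' 512 x 512 px every 2 min for 3 h: initial (t = 0) disc area 1400 um^2,
#' decaying with a 20 min timescale to a 5% floor so the area at the 9-10
#' min classification window is ~900 um^2 (the "large" class) and the
#' wound closes to 20% of its classification-window area at ~50 min.
#' Behaviour fields: peak inward speed 0.3 um/min
#' decaying over 30 um and 30 min, peak radial elongation 0.1 decaying over
#' 15 um and relaxing over 15 min, base division rate 1.5e-5 um^-2 min^-1
#' with 80% suppression within 40 um until 80 min and a burst of amplitude
#' 4 in the 20-70 um annulus during 90-150 min.
#'
#' @param field_size_px Pixels per side.
#' @param pixel_size_um um per pixel.
#' @param frame_interval_min Minutes between frames.
#' @param n_frames Number of frames.
#' @param n_cells_initial Target cell count before wounding.
#' @param wound_centre_px Wound centre, 0-based pixel coordinates (x, y).
#' @param wound_initial_area_um2 Initial wound area, um^2; 0 disables the
#'   wound (unwounded tissue).
#' @param closure_timescale_min,closure_floor_fraction Area law
#'   \eqn{A(t) = A_0[(1-floor)e^{-t/\tau} + floor]}.
#' @param v0_um_per_min,v_decay_length_um,v_decay_time_min Inward speed
#'   \eqn{v(d,t) = v_0 e^{-d/L_d} e^{-t/L_t}}, d the distance to the true
#'   wound-disc edge.
#' @param elong0,elong_decay_length_um,elong_relax_time_min Radial
#'   elongation \eqn{e(d,t) = e_0 e^{-d/L_e} e^{-t/T_e}}.
#' @param div_rate_base Division intensity, um^-2 min^-1.
#' @param div_suppression_depth,div_suppression_radius_um,div_suppression_end_min
#'   Suppression factor (1 - depth) applied for d < radius and t < end.
#' @param burst_amplitude,burst_annulus_um,burst_window_min Burst factor
#'   (1 + amplitude) inside the annulus during the window; amplitude 0
#'   disables the burst.
#' @param detection_jitter_um Isotropic Gaussian jitter of nucleus
#'   detections, um.
#' @param rng_seed Integer seed; identical parameters and seed give
#'   bit-identical outputs.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(field_size_px = 512,
                       pixel_size_um = 123.26 / 512,
                       frame_interval_min = 2,
                       n_frames = 91,
                       n_cells_initial = 400,
                       wound_centre_px = NULL,
                       wound_initial_area_um2 = 1400,
                       closure_timescale_min = 20,
                       closure_floor_fraction = 0.05,
                       v0_um_per_min = 0.3,
                       v_decay_length_um = 30,
                       v_decay_time_min = 30,
                       elong0 = 0.1,
                       elong_decay_length_um = 15,
                       elong_relax_time_min = 15,
                       div_rate_base = 1.5e-5,
                       div_suppression_depth = 0.8,
                       div_suppression_radius_um = 40,
                       div_suppression_end_min = 80,
                       burst_amplitude = 4,
                       burst_annulus_um = c(20, 70),
                       burst_window_min = c(90, 150),
                       detection_jitter_um = 0.05,
                       rng_seed = 1L) {
  if (is.null(wound_centre_px))
    wound_centre_px <- rep((field_size_px - 1) / 2, 2)
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_um = pixel_size_um,
            frame_interval_min = frame_interval_min,
            n_frames = as.integer(n_frames),
            n_cells_initial = as.integer(n_cells_initial),
            wound_centre_px = wound_centre_px,
            wound_initial_area_um2 = wound_initial_area_um2,
            closure_timescale_min = closure_timescale_min,
            closure_floor_fraction = closure_floor_fraction,
            v0_um_per_min = v0_um_per_min,
            v_decay_length_um = v_decay_length_um,
            v_decay_time_min = v_decay_time_min,
            elong0 = elong0,
            elong_decay_length_um = elong_decay_length_um,
            elong_relax_time_min = elong_relax_time_min,
            div_rate_base = div_rate_base,
            div_suppression_depth = div_suppression_depth,
            div_suppression_radius_um = div_suppression_radius_um,
            div_suppression_end_min = div_suppression_end_min,
            burst_amplitude = burst_amplitude,
            burst_annulus_um = burst_annulus_um,
            burst_window_min = burst_window_min,
            detection_jitter_um = detection_jitter_um,
            rng_seed = as.integer(rng_seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$field_size_px >= 16, p$pixel_size_um > 0,
            p$frame_interval_min > 0, p$n_frames >= 0,
            p$n_cells_initial >= 4,
            length(p$wound_centre_px) == 2,
            p$wound_initial_area_um2 >= 0,
            p$closure_timescale_min > 0,
            p$closure_floor_fraction >= 0, p$closure_floor_fraction < 1,
            p$v0_um_per_min >= 0, p$v_decay_length_um > 0, p$v_decay_time_min > 0,
            p$elong0 >= 0, p$elong0 < 0.45,
            p$elong_decay_length_um > 0, p$elong_relax_time_min > 0,
            p$div_rate_base >= 0,
            p$div_suppression_depth >= 0, p$div_suppression_depth <= 1,
            p$div_suppression_radius_um > 0, p$div_suppression_end_min > 0,
            p$burst_amplitude >= 0,
            length(p$burst_annulus_um) == 2, diff(p$burst_annulus_um) > 0,
            length(p$burst_window_min) == 2, diff(p$burst_window_min) > 0,
            p$detection_jitter_um >= 0)
  if (p$wound_initial_area_um2 > 0) {
    L <- p$field_size_px * p$pixel_size_um
    r0 <- sqrt(p$wound_initial_area_um2 / pi)
    ctr <- p$wound_centre_px * p$pixel_size_um
    margin <- min(ctr, L - ctr) - r0
    if (margin < 20)
      stop("wound does not fit in the field with a 20 um margin (margin = ",
           signif(margin, 3), " um)")
  }
  invisible(p)
}

# true wound radius (um) at time t (min)
wound_radius_at <- function(p, t) {
  if (p$wound_initial_area_um2 <= 0) return(0)
  A <- p$wound_initial_area_um2 *
    ((1 - p$closure_floor_fraction) * exp(-t / p$closure_timescale_min) +
       p$closure_floor_fraction)
  sqrt(A / pi)
}

# inward speed (um/min) at distance d (um) from the true wound edge, time t
v_field <- function(p, d, t) {
  p$v0_um_per_min * exp(-d / p$v_decay_length_um) * exp(-t / p$v_decay_time_min)
}

# radial elongation (dimensionless) at distance d, time t
e_field <- function(p, d, t) {
  p$elong0 * exp(-d / p$elong_decay_length_um) * exp(-t / p$elong_relax_time_min)
}

# division intensity (um^-2 min^-1) at distance d, time t
div_intensity <- function(p, d, t) {
  supp <- ifelse(d < p$div_suppression_radius_um & t < p$div_suppression_end_min,
                 p$div_suppression_depth, 0)
  burst <- ifelse(d >= p$burst_annulus_um[1] & d < p$burst_annulus_um[2] &
                    t >= p$burst_window_min[1] & t < p$burst_window_min[2],
                  p$burst_amplitude, 0)
  p$div_rate_base * (1 - supp) * (1 + burst)
}

#' Simulate a synthetic wound-healing movie with known ground truth
#'
#' The movie has two statistically coupled layers sharing one wound and one
#' set of imposed fields.
#'
#' \strong{Nuclei (migration ground truth).} Nucleus positions start at the
#' rendered cell centres and are advected each frame by the inward radial
#' field \eqn{v(d,t)}, with d the distance to the true wound-disc edge
#' (the analytic disc, removing pixelisation noise from the ground truth).
#' Detections are true positions plus isotropic Gaussian jitter.
#'
#' \strong{Cell shapes (elongation ground truth).} Label images are the
#' image of a static, isotropic, jittered hexagonal reference tessellation
#' under a radial warp whose local radial/tangential aspect ratio is
#' exactly \eqn{(1+e)/(1-e)} at every point, so the rendered q-tensor of a
#' cell equals \eqn{e/(1+e^2)} of the local imposed elongation by
#' construction. The wound is a disc whose area follows the
#' exponential-with-floor closure law; the disc simply occludes the
#' reference cells beneath it, so closure reveals intact, unstrained cells
#' at the leading edge and the visible tessellation never accumulates
#' packing strain. Cells crossed by the disc edge are truncated by it
#' (as in real segmented movies), so the first distance band carries a
#' wound-truncation shape bias that is not part of the imposed field.
#' Because the shape layer is warped rather than advected, label
#' identities and nucleus identities are deliberately decoupled; the
#' analysis never links the two.
#'
#' \strong{Divisions.} Events are drawn per frame from the inhomogeneous
#' Poisson intensity \eqn{\lambda(d,t)} by thinning; each accepted event is
#' recorded at its parent nucleus position and splits both the parent
#' nucleus and the nearest reference seed into two adjacent children, so
#' the cell count increases by exactly one per division (no cell death).
#'
#' All stochastic draws come from one RNG seeded with \code{rng_seed}, in a
#' fixed order (lattice jitter, then per frame: division count, candidate
#' positions, thinning, split directions, detection jitter), so identical
#' parameters give bit-identical outputs.
#'
#' @param params A [sim_params()].
#' @return A list of class \code{sim_movie}: \code{labels}, \code{wound_masks},
#'   \code{tissue_masks} (lists of matrices); \code{nuclei} (data.frame
#'   \code{frame, x_px, y_px, truth_id}); \code{divisions} (data.frame
#'   \code{frame, x_px, y_px}); and \code{truth} (params, per-nucleus
#'   trajectories in um, wound radius per frame, division truth with parent
#'   ids, and the field functions \code{v(d, t)}, \code{e(d, t)},
#'   \code{lambda(d, t)}).
#' @export
simulate_epithelium <- function(params) {
  p <- validate_sim_params(params)
  if (p$n_frames == 0) stop("empty movie (n_frames = 0)")
  set.seed(p$rng_seed)
  ps <- p$pixel_size_um
  npx <- p$field_size_px
  L <- npx * ps
  ctr <- p$wound_centre_px * ps
  s_max <- sqrt(max(ctr[1], L - ctr[1])^2 + max(ctr[2], L - ctr[2])^2) + 2

  # isotropic jittered hexagonal reference lattice (u-space)
  a <- sqrt(L^2 / (p$n_cells_initial * sqrt(3) / 2))
  xs <- seq(a / 2, L - 1e-9, by = a)
  ys <- seq(a / 2, L - 1e-9, by = a * sqrt(3) / 2)
  gx <- rep(xs, times = length(ys)) +
    rep(ifelse(seq_along(ys) %% 2 == 0, a / 2, 0), each = length(xs))
  gy <- rep(ys, each = length(xs))
  jit <- 0.10 * a
  ux <- gx + rnorm(length(gx), 0, jit)
  uy <- gy + rnorm(length(gy), 0, jit)
  inside <- ux > 0 & ux < L & uy > 0 & uy < L
  ux <- ux[inside]; uy <- uy[inside]

  ref_ids <- seq_along(ux)
  next_id <- length(ref_ids) + 1L

  # nuclei start at the rendered positions of the reference cells that are
  # visible at t = 0 (cells under the initial wound disc stay hidden and are
  # revealed as the wound closes; they never carry a nucleus)
  r0 <- wound_radius_at(p, 0)
  warp0 <- radial_warp(p, 0, r0, s_max)
  rend0 <- warp_render(warp0, ux, uy, ctr)
  vis <- sqrt((rend0$x - ctr[1])^2 + (rend0$y - ctr[2])^2) > r0 + 0.25
  nx_um <- rend0$x[vis]; ny_um <- rend0$y[vis]
  nuc_ids <- ref_ids[vis]

  labels <- wound_masks <- tissue_masks <- vector("list", p$n_frames)
  traj <- vector("list", p$n_frames)
  nuc <- vector("list", p$n_frames)
  div_truth <- list()
  radii <- numeric(p$n_frames)
  dt <- p$frame_interval_min
  lambda_max <- p$div_rate_base * (1 + p$burst_amplitude)

  for (f in seq_len(p$n_frames) - 1L) {
    t <- f * dt
    R <- wound_radius_at(p, t)
    radii[f + 1L] <- R
    warp <- radial_warp(p, t, R, s_max)
    if (f > 0) {
      t_prev <- (f - 1) * dt
      R_prev <- wound_radius_at(p, t_prev)
      # advect nuclei with the field at the previous frame
      rx <- nx_um - ctr[1]; ry <- ny_um - ctr[2]
      rn <- pmax(sqrt(rx^2 + ry^2), 1e-9)
      d <- pmax(0, rn - R_prev)
      step <- v_field(p, d, t_prev) * dt
      nx_um <- nx_um - step * rx / rn
      ny_um <- ny_um - step * ry / rn
      if (R > 0) {
        rn2 <- sqrt((nx_um - ctr[1])^2 + (ny_um - ctr[2])^2)
        tooin <- rn2 < R + 0.25
        if (any(tooin)) {
          sc <- (R + 0.25) / pmax(rn2[tooin], 1e-9)
          nx_um[tooin] <- ctr[1] + (nx_um[tooin] - ctr[1]) * sc
          ny_um[tooin] <- ctr[2] + (ny_um[tooin] - ctr[2]) * sc
        }
      }
      # divisions over (t_prev, t], intensity evaluated at t
      if (p$div_rate_base > 0) {
        tiss_area <- L^2 - pi * R^2
        n_cand <- rpois(1, lambda_max * tiss_area * dt)
        if (n_cand > 0) {
          ev <- matrix(numeric(0), 0, 2)
          got <- 0L
          while (got < n_cand) {
            m <- (n_cand - got) * 2L + 8L
            cx <- runif(m, 0, L); cy <- runif(m, 0, L)
            ok <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2) > R
            take <- which(ok)[seq_len(min(sum(ok), n_cand - got))]
            ev <- rbind(ev, cbind(cx[take], cy[take]))
            got <- got + length(take)
          }
          dd <- pmax(0, sqrt((ev[, 1] - ctr[1])^2 + (ev[, 2] - ctr[2])^2) - R)
          acc <- runif(n_cand) < div_intensity(p, dd, t) / lambda_max
          for (k in which(acc)) {
            parent <- which.min((nx_um - ev[k, 1])^2 + (ny_um - ev[k, 2])^2)
            px0 <- nx_um[parent]; py0 <- ny_um[parent]
            div_truth[[length(div_truth) + 1L]] <-
              data.frame(frame = f, x_um = px0, y_um = py0,
                         parent_id = nuc_ids[parent])
            th <- runif(1, 0, 2 * pi)
            off <- 0.3 * a
            id1 <- next_id; id2 <- next_id + 1L; next_id <- next_id + 2L
            nx_um <- c(nx_um[-parent], px0 + off * cos(th), px0 - off * cos(th))
            ny_um <- c(ny_um[-parent], py0 + off * sin(th), py0 - off * sin(th))
            nuc_ids <- c(nuc_ids[-parent], id1, id2)
            # split the matching reference seed (event mapped to u-space)
            s_ev <- sqrt((px0 - ctr[1])^2 + (py0 - ctr[2])^2)
            u_ev <- warp_u_at(warp, s_ev)
            scl <- if (s_ev > 1e-9) u_ev / s_ev else 1
            ex <- ctr[1] + scl * (px0 - ctr[1]); ey <- ctr[2] + scl * (py0 - ctr[2])
            rparent <- which.min((ux - ex)^2 + (uy - ey)^2)
            rx0 <- ux[rparent]; ry0 <- uy[rparent]
            th2 <- runif(1, 0, 2 * pi)
            ux <- c(ux[-rparent], rx0 + off * cos(th2), rx0 - off * cos(th2))
            uy <- c(uy[-rparent], ry0 + off * sin(th2), ry0 - off * sin(th2))
            ref_ids <- c(ref_ids[-rparent], id1, id2)
          }
        }
      }
      if (length(nx_um) < L^2 / 100)
        stop("seed density collapsed below 1 cell per (10 um)^2 at frame ", f)
    }
    # render labels through the warp
    utab_px <- warp_px_table(warp, ps, s_max)
    lab <- rasterise_warped(ux / ps, uy / ps, as.integer(ref_ids), npx, npx,
                            p$wound_centre_px[1], p$wound_centre_px[2],
                            R / ps, utab_px, 1.0)
    labels[[f + 1L]] <- lab
    wound_masks[[f + 1L]] <- matrix(as.integer(lab == 0L), npx, npx)
    tissue_masks[[f + 1L]] <- matrix(as.integer(lab != 0L), npx, npx)
    traj[[f + 1L]] <- data.frame(cell_id = nuc_ids, frame = f,
                                 x_um = nx_um, y_um = ny_um)
    jx <- rnorm(length(nx_um), 0, p$detection_jitter_um)
    jy <- rnorm(length(ny_um), 0, p$detection_jitter_um)
    nuc[[f + 1L]] <- data.frame(frame = f, x_px = (nx_um + jx) / ps,
                                y_px = (ny_um + jy) / ps, truth_id = nuc_ids)
  }

  div_df <- if (length(div_truth) > 0) do.call(rbind, div_truth) else
    data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
               parent_id = integer())
  structure(list(
    labels = labels, wound_masks = wound_masks, tissue_masks = tissue_masks,
    nuclei = do.call(rbind, nuc),
    divisions = data.frame(frame = div_df$frame, x_px = div_df$x_um / ps,
                           y_px = div_df$y_um / ps),
    truth = c(list(
      params = p,
      seed_trajectories = do.call(rbind, traj),
      wound_radius_by_frame_um = radii,
      division_truth = div_df),
      field_functions(p))
  ), class = "sim_movie")
}

# truth field closures built in a minimal environment so that keeping the
# truth object alive does not retain the simulation's image stacks
field_functions <- function(p) {
  force(p)
  list(v = function(d, t) v_field(p, d, t),
       e = function(d, t) e_field(p, d, t),
       lambda = function(d, t) div_intensity(p, d, t))
}

# Radial warp for the shape layer at time t: reference radius u(s) solves
# du/ds = u / (k(s) s) with k = (1+e)/(1-e) at distance d = max(0, s - R),
# anchored at u(s_max) = s_max, so the local radial/tangential aspect of the
# map u -> s is exactly k. Integrated with midpoint steps on a 0.25 um grid.
radial_warp <- function(p, t, R, s_max) {
  h <- 0.25
  s <- seq(h, s_max + h, by = h)
  n <- length(s)
  u <- numeric(n)
  u[n] <- s[n]
  if (p$elong0 == 0) {
    u <- s
  } else {
    kf <- function(sv) {
      e <- e_field(p, pmax(0, sv - R), t)
      (1 + e) / (1 - e)
    }
    lo <- max(1L, floor(max(R - 1, 0) / h))   # integrate down to just inside R
    for (i in seq(n - 1L, lo)) {
      d1 <- u[i + 1L] / (kf(s[i + 1L]) * s[i + 1L])
      um <- u[i + 1L] - d1 * h / 2
      d2 <- um / (kf(s[i] + h / 2) * (s[i] + h / 2))
      u[i] <- u[i + 1L] - d2 * h
    }
    if (lo > 1L) u[seq_len(lo - 1L)] <- s[seq_len(lo - 1L)] * (u[lo] / s[lo])
  }
  list(s = c(0, s), u = c(0, u))
}

# u(s) lookup on a warp
warp_u_at <- function(warp, s) {
  stats::approx(warp$s, warp$u, xout = s, rule = 2)$y
}

# rendered position of reference points: invert u(s)
warp_render <- function(warp, ux, uy, ctr) {
  ur <- sqrt((ux - ctr[1])^2 + (uy - ctr[2])^2)
  sr <- stats::approx(warp$u, warp$s, xout = ur, rule = 2)$y
  sc <- ifelse(ur > 1e-9, sr / ur, 1)
  list(x = ctr[1] + sc * (ux - ctr[1]), y = ctr[2] + sc * (uy - ctr[2]))
}

# u(s) table resampled on a 1-pixel grid for the rasteriser
warp_px_table <- function(warp, ps, s_max) {
  s_px <- seq(0, ceiling(s_max / ps) + 2)
  stats::approx(warp$s / ps, warp$u / ps, xout = s_px, rule = 2)$y
}

#' @export
print.sim_movie <- function(x, ...) {
  p <- x$truth$params
  cat("<sim_movie>", p$n_frames, "frames,", p$field_size_px, "px,",
      signif(p$pixel_size_um, 4), "um/px,", p$frame_interval_min, "min/frame\n")
  cat("  cells (first frame):", sum(x$truth$seed_trajectories$frame == 0),
      " divisions:", nrow(x$divisions), "\n")
  cat("  wound:", if (p$wound_initial_area_um2 > 0)
    paste0(p$wound_initial_area_um2, " um^2 initial") else "none", "\n")
  invisible(x)
}

#' Write a simulated movie to a fixture directory
#'
#' Emits the movie in the pipeline's external formats -- 16-bit label TIFF
#' stack, 8-bit wound and tissue mask stacks, nucleus and division tables
#' (tab-delimited with header), acquisition metadata and ground truth as
#' JSON -- plus a manifest listing every file with its MD5 content hash.
#'
#' @param movie A [simulate_epithelium()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (\code{file, md5}), invisibly written as
#'   \code{manifest.json}.
#' @export
write_fixture <- function(movie, dir) {
  stopifnot(inherits(movie, "sim_movie"))
  if (length(movie$labels) == 0) stop("empty movie (no frames)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  p <- movie$truth$params
  max_lab <- max(vapply(movie$labels, max, numeric(1)))
  if (max_lab > 65535) stop("label values exceed 16-bit range")
  tiff::writeTIFF(lapply(movie$labels, function(m) m / 65535),
                  file.path(dir, "labels.tif"), bits.per.sample = 16)
  tiff::writeTIFF(lapply(movie$wound_masks, function(m) m * 1.0),
                  file.path(dir, "wound_mask.tif"), bits.per.sample = 8)
  tiff::writeTIFF(lapply(movie$tissue_masks, function(m) m * 1.0),
                  file.path(dir, "tissue_mask.tif"), bits.per.sample = 8)
  nuc <- movie$nuclei[, c("frame", "x_px", "y_px")]
  write.table(nuc, file.path(dir, "nuclei.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(movie$divisions, file.path(dir, "divisions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(pixel_size_um = p$pixel_size_um,
               frame_interval_min = p$frame_interval_min,
               n_frames = p$n_frames, field_size_px = p$field_size_px)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "metadata.json"))
  gt <- list(params = unclass(p),
             wound_radius_by_frame_um = movie$truth$wound_radius_by_frame_um,
             division_truth = movie$truth$division_truth,
             seed_trajectories = movie$truth$seed_trajectories)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "ground_truth.json"))
  files <- c("labels.tif", "wound_mask.tif", "tissue_mask.tif",
             "nuclei.tsv", "divisions.tsv", "metadata.json", "ground_truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  writeLines(jsonlite::toJSON(manifest, dataframe = "rows", digits = NA),
             file.path(dir, "manifest.json"))
  manifest
}
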