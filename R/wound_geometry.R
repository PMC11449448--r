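#' Wound area over time
#'
#' Pixel count of the largest connected component of each binary wound
#' mask, scaled to um^2. An empty mask gives area 0 (the wound has closed);
#' stray small components are ignored.
#'
#' @param wound_masks List of binary matrices (one per frame).
#' @param pixel_size_um Pixel size, um/px.
#' @return Numeric vector of areas, um^2, one per frame.
#' @export
wound_area_series <- function(wound_masks, pixel_size_um) {
  vapply(wound_masks, function(m) {
    cc <- largest_component(m)
    cc$area_px * pixel_size_um^2
  }, numeric(1))
}

# largest connected component of a binary matrix: area (px) and centroid
# (0-based px, x = col, y = row); area 0 and NA centroid when empty
largest_component <- function(mask) {
  if (!any(mask > 0)) return(list(area_px = 0, centroid_px = c(NA_real_, NA_real_)))
  lab <- EBImage::bwlabel(mask > 0)
  tab <- tabulate(lab[lab > 0])
  k <- which.max(tab)
  idx <- which(lab == k)
  ny <- nrow(mask)
  list(area_px = tab[k],
       centroid_px = c(mean((idx - 1L) %/% ny), mean((idx - 1L) %% ny)))
}

#' Classify wound size from its area series
#'
#' The wound is classified by its mean area over the classification window
#' (default 9-10 min after wounding): small if within 200-400 um^2, large
#' if within 700-1100 um^2, otherwise unclassified. The window mean also
#' serves as the reference area for the closure rule.
#'
#' @param areas_um2 Wound area per frame, um^2.
#' @param frame_interval_min Frame interval, minutes.
#' @param config An [analysis_config()] supplying the window and class
#'   ranges.
#' @return List with \code{size_class} ("small", "large" or "unclassified")
#'   and \code{reference_area_um2}.
#' @export
classify_wound <- function(areas_um2, frame_interval_min, config = analysis_config()) {
  t_min <- (seq_along(areas_um2) - 1) * frame_interval_min
  win <- config$classification_window_min
  in_win <- t_min >= win[1] & t_min <= win[2]
  if (!any(in_win)) stop("area series does not cover the classification window [",
                         win[1], ", ", win[2], "] min")
  ref <- mean(areas_um2[in_win])
  sr <- config$small_range_um2; lr <- config$large_range_um2
  cls <- if (ref >= sr[1] && ref <= sr[2]) "small"
         else if (ref >= lr[1] && ref <= lr[2]) "large"
         else "unclassified"
  list(size_class = cls, reference_area_um2 = ref)
}

#' First frame at which a wound counts as closed
#'
#' A wound is closed at the first frame whose area is at most
#' \code{fraction} (default 20%) of the reference area; the leading edge is
#' too noisy to follow beyond this point and the wound site is tracked
#' instead.
#'
#' @param areas_um2 Wound area per frame, um^2.
#' @param reference_area_um2 Reference (classification-window) area, um^2.
#' @param fraction Closure fraction.
#' @return 0-based frame index, or NA if the threshold is never reached.
#' @export
closure_frame <- function(areas_um2, reference_area_um2, fraction = 0.2) {
  stopifnot(reference_area_um2 > 0, fraction > 0, fraction < 1)
  i <- which(areas_um2 <= fraction * reference_area_um2)
  if (length(i) == 0) NA_integer_ else as.integer(i[1] - 1L)
}

#' Track the wound site after closure
#'
#' Advects a reference point with the local tissue flow:
#' \eqn{p(f+1) = p(f) + \bar V(f)\,\Delta t}, with \eqn{\bar V} the mean raw
#' velocity of nuclei within \code{radius_um} of \eqn{p(f)}; when no nuclei
#' fall inside the radius the global frame-mean velocity is used, and a
#' frame with no velocity samples at all advances the point unchanged.
#'
#' @param start_point_um Site position at \code{start_frame}, um.
#' @param start_frame 0-based frame at which tracking starts.
#' @param velocities Data.frame from [track_velocities()] (raw velocities;
#'   deviation velocities are zero-mean and would freeze the site).
#' @param n_frames Total frames in the movie.
#' @param radius_um Neighbourhood radius, um.
#' @param frame_interval_min Frame interval, minutes.
#' @return An \code{n_frames} x 2 matrix of site positions (um), NA before
#'   \code{start_frame}.
#' @export
track_wound_site <- function(start_point_um, start_frame, velocities, n_frames,
                             radius_um = 30, frame_interval_min = 2) {
  if (nrow(velocities) == 0) stop("no velocity samples in movie; cannot track wound site")
  site <- matrix(NA_real_, n_frames, 2)
  site[start_frame + 1L, ] <- start_point_um
  if (start_frame + 1L >= n_frames) return(site)
  for (f in start_frame:(n_frames - 2L)) {
    p <- site[f + 1L, ]
    sel <- velocities$frame == f
    V <- c(0, 0)
    if (any(sel)) {
      near <- sel & sqrt((velocities$x_um - p[1])^2 + (velocities$y_um - p[2])^2) <= radius_um
      use <- if (any(near)) near else sel
      V <- c(mean(velocities$vx[use]), mean(velocities$vy[use]))
    }
    site[f + 2L, ] <- p + V * frame_interval_min
  }
  site
}

#' Wound frame of reference for one movie
#'
#' Builds everything the wound-centred analysis needs from the mask stacks:
#' the wound-area series, per-frame wound centres (area centroid of the
#' largest component, back-filled before the first valid frame), the size
#' class and reference area, the closure frame (20% rule), and -- when
#' velocities are supplied and the wound closes -- the tracked wound-site
#' trajectory used for post-closure distances and directions.
#'
#' @param wound_masks,tissue_masks Lists of binary matrices, one per frame;
#'   a wound pixel is never a tissue pixel.
#' @param config An [analysis_config()].
#' @param velocities Optional data.frame from [track_velocities()], needed
#'   for post-closure site tracking.
#' @return An object of class \code{wound_frame_model}.
#' @export
wound_frame_model <- function(wound_masks, tissue_masks, config = analysis_config(),
                              velocities = NULL) {
  n <- length(wound_masks)
  stopifnot(n >= 1, length(tissue_masks) == n)
  for (f in seq_len(n))
    if (any(wound_masks[[f]] > 0 & tissue_masks[[f]] > 0))
      stop("wound and tissue masks overlap at frame ", f - 1L)
  ps <- config$pixel_size_um
  comp <- lapply(wound_masks, largest_component)
  areas <- vapply(comp, function(z) z$area_px * ps^2, numeric(1))
  centres <- t(vapply(comp, function(z) z$centroid_px * ps, numeric(2)))
  # back/forward-fill missing centres from the nearest valid frame
  valid <- which(!is.na(centres[, 1]))
  if (length(valid) > 0) {
    for (f in seq_len(n)[-valid]) {
      nearest <- valid[which.min(abs(valid - f))]
      centres[f, ] <- centres[nearest, ]
    }
  }
  cls <- tryCatch(classify_wound(areas, config$frame_interval_min, config),
                  error = function(e) list(size_class = "unclassified",
                                           reference_area_um2 = areas[1]))
  closure <- if (is.finite(cls$reference_area_um2) && cls$reference_area_um2 > 0)
    closure_frame(areas, cls$reference_area_um2, config$closure_fraction)
  else NA_integer_
  site <- matrix(NA_real_, n, 2)
  if (!is.na(closure) && !is.null(velocities) && nrow(velocities) > 0) {
    start_f <- max(which(!is.na(centres[seq_len(closure + 1L), 1])), 1L) - 1L
    start_p <- centres[start_f + 1L, ]
    if (!any(is.na(start_p))) {
      full <- track_wound_site(start_p, start_f, velocities, n,
                               config$site_tracking_radius_um,
                               config$frame_interval_min)
      keep <- seq.int(closure + 1L, n)
      site[keep, ] <- full[keep, , drop = FALSE]
    }
  }
  structure(list(
    wound_masks = wound_masks, tissue_masks = tissue_masks,
    n_frames = n, pixel_size_um = ps,
    frame_interval_min = config$frame_interval_min,
    wound_area_um2 = areas, wound_centre_um = centres,
    size_class = cls$size_class, reference_area_um2 = cls$reference_area_um2,
    closure_frame = closure, site_trajectory_um = site,
    virtual = FALSE), class = "wound_frame_model")
}

#' Virtual wound in unwounded tissue
#'
#' A negative-control frame of reference: a "wound site" placed at the
#' field centre in the first frame and advected with the mean tissue flow,
#' behaving like a closed wound (closure frame 0). All distances and
#' directions are measured from the moving site.
#'
#' @param tissue_masks List of binary tissue masks.
#' @param velocities Data.frame from [track_velocities()].
#' @param config An [analysis_config()].
#' @return A \code{wound_frame_model} with an empty wound.
#' @export
virtual_wound <- function(tissue_masks, velocities, config = analysis_config()) {
  n <- length(tissue_masks)
  stopifnot(n >= 1)
  ps <- config$pixel_size_um
  nyx <- dim(tissue_masks[[1]])
  centre <- c((nyx[2] - 1) / 2, (nyx[1] - 1) / 2) * ps
  site <- track_wound_site(centre, 0L, velocities, n,
                           config$site_tracking_radius_um,
                           config$frame_interval_min)
  empty <- lapply(seq_len(n), function(f) matrix(0L, nyx[1], nyx[2]))
  structure(list(
    wound_masks = empty, tissue_masks = tissue_masks,
    n_frames = n, pixel_size_um = ps,
    frame_interval_min = config$frame_interval_min,
    wound_area_um2 = rep(0, n),
    wound_centre_um = site,
    size_class = "unclassified", reference_area_um2 = NA_real_,
    closure_frame = 0L, site_trajectory_um = site,
    virtual = TRUE), class = "wound_frame_model")
}

#' @export
print.wound_frame_model <- function(x, ...) {
  cat("<wound_frame_model>", if (x$virtual) "(virtual wound)", "\n")
  cat("  frames:", x$n_frames, " pixel:", signif(x$pixel_size_um, 4), "um ",
      " interval:", x$frame_interval_min, "min\n")
  cat("  size class:", x$size_class,
      " reference area:", signif(x$reference_area_um2, 4), "um^2\n")
  cat("  closure frame:", if (is.na(x$closure_frame)) "never" else
    paste0(x$closure_frame, " (", x$closure_frame * x$frame_interval_min, " min)"), "\n")
  invisible(x)
}

# is frame f (0-based) analysed in the post-closure (site) regime?
post_closure <- function(model, frame) {
  !is.na(model$closure_frame) && frame >= model$closure_frame &&
    !any(is.na(model$site_trajectory_um[frame + 1L, ]))
}

#' Direction-reference point at a frame
#'
#' The wound centre (pre-closure) or the tracked wound site (post-closure),
#' in um.
#'
#' @param model A \code{wound_frame_model}.
#' @param frame 0-based frame index.
#' @return Length-2 point, um.
#' @export
wound_centre_at <- function(model, frame) {
  if (post_closure(model, frame)) model$site_trajectory_um[frame + 1L, ]
  else model$wound_centre_um[frame + 1L, ]
}

#' Distance-to-wound map for one frame
#'
#' Pre-closure: the Euclidean distance transform of the wound mask (0
#' inside the wound), in um. Post-closure (or for a virtual wound): the
#' Euclidean distance to the tracked wound site.
#'
#' @param model A \code{wound_frame_model}.
#' @param frame 0-based frame index.
#' @return Matrix of distances, um.
#' @export
distance_map <- function(model, frame) {
  m <- model$wound_masks[[frame + 1L]]
  ps <- model$pixel_size_um
  if (!post_closure(model, frame) && any(m > 0)) {
    return(EBImage::distmap(1 - (m > 0)) * ps)
  }
  if (post_closure(model, frame)) {
    p <- model$site_trajectory_um[frame + 1L, ]
    ny <- nrow(m); nx <- ncol(m)
    x <- (seq_len(nx) - 1) * ps; y <- (seq_len(ny) - 1) * ps
    return(sqrt(outer((y - p[2])^2, (x - p[1])^2, "+")))
  }
  stop("frame ", frame, ": no wound mask and no tracked site to measure distance from")
}

#' Distances of point samples from the wound
#'
#' Looks up the frame's distance map (pre-closure) or computes the distance
#' to the tracked site (post-closure) for a set of sample points.
#'
#' @param model A \code{wound_frame_model}.
#' @param frame 0-based frame index.
#' @param x_um,y_um Sample coordinates, um.
#' @param dmap Optional precomputed [distance_map()] for this frame.
#' @return Numeric vector of distances, um (NA for samples off the field).
#' @export
sample_distances <- function(model, frame, x_um, y_um, dmap = NULL) {
  ps <- model$pixel_size_um
  if (post_closure(model, frame)) {
    p <- model$site_trajectory_um[frame + 1L, ]
    return(sqrt((x_um - p[1])^2 + (y_um - p[2])^2))
  }
  if (is.null(dmap)) dmap <- distance_map(model, frame)
  ny <- nrow(dmap); nx <- ncol(dmap)
  col <- round(x_um / ps) + 1L
  row <- round(y_um / ps) + 1L
  ok <- col >= 1L & col <= nx & row >= 1L & row <= ny
  out <- rep(NA_real_, length(x_um))
  out[ok] <- dmap[cbind(row[ok], col[ok])]
  out
}

#' Tissue area in annular distance bands
#'
#' Area of tissue-mask pixels whose wound distance falls in each half-open
#' band \code{[lo, hi)}, per frame. Band areas over a partition sum exactly
#' (in pixels) to the tissue area within the last edge.
#'
#' @param model A \code{wound_frame_model}.
#' @param dist_edges_um Increasing vector of band edges, um.
#' @param frames 0-based frames to evaluate (default all).
#' @return Matrix (frames x bands) of areas, um^2, with an attribute
#'   \code{"beyond_um2"}: per-frame tissue area beyond the last edge.
#' @export
band_tissue_areas <- function(model, dist_edges_um, frames = seq_len(model$n_frames) - 1L) {
  nb <- length(dist_edges_um) - 1L
  stopifnot(nb >= 1, all(diff(dist_edges_um) > 0))
  ps <- model$pixel_size_um
  out <- matrix(0, length(frames), nb)
  beyond <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    dmap <- distance_map(model, f)
    d <- dmap[model$tissue_masks[[f + 1L]] > 0]
    bin <- findInterval(d, dist_edges_um)
    bin[d >= dist_edges_um[nb + 1L]] <- nb + 1L   # beyond last edge
    cnt <- tabulate(bin, nbins = nb + 1L)
    out[i, ] <- cnt[seq_len(nb)] * ps^2
    beyond[i] <- cnt[nb + 1L] * ps^2
  }
  attr(out, "beyond_um2") <- beyond
  out
}

#' Tissue area of a single band at one frame
#'
#' @param model A \code{wound_frame_model}.
#' @param frame 0-based frame index.
#' @param band Two-element half-open interval \code{c(lo, hi)}, um.
#' @return Area, um^2 (zero is a valid return).
#' @export
band_tissue_area <- function(model, frame, band) {
  stopifnot(length(band) == 2, band[2] > band[1])
  band_tissue_areas(model, band, frames = frame)[1, 1]
}
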