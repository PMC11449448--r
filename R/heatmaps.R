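#' Spatiotemporal heatmap container
#'
#' The common output currency of the pipeline: a statistic on a
#' (distance-from-wound x time-after-wounding) grid, with per-bin weights
#' (tissue band area, um^2, summed over the frames of the time bin), per-bin
#' contributing sample counts, a kind tag, and metadata (units, conventions,
#' normalisation constants, overflow tallies). Values are NA where no data
#' contribute. Distance bands are half-open \code{[lo, hi)}; rows index
#' distance bins, columns time bins.
#'
#' @param values,weights,counts Matrices (n_dist_bins x n_time_bins).
#' @param dist_edges_um,time_edges_min Bin edges.
#' @param kind One of "velocity", "shape", "division_density",
#'   "cell_density", "snr", "difference".
#' @param metadata Named list.
#' @return An object of class \code{st_heatmap}.
#' @export
st_heatmap <- function(values, weights, counts, dist_edges_um, time_edges_min,
                       kind, metadata = list()) {
  nd <- length(dist_edges_um) - 1L; nt <- length(time_edges_min) - 1L
  stopifnot(is.matrix(values), all(dim(values) == c(nd, nt)),
            all(dim(weights) == c(nd, nt)), all(dim(counts) == c(nd, nt)),
            all(diff(dist_edges_um) > 0), all(diff(time_edges_min) > 0),
            kind %in% c("velocity", "shape", "division_density",
                        "cell_density", "snr", "difference"),
            all(weights >= 0, na.rm = TRUE))
  structure(list(values = values, weights = weights, counts = counts,
                 dist_edges_um = dist_edges_um, time_edges_min = time_edges_min,
                 kind = kind, metadata = metadata), class = "st_heatmap")
}

#' @export
print.st_heatmap <- function(x, ...) {
  occ <- sum(is.finite(x$values))
  cat(sprintf("<st_heatmap: %s> %d x %d bins (%g um bands to %g um, %g min bins to %g min)\n",
              x$kind, nrow(x$values), ncol(x$values),
              diff(x$dist_edges_um)[1], max(x$dist_edges_um),
              diff(x$time_edges_min)[1], max(x$time_edges_min)))
  cat(sprintf("  occupied bins: %d/%d; value range [%.4g, %.4g]\n", occ,
              length(x$values), suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  if (length(x$metadata$units)) cat("  units:", x$metadata$units, "\n")
  invisible(x)
}

#' @export
as.data.frame.st_heatmap <- function(x, ...) {
  nd <- nrow(x$values); nt <- ncol(x$values)
  data.frame(
    dist_lo_um = rep(x$dist_edges_um[-(nd + 1)], nt),
    dist_hi_um = rep(x$dist_edges_um[-1], nt),
    time_lo_min = rep(x$time_edges_min[-(nt + 1)], each = nd),
    time_hi_min = rep(x$time_edges_min[-1], each = nd),
    value = as.vector(x$values), weight = as.vector(x$weights),
    count = as.vector(x$counts))
}

#' Plot a spatiotemporal heatmap
#'
#' Time runs rightward, distance-from-wound upward. Signed kinds use a
#' blue-white-red diverging palette centred on zero (red = towards the
#' wound / elongated towards the wound / above control); densities use
#' white-to-red.
#'
#' @param x An \code{st_heatmap}.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.st_heatmap <- function(x, main = x$kind, ...) {
  v <- x$values
  signed <- x$kind %in% c("velocity", "shape", "difference")
  if (signed) {
    lim <- max(abs(v), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    pal <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
    brk <- seq(-lim, lim, length.out = 102)
  } else {
    pal <- colorRampPalette(c("white", "#B2182B"))(101)
    hi <- max(v, na.rm = TRUE); if (!is.finite(hi) || hi == 0) hi <- 1
    brk <- seq(0, hi, length.out = 102)
  }
  image(x = x$time_edges_min, y = x$dist_edges_um, z = t(v), col = pal,
        breaks = brk, xlab = "time after wounding (min)",
        ylab = "distance from wound (um)", main = main, useRaster = TRUE, ...)
  box()
  invisible(x)
}

#' Bin point samples of a behaviour into a heatmap
#'
#' Per-bin unweighted mean of the sample values; the bin weight is the
#' tissue band area summed over the frames of the time bin (used later for
#' across-video combination). Samples beyond the last distance edge are
#' tallied as overflow, never silently dropped; samples with NA distance or
#' value are counted as skipped.
#'
#' @param distance_um,time_min,value Equal-length sample vectors.
#' @param dist_edges_um,time_edges_min Bin edges.
#' @param band_areas_um2 Weight matrix (n_dist x n_time): tissue band area
#'   summed over frames per time bin, as from [summed_band_areas()].
#' @param kind Heatmap kind tag.
#' @param metadata Extra metadata entries.
#' @return An [st_heatmap()].
#' @export
bin_behaviour <- function(distance_um, time_min, value, dist_edges_um,
                          time_edges_min, band_areas_um2,
                          kind = "velocity", metadata = list()) {
  nd <- length(dist_edges_um) - 1L; nt <- length(time_edges_min) - 1L
  stopifnot(nd >= 1, nt >= 1, length(time_min) == length(distance_um),
            length(value) == length(distance_um))
  ok <- is.finite(distance_um) & is.finite(time_min) & is.finite(value)
  n_skipped <- sum(!ok)
  d <- distance_um[ok]; tm <- time_min[ok]; v <- value[ok]
  db <- findInterval(d, dist_edges_um)
  tb <- findInterval(tm, time_edges_min, rightmost.closed = TRUE)
  overflow <- sum(db > nd | d >= dist_edges_um[nd + 1L] | tb < 1 | tb > nt)
  keep <- db >= 1 & db <= nd & d < dist_edges_um[nd + 1L] & tb >= 1 & tb <= nt
  db <- db[keep]; tb <- tb[keep]; v <- v[keep]
  flat <- (tb - 1L) * nd + db
  counts <- matrix(tabulate(flat, nbins = nd * nt), nd, nt)
  sums <- matrix(0, nd, nt)
  if (length(flat) > 0) {
    agg <- rowsum(v, flat)
    sums[as.integer(rownames(agg))] <- agg
  }
  values <- ifelse(counts > 0, sums / counts, NA_real_)
  st_heatmap(values, band_areas_um2, counts, dist_edges_um, time_edges_min,
             kind, c(list(overflow = overflow, n_skipped = n_skipped,
                          statistic = "unweighted bin mean"), metadata))
}

#' Band areas summed over the frames of each time bin
#'
#' Helper producing the weight matrix used by the binning operations.
#'
#' @param model A [wound_frame_model()].
#' @param dist_edges_um,time_edges_min Bin edges.
#' @return Matrix (n_dist x n_time) of summed areas, um^2, with attribute
#'   \code{"beyond_um2"} (per-time-bin area beyond the last distance edge).
#' @export
summed_band_areas <- function(model, dist_edges_um, time_edges_min) {
  per_frame <- band_tissue_areas(model, dist_edges_um)          # frames x bands
  t_frame <- (seq_len(model$n_frames) - 1) * model$frame_interval_min
  tb <- findInterval(t_frame, time_edges_min, rightmost.closed = TRUE)
  nt <- length(time_edges_min) - 1L
  out <- matrix(0, ncol(per_frame), nt)
  beyond <- numeric(nt)
  for (b in seq_len(nt)) {
    rows <- which(tb == b)
    if (length(rows) > 0) {
      out[, b] <- colSums(per_frame[rows, , drop = FALSE])
      beyond[b] <- sum(attr(per_frame, "beyond_um2")[rows])
    }
  }
  attr(out, "beyond_um2") <- beyond
  out
}

#' Division-density heatmap
#'
#' Events per unit tissue band area per time bin: the count of division
#' events in each (distance, time) bin divided by the band's tissue area
#' summed over the bin's frames (um^-2 per time bin). Events beyond the
#' last distance edge go to the overflow tally. A bin with events but zero
#' band area is flagged invalid (NA, counted in metadata).
#'
#' @param events Data.frame with \code{frame} (0-based), \code{x_um},
#'   \code{y_um}.
#' @param model A [wound_frame_model()].
#' @param dist_edges_um,time_edges_min Bin edges.
#' @param kind "division_density" or "cell_density".
#' @return An [st_heatmap()].
#' @export
division_density_map <- function(events, model, dist_edges_um, time_edges_min,
                                 kind = "division_density") {
  nd <- length(dist_edges_um) - 1L; nt <- length(time_edges_min) - 1L
  areas <- summed_band_areas(model, dist_edges_um, time_edges_min)
  counts <- matrix(0L, nd, nt)
  overflow <- 0L; n_skipped <- 0L
  if (nrow(events) > 0) {
    d <- numeric(nrow(events))
    for (f in sort(unique(events$frame))) {
      sel <- events$frame == f
      d[sel] <- sample_distances(model, f, events$x_um[sel], events$y_um[sel])
    }
    tm <- events$frame * model$frame_interval_min
    ok <- is.finite(d)
    n_skipped <- sum(!ok)
    db <- findInterval(d[ok], dist_edges_um)
    tb <- findInterval(tm[ok], time_edges_min, rightmost.closed = TRUE)
    keep <- db >= 1 & db <= nd & d[ok] < dist_edges_um[nd + 1L] & tb >= 1 & tb <= nt
    overflow <- sum(!keep)
    flat <- (tb[keep] - 1L) * nd + db[keep]
    counts <- matrix(tabulate(flat, nbins = nd * nt), nd, nt)
  }
  values <- ifelse(areas > 0, counts / areas, ifelse(counts > 0, NA_real_, NA_real_))
  n_invalid <- sum(counts > 0 & areas == 0)
  st_heatmap(values, areas, counts, dist_edges_um, time_edges_min, kind,
             list(overflow = overflow, n_skipped = n_skipped,
                  n_invalid_bins = n_invalid,
                  units = "events per um^2 per time bin"))
}

#' Cell-density heatmap
#'
#' Cell centroids (or nucleus positions) per unit band area, time-averaged
#' over the frames of each time bin -- the same counting machinery as
#' divisions, so values are mean cell densities in cells/um^2.
#'
#' @param positions Data.frame with \code{frame, x_um, y_um}, one row per
#'   cell per frame.
#' @inheritParams division_density_map
#' @return An [st_heatmap()].
#' @export
cell_density_map <- function(positions, model, dist_edges_um, time_edges_min) {
  m <- division_density_map(positions, model, dist_edges_um, time_edges_min,
                            kind = "cell_density")
  # counts accumulate over frames and areas are frame-summed, so the ratio
  # is already a time-averaged density in cells/um^2
  m$metadata$units <- "cells per um^2 (time-averaged)"
  m
}

#' Combine replicate videos by tissue-area weighting
#'
#' Per bin, the weighted mean of the per-video bin values with weights the
#' videos' tissue band areas in that bin. For density kinds this equals
#' pooled counts over pooled areas. Videos with zero weight or missing
#' value in a bin do not contribute there.
#'
#' @param maps List of [st_heatmap()]s on identical grids and of one kind.
#' @return An [st_heatmap()].
#' @export
combine_videos <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(m$dist_edges_um, g$dist_edges_um) ||
        !identical(m$time_edges_min, g$time_edges_min))
      stop("heatmap grids differ between videos")
    if (!identical(m$kind, g$kind)) stop("heatmap kinds differ between videos")
  }
  wsum <- vsum <- csum <- matrix(0, nrow(g$values), ncol(g$values))
  for (m in maps) {
    w <- m$weights
    w[!is.finite(m$values)] <- 0
    v <- m$values; v[!is.finite(v)] <- 0
    wsum <- wsum + w
    vsum <- vsum + w * v
    csum <- csum + m$counts
  }
  values <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  st_heatmap(values, wsum, csum, g$dist_edges_um, g$time_edges_min, g$kind,
             list(n_videos = length(maps),
                  combination = "tissue-area-weighted mean",
                  units = maps[[1]]$metadata$units))
}

#' Normalise a shape map by a large-wound reference
#'
#' Divides all values by a robust maximum of the reference map: the
#' \code{percentile}-th percentile of |dQ1| over its occupied bins (default
#' 95). The constant is recorded in the metadata and should be reused
#' across all conditions being compared so difference maps stay comparable.
#'
#' @param map,reference [st_heatmap()]s of kind "shape"; the reference is
#'   the designated large-wound control map.
#' @param percentile Percentile of |values| used as the robust maximum.
#' @return The normalised map.
#' @export
normalise_shape_map <- function(map, reference = map, percentile = 95) {
  occ <- is.finite(reference$values)
  if (!any(occ)) stop("reference map has no occupied bins")
  k <- as.numeric(quantile(abs(reference$values[occ]), percentile / 100,
                           names = FALSE, type = 7))
  if (k == 0) stop("reference map is identically zero; cannot normalise")
  map$values <- map$values / k
  map$metadata$normalisation_constant <- k
  map$metadata$normalisation <- sprintf(
    "divided by the %gth percentile of |dQ1| over occupied reference bins (robust maximum)",
    percentile)
  map
}

#' Signal-to-noise heatmap across replicate videos
#'
#' Per bin, |mean across videos| divided by the sample (n-1) standard
#' deviation across videos of the per-video bin values. Bins with fewer
#' than \code{min_videos} contributing videos, or zero variance, are
#' flagged missing.
#'
#' @param maps List of per-video [st_heatmap()]s on one grid.
#' @param min_videos Minimum contributing videos per bin.
#' @return An [st_heatmap()] of kind "snr".
#' @export
snr_map <- function(maps, min_videos = 2) {
  stopifnot(length(maps) >= min_videos, min_videos >= 2)
  g <- maps[[1]]
  arr <- vapply(maps, function(m) {
    if (!identical(m$dist_edges_um, g$dist_edges_um) ||
        !identical(m$time_edges_min, g$time_edges_min))
      stop("heatmap grids differ between videos")
    m$values
  }, g$values)
  dim(arr) <- c(length(g$values), length(maps))
  n <- rowSums(is.finite(arr))
  mu <- rowMeans(arr, na.rm = TRUE)
  s <- apply(arr, 1, sd, na.rm = TRUE)
  snr <- ifelse(n >= min_videos & is.finite(s) & s > 0, abs(mu) / s, NA_real_)
  values <- matrix(snr, nrow(g$values), ncol(g$values))
  counts <- matrix(n, nrow(g$values), ncol(g$values))
  w <- Reduce(`+`, lapply(maps, function(m) m$weights))
  st_heatmap(values, w, counts, g$dist_edges_um, g$time_edges_min, "snr",
             list(n_videos = length(maps), source_kind = g$kind,
                  statistic = "|across-video mean| / sample sd"))
}

#' Centred moving average with shrinking end windows
#'
#' @param x Numeric series.
#' @param window Odd window length; at the ends the window shrinks to the
#'   available points.
#' @return Smoothed series, same length.
#' @export
#' @examples
#' moving_average(c(0, 3, 0, 3, 0))   # 1.5 1 2 1 1.5
moving_average <- function(x, window = 3) {
  n <- length(x)
  if (n == 0) stop("empty series")
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Subtract an unwounded division-density baseline
#'
#' Removes the developmental background: the (already smoothed) unwounded
#' whole-tissue division density, a function of time only, is subtracted
#' from every distance bin of the corresponding time column.
#'
#' @param map Division-density [st_heatmap()].
#' @param baseline Either a numeric vector with one value per time bin of
#'   \code{map}, or a data.frame \code{time_mid_min, density} covering every
#'   occupied time bin (matched on bin midpoints).
#' @return The corrected map (kind unchanged; correction noted in
#'   metadata).
#' @export
baseline_correct_divisions <- function(map, baseline) {
  nt <- ncol(map$values)
  mids <- (map$time_edges_min[-1] + map$time_edges_min[-(nt + 1)]) / 2
  if (is.data.frame(baseline)) {
    idx <- match(round(mids, 9), round(baseline$time_mid_min, 9))
    if (any(is.na(idx) & colSums(is.finite(map$values)) > 0))
      stop("baseline series does not cover all occupied time bins of the map")
    b <- baseline$density[idx]
  } else {
    if (length(baseline) != nt)
      stop("baseline vector must have one value per time bin (", nt, ")")
    b <- baseline
  }
  map$values <- sweep(map$values, 2, b, "-")
  map$metadata$baseline_corrected <- TRUE
  map
}

#' Difference between a perturbed and a control heatmap
#'
#' Per-bin perturbed minus control; negative means less than control
#' (rendered blue), positive more (red). Bins missing in either map are
#' missing in the difference.
#'
#' @param perturbed,control [st_heatmap()]s on one grid and of one kind.
#' @return An [st_heatmap()] of kind "difference".
#' @export
difference_map <- function(perturbed, control) {
  if (!identical(perturbed$dist_edges_um, control$dist_edges_um) ||
      !identical(perturbed$time_edges_min, control$time_edges_min))
    stop("heatmap grids differ")
  if (!identical(perturbed$kind, control$kind))
    stop("heatmap kinds differ (", perturbed$kind, " vs ", control$kind, ")")
  values <- perturbed$values - control$values
  st_heatmap(values, (perturbed$weights + control$weights) / 2,
             perturbed$counts + control$counts,
             perturbed$dist_edges_um, perturbed$time_edges_min, "difference",
             list(source_kind = perturbed$kind,
                  convention = "perturbed - control; negative = less than control"))
}
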