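#' Assemble a movie bundle from a simulated movie
#'
#' Converts a [simulate_epithelium()] result into the validated input
#' bundle the quantification pipeline consumes (the same structure
#' [load_inputs()] builds from a fixture directory).
#'
#' @param movie A \code{sim_movie}.
#' @return A list of class \code{movie_bundle}.
#' @export
as_movie_bundle <- function(movie) {
  stopifnot(inherits(movie, "sim_movie"))
  p <- movie$truth$params
  structure(list(
    labels = movie$labels, wound_masks = movie$wound_masks,
    tissue_masks = movie$tissue_masks,
    nuclei = movie$nuclei[, c("frame", "x_px", "y_px")],
    divisions = movie$divisions,
    metadata = list(pixel_size_um = p$pixel_size_um,
                    frame_interval_min = p$frame_interval_min,
                    n_frames = p$n_frames,
                    field_size_px = p$field_size_px)), class = "movie_bundle")
}

#' Load and validate a movie bundle from a fixture directory
#'
#' Expects \code{labels.tif}, \code{wound_mask.tif}, \code{tissue_mask.tif}
#' (multi-page TIFF, one page per frame), \code{nuclei.tsv},
#' \code{divisions.tsv} (tab-delimited with header; columns \code{frame,
#' x_px, y_px}) and \code{metadata.json} (pixel size, frame interval, frame
#' count). Frame counts must agree across stacks and metadata; masks must
#' be binary; table frames must lie within the movie (violations are
#' reported with the offending file or row).
#'
#' @param dir Fixture directory.
#' @return A list of class \code{movie_bundle}.
#' @export
load_inputs <- function(dir) {
  need <- c("labels.tif", "wound_mask.tif", "tissue_mask.tif",
            "nuclei.tsv", "divisions.tsv", "metadata.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  for (nm in c("pixel_size_um", "frame_interval_min", "n_frames"))
    if (is.null(meta[[nm]])) stop("metadata.json lacks field ", nm)
  n <- meta$n_frames
  read_stack <- function(file, scale) {
    pages <- tiff::readTIFF(file.path(dir, file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != n)
      stop(file, " has ", length(pages), " frames, metadata says ", n)
    lapply(pages, function(m) matrix(as.integer(round(m * scale)),
                                     nrow(m), ncol(m)))
  }
  labels <- read_stack("labels.tif", 65535)
  wound <- read_stack("wound_mask.tif", 255)
  tissue <- read_stack("tissue_mask.tif", 255)
  for (nm in c("wound_mask.tif", "tissue_mask.tif")) {
    stk <- if (nm == "wound_mask.tif") wound else tissue
    vals <- unique(unlist(lapply(stk, function(m) unique(as.vector(m)))))
    if (!all(vals %in% c(0L, 1L, 255L)))
      stop(nm, " is not a binary mask (values ", paste(head(vals), collapse = ","), ")")
  }
  wound <- lapply(wound, function(m) (m > 0) * 1L)
  tissue <- lapply(tissue, function(m) (m > 0) * 1L)
  read_table <- function(file, cols) {
    tab <- read.delim(file.path(dir, file))
    miss <- setdiff(cols, names(tab))
    if (length(miss) > 0) stop(file, " lacks column(s): ", paste(miss, collapse = ", "))
    bad <- which(tab$frame < 0 | tab$frame >= n)
    if (length(bad) > 0)
      stop(file, " row ", bad[1], " references frame ", tab$frame[bad[1]],
           " outside 0..", n - 1)
    tab[, cols, drop = FALSE]
  }
  structure(list(labels = labels, wound_masks = wound, tissue_masks = tissue,
                 nuclei = read_table("nuclei.tsv", c("frame", "x_px", "y_px")),
                 divisions = read_table("divisions.tsv", c("frame", "x_px", "y_px")),
                 metadata = meta), class = "movie_bundle")
}

#' Quantify one wound movie end to end
#'
#' Composes the whole pipeline: per-cell shape tensors and per-frame tissue
#' means from the label images; nucleus linking, velocities and mean-flow
#' subtraction from the detections; the wound frame of reference (areas,
#' classification, closure, post-closure site tracking, distance maps);
#' and the four spatiotemporal heatmaps (towards-wound velocity, radial
#' elongation dQ1, division density, cell density) plus global summaries
#' and a run log of counts.
#'
#' Deterministic given inputs and configuration; every heatmap carries the
#' configuration hash and units in its metadata.
#'
#' @param bundle A \code{movie_bundle} (or a \code{sim_movie}, converted
#'   automatically).
#' @param config An [analysis_config()]; its pixel size and frame interval
#'   are overridden by the bundle's acquisition metadata.
#' @param virtual_wound Analyse around a virtual wound advected with the
#'   tissue flow instead of a real wound mask.
#' @param keep_masks Keep the mask stacks inside the returned model
#'   (memory-heavy; off by default).
#' @return An object of class \code{wound_quantification}: \code{model},
#'   \code{cells}, \code{velocities}, \code{heatmaps} (named list),
#'   \code{summaries}, \code{log}, \code{config}.
#' @export
run_quantify <- function(bundle, config = analysis_config(),
                         virtual_wound = FALSE, keep_masks = FALSE) {
  if (inherits(bundle, "sim_movie")) bundle <- as_movie_bundle(bundle)
  stopifnot(inherits(bundle, "movie_bundle"))
  meta <- bundle$metadata
  config$pixel_size_um <- meta$pixel_size_um
  config$frame_interval_min <- meta$frame_interval_min
  ps <- config$pixel_size_um
  dt <- config$frame_interval_min
  n <- meta$n_frames
  if (n < 1) stop("empty movie")

  # --- shape: per-cell tensors, per-frame tissue mean and deviations
  n_small <- 0L
  cells_list <- vector("list", n)
  for (f in seq_len(n) - 1L) {
    cf <- cells_from_labels(bundle$labels[[f + 1L]], ps, f, config$min_cell_area_px)
    n_small <- n_small + attr(cf, "n_dropped")
    if (nrow(cf) > 0 && any(!cf$border_flag)) {
      cells_list[[f + 1L]] <- tissue_shape_summary(cf)$cells
    } else {
      cf$dqxx <- rep(NA_real_, nrow(cf)); cf$dqxy <- rep(NA_real_, nrow(cf))
      cells_list[[f + 1L]] <- cf
    }
  }
  cells <- do.call(rbind, cells_list)

  # --- kinematics
  det <- data.frame(frame = bundle$nuclei$frame,
                    x_um = bundle$nuclei$x_px * ps,
                    y_um = bundle$nuclei$y_px * ps)
  tracks <- link_detections(det, config$max_link_distance_um)
  vel <- subtract_mean_flow(track_velocities(tracks, dt))

  # --- wound frame of reference
  model <- if (virtual_wound)
    virtual_wound(bundle$tissue_masks, vel, config)
  else
    wound_frame_model(bundle$wound_masks, bundle$tissue_masks, config, vel)

  ctr_by_frame <- t(vapply(seq_len(n) - 1L, function(f) wound_centre_at(model, f),
                           numeric(2)))
  vel <- toward_wound_component(vel, ctr_by_frame[vel$frame + 1L, , drop = FALSE])
  n_skip_vel <- attr(vel, "n_skipped")

  inc <- !is.na(cells$dqxx) & !cells$border_flag
  cells$dQ1 <- NA_real_
  cells$dQ1[inc] <- radial_elongation(
    cells$dqxx[inc], cells$dqxy[inc],
    cells$centroid_x_um[inc], cells$centroid_y_um[inc],
    ctr_by_frame[cells$frame[inc] + 1L, , drop = FALSE])

  # --- distances and band areas (one distance map per frame)
  dist_edges <- dist_edges_of(config)
  time_edges <- time_edges_of(config, n)
  nb <- length(dist_edges) - 1L
  band_mat <- matrix(0, n, nb)
  beyond <- numeric(n)
  tissue_area <- numeric(n)
  vel$distance_um <- NA_real_
  cells$distance_um <- NA_real_
  ev <- bundle$divisions
  ev_d <- rep(NA_real_, nrow(ev))
  ev_x <- ev$x_px * ps; ev_y <- ev$y_px * ps
  for (f in seq_len(n) - 1L) {
    dmap <- distance_map(model, f)
    tm <- bundle$tissue_masks[[f + 1L]] > 0
    d_t <- dmap[tm]
    bin <- findInterval(d_t, dist_edges)
    bin[d_t >= dist_edges[nb + 1L]] <- nb + 1L
    cnt <- tabulate(bin, nbins = nb + 1L)
    band_mat[f + 1L, ] <- cnt[seq_len(nb)] * ps^2
    beyond[f + 1L] <- cnt[nb + 1L] * ps^2
    tissue_area[f + 1L] <- sum(tm) * ps^2
    sel <- which(vel$frame == f)
    if (length(sel) > 0)
      vel$distance_um[sel] <- sample_distances(model, f, vel$x_um[sel],
                                               vel$y_um[sel], dmap)
    sel <- which(cells$frame == f)
    if (length(sel) > 0)
      cells$distance_um[sel] <- sample_distances(model, f, cells$centroid_x_um[sel],
                                                 cells$centroid_y_um[sel], dmap)
    sel <- which(ev$frame == f)
    if (length(sel) > 0)
      ev_d[sel] <- sample_distances(model, f, ev_x[sel], ev_y[sel], dmap)
  }
  areas_tm <- aggregate_band_areas(band_mat, beyond, dt, time_edges)
  chash <- config_hash(config)

  # --- heatmaps
  vel_map <- bin_behaviour(vel$distance_um, vel$frame * dt, vel$s_toward,
                           dist_edges, time_edges, areas_tm, kind = "velocity",
                           metadata = list(units = "um/min towards wound",
                                           config_hash = chash))
  shp_map <- bin_behaviour(cells$distance_um, cells$frame * dt, cells$dQ1,
                           dist_edges, time_edges, areas_tm, kind = "shape",
                           metadata = list(units = "dQ1 (dimensionless)",
                                           config_hash = chash,
                                           normalisation_readings = paste(
                                             "robust-maximum (95th percentile of |dQ1|)",
                                             "adopted; alternative reading:",
                                             "maximum absolute value")))
  div_map <- density_map_from(ev_d, ev$frame * dt, dist_edges, time_edges,
                              areas_tm, "division_density", chash)
  den_map <- density_map_from(cells$distance_um, cells$frame * dt, dist_edges,
                              time_edges, areas_tm, "cell_density", chash)
  den_map$metadata$units <- "cells per um^2 (time-averaged)"

  # --- global summaries
  tb_frame <- findInterval((seq_len(n) - 1) * dt, time_edges, rightmost.closed = TRUE)
  nt <- length(time_edges) - 1L
  area_by_tb <- vapply(seq_len(nt), function(b) sum(tissue_area[tb_frame == b]),
                       numeric(1))
  div_tb <- tabulate(findInterval(ev$frame * dt, time_edges,
                                  rightmost.closed = TRUE), nbins = nt)
  summaries <- list(
    mean_speed_um_min = if (nrow(vel) > 0) mean(sqrt(vel$vx^2 + vel$vy^2)) else NA_real_,
    mean_deviation_speed_um_min = if (nrow(vel) > 0)
      mean(sqrt(vel$dvx^2 + vel$dvy^2)) else NA_real_,
    mean_abs_elongation = if (any(inc))
      global_mean_elongation(cells$qxx[inc], cells$qxy[inc]) else NA_real_,
    division_density = data.frame(
      time_mid_min = (time_edges[-1] + time_edges[-(nt + 1)]) / 2,
      count = div_tb, tissue_area_um2 = area_by_tb,
      density = ifelse(area_by_tb > 0, div_tb / area_by_tb, NA_real_)))

  run_log <- list(n_frames = n, n_cells = nrow(cells),
              n_border_excluded = sum(cells$border_flag),
              n_small_dropped = n_small,
              n_tracks = length(unique(tracks$track_id)),
              n_velocity_samples = nrow(vel),
              n_skipped_velocity = n_skip_vel,
              overflow_velocity = vel_map$metadata$overflow,
              overflow_shape = shp_map$metadata$overflow,
              overflow_divisions = div_map$metadata$overflow,
              config_hash = chash)
  if (!keep_masks) model$wound_masks <- model$tissue_masks <- NULL
  structure(list(model = model, cells = cells, velocities = vel,
                 heatmaps = list(velocity = vel_map, shape = shp_map,
                                 division_density = div_map,
                                 cell_density = den_map),
                 summaries = summaries, log = run_log, config = config),
            class = "wound_quantification")
}

# band_mat (frames x bands) -> (bands x time bins) summed areas
aggregate_band_areas <- function(band_mat, beyond, frame_interval_min, time_edges) {
  n <- nrow(band_mat)
  tb <- findInterval((seq_len(n) - 1) * frame_interval_min, time_edges,
                     rightmost.closed = TRUE)
  nt <- length(time_edges) - 1L
  out <- matrix(0, ncol(band_mat), nt)
  bey <- numeric(nt)
  for (b in seq_len(nt)) {
    rows <- which(tb == b)
    if (length(rows) > 0) {
      out[, b] <- colSums(band_mat[rows, , drop = FALSE])
      bey[b] <- sum(beyond[rows])
    }
  }
  attr(out, "beyond_um2") <- bey
  out
}

# density heatmap from precomputed sample distances
density_map_from <- function(d, tm, dist_edges, time_edges, areas, kind, chash) {
  nd <- length(dist_edges) - 1L; nt <- length(time_edges) - 1L
  ok <- is.finite(d)
  db <- findInterval(d[ok], dist_edges)
  tb <- findInterval(tm[ok], time_edges, rightmost.closed = TRUE)
  keep <- db >= 1 & db <= nd & d[ok] < dist_edges[nd + 1L] & tb >= 1 & tb <= nt
  counts <- matrix(tabulate((tb[keep] - 1L) * nd + db[keep], nbins = nd * nt), nd, nt)
  values <- ifelse(areas > 0, counts / areas, NA_real_)
  st_heatmap(values, areas, counts, dist_edges, time_edges, kind,
             list(overflow = sum(!keep), n_skipped = sum(!ok),
                  n_invalid_bins = sum(counts > 0 & areas == 0),
                  units = "events per um^2 per time bin", config_hash = chash))
}

#' Global (whole-field) summaries of a quantified movie
#'
#' Mean raw nucleus speed, mean deviation speed, mean cell elongation
#' magnitude, and the whole-tissue division density per time bin -- the
#' unbinned counterparts of the heatmaps, used for developmental-stage and
#' unwounded-tissue comparisons.
#'
#' @param result A [run_quantify()] result.
#' @return A list with \code{mean_speed_um_min},
#'   \code{mean_deviation_speed_um_min}, \code{mean_abs_elongation}, and
#'   \code{division_density} (data.frame \code{time_mid_min, count,
#'   tissue_area_um2, density}).
#' @export
global_summaries <- function(result) {
  stopifnot(inherits(result, "wound_quantification"))
  result$summaries
}

#' @export
print.wound_quantification <- function(x, ...) {
  cat("<wound_quantification>\n")
  print(x$model)
  cat("  cells:", x$log$n_cells, "(", x$log$n_border_excluded, "border-excluded,",
      x$log$n_small_dropped, "dropped )\n")
  cat("  tracks:", x$log$n_tracks, " velocity samples:", x$log$n_velocity_samples, "\n")
  cat("  heatmaps:", paste(names(x$heatmaps), collapse = ", "), "\n")
  invisible(x)
}

#' Compare control and perturbed wound movies
#'
#' Combines each arm's replicate heatmaps by tissue-area weighting, puts
#' the shape maps on the control arm's normalisation constant (robust
#' maximum of |dQ1|), optionally subtracts the smoothed unwounded
#' division-density baseline from both arms, and forms perturbed-minus-
#' control difference maps for all three behaviours.
#'
#' @param control,perturbed Lists of [run_quantify()] results (>= 1 each),
#'   on matching grids.
#' @param config An [analysis_config()].
#' @param unwounded Optional baseline: a list of unwounded
#'   [run_quantify()] results (pooled, then smoothed with a 3-point moving
#'   average), or a data.frame \code{time_mid_min, density} already
#'   smoothed. Without it, division differences are produced uncorrected
#'   with a warning.
#' @return An object of class \code{wound_comparison}: per-arm combined
#'   maps, difference maps, SNR maps per arm, and the baseline used.
#' @export
run_compare <- function(control, perturbed, config = analysis_config(),
                        unwounded = NULL) {
  stopifnot(length(control) >= 1, length(perturbed) >= 1)
  get_maps <- function(arm, kind) lapply(arm, function(r) r$heatmaps[[kind]])
  comb <- function(arm) list(
    velocity = combine_videos(get_maps(arm, "velocity")),
    shape = combine_videos(get_maps(arm, "shape")),
    division_density = combine_videos(get_maps(arm, "division_density")))
  ctl <- comb(control); prt <- comb(perturbed)

  # normalise both arms' shape maps by the control-arm constant
  ref <- ctl$shape
  ctl$shape <- normalise_shape_map(ctl$shape, ref, config$normalisation_percentile)
  prt$shape <- normalise_shape_map(prt$shape, ref, config$normalisation_percentile)
  baseline <- NULL
  if (!is.null(unwounded)) {
    baseline <- if (is.data.frame(unwounded)) unwounded else
      pooled_division_baseline(unwounded)
    ctl$division_density <- baseline_correct_divisions(ctl$division_density, baseline)
    prt$division_density <- baseline_correct_divisions(prt$division_density, baseline)
  } else {
    warning("no unwounded baseline supplied; division difference maps are uncorrected")
  }
  diffs <- list(
    velocity = difference_map(prt$velocity, ctl$velocity),
    shape = difference_map(prt$shape, ctl$shape),
    division_density = difference_map(prt$division_density, ctl$division_density))
  snr <- list()
  if (length(control) >= config$snr_min_videos)
    snr$control_velocity <- snr_map(get_maps(control, "velocity"),
                                    config$snr_min_videos)
  structure(list(control = ctl, perturbed = prt, difference = diffs,
                 snr = snr, baseline = baseline, config = config),
            class = "wound_comparison")
}

# pooled, smoothed whole-tissue division-density series from unwounded runs
pooled_division_baseline <- function(results) {
  stopifnot(length(results) >= 1)
  dd <- lapply(results, function(r) r$summaries$division_density)
  mids <- dd[[1]]$time_mid_min
  for (d in dd) if (!isTRUE(all.equal(d$time_mid_min, mids)))
    stop("unwounded runs have mismatched time bins")
  counts <- Reduce(`+`, lapply(dd, function(d) d$count))
  areas <- Reduce(`+`, lapply(dd, function(d) d$tissue_area_um2))
  dens <- ifelse(areas > 0, counts / areas, NA_real_)
  data.frame(time_mid_min = mids, density = moving_average(dens, 3))
}

#' @export
print.wound_comparison <- function(x, ...) {
  cat("<wound_comparison>\n")
  cat("  corrected for unwounded baseline:", !is.null(x$baseline), "\n")
  for (k in names(x$difference)) {
    v <- x$difference[[k]]$values
    cat(sprintf("  diff %-18s occupied %d, range [%.3g, %.3g]\n", k,
                sum(is.finite(v)), suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
  }
  invisible(x)
}

#' Serialise a heatmap to JSON (and back)
#'
#' Structured-text round trip for [st_heatmap()] objects: bin edges,
#' values, weights, counts, kind and metadata (including any normalisation
#' constant). Missing bins are stored as nulls.
#'
#' @param map An \code{st_heatmap}.
#' @param path Output file.
#' @return \code{write_st_heatmap}: the path, invisibly;
#'   \code{read_st_heatmap}: the reconstructed \code{st_heatmap}.
#' @export
write_st_heatmap <- function(map, path) {
  obj <- list(kind = map$kind, dist_edges_um = map$dist_edges_um,
              time_edges_min = map$time_edges_min,
              values = map$values, weights = map$weights, counts = map$counts,
              metadata = map$metadata)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null", matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname write_st_heatmap
#' @export
read_st_heatmap <- function(path) {
  obj <- jsonlite::fromJSON(path)
  as_mat <- function(m) {
    m[vapply(m, is.null, logical(1))] <- NA_real_
    matrix(as.numeric(unlist(m)), length(obj$dist_edges_um) - 1L,
           length(obj$time_edges_min) - 1L, byrow = TRUE)
  }
  to_m <- function(x) if (is.matrix(x)) x else as_mat(x)
  st_heatmap(to_m(obj$values), to_m(obj$weights), to_m(obj$counts),
             obj$dist_edges_um, obj$time_edges_min, obj$kind,
             as.list(obj$metadata))
}
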