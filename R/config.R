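#' Analysis configuration
#'
#' Collects every figure-affecting constant of the quantification pipeline.
#' Acquisition defaults match a 123.26 x 123.26 um field imaged at
#' 512 x 512 px every 2 min; wound-size classes and the 20% closure rule use
#' the published thresholds; binning and tracking defaults are package
#' choices recorded in all outputs.
#'
#' @param pixel_size_um Pixel size, um/px.
#' @param frame_interval_min Frame interval, minutes.
#' @param band_width_um Width of the annular distance bands, um.
#' @param time_width_min Width of the time bins, minutes.
#' @param distance_max_um Largest distance edge of the heatmap grid, um.
#'   Samples beyond it are tallied as overflow, never silently dropped.
#' @param closure_fraction A wound is closed at the first frame its area
#'   falls to this fraction of the reference (classification-window) area.
#' @param classification_window_min Two-element window (minutes) whose mean
#'   area classifies wound size.
#' @param small_range_um2,large_range_um2 Inclusive area ranges (um^2) for
#'   the small and large wound classes.
#' @param site_tracking_radius_um Neighbourhood radius for post-closure
#'   wound-site tracking, um.
#' @param normalisation_percentile Percentile of |dQ1| used as the robust
#'   maximum when normalising shape maps.
#' @param snr_min_videos Minimum replicate videos for a signal-to-noise bin.
#' @param min_cell_area_px Segmented regions smaller than this are dropped
#'   (and counted) before shape analysis.
#' @param max_link_distance_um Longest frame-to-frame link the nucleus
#'   linker will accept, um.
#'
#' @return A list of class \code{wq_config}.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$band_width_um
analysis_config <- function(pixel_size_um = 123.26 / 512,
                            frame_interval_min = 2,
                            band_width_um = 10,
                            time_width_min = 4,
                            distance_max_um = 120,
                            closure_fraction = 0.2,
                            classification_window_min = c(9, 10),
                            small_range_um2 = c(200, 400),
                            large_range_um2 = c(700, 1100),
                            site_tracking_radius_um = 30,
                            normalisation_percentile = 95,
                            snr_min_videos = 2,
                            min_cell_area_px = 9,
                            max_link_distance_um = 3) {
  stopifnot(pixel_size_um > 0, frame_interval_min > 0, band_width_um > 0,
            time_width_min > 0, distance_max_um > 0,
            closure_fraction > 0, closure_fraction < 1,
            length(classification_window_min) == 2,
            diff(classification_window_min) >= 0,
            length(small_range_um2) == 2, length(large_range_um2) == 2,
            site_tracking_radius_um > 0,
            normalisation_percentile > 0, normalisation_percentile <= 100,
            snr_min_videos >= 2, min_cell_area_px >= 1,
            max_link_distance_um > 0)
  structure(list(
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min,
    band_width_um = band_width_um,
    time_width_min = time_width_min,
    distance_max_um = distance_max_um,
    closure_fraction = closure_fraction,
    classification_window_min = classification_window_min,
    small_range_um2 = small_range_um2,
    large_range_um2 = large_range_um2,
    site_tracking_radius_um = site_tracking_radius_um,
    normalisation_percentile = normalisation_percentile,
    snr_min_videos = snr_min_videos,
    min_cell_area_px = min_cell_area_px,
    max_link_distance_um = max_link_distance_um
  ), class = "wq_config")
}

#' @export
print.wq_config <- function(x, ...) {
  cat("<wq_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# stable short hash of a config, recorded in every output
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), f)
  unname(substr(tools::md5sum(f), 1, 12))
}

# distance-bin edges implied by a config
dist_edges_of <- function(config) {
  seq(0, config$distance_max_um, by = config$band_width_um)
}

# time-bin edges covering n frames
time_edges_of <- function(config, n_frames) {
  t_end <- n_frames * config$frame_interval_min
  seq(0, ceiling(t_end / config$time_width_min) * config$time_width_min,
      by = config$time_width_min)
}
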