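#' Link per-frame nucleus detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: a
#' detection in frame f links to a detection in frame f+1 only if each is
#' the other's nearest neighbour and they are at most
#' \code{max_link_distance_um} apart. Unlinked detections start new tracks.
#' No gap closing, merging or splitting is attempted.
#'
#' @param detections Data.frame with columns \code{frame} (0-based),
#'   \code{x_um}, \code{y_um}.
#' @param max_link_distance_um Longest accepted link, um.
#' @return Data.frame \code{track_id, frame, x_um, y_um}, ordered by track
#'   then frame.
#' @export
link_detections <- function(detections, max_link_distance_um) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)),
            max_link_distance_um > 0)
  d <- detections[order(detections$frame), , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric()))
  frames <- sort(unique(d$frame))
  rows_of <- split(seq_len(nrow(d)), d$frame)
  track <- integer(nrow(d))
  next_id <- 1L
  prev <- rows_of[[as.character(frames[1])]]
  track[prev] <- seq_len(length(prev))
  next_id <- length(prev) + 1L
  for (k in seq_along(frames)[-1]) {
    cur <- rows_of[[as.character(frames[k])]]
    linked <- rep(FALSE, length(cur))
    if (frames[k] == frames[k - 1] + 1 && length(prev) > 0) {
      dx <- outer(d$x_um[prev], d$x_um[cur], "-")
      dy <- outer(d$y_um[prev], d$y_um[cur], "-")
      dist <- sqrt(dx^2 + dy^2)
      nn_fwd <- apply(dist, 1, which.min)   # for each prev, nearest cur
      nn_bwd <- apply(dist, 2, which.min)   # for each cur, nearest prev
      for (i in seq_along(prev)) {
        j <- nn_fwd[i]
        if (nn_bwd[j] == i && dist[i, j] <= max_link_distance_um) {
          track[cur[j]] <- track[prev[i]]
          linked[j] <- TRUE
        }
      }
    }
    if (any(!linked)) {
      nnew <- sum(!linked)
      track[cur[!linked]] <- seq.int(next_id, length.out = nnew)
      next_id <- next_id + nnew
    }
    prev <- cur
  }
  out <- data.frame(track_id = track, frame = d$frame, x_um = d$x_um, y_um = d$y_um)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-difference velocities along tracks
#'
#' \eqn{v(f) = (x(f+1) - x(f)) / \Delta t}, assigned to the earlier frame f.
#' The last sample of a track, and samples followed by a gap, yield no
#' velocity and are omitted from the output.
#'
#' @param tracks Data.frame \code{track_id, frame, x_um, y_um}.
#' @param frame_interval_min Frame interval, minutes.
#' @return Data.frame \code{track_id, frame, x_um, y_um, vx, vy} with
#'   velocities in um/min.
#' @export
track_velocities <- function(tracks, frame_interval_min) {
  stopifnot(frame_interval_min > 0)
  t <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  n <- nrow(t)
  if (n < 2)
    return(data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
                      y_um = numeric(), vx = numeric(), vy = numeric()))
  same <- t$track_id[-n] == t$track_id[-1]
  consec <- t$frame[-1] == t$frame[-n] + 1L
  ok <- which(same & consec)
  data.frame(track_id = t$track_id[ok], frame = t$frame[ok],
             x_um = t$x_um[ok], y_um = t$y_um[ok],
             vx = (t$x_um[ok + 1] - t$x_um[ok]) / frame_interval_min,
             vy = (t$y_um[ok + 1] - t$y_um[ok]) / frame_interval_min,
             row.names = NULL)
}

#' Subtract the per-frame mean tissue flow
#'
#' Removes the general migration of the tissue: for every frame the
#' unweighted mean velocity over all samples in that frame is subtracted,
#' leaving deviation velocities \code{dvx, dvy} whose per-frame mean is the
#' zero vector. The operation is idempotent.
#'
#' @param velocities Data.frame as from [track_velocities()].
#' @return The input with columns \code{dvx, dvy} added or refilled.
#' @export
subtract_mean_flow <- function(velocities) {
  if (nrow(velocities) == 0) {
    velocities$dvx <- numeric(0); velocities$dvy <- numeric(0)
    return(velocities)
  }
  velocities$dvx <- velocities$vx - ave(velocities$vx, velocities$frame)
  velocities$dvy <- velocities$vy - ave(velocities$vy, velocities$frame)
  velocities
}

#' Towards-wound component of the deviation velocity
#'
#' Projects the deviation velocity onto the wound-radial axis:
#' \eqn{s_{toward} = -\,dv \cdot \hat r} with \eqn{\hat r} the outward unit
#' vector from the wound centre to the nucleus, so positive values mean
#' motion towards the wound.
#'
#' @param velocities Data.frame with \code{frame, x_um, y_um, dvx, dvy}.
#' @param centre_um Wound centre: length-2 point, or an n x 2 matrix of
#'   per-sample centres (e.g. the tracked wound site at each sample's frame).
#' @return The input with an \code{s_toward} column (um/min); samples
#'   coincident with the centre get NA with a warning (count in attribute
#'   \code{"n_skipped"}).
#' @export
toward_wound_component <- function(velocities, centre_um) {
  ctr <- if (is.matrix(centre_um)) centre_um else
    matrix(centre_um, nrow = nrow(velocities), ncol = 2, byrow = TRUE)
  rx <- velocities$x_um - ctr[, 1]; ry <- velocities$y_um - ctr[, 2]
  rn <- sqrt(rx^2 + ry^2)
  bad <- rn < .Machine$double.eps * 100
  rn[bad] <- NA_real_
  velocities$s_toward <- -(velocities$dvx * rx + velocities$dvy * ry) / rn
  if (any(bad, na.rm = TRUE))
    warning(sum(bad), " sample(s) coincident with the wound centre skipped")
  attr(velocities, "n_skipped") <- sum(bad, na.rm = TRUE)
  velocities
}
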