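#' Per-cell nematic shape tensor (q-tensor)
#'
#' The q-tensor of a cell is the dimensionless, traceless, symmetric 2x2
#' tensor \eqn{q = S/\mathrm{tr}(S) - I/2}, where \eqn{S} is the centred
#' second-moment-of-area tensor of the cell region. Its eigenvalues are
#' \eqn{\pm\sqrt{q_{xx}^2+q_{xy}^2}} and lie in (-1/2, 1/2); the positive
#' eigenvector is the elongation axis. A disc has q = 0; an axis-aligned
#' ellipse with semi-axes a > b has \eqn{q_{xx} = (a^2-b^2)/(2(a^2+b^2))}.
#' q is invariant under translation and uniform scaling and equivariant
#' under rotation (\eqn{q' = R q R^T}).
#'
#' Two evaluation paths are provided. \code{shape_tensor_polygon} integrates
#' the moments exactly over a simple polygon (Green's theorem);
#' \code{shape_tensor_pixels} sums over pixel centres, adding the 1/12
#' per-pixel variance so a pixel is treated as a unit square. The two agree
#' within 0.01 on regions of 100 px or more.
#'
#' @param vertices Two-column matrix of polygon vertices (any units), in
#'   order, open or closed.
#' @param x,y Pixel-centre coordinates of the region's pixels (pixel units).
#' @param cell Optional cell identifier used in error messages.
#' @return A list with components \code{qxx}, \code{qxy}, \code{area},
#'   \code{centroid} (length-2). Area and centroid are in the input units.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)[-1]
#' ell <- cbind(20 * cos(th), 10 * sin(th))   # 2:1 ellipse
#' shape_tensor_polygon(ell)$qxx              # ~ 0.3
shape_tensor_polygon <- function(vertices, cell = NULL) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) stop("polygon needs >= 3 two-column vertices")
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop("degenerate region (zero area)", if (!is.null(cell)) paste0(" for cell ", cell))
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # raw second moments about the origin, per unit area after division by A
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  sxx <- ixx / A - cx^2
  syy <- iyy / A - cy^2
  sxy <- ixy / A - cx * cy
  q_from_s(sxx, syy, sxy, cell = cell, area = abs(A), centroid = c(cx, cy))
}

#' @rdname shape_tensor_polygon
#' @export
shape_tensor_pixels <- function(x, y, cell = NULL) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 1) stop("degenerate region (zero area)",
                  if (!is.null(cell)) paste0(" for cell ", cell))
  cx <- mean(x); cy <- mean(y)
  sxx <- mean(x^2) - cx^2 + 1 / 12
  syy <- mean(y^2) - cy^2 + 1 / 12
  sxy <- mean(x * y) - cx * cy
  q_from_s(sxx, syy, sxy, cell = cell, area = n, centroid = c(cx, cy))
}

#' @rdname shape_tensor_polygon
#' @param region Either an n x 2 matrix of pixel-centre coordinates
#'   (\code{type = "pixels"}) or of polygon vertices (\code{type =
#'   "polygon"}).
#' @param type Which evaluation path to use.
#' @export
cell_shape_tensor <- function(region, type = c("pixels", "polygon"), cell = NULL) {
  region <- as.matrix(region)
  if (ncol(region) != 2) stop("region must have two columns (x, y)")
  switch(match.arg(type),
         pixels = shape_tensor_pixels(region[, 1], region[, 2], cell = cell),
         polygon = shape_tensor_polygon(region, cell = cell))
}

q_from_s <- function(sxx, syy, sxy, cell = NULL, area = NA, centroid = c(NA, NA)) {
  tr <- sxx + syy
  if (!is.finite(tr) || tr <= 0)
    stop("degenerate region (tr(S) = 0)", if (!is.null(cell)) paste0(" for cell ", cell))
  list(qxx = sxx / tr - 0.5, qxy = sxy / tr, area = area, centroid = centroid)
}

#' Per-cell measurements from a label image
#'
#' Vectorised region analysis of one segmented frame: area, centroid and
#' q-tensor of every labelled region, with cells touching the field border
#' flagged (border-truncated cells bias elongation and are excluded from
#' tissue means and binned shape statistics downstream). Regions smaller
#' than \code{min_area_px} are dropped and counted in the
#' \code{"n_dropped"} attribute.
#'
#' @param labels Integer matrix; 0 is background, positive values are cell
#'   labels. Rows are y (downward), columns x (rightward), pixel centres at
#'   0-based integer coordinates.
#' @param pixel_size_um Pixel size, um/px.
#' @param frame 0-based frame index stored in the output.
#' @param min_area_px Minimum region area in pixels.
#' @return A data.frame with columns \code{frame, cell_id, centroid_x_um,
#'   centroid_y_um, area_px, area_um2, qxx, qxy, border_flag}.
#' @export
cells_from_labels <- function(labels, pixel_size_um, frame = 0L, min_area_px = 9) {
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    out <- data.frame(frame = integer(), cell_id = integer(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      area_px = numeric(), area_um2 = numeric(),
                      qxx = numeric(), qxy = numeric(), border_flag = logical())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  ny <- nrow(labels); nx <- ncol(labels)
  lab <- labels[idx]
  yy <- (idx - 1L) %% ny          # 0-based row
  xx <- (idx - 1L) %/% ny         # 0-based col
  m <- rowsum(cbind(1, xx, yy, xx^2, yy^2, xx * yy), lab)
  ids <- as.integer(rownames(m))
  n <- m[, 1]
  cx <- m[, 2] / n; cy <- m[, 3] / n
  sxx <- m[, 4] / n - cx^2 + 1 / 12
  syy <- m[, 5] / n - cy^2 + 1 / 12
  sxy <- m[, 6] / n - cx * cy
  tr <- sxx + syy
  border_ids <- unique(c(labels[1, ], labels[ny, ], labels[, 1], labels[, nx]))
  out <- data.frame(
    frame = as.integer(frame), cell_id = ids,
    centroid_x_um = cx * pixel_size_um, centroid_y_um = cy * pixel_size_um,
    area_px = n, area_um2 = n * pixel_size_um^2,
    qxx = sxx / tr - 0.5, qxy = sxy / tr,
    border_flag = ids %in% border_ids, row.names = NULL)
  keep <- out$area_px >= min_area_px & tr > 0
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tissue mean tensor and per-cell deviations
#'
#' The tissue mean Q is the unweighted component-wise mean q-tensor over the
#' included cells (border-flagged cells excluded); subtracting it from each
#' cell removes the tissue's global nematic order, leaving deviations
#' \eqn{\delta q_i = q_i - Q} whose mean over included cells is the zero
#' tensor by construction.
#'
#' @param cells Data.frame as from [cells_from_labels()] (one frame).
#' @param include Logical vector of cells entering the mean; default
#'   excludes border-flagged cells.
#' @return A list with \code{Q} (named c(qxx, qxy)) and \code{cells}: the
#'   input with deviation columns \code{dqxx, dqxy} (NA for excluded cells).
#' @export
tissue_shape_summary <- function(cells, include = !cells$border_flag) {
  if (nrow(cells) == 0 || sum(include) == 0)
    stop("no included cells for tissue mean")
  Q <- c(qxx = mean(cells$qxx[include]), qxy = mean(cells$qxy[include]))
  cells$dqxx <- ifelse(include, cells$qxx - Q[["qxx"]], NA_real_)
  cells$dqxy <- ifelse(include, cells$qxy - Q[["qxy"]], NA_real_)
  list(Q = Q, cells = cells)
}

#' Radial elongation dQ1 relative to a wound centre
#'
#' Rotates a deviation tensor into the frame whose first axis points from
#' the wound centre to the cell and returns its radial-radial component,
#' \eqn{dQ1 = \hat r^T \,\delta q\, \hat r}. Positive values mean the cell
#' is elongated along the wound-radial axis (towards the wound); by
#' tracelessness the tangential component is \code{-dQ1}, so negative
#' values mean elongation along the wound margin.
#'
#' @param dqxx,dqxy Deviation tensor components (vectorised).
#' @param x_um,y_um Cell centroid coordinates, um.
#' @param centre_um Wound centre, length-2 (um), or an n x 2 matrix of
#'   per-sample centres.
#' @return Numeric vector of dQ1 values; samples coincident with the centre
#'   get NA with a warning (count in attribute \code{"n_skipped"}).
#' @export
#' @examples
#' radial_elongation(0.1, 0, 1, 0, c(0, 0))   #  0.1 (radial)
#' radial_elongation(0.1, 0, 0, 1, c(0, 0))   # -0.1 (tangential)
radial_elongation <- function(dqxx, dqxy, x_um, y_um, centre_um) {
  ctr <- if (is.matrix(centre_um)) centre_um else
    matrix(centre_um, nrow = length(x_um), ncol = 2, byrow = TRUE)
  rx <- x_um - ctr[, 1]; ry <- y_um - ctr[, 2]
  r2 <- rx^2 + ry^2
  bad <- r2 < .Machine$double.eps * 100
  r2[bad] <- NA_real_
  out <- dqxx * (rx^2 - ry^2) / r2 + dqxy * 2 * rx * ry / r2
  if (any(bad, na.rm = TRUE))
    warning(sum(bad), " sample(s) coincident with the wound centre skipped")
  attr(out, "n_skipped") <- sum(bad, na.rm = TRUE)
  out
}

#' Global mean elongation magnitude
#'
#' Mean over cells of the largest-magnitude eigenvalue of the q-tensor,
#' \eqn{\sqrt{q_{xx}^2 + q_{xy}^2}}; a whole-tissue elongation summary used
#' as a developmental-stage proxy and for unwounded-tissue comparisons.
#'
#' @param qxx,qxy q-tensor components (vectorised over cells).
#' @return Scalar mean elongation magnitude.
#' @export
global_mean_elongation <- function(qxx, qxy) {
  if (length(qxx) == 0) stop("no cells")
  mean(sqrt(qxx^2 + qxy^2))
}

#' Shape orientation angle
#'
#' Orientation of the elongation axis, \eqn{\theta = \frac12
#' \mathrm{atan2}(2 q_{xy},\; q_{xx} - q_{yy})}, reported in [0, pi).
#' Derived from the tensor, not stored.
#'
#' @inheritParams global_mean_elongation
#' @return Angles in radians in [0, pi).
#' @export
cell_orientation <- function(qxx, qxy) {
  (0.5 * atan2(2 * qxy, 2 * qxx)) %% pi
}
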