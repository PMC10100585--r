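#' Image grid
#'
#' A square-pixel image grid centred on the rotation axis. Pixel (r, c)
#' (1-based) has its centre at
#' \eqn{x = (c - 1 - (n_{cols}-1)/2)\,h}, \eqn{y = ((n_{rows}-1)/2 - (r - 1))\,h}
#' with \eqn{h} the pixel size, so symmetric grids centre exactly on the axis.
#'
#' @param n_rows,n_cols Number of rows/columns (>= 1).
#' @param pixel_size Physical pixel side length (> 0); arbitrary units,
#'   the reconstruction grid conventionally uses 1.0.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(n_rows, n_cols = n_rows, pixel_size = 1.0) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L, length(pixel_size) == 1L)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("image_grid: n_rows and n_cols must be >= 1")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("image_grid: pixel_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size),
            class = "image_grid")
}

#' Detector description
#'
#' A 1-D array of equally spaced detection bins. Bin b (0-based) has its
#' centre at \eqn{s_b = (b - (n_{bins}-1)/2)\,w + \delta} where \eqn{w} is the
#' bin width and \eqn{\delta} the signed offset of the detector midpoint from
#' the projection of the rotation axis; a nonzero offset makes the detector
#' asymmetric (the truncated, interior-problem configuration).
#'
#' @param n_bins Number of bins (>= 1).
#' @param bin_width Bin width (> 0), same units as the grid pixel size.
#' @param center_offset Signed displacement of the detector midpoint from the
#'   axis (default 0 = symmetric).
#' @return An object of class `detector`.
#' @export
detector <- function(n_bins, bin_width = 1.0, center_offset = 0.0) {
  stopifnot(length(n_bins) == 1L)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("detector: n_bins must be >= 1")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("detector: bin_width must be > 0")
  if (!is.finite(center_offset))
    stop("detector: center_offset must be finite")
  structure(list(n_bins = n_bins, bin_width = bin_width,
                 center_offset = center_offset),
            class = "detector")
}

#' Bin centre positions of a detector
#'
#' @param d A `detector`.
#' @return Numeric vector of signed bin-centre positions, strictly increasing.
#' @export
bin_centers <- function(d) {
  stopifnot(inherits(d, "detector"))
  (seq_len(d$n_bins) - 1 - (d$n_bins - 1) / 2) * d$bin_width + d$center_offset
}

#' View-angle set
#'
#' Equally spaced view angles; the default is the 180-view, 1-degree-step
#' half-turn acquisition (a 180 degree span suffices for parallel beams).
#'
#' @param n_views Number of views (>= 1).
#' @param start_angle First view angle in degrees.
#' @param angular_increment Step between views in degrees.
#' @return An object of class `view_set`.
#' @export
view_set <- function(n_views = 180L, start_angle = 0.0, angular_increment = 1.0) {
  n_views <- as.integer(n_views)
  if (is.na(n_views) || n_views < 1L)
    stop("view_set: n_views must be >= 1")
  structure(list(n_views = n_views, start_angle = start_angle,
                 angular_increment = angular_increment),
            class = "view_set")
}

#' View angles in degrees
#' @param v A `view_set`.
#' @return Numeric vector of angles.
#' @export
view_angles <- function(v) {
  stopifnot(inherits(v, "view_set"))
  v$start_angle + (seq_len(v$n_views) - 1) * v$angular_increment
}

#' Assemble a parallel-beam scan geometry
#'
#' Combines grid, physical detector and views, and constructs the extended
#' virtual detector on which sinograms live: the smallest odd-count symmetric
#' detector whose span covers the grid diagonal, grown further (staying odd
#' and symmetric) until every physical bin centre lies on one of its bin
#' centres. Unmeasured projection values live on the extended bins; the
#' physical bins form the contiguous measured subset, identical at every view.
#'
#' @param grid An `image_grid`.
#' @param det A `detector` (the physical detector).
#' @param views A `view_set`.
#' @return An object of class `scan_geometry` with elements `grid`, `detector`,
#'   `views`, `extended_detector` and `measured` (logical mask over extended
#'   bins).
#' @export
make_geometry <- function(grid, det, views = view_set()) {
  stopifnot(inherits(grid, "image_grid"), inherits(det, "detector"),
            inherits(views, "view_set"))
  w <- det$bin_width
  diag_len <- sqrt((grid$n_rows * grid$pixel_size)^2 +
                   (grid$n_cols * grid$pixel_size)^2)
  phys <- bin_centers(det)
  # A symmetric extended detector has centers at integer multiples of w when
  # its bin count is odd, half-integer multiples when even; the physical
  # centers must sit on one of the two lattices.
  lat <- phys / w
  on_int <- max(abs(lat - round(lat))) < 1e-9
  on_half <- max(abs(lat + 0.5 - round(lat + 0.5))) < 1e-9
  if (!on_int && !on_half)
    stop("make_geometry: physical bin centers do not align with a symmetric extended-detector lattice (invalid geometry)")
  # (n_ext - 1)/2 must reach both the grid half-diagonal and the outermost
  # physical bin center
  half_need <- max(diag_len / (2 * w), max(abs(lat)))
  n_ext <- 2L * as.integer(ceiling(half_need - if (on_int) 0 else 0.5)) +
    if (on_int) 1L else 2L
  ext <- detector(n_ext, bin_width = w, center_offset = 0.0)
  ec <- bin_centers(ext)
  idx <- as.integer(round(lat + (n_ext - 1) / 2)) + 1L
  if (any(idx < 1L | idx > n_ext))
    stop("make_geometry: physical detector wider than extended detector (invalid geometry)")
  measured <- logical(n_ext)
  measured[idx] <- TRUE
  stopifnot(max(abs(ec[idx] - phys)) < 1e-9 * w + 1e-12)
  structure(list(grid = grid, detector = det, views = views,
                 extended_detector = ext, measured = measured),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %dx%d grid (pixel %g), %d views, %d/%d measured bins (width %g, offset %g)\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_size,
              x$views$n_views, sum(x$measured), x$extended_detector$n_bins,
              x$detector$bin_width, x$detector$center_offset))
  invisible(x)
}

# pixel-centre coordinates (x, y) in physical units, row-major order
# (row 1 = top). Internal.
pixel_centers <- function(grid) {
  h <- grid$pixel_size
  cx <- (seq_len(grid$n_cols) - 1 - (grid$n_cols - 1) / 2) * h
  cy <- ((grid$n_rows - 1) / 2 - (seq_len(grid$n_rows) - 1)) * h
  list(x = matrix(cx, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(cy, grid$n_rows, grid$n_cols))
}

# measured span [lo, hi] of signed detector coordinates, or NULL if no
# measured bins. Internal.
measured_span <- function(g) {
  if (!any(g$measured)) return(NULL)
  ec <- bin_centers(g$extended_detector)
  w <- g$extended_detector$bin_width
  mc <- ec[g$measured]
  c(min(mc) - w / 2, max(mc) + w / 2)
}

#' Angular-coverage map
#'
#' For each pixel, the fraction of view angles at which the parallel ray
#' through the pixel centre falls inside the measured detector span. A pixel
#' with coverage 1 satisfies the 2-D Kirillov criterion: every line through it
#' over the half-turn is measured.
#'
#' A pixel counts as covered at a view when its centre's signed distance to
#' the axis, \eqn{s = x\cos\theta + y\sin\theta}, lies within
#' [first measured bin centre - width/2, last measured bin centre + width/2].
#'
#' @param g A `scan_geometry`.
#' @return Matrix (n_rows x n_cols) of coverage fractions in [0, 1].
#' @export
angular_coverage_map <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  span <- measured_span(g)
  if (is.null(span))
    return(matrix(0, g$grid$n_rows, g$grid$n_cols))
  th <- view_angles(g$views) * pi / 180
  pc <- pixel_centers(g$grid)
  # s for all pixels x views: N x V
  s <- cbind(as.vector(pc$x), as.vector(pc$y)) %*% rbind(cos(th), sin(th))
  cov <- rowMeans(s >= span[1] & s <= span[2])
  matrix(cov, g$grid$n_rows, g$grid$n_cols)
}

#' Region-of-interest mask (Kirillov criterion)
#'
#' Pixels whose angular coverage is exactly 1, i.e. every line through the
#' pixel over the view span is measured. For a symmetric detector this is a
#' centred disk of radius half the measured span; an asymmetric (truncated)
#' detector shrinks it to a disk of radius equal to the nearer measured edge.
#'
#' @param g A `scan_geometry`.
#' @return Logical matrix, `TRUE` inside the ROI.
#' @export
roi_mask <- function(g) {
  angular_coverage_map(g) == 1
}
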