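#' Build the parallel-beam projection operator
#'
#' Constructs the sparse system matrix A for a scan geometry: one row per
#' (view, extended bin) ray, one column per pixel (row-major), entries the
#' exact intersection length of the bin's central ray with the pixel
#' (Siddon ray marching, compiled). Forward projection is `A x`,
#' back-projection the literal transpose `t(A) p`, so the pair is an exact
#' adjoint by construction.
#'
#' @param g A `scan_geometry`.
#' @return An object of class `projection_operator` with elements `geometry`,
#'   `A` (a `Matrix::dgCMatrix` of size n_views*n_bins_ext x n_pixels),
#'   `scheme` ("siddon-central-ray").
#' @export
projection_operator <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  tr <- siddon_triplets(g$grid$n_rows, g$grid$n_cols, g$grid$pixel_size,
                        bin_centers(g$extended_detector),
                        view_angles(g$views))
  A <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                            dims = c(tr$n_rays, tr$n_pixels))
  structure(list(geometry = g, A = A, scheme = "siddon-central-ray"),
            class = "projection_operator")
}

#' @export
print.projection_operator <- function(x, ...) {
  cat(sprintf("projection_operator (%s): %d rays x %d pixels, %d nonzeros\n",
              x$scheme, nrow(x$A), ncol(x$A), Matrix::nnzero(x$A)))
  invisible(x)
}

#' Construct a sinogram container
#'
#' @param values Matrix n_views x n_bins_extended of line-integral values.
#' @param g The `scan_geometry` the values live on.
#' @return An object of class `sinogram` (`values`, `measured`, `geometry`).
#' @export
sinogram <- function(values, g) {
  stopifnot(inherits(g, "scan_geometry"), is.matrix(values))
  if (nrow(values) != g$views$n_views ||
      ncol(values) != g$extended_detector$n_bins)
    stop("sinogram: values must be n_views x n_bins_extended")
  if (any(!is.finite(values)))
    stop("sinogram: values must be finite")
  structure(list(values = values, measured = g$measured, geometry = g),
            class = "sinogram")
}

# view-major ray vector <-> views x bins matrix
sino_vec <- function(values) as.vector(t(values))
vec_sino <- function(v, g) {
  matrix(v, g$views$n_views, g$extended_detector$n_bins, byrow = TRUE)
}

#' Forward projection
#'
#' Line integrals of an image over every (view, extended bin) ray:
#' \eqn{p_j = \sum_i a_{ij} x_i}. Linear in the image.
#'
#' @param op A `projection_operator`.
#' @param x Numeric matrix matching the operator's grid.
#' @return A `sinogram`.
#' @export
forward_project <- function(op, x) {
  stopifnot(inherits(op, "projection_operator"), is.matrix(x))
  g <- op$geometry
  if (nrow(x) != g$grid$n_rows || ncol(x) != g$grid$n_cols)
    stop("forward_project: image shape does not match operator grid")
  p <- as.numeric(op$A %*% as.vector(t(x)))
  sinogram(vec_sino(p, g), g)
}

#' Back-projection (adjoint of the forward projector)
#'
#' \eqn{x_i = \sum_j a_{ij} p_j}, the exact transpose of [forward_project()].
#'
#' @param op A `projection_operator`.
#' @param s A `sinogram` on the operator's geometry, or a values matrix.
#' @return Numeric image matrix.
#' @export
back_project <- function(op, s) {
  stopifnot(inherits(op, "projection_operator"))
  v <- if (inherits(s, "sinogram")) s$values else s
  g <- op$geometry
  if (!is.matrix(v) || nrow(v) != g$views$n_views ||
      ncol(v) != g$extended_detector$n_bins)
    stop("back_project: sinogram shape does not match operator geometry")
  xv <- as.numeric(Matrix::crossprod(op$A, sino_vec(v)))
  matrix(xv, g$grid$n_rows, g$grid$n_cols, byrow = TRUE)
}

#' Combine adjacent detector bins
#'
#' Averages each group of `factor` consecutive measured bins into one coarse
#' bin (the fine-to-coarse detector bin-down of the data-generation protocol;
#' averaging rather than summing keeps values on the line-integral scale of
#' the coarse system matrix). The returned sinogram lives on the coarse
#' geometry: grid downsampled by `factor` at `factor`-times the pixel size,
#' detector with n/`factor` bins of `factor`-times the width and the same
#' centre offset.
#'
#' @param s A `sinogram` whose measured bin count is divisible by `factor`.
#' @param factor Integer bin-combination factor (default 3).
#' @return A `sinogram` on the coarse geometry; unmeasured coarse bins are 0.
#' @export
bin_down <- function(s, factor = 3L) {
  stopifnot(inherits(s, "sinogram"))
  factor <- as.integer(factor)
  g <- s$geometry
  n_meas <- sum(g$measured)
  if (n_meas %% factor != 0L)
    stop("bin_down: measured bin count not divisible by factor")
  if (g$grid$n_rows %% factor != 0L || g$grid$n_cols %% factor != 0L)
    stop("bin_down: grid size not divisible by factor")
  M <- s$values[, g$measured, drop = FALSE]     # views x n_meas
  nv <- nrow(M); nc2 <- n_meas %/% factor
  dim(M) <- c(nv, factor, nc2)
  Mc <- apply(M, c(1, 3), mean)
  coarse_grid <- image_grid(g$grid$n_rows %/% factor, g$grid$n_cols %/% factor,
                            g$grid$pixel_size * factor)
  coarse_det <- detector(nc2, bin_width = g$detector$bin_width * factor,
                         center_offset = g$detector$center_offset)
  cg <- make_geometry(coarse_grid, coarse_det, g$views)
  vals <- matrix(0, nv, cg$extended_detector$n_bins)
  vals[, cg$measured] <- Mc
  sinogram(vals, cg)
}

#' Add Poisson noise to measured line integrals
#'
#' Each measured bin value v is replaced by
#' `rpois(counts_per_unit * v) / counts_per_unit` (emission-style scaled
#' Poisson applied directly to the line integrals); unmeasured bins are left
#' untouched. Deterministic for a given seed; the caller's RNG state is
#' preserved.
#'
#' @param s A `sinogram` with nonnegative measured values.
#' @param counts_per_unit Expected photon counts per line-integral unit
#'   (> 0); larger means less relative noise. Default 500.
#' @param seed Integer seed.
#' @return A noisy `sinogram`.
#' @export
add_poisson_noise <- function(s, counts_per_unit = 500, seed) {
  stopifnot(inherits(s, "sinogram"), counts_per_unit > 0)
  v <- s$values[, s$measured, drop = FALSE]
  if (any(v < -1e-9)) stop("add_poisson_noise: negative sinogram values")
  v[v < 0] <- 0
  noisy <- with_private_seed(seed, {
    matrix(stats::rpois(length(v), counts_per_unit * v) / counts_per_unit,
           nrow(v), ncol(v))
  })
  out <- s$values
  out[, s$measured] <- noisy
  sinogram(out, s$geometry)
}
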