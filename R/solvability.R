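#' Squared-error image
#'
#' Pixel-wise squared difference between a reconstruction and its
#' reconstruction-scale ground truth: \eqn{e_i = (x_i - x_i^{true})^2}.
#'
#' @param recon Reconstructed image matrix (or a `recon_result`).
#' @param truth Ground-truth matrix of the same shape.
#' @return Nonnegative matrix of squared errors.
#' @export
squared_error_image <- function(recon, truth) {
  if (inherits(recon, "recon_result")) recon <- recon$image
  stopifnot(is.matrix(recon), is.matrix(truth))
  if (!identical(dim(recon), dim(truth)))
    stop("squared_error_image: shape mismatch")
  (recon - truth)^2
}

#' Streaming accumulator for solvability maps
#'
#' Keeps a running sum of squared-error images so maps over many phantoms can
#' be built without storing all error images; the running mean equals the
#' batch mean exactly (sum associativity).
#'
#' @param n_rows,n_cols Map dimensions.
#' @return An environment with `add(err)` and `result()` methods.
#' @export
map_accumulator <- function(n_rows, n_cols) {
  sum_img <- matrix(0, n_rows, n_cols)
  n <- 0L
  add <- function(err) {
    stopifnot(identical(dim(err), dim(sum_img)))
    sum_img <<- sum_img + err
    n <<- n + 1L
    invisible(NULL)
  }
  result <- function() {
    if (n == 0L) stop("map_accumulator: no error images accumulated")
    solvability_map(sum_img / n, n)
  }
  state <- function() list(sum = sum_img, n = n)
  restore <- function(st) { sum_img <<- st$sum; n <<- st$n; invisible(NULL) }
  environment()
}

#' Construct a solvability map object
#'
#' @param values Nonnegative matrix of per-pixel mean squared errors.
#' @param n_phantoms Number of phantoms averaged.
#' @return An object of class `solvability_map` with `values`, `n_phantoms`
#'   and `summary = list(min, max)`.
#' @export
solvability_map <- function(values, n_phantoms) {
  stopifnot(is.matrix(values), n_phantoms >= 1)
  if (any(values < 0)) stop("solvability_map: negative values")
  structure(list(values = values, n_phantoms = as.integer(n_phantoms),
                 summary = list(min = min(values), max = max(values))),
            class = "solvability_map")
}

#' @export
print.solvability_map <- function(x, ...) {
  cat(sprintf("solvability_map: %dx%d, n = %d phantoms, min %.4g, max %.4g\n",
              nrow(x$values), ncol(x$values), x$n_phantoms,
              x$summary$min, x$summary$max))
  invisible(x)
}

#' Average squared-error images into a solvability map
#'
#' The image solvability map is the pixel-wise arithmetic mean of the
#' squared-error images over the simulated phantoms; small values mark pixels
#' the geometry/algorithm pair reconstructs stably.
#'
#' @param errors Nonempty list of equally shaped squared-error matrices.
#' @return A `solvability_map`.
#' @export
accumulate_map <- function(errors) {
  if (!length(errors)) stop("accumulate_map: empty sequence of error images")
  acc <- map_accumulator(nrow(errors[[1]]), ncol(errors[[1]]))
  for (e in errors) acc$add(e)
  acc$result()
}

#' Display transform for solvability maps
#'
#' \eqn{v_o = 1 - e^{-20 v_i}}: a strictly increasing map from [0, Inf) to
#' [0, 1) that spreads out near-zero map values and compresses large ones,
#' used when rendering maps to PNG.
#'
#' @param v Nonnegative value, vector or matrix (a `solvability_map` is also
#'   accepted).
#' @return Transformed values in [0, 1), same shape as the input.
#' @export
display_transform <- function(v) {
  if (inherits(v, "solvability_map")) v <- v$values
  if (any(v < 0)) stop("display_transform: negative input")
  1 - exp(-20 * v)
}

#' Minimum and maximum of a solvability map
#'
#' The two summary numbers reported per algorithm variant.
#'
#' @param m A `solvability_map`.
#' @return `list(min =, max =)`.
#' @export
map_summary <- function(m) {
  stopifnot(inherits(m, "solvability_map"))
  m$summary
}

#' Save a solvability map as raw TIFF plus display PNG
#'
#' @param m A `solvability_map`.
#' @param path_base Path without extension; writes `<base>.tif` (32-bit float,
#'   values scaled by the map maximum, which is recorded with `min` and `n` in
#'   a `<base>.json` sidecar) and `<base>.png` (display transform, linear gray
#'   [0, 1]).
#' @return Invisibly, the three paths.
#' @export
save_map <- function(m, path_base) {
  stopifnot(inherits(m, "solvability_map"))
  tif <- paste0(path_base, ".tif")
  pngf <- paste0(path_base, ".png")
  sidecar <- paste0(path_base, ".json")
  scale <- max(m$summary$max, .Machine$double.xmin)
  tiff::writeTIFF(m$values / scale, tif, bits.per.sample = 32L)
  png::writePNG(display_transform(m), pngf)
  jsonlite::write_json(list(n_phantoms = m$n_phantoms, min = m$summary$min,
                            max = m$summary$max, tiff_scale = scale),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, pngf, sidecar))
}
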