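# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian convolution with reflective boundaries; kernel truncated
# at 4 sigma
gaussian_smooth <- function(img, sigma = 1.0) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_pad_idx <- function(n) {
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    pmin(pmax(idx, 1L), n)
  }
  conv_cols <- function(m) {
    n <- nrow(m)
    mp <- m[reflect_pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

# rasterize one ellipse (pixel-index coordinates, 1-based centres) additively
rasterize_ellipse <- function(acc, cx, cy, a, b, theta_deg, intensity) {
  nr <- nrow(acc); nc <- ncol(acc)
  th <- theta_deg * pi / 180
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  rr <- matrix(seq_len(nr), nr, nc) - cy
  u <- (cc * cos(th) + rr * sin(th)) / a
  v <- (-cc * sin(th) + rr * cos(th)) / b
  acc + intensity * (u * u + v * v <= 1)
}

#' Generate a random ellipse phantom
#'
#' Draws `n_ellipses` ellipses with random centres, semi-axes, orientations
#' and intensities (overlaps add), smooths the result with a Gaussian of
#' standard deviation `sigma` pixels (reflective boundaries), and min-max
#' normalizes to [0, 1]. Degenerate draws whose pre-normalization image is
#' constant are redrawn from the same stream, up to `max_retries` times.
#'
#' Default parameter ranges are expressed as fractions of the grid side so the
#' same statistical family is produced at any simulation scale: centres
#' uniform in the central 70 % of the grid, semi-axes uniform in
#' [0.04, 0.235] of the side (15--90 pixels on a 384-pixel grid), orientation
#' uniform in [0, 180) degrees, intensity uniform in [0.2, 1].
#'
#' @param seed Integer seed; the phantom is a deterministic function of it.
#'   The caller's RNG state is left untouched.
#' @param grid An `image_grid` (default the 384 x 384 fine simulation grid,
#'   pixel size 1/3 so the physical extent matches a 128 x 128 unit-pixel
#'   reconstruction grid).
#' @param n_ellipses Number of ellipses (default 4).
#' @param param_ranges Optional list overriding any of `center_frac`,
#'   `semiaxis_frac`, `angle_deg`, `intensity` (each a length-2 range;
#'   `center_frac` is the centred fraction of the side available to centres).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param max_retries Redraw budget for degenerate (constant) images.
#' @return An object of class `phantom`: list with `image` (values in [0, 1],
#'   min 0 and max 1 exactly), `ellipses` (data frame), `seed`, `grid`.
#' @export
generate_phantom <- function(seed, grid = image_grid(384L, 384L, 1 / 3),
                             n_ellipses = 4L, param_ranges = list(),
                             sigma = 1.0, max_retries = 10L) {
  stopifnot(inherits(grid, "image_grid"))
  n_ellipses <- as.integer(n_ellipses)
  if (is.na(n_ellipses) || n_ellipses < 1L)
    stop("generate_phantom: n_ellipses must be >= 1")
  rng <- list(center_frac = c(0.15, 0.85),
              semiaxis_frac = c(0.04, 0.235),
              angle_deg = c(0, 180),
              intensity = c(0.2, 1.0))
  rng[names(param_ranges)] <- param_ranges
  side <- min(grid$n_rows, grid$n_cols)
  with_private_seed(seed, {
    for (try in seq_len(max_retries)) {
      ell <- data.frame(
        cx = runif(n_ellipses, rng$center_frac[1] * grid$n_cols,
                   rng$center_frac[2] * grid$n_cols),
        cy = runif(n_ellipses, rng$center_frac[1] * grid$n_rows,
                   rng$center_frac[2] * grid$n_rows),
        a = runif(n_ellipses, rng$semiaxis_frac[1] * side,
                  rng$semiaxis_frac[2] * side),
        b = runif(n_ellipses, rng$semiaxis_frac[1] * side,
                  rng$semiaxis_frac[2] * side),
        theta = runif(n_ellipses, rng$angle_deg[1], rng$angle_deg[2]),
        intensity = runif(n_ellipses, rng$intensity[1], rng$intensity[2]))
      img <- matrix(0, grid$n_rows, grid$n_cols)
      for (i in seq_len(n_ellipses))
        img <- rasterize_ellipse(img, ell$cx[i], ell$cy[i], ell$a[i],
                                 ell$b[i], ell$theta[i], ell$intensity[i])
      img <- gaussian_smooth(img, sigma)
      lo <- min(img); hi <- max(img)
      if (hi > lo) {
        img <- (img - lo) / (hi - lo)
        return(structure(list(image = img, ellipses = ell, seed = seed,
                              grid = grid),
                         class = "phantom"))
      }
    }
    stop("generate_phantom: exhausted retries drawing a non-degenerate phantom")
  })
}

#' Block-mean downsampling of the fine ground truth
#'
#' The reconstruction-scale ground truth is the mean of each
#' `factor` x `factor` block of the fine phantom, mirroring the 3:1 detector
#' bin-down used in data generation.
#'
#' @param p A `phantom` or a plain numeric matrix.
#' @param factor Integer block side (default 3).
#' @return Numeric matrix of size (n_rows/factor) x (n_cols/factor).
#' @export
downsample_truth <- function(p, factor = 3L) {
  img <- if (inherits(p, "phantom")) p$image else p
  stopifnot(is.matrix(img))
  factor <- as.integer(factor)
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop("downsample_truth: image size not divisible by factor")
  nr2 <- nr %/% factor; nc2 <- nc %/% factor
  dim(img) <- c(factor, nr2, factor * nc2)
  m <- colMeans(img)                      # nr2 x (factor*nc2)
  dim(m) <- c(nr2, factor, nc2)
  apply(m, c(1, 3), mean)
}

#' Object support mask from a reconstruction-scale truth image
#'
#' Pixels where the truth is positive, dilated by one pixel (3 x 3 square
#' structuring element) so single-pixel boundary effects of the block mean do
#' not clip the object.
#'
#' @param truth Numeric matrix (downsampled truth).
#' @param dilate Number of one-pixel dilation passes (default 1).
#' @param threshold Positivity threshold (default 1e-12).
#' @return Logical matrix.
#' @export
support_from_truth <- function(truth, dilate = 1L, threshold = 1e-12) {
  stopifnot(is.matrix(truth))
  m <- truth > threshold
  for (i in seq_len(dilate)) {
    nr <- nrow(m); nc <- ncol(m)
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    m <- p[1:nr, 2:(nc + 1)] | p[3:(nr + 2), 2:(nc + 1)] |
      p[2:(nr + 1), 1:nc] | p[2:(nr + 1), 3:(nc + 2)] |
      p[1:nr, 1:nc] | p[1:nr, 3:(nc + 2)] |
      p[3:(nr + 2), 1:nc] | p[3:(nr + 2), 3:(nc + 2)] |
      p[2:(nr + 1), 2:(nc + 1)]
  }
  m
}

#' Save a phantom as 32-bit float TIFF plus a JSON sidecar
#'
#' @param p A `phantom`.
#' @param path Output TIFF path; the sidecar is written at `path` with a
#'   `.json` extension appended.
#' @return Invisibly, the TIFF path.
#' @export
save_phantom <- function(p, path) {
  stopifnot(inherits(p, "phantom"))
  tiff::writeTIFF(p$image, path, bits.per.sample = 32L)
  jsonlite::write_json(list(seed = p$seed, ellipses = p$ellipses),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
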