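# Exact ray-pixel intersection length by slab clipping, independent of the
# compiled Siddon march. Axis-aligned rays use the same half-open pixel
# convention as the march: x in [x0, x1), y in (y0, y1].
.clip_length <- function(px, py, dx, dy, x0, x1, y0, y1) {
  eps <- 1e-12
  tmin <- -Inf; tmax <- Inf
  if (abs(dx) > eps) {
    t1 <- (x0 - px) / dx; t2 <- (x1 - px) / dx
    tmin <- pmax(tmin, pmin(t1, t2)); tmax <- pmin(tmax, pmax(t1, t2))
  } else if (px < x0 || px >= x1) return(0)
  if (abs(dy) > eps) {
    t1 <- (y0 - py) / dy; t2 <- (y1 - py) / dy
    tmin <- pmax(tmin, pmin(t1, t2)); tmax <- pmin(tmax, pmax(t1, t2))
  } else if (py <= y0 || py > y1) return(0)
  max(0, tmax - tmin)
}

#' Build the dense system matrix of the measured rays
#'
#' Explicitly materializes A for small grids: one row per measured
#' (view, bin) ray, one column per pixel (row-major), entries the exact
#' intersection length of the bin's central ray with the pixel. Computed by a
#' pure-R slab-clipping route, deliberately independent of the compiled
#' projector, so operator-versus-matrix tests compare two code paths.
#'
#' @param op A `projection_operator` (grid limited to at most 64 x 64 pixels;
#'   dense SVD diagnostics exist for validation at toy scale only).
#' @return An object of class `dense_system`: `matrix`
#'   (n_views * n_measured_bins x n_pixels), `rays` (data frame mapping rows
#'   to view/bin indices), `geometry`.
#' @export
build_dense_matrix <- function(op) {
  stopifnot(inherits(op, "projection_operator"))
  g <- op$geometry
  np <- g$grid$n_rows * g$grid$n_cols
  if (g$grid$n_rows > 64L || g$grid$n_cols > 64L)
    stop("build_dense_matrix: grid larger than the 64x64 dense-oracle guard")
  h <- g$grid$pixel_size
  nr <- g$grid$n_rows; nc <- g$grid$n_cols
  xmin <- -nc * h / 2; ymax <- nr * h / 2
  # pixel bounds, row-major (column varies fastest)
  cc <- rep(0:(nc - 1), nr)
  rr <- rep(0:(nr - 1), each = nc)
  x0 <- xmin + cc * h; x1 <- x0 + h
  y1 <- ymax - rr * h; y0 <- y1 - h
  th <- view_angles(g$views) * pi / 180
  sc <- bin_centers(g$extended_detector)[g$measured]
  binid <- which(g$measured)
  n_rays <- length(th) * length(sc)
  A <- matrix(0, n_rays, np)
  rays <- data.frame(view = integer(n_rays), bin = integer(n_rays))
  row <- 0L
  for (a in seq_along(th)) {
    ux <- cos(th[a]); uy <- sin(th[a])
    dx <- -uy; dy <- ux
    for (b in seq_along(sc)) {
      row <- row + 1L
      rays$view[row] <- a
      rays$bin[row] <- binid[b]
      px <- sc[b] * ux; py <- sc[b] * uy
      A[row, ] <- vapply(seq_len(np), function(i)
        .clip_length(px, py, dx, dy, x0[i], x1[i], y0[i], y1[i]), numeric(1))
    }
  }
  structure(list(matrix = A, rays = rays, geometry = g),
            class = "dense_system")
}

#' Condition number of the measured system
#'
#' The ratio of largest to smallest singular value of A. Singular values
#' below `tol * sigma_max` are treated as numerically zero; when any fall
#' below, the system is rank deficient and the condition number is
#' effectively infinite (`infinite = TRUE`), and `kappa` reports the ratio
#' over the singular values above the cutoff.
#'
#' @param sys A `dense_system`.
#' @param tol Relative numerical-rank cutoff (default 1e-10).
#' @return `list(kappa, sigma_max, sigma_min, infinite, rank)`.
#' @export
condition_number <- function(sys, tol = 1e-10) {
  stopifnot(inherits(sys, "dense_system"))
  sv <- svd(sys$matrix, nu = 0, nv = 0)$d
  smax <- sv[1]
  keep <- sv > smax * tol
  list(kappa = smax / min(sv[keep]),
       sigma_max = smax,
       sigma_min = min(sv),
       infinite = any(!keep) || ncol(sys$matrix) > length(sv),
       rank = sum(keep))
}

#' Pixel solvability from the Moore-Penrose pseudo-inverse
#'
#' Computes diag(A+ A) where A+ is the SVD pseudo-inverse with singular
#' values below `tol * sigma_max` discarded. A+ A is the orthogonal projector
#' onto the row space of A, so its diagonal lies in [0, 1]; a diagonal entry
#' of 1 marks a pixel the generalized solution recovers exactly, values below
#' 1 mark pixels in (or leaking into) the null space. Using
#' diag(A+ A) = rowSums(V_r^2) over the retained right singular vectors
#' avoids forming A+.
#'
#' @param sys A `dense_system`.
#' @param tol Relative singular-value cutoff (default 1e-10).
#' @return Matrix of diagonal values reshaped to the image grid.
#' @export
pinv_solvability_map <- function(sys, tol = 1e-10) {
  stopifnot(inherits(sys, "dense_system"))
  sv <- svd(sys$matrix)
  keep <- sv$d > sv$d[1] * tol
  d <- rowSums(sv$v[, keep, drop = FALSE]^2)
  g <- sys$geometry$grid
  matrix(d, g$n_rows, g$n_cols, byrow = TRUE)
}
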