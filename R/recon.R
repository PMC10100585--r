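#' Reconstruction configuration
#'
#' Describes one of the algorithm variants: gradient descent (GD) on the
#' least-squares objective or maximum-likelihood expectation-maximization
#' (MLEM) for the Poisson likelihood, each optionally with finite-support
#' enforcement and/or the truncation modification (unmeasured bins overwritten
#' with the current forward projection so they exert no data-fit force; in
#' naive mode unmeasured bins are treated as measured zeros).
#'
#' @param algorithm "GD" or "MLEM".
#' @param n_iterations Iteration count (>= 1). Defaults: 200 for GD, 100 for
#'   MLEM (error plateaus on toy problems).
#' @param step_size_alpha GD step size; `NULL` (default) selects
#'   `1.9 / lambda_max` with `lambda_max` the largest eigenvalue of `AtA`
#'   estimated by power iteration, a guaranteed-stable steepest-descent step.
#' @param use_support Enforce a known object support? GD zeroes out-of-support
#'   pixels after every update; MLEM only needs the support imposed on the
#'   initial image because its multiplicative updates keep zeros at zero.
#' @param use_truncation_modification Replace unmeasured bins by the current
#'   forward projection each iteration?
#' @param support_mask Logical matrix (required when `use_support`).
#' @param epsilon_guard Small positive guard added to MLEM denominators
#'   (default 1e-12).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(algorithm = c("GD", "MLEM"),
                         n_iterations = NULL,
                         step_size_alpha = NULL,
                         use_support = FALSE,
                         use_truncation_modification = FALSE,
                         support_mask = NULL,
                         epsilon_guard = 1e-12) {
  algorithm <- match.arg(algorithm)
  if (is.null(n_iterations))
    n_iterations <- if (algorithm == "GD") 200L else 100L
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("recon_config: n_iterations must be >= 1")
  if (!is.null(step_size_alpha) && step_size_alpha <= 0)
    stop("recon_config: step_size_alpha must be > 0")
  if (use_support && is.null(support_mask))
    stop("recon_config: support_mask required when use_support is set")
  stopifnot(epsilon_guard > 0)
  structure(list(algorithm = algorithm, n_iterations = n_iterations,
                 step_size_alpha = step_size_alpha, use_support = use_support,
                 use_truncation_modification = use_truncation_modification,
                 support_mask = support_mask, epsilon_guard = epsilon_guard),
            class = "recon_config")
}

#' Largest eigenvalue of AtA by power iteration
#'
#' Deterministic (fixed start vector), used for the default GD step size
#' bound `alpha < 2 / lambda_max`.
#'
#' @param op A `projection_operator`.
#' @param n_iter Power-iteration count (default 50).
#' @return Estimated largest eigenvalue of `t(A) %*% A`.
#' @export
estimate_lambda_max <- function(op, n_iter = 50L) {
  A <- op$A
  n <- ncol(A)
  v <- 1 + seq_len(n) / n          # deterministic, not axis-aligned
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(n_iter)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

#' Overwrite unmeasured bins with the current forward projection
#'
#' The truncation modification: measured entries are kept from the data,
#' unmeasured entries are copied from the current iterate's forward
#' projection, so unmeasured rays contribute zero residual.
#'
#' @param s Data `sinogram`.
#' @param current_forward `sinogram` (or values matrix) of the current
#'   iterate's forward projection on the same geometry.
#' @return A `sinogram` with modified unmeasured entries.
#' @export
apply_truncation_modification <- function(s, current_forward) {
  stopifnot(inherits(s, "sinogram"))
  fv <- if (inherits(current_forward, "sinogram")) current_forward$values
        else current_forward
  if (!identical(dim(fv), dim(s$values)))
    stop("apply_truncation_modification: shape mismatch")
  out <- s$values
  out[, !s$measured] <- fv[, !s$measured, drop = FALSE]
  sinogram(out, s$geometry)
}

# shared input checks; returns the data as a ray vector
.recon_check <- function(s, op, cfg) {
  stopifnot(inherits(s, "sinogram"), inherits(op, "projection_operator"),
            inherits(cfg, "recon_config"))
  g <- op$geometry
  if (nrow(s$values) != g$views$n_views ||
      ncol(s$values) != g$extended_detector$n_bins)
    stop("reconstruct: sinogram geometry does not match operator")
  if (cfg$use_support &&
      !identical(dim(cfg$support_mask), c(g$grid$n_rows, g$grid$n_cols)))
    stop("reconstruct: support_mask shape does not match grid")
  sino_vec(s$values)
}

#' Gradient-descent reconstruction
#'
#' Iterates \eqn{x^{k+1} = x^k - \alpha A^T (A x^k - p)} from the zero image.
#' Unmeasured bins carry p = 0 ("naive" mode) unless the truncation
#' modification is active, in which case their residual is forced to zero
#' each iteration. With support enforcement, out-of-support pixels are zeroed
#' after every update.
#'
#' @param s Data `sinogram`.
#' @param op `projection_operator` on the reconstruction grid.
#' @param cfg A `recon_config` with `algorithm = "GD"`.
#' @return An object of class `recon_result`: `image`, `data_fit` (per
#'   iteration, 0.5 * sum of squared residuals over the bins in play),
#'   `config`, `alpha`.
#' @export
run_gd <- function(s, op, cfg) {
  if (cfg$algorithm != "GD") stop("run_gd: config algorithm must be GD")
  p <- .recon_check(s, op, cfg)
  A <- op$A
  g <- op$geometry
  alpha <- cfg$step_size_alpha
  if (is.null(alpha)) alpha <- 1.9 / estimate_lambda_max(op)
  if (alpha <= 0) stop("run_gd: step size alpha must be > 0")
  unmeas <- sino_vec(matrix(rep(!g$measured, each = g$views$n_views),
                            g$views$n_views, g$extended_detector$n_bins))
  x <- numeric(ncol(A))
  supp <- if (cfg$use_support) as.vector(t(cfg$support_mask)) else NULL
  fit <- numeric(cfg$n_iterations)
  for (k in seq_len(cfg$n_iterations)) {
    r <- as.numeric(A %*% x) - p
    if (cfg$use_truncation_modification) r[unmeas] <- 0
    fit[k] <- 0.5 * sum(r^2)
    x <- x - alpha * as.numeric(Matrix::crossprod(A, r))
    if (cfg$use_support) x[!supp] <- 0
    if (any(!is.finite(x)))
      stop(sprintf("run_gd: iterates diverged (non-finite values) at iteration %d with step size alpha = %g", k, alpha))
  }
  structure(list(image = matrix(x, g$grid$n_rows, g$grid$n_cols, byrow = TRUE),
                 data_fit = fit, config = cfg, alpha = alpha),
            class = "recon_result")
}

#' ML-EM reconstruction
#'
#' Iterates the multiplicative update
#' \eqn{x_i^{k+1} = \frac{x_i^k}{\sum_j a_{ij}} \sum_j a_{ij} \frac{p_j}{\sum_n a_{nj} x_n^k}}
#' from the all-ones image (or the support mask cast to 0/1 when
#' `use_support`; zero-initialized pixels remain zero forever under the
#' multiplicative update). Unmeasured bins carry p = 0 in naive mode; with
#' the truncation modification their data/forward ratio is forced to 1.
#' Denominators are guarded by `epsilon_guard`; pixels with zero sensitivity
#' are held at 0.
#'
#' @inheritParams run_gd
#' @param cfg A `recon_config` with `algorithm = "MLEM"`.
#' @return A `recon_result`; `data_fit` is the Poisson log-likelihood
#'   `sum(p * log(q) - q)` over measured bins at each iteration.
#' @export
run_mlem <- function(s, op, cfg) {
  if (cfg$algorithm != "MLEM") stop("run_mlem: config algorithm must be MLEM")
  p <- .recon_check(s, op, cfg)
  g <- op$geometry
  A <- op$A
  meas <- sino_vec(matrix(rep(g$measured, each = g$views$n_views),
                          g$views$n_views, g$extended_detector$n_bins))
  if (any(p[meas] < 0)) stop("run_mlem: negative measured data")
  eps <- cfg$epsilon_guard
  sens <- as.numeric(Matrix::crossprod(A, rep(1, nrow(A))))
  if (all(sens == 0)) stop("run_mlem: all-zero sensitivity")
  pos <- sens > 0
  x <- rep(1, ncol(A))
  if (cfg$use_support) x <- as.numeric(as.vector(t(cfg$support_mask)) > 0)
  x[!pos] <- 0
  fit <- numeric(cfg$n_iterations)
  for (k in seq_len(cfg$n_iterations)) {
    q <- as.numeric(A %*% x)
    ratio <- p / (q + eps)
    if (cfg$use_truncation_modification) ratio[!meas] <- 1
    fit[k] <- sum(p[meas] * log(q[meas] + eps) - q[meas])
    bp <- as.numeric(Matrix::crossprod(A, ratio))
    x[pos] <- x[pos] / sens[pos] * bp[pos]
  }
  structure(list(image = matrix(x, g$grid$n_rows, g$grid$n_cols, byrow = TRUE),
                 data_fit = fit, config = cfg, alpha = NULL),
            class = "recon_result")
}

#' Run the reconstruction described by a config
#'
#' @inheritParams run_gd
#' @return A `recon_result`.
#' @export
reconstruct <- function(s, op, cfg) {
  if (cfg$algorithm == "GD") run_gd(s, op, cfg) else run_mlem(s, op, cfg)
}
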