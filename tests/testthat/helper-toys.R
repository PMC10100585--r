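# shared fixture builders and a cache for the reduced-scale Monte Carlo runs

relerr <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# logical mask over view-major ray indices marking measured rays
measured_rays <- function(g) rep(g$measured, times = g$views$n_views)

# sinogram values as the view-major ray vector the operator uses
ray_vector <- function(s) as.vector(t(s$values))

# 16x16 untruncated full-rank toy: 23 bins, 24 views over 180 degrees
toy16 <- function() {
  make_geometry(image_grid(16), detector(23), view_set(24, 0, 7.5))
}

# smooth strictly-bounded test object on a grid (zero near the corners so
# untruncated toy data are consistent on every extended bin)
smooth_bump <- function(grid, radius = 0.6 * grid$n_rows / 2) {
  h <- grid$pixel_size
  cx <- (seq_len(grid$n_cols) - 1 - (grid$n_cols - 1) / 2) * h
  cy <- ((grid$n_rows - 1) / 2 - (seq_len(grid$n_rows) - 1)) * h
  r2 <- outer(cy^2, cx^2, `+`)
  exp(-r2 / (2 * (radius * h)^2)) * (r2 <= (grid$n_rows * h / 2 - 1)^2)
}

# reduced-scale Monte Carlo runs shared by several acceptance checks;
# computed once per test session
.run_cache <- new.env(parent = emptyenv())

reduced_variants <- function() {
  list(variant_spec("GD"), variant_spec("GD", trunc_mod = TRUE),
       variant_spec("GD", support = TRUE, trunc_mod = TRUE),
       variant_spec("MLEM"), variant_spec("MLEM", trunc_mod = TRUE),
       variant_spec("MLEM", support = TRUE, trunc_mod = TRUE))
}

reduced_truncated_run <- function() {
  if (is.null(.run_cache$trunc)) {
    cfg <- run_profile("test", truncated = TRUE, base_seed = 1L,
                       variants = reduced_variants())
    .run_cache$trunc <- run_experiment(cfg)
  }
  .run_cache$trunc
}

reduced_untruncated_run <- function() {
  if (is.null(.run_cache$untrunc)) {
    cfg <- run_profile("test", truncated = FALSE, base_seed = 1L,
                       variants = list(variant_spec("GD"),
                                       variant_spec("MLEM")))
    .run_cache$untrunc <- run_experiment(cfg)
  }
  .run_cache$untrunc
}

# underdetermined truncated 24x24 toy (504 measured rays < 576 pixels) plus
# its 200-phantom Monte Carlo map for the truncation-modified GD variant
toy_oracle_setup <- function() {
  if (is.null(.run_cache$toy_oracle)) {
    g <- make_geometry(image_grid(24), detector(21, 1, 7),
                       view_set(24, 0, 7.5))
    sys <- build_dense_matrix(projection_operator(g))
    cfg <- run_profile("test", truncated = TRUE, recon_n = 24L,
                       det_bins = 21L, det_offset = 7, n_views = 24L,
                       step_deg = 7.5, n_phantoms = 200L, base_seed = 1L,
                       variants = list(variant_spec("GD", trunc_mod = TRUE)))
    .run_cache$toy_oracle <- list(geometry = g, sys = sys,
                                  mc = run_experiment(cfg))
  }
  .run_cache$toy_oracle
}

# dense_system wrapper around an arbitrary matrix, for the linear-algebra
# diagnostics that only look at sys$matrix (and the grid for reshaping)
fake_dense <- function(M, n_rows = 1L, n_cols = ncol(M)) {
  structure(list(matrix = M, rays = NULL,
                 geometry = list(grid = image_grid(n_rows, n_cols))),
            class = "dense_system")
}
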