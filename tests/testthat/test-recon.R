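test_that("truncation modification selects measured data and forward values per bin", {
  g <- make_geometry(image_grid(16), detector(9, 1, 2), view_set(6, 0, 30))
  nb <- g$extended_detector$n_bins
  set.seed(5)
  s <- sinogram(matrix(runif(6 * nb), 6, nb), g)
  fwd <- matrix(rnorm(6 * nb), 6, nb)
  out <- apply_truncation_modification(s, fwd)
  expect_equal(out$values[, g$measured], s$values[, g$measured])
  expect_equal(out$values[, !g$measured], fwd[, !g$measured])
  # all bins measured -> identity
  gu <- make_geometry(image_grid(16), detector(25), view_set(6, 0, 30))
  su <- sinogram(matrix(runif(6 * 25), 6, 25), gu)
  expect_equal(apply_truncation_modification(su, matrix(0, 6, 25))$values,
               su$values)
  # no bins measured -> the forward values
  g0 <- g; g0$measured[] <- FALSE
  s0 <- sinogram(s$values, g)
  s0$measured[] <- FALSE
  expect_equal(apply_truncation_modification(s0, fwd)$values, fwd)
})

test_that("GD residual is monotone below the stability bound and errors when diverging", {
  g <- toy16()
  op <- projection_operator(g)
  truth <- smooth_bump(g$grid)
  s <- forward_project(op, truth)
  lam <- estimate_lambda_max(op)
  res <- run_gd(s, op, recon_config("GD", n_iterations = 60,
                                    step_size_alpha = 1.9 / lam))
  expect_true(all(diff(res$data_fit) <= 1e-9))
  expect_error(run_gd(s, op, recon_config("GD", n_iterations = 400,
                                          step_size_alpha = 1000 / lam)),
               "alpha")
  expect_error(recon_config("GD", step_size_alpha = -1), "alpha")
})

test_that("GD with support equals dense GD restricted to the support columns", {
  g <- toy16()
  op <- projection_operator(g)
  truth <- smooth_bump(g$grid)
  supp <- truth > 1e-6
  s <- forward_project(op, truth)
  alpha <- 1.5 / estimate_lambda_max(op)
  cfg <- recon_config("GD", n_iterations = 40, step_size_alpha = alpha,
                      use_support = TRUE, support_mask = supp)
  res <- run_gd(s, op, cfg)
  # dense oracle: iterate on A restricted to support columns only
  A <- as.matrix(op$A)
  keep <- as.vector(t(supp))
  Ak <- A[, keep]
  p <- ray_vector(s)
  xk <- numeric(ncol(Ak))
  for (k in 1:40) xk <- xk - alpha * crossprod(Ak, Ak %*% xk - p)
  full <- numeric(256)
  full[keep] <- xk
  expect_equal(as.vector(t(res$image)), full, tolerance = 1e-10)
})

test_that("MLEM preserves zeros, nonnegativity, and its multiplicative fixed point", {
  g <- toy16()
  op <- projection_operator(g)
  truth <- smooth_bump(g$grid)
  s <- forward_project(op, truth)
  # pixels zeroed at initialization stay zero forever
  supp <- truth > 1e-6
  res <- run_mlem(s, op, recon_config("MLEM", n_iterations = 30,
                                      use_support = TRUE,
                                      support_mask = supp))
  expect_true(all(res$image[!supp] == 0))
  expect_true(all(res$image >= 0))
  # p = forward(all-ones init) is a fixed point of the update
  ones <- matrix(1, 16, 16)
  s1 <- forward_project(op, ones)
  r1 <- run_mlem(s1, op, recon_config("MLEM", n_iterations = 1))
  expect_lt(max(abs(r1$image - 1)), 1e-8)
  # negative measured data are rejected
  bad <- s$values; bad[1, which(g$measured)[1]] <- -0.1
  expect_error(run_mlem(sinogram(bad, g), op,
                        recon_config("MLEM", n_iterations = 1)),
               "negative")
})

test_that("with the truncation modification unmeasured bins exert no gradient force", {
  g <- make_geometry(image_grid(16), detector(13, 1, 3), view_set(18, 0, 10))
  op <- projection_operator(g)
  truth <- smooth_bump(g$grid)
  full <- forward_project(op, truth)
  # data with unmeasured bins zeroed, as produced by acquisition
  vals <- full$values
  vals[, !g$measured] <- 0
  s <- sinogram(vals, g)
  alpha <- 1.5 / estimate_lambda_max(op)
  res_mod <- run_gd(s, op, recon_config("GD", n_iterations = 25,
                                        step_size_alpha = alpha,
                                        use_truncation_modification = TRUE))
  # oracle: explicit gradient iteration using measured rays only
  A <- as.matrix(op$A)
  mrays <- measured_rays(g)
  Am <- A[mrays, ]
  pm <- ray_vector(s)[mrays]
  x <- numeric(256)
  for (k in 1:25) x <- x - alpha * crossprod(Am, Am %*% x - pm)
  expect_equal(as.vector(t(res_mod$image)), as.vector(x), tolerance = 1e-10)
})

test_that("both solvers converge to the truth on consistent untruncated data", {
  g <- toy16()
  op <- projection_operator(g)
  truth <- smooth_bump(g$grid)
  s <- forward_project(op, truth)
  gd <- run_gd(s, op, recon_config("GD", n_iterations = 800))
  expect_lt(relerr(gd$image, truth), 1e-3)
  em <- run_mlem(s, op, recon_config("MLEM", n_iterations = 800))
  expect_lt(relerr(em$image, truth), 5e-3)
})
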