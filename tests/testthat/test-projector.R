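test_that("forward projection is linear and vanishes on the zero image", {
  g <- toy16()
  op <- projection_operator(g)
  expect_true(all(forward_project(op, matrix(0, 16, 16))$values == 0))
  set.seed(2)
  x1 <- matrix(runif(256), 16, 16)
  x2 <- matrix(runif(256), 16, 16)
  s12 <- forward_project(op, 2 * x1 - 3 * x2)$values
  expect_equal(s12, 2 * forward_project(op, x1)$values -
                 3 * forward_project(op, x2)$values, tolerance = 1e-12)
  expect_error(forward_project(op, matrix(0, 8, 8)), "shape")
})

test_that("a centred uniform disk projects to near-constant chords of length 2r", {
  g <- make_geometry(image_grid(64), detector(93), view_set(30, 0, 6))
  op <- projection_operator(g)
  pc <- solvmap:::pixel_centers(g$grid)
  disk <- (pc$x^2 + pc$y^2 <= 100) * 1.0
  s <- forward_project(op, disk)
  ctr <- which(abs(bin_centers(g$extended_detector)) < 1e-9)
  # analytic chord through the centre of a radius-10 disk is 20, up to
  # pixelization of the disk edge
  expect_true(all(abs(s$values[, ctr] - 20) < 1.5))
  # quadrature oracle: the same disk sampled on a 4x finer grid
  gf <- make_geometry(image_grid(256, 256, 0.25), detector(93), view_set(1))
  opf <- projection_operator(gf)
  pcf <- solvmap:::pixel_centers(gf$grid)
  diskf <- (pcf$x^2 + pcf$y^2 <= 100) * 1.0
  sf <- forward_project(opf, diskf)
  ctrf <- which(abs(bin_centers(gf$extended_detector)) < 1e-9)
  expect_lt(abs(sf$values[1, ctrf] - 20), 0.5)
  # rotational symmetry: every view sees the same profile up to the
  # pixelization jitter of the disk edge under single central rays
  prof <- colMeans(s$values)
  relL2 <- apply(s$values, 1, function(r) sqrt(sum((r - prof)^2) /
                                                 sum(prof^2)))
  expect_lt(max(relL2), 0.15)
})

test_that("back-projection is the exact adjoint across random geometries", {
  cases <- list(c(16, 23, 0, 24), c(16, 30, 0, 20), c(24, 21, 7, 24),
                c(12, 17, 2, 15))
  set.seed(3)
  for (cs in cases) {
    g <- make_geometry(image_grid(cs[1]), detector(cs[2], 1, cs[3]),
                       view_set(cs[4], 0, 180 / cs[4]))
    op <- projection_operator(g)
    x <- matrix(rnorm(cs[1]^2), cs[1], cs[1])
    y <- matrix(rnorm(g$views$n_views * g$extended_detector$n_bins),
                g$views$n_views, g$extended_detector$n_bins)
    lhs <- sum(forward_project(op, x)$values * y)
    rhs <- sum(x * back_project(op, y))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-300), 1e-12)
  }
  g <- toy16()
  op <- projection_operator(g)
  expect_true(all(back_project(op, matrix(0, 24,
    g$extended_detector$n_bins)) == 0))
})

test_that("bin combination averages groups and maps fine to coarse geometry", {
  # hand-checked values: grid 6x6 at pixel 1/3, six fine measured bins
  g <- make_geometry(image_grid(6, 6, 1 / 3), detector(6, 1 / 3),
                     view_set(2, 0, 90))
  vals <- matrix(0, 2, g$extended_detector$n_bins)
  vals[, g$measured] <- matrix(rep(c(3, 6, 9, 0, 3, 6), each = 2), 2)
  s <- sinogram(vals, g)
  sc <- bin_down(s, 3)
  expect_equal(sc$values[, sc$measured], matrix(c(6, 6, 3, 3), 2, 2))
  expect_equal(sc$geometry$grid$n_rows, 2L)
  expect_equal(sc$geometry$detector$bin_width, 1)
  # group means are preserved under scaling
  s2 <- sinogram(2 * vals, g)
  expect_equal(bin_down(s2, 3)$values, 2 * sc$values)
  # full-protocol bin counts: 321 -> 107 and 555 -> 185
  gf <- make_geometry(image_grid(384, 384, 1 / 3), detector(321, 1 / 3, 39),
                      view_set(2, 0, 90))
  sf <- sinogram(matrix(0, 2, gf$extended_detector$n_bins), gf)
  expect_equal(sum(bin_down(sf, 3)$measured), 107L)
  gu <- make_geometry(image_grid(384, 384, 1 / 3), detector(555, 1 / 3),
                      view_set(2, 0, 90))
  su <- sinogram(matrix(0, 2, gu$extended_detector$n_bins), gu)
  expect_equal(sum(bin_down(su, 3)$measured), 185L)
  expect_error(bin_down(sc, 3), "divisible")
})

test_that("fine and coarse detector lattices stay aligned through bin-down", {
  # the mean of each fine bin triple must sit exactly on the coarse centre
  gf <- make_geometry(image_grid(192, 192, 1 / 3), detector(159, 1 / 3, 19),
                      view_set(2, 0, 90))
  sf <- sinogram(matrix(0, 2, gf$extended_detector$n_bins), gf)
  cg <- bin_down(sf, 3)$geometry
  fine_centers <- bin_centers(gf$extended_detector)[gf$measured]
  triple_means <- colMeans(matrix(fine_centers, 3))
  expect_equal(triple_means,
               bin_centers(cg$extended_detector)[cg$measured],
               tolerance = 1e-12)
})

test_that("poisson noise has the right mean, decays with dose, and is seeded", {
  g <- make_geometry(image_grid(8), detector(11), view_set(100, 0, 1.8))
  v <- matrix(2, 100, g$extended_detector$n_bins)
  s <- sinogram(v, g)
  n1 <- add_poisson_noise(s, 500, seed = 7L)
  n2 <- add_poisson_noise(s, 500, seed = 7L)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values,
                         add_poisson_noise(s, 500, seed = 8L)$values))
  # very high dose: output converges to the input
  hi <- add_poisson_noise(s, 1e9, seed = 1L)
  expect_lt(max(abs(hi$values[, g$measured] - 2)), 5e-3)
  # negative measured values are rejected
  v2 <- v; v2[1, which(g$measured)[1]] <- -1
  expect_error(add_poisson_noise(sinogram(v2, g), 500, seed = 1L),
               "negative")
})
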