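test_that("constructors validate their invariants", {
  expect_error(image_grid(0), "n_rows")
  expect_error(image_grid(8, 8, 0), "pixel_size")
  expect_error(detector(0), "n_bins")
  expect_error(detector(5, bin_width = -1), "bin_width")
  expect_error(view_set(0), "n_views")
  expect_true(all(diff(bin_centers(detector(11, 0.5, 3.2))) > 0))
})

test_that("the extended detector embeds the physical detector on its lattice", {
  # symmetric full detector: all 185 bins measured, extended == physical
  g <- make_geometry(image_grid(128), detector(185), view_set(180))
  expect_equal(g$extended_detector$n_bins, 185L)
  ec <- bin_centers(g$extended_detector)
  expect_true(all(g$measured == (abs(ec) <= 92 + 1e-9)))

  # asymmetric truncated detector: measured centers span [-14, 92]
  g2 <- make_geometry(image_grid(128), detector(107, 1, 39), view_set(180))
  mc <- bin_centers(g2$extended_detector)[g2$measured]
  expect_equal(range(mc), c(-14, 92))
  expect_true(g2$extended_detector$n_bins %% 2L == 1L)

  # even-count physical detectors live on the half-integer lattice
  g3 <- make_geometry(image_grid(16), detector(30), view_set(20, 0, 9))
  expect_equal(sum(g3$measured), 30L)

  # off-lattice offsets cannot be embedded
  expect_error(make_geometry(image_grid(64), detector(53, 1, 19.25)),
               "lattice")
})

test_that("angular coverage matches brute-force per-ray enumeration", {
  g <- make_geometry(image_grid(32), detector(17, 1, 5), view_set(36, 0, 5))
  cov <- angular_coverage_map(g)
  # independent scalar-loop oracle
  span <- range(bin_centers(g$extended_detector)[g$measured]) + c(-0.5, 0.5)
  th <- view_angles(g$views) * pi / 180
  brute <- matrix(0, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    x <- (cc - 1 - 31 / 2); y <- (31 / 2 - (r - 1))
    hits <- 0L
    for (t in th) {
      s <- x * cos(t) + y * sin(t)
      if (s >= span[1] && s <= span[2]) hits <- hits + 1L
    }
    brute[r, cc] <- hits / length(th)
  }
  expect_equal(cov, brute, tolerance = 1e-12)
  expect_true(all(cov >= 0 & cov <= 1))
})

test_that("untruncated geometry has full coverage; no measured bins give none", {
  g <- make_geometry(image_grid(128), detector(185), view_set(180))
  expect_true(all(angular_coverage_map(g) == 1))
  expect_true(all(roi_mask(g)))
  g$measured[] <- FALSE
  expect_true(all(angular_coverage_map(g) == 0))
  expect_false(any(roi_mask(g)))
})

test_that("asymmetric half-turn ROI is the intersection of the measured strips", {
  # continuum closed form: with measured span [lo, hi] (lo < 0 < hi) and view
  # normals sweeping the upper half circle, a point (x, y) is fully measured
  # iff (y >= 0 and |x| <= -lo and x^2+y^2 <= hi^2) or (y < 0 and
  # x^2+y^2 <= lo^2). Discrete views sample that sweep, so the discrete ROI
  # contains the continuum region and exceeds it only near its boundary.
  g <- make_geometry(image_grid(128), detector(107, 1, 39), view_set(180))
  roi <- roi_mask(g)
  lo <- -14.5; hi <- 92.5
  x <- matrix(seq_len(128) - 1 - 127 / 2, 128, 128, byrow = TRUE)
  y <- matrix(127 / 2 - (seq_len(128) - 1), 128, 128)
  continuum <- ifelse(y >= 0,
                      abs(x) <= -lo & x^2 + y^2 <= hi^2,
                      x^2 + y^2 <= lo^2)
  expect_true(all(roi[continuum]))
  # anything the discrete ROI adds sits within half a view step of the
  # continuum boundary
  slack <- ifelse(y >= 0,
                  abs(x) <= -lo + 1 & x^2 + y^2 <= (hi + 1)^2,
                  x^2 + y^2 <= (abs(lo) + 1)^2)
  expect_true(all(slack[roi]))
  # the ROI always contains the near-edge disk
  expect_true(all(roi[x^2 + y^2 <= lo^2]))
})

test_that("symmetric-detector ROI is a centred disk, invariant under rotation by 180 degrees", {
  g <- make_geometry(image_grid(64), detector(41), view_set(90, 0, 2))
  roi <- roi_mask(g)
  x <- matrix(seq_len(64) - 1 - 63 / 2, 64, 64, byrow = TRUE)
  y <- matrix(63 / 2 - (seq_len(64) - 1), 64, 64)
  expect_equal(roi, x^2 + y^2 <= 20.5^2)
  # 180-degree rotation of pixel positions maps the grid onto itself
  expect_equal(roi, roi[64:1, 64:1])
  cov <- angular_coverage_map(g)
  expect_equal(cov, cov[64:1, 64:1], tolerance = 1e-12)
})

test_that("enlarging the measured span never removes ROI pixels", {
  base <- roi_mask(make_geometry(image_grid(64), detector(25, 1, 7),
                                 view_set(45, 0, 4)))
  wider <- roi_mask(make_geometry(image_grid(64), detector(41, 1, 7),
                                  view_set(45, 0, 4)))
  expect_true(all(wider[base]))
})
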