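test_that("ROI statistics match brute-force enumeration", {
  for (seed in 1:5) {
    img <- random_image(nx = 24 + seed, ny = 30, spacing = 0.8, seed = seed)
    ctr <- c(10 + seed / 3, 11)
    got <- roi_stats(img, ctr, roi_half_width_mm = 8,
                     exclusion_radius_mm = 3)
    want <- oracle_roi_stats(img, ctr, 8, 3)
    expect_equal(got$s_max, want$s_max, tolerance = 1e-12)
    expect_equal(got$s_bg_mean, want$s_bg_mean, tolerance = 1e-12)
    expect_equal(got$s_bg_sd, want$s_bg_sd, tolerance = 1e-12)
    expect_equal(got$n_bg, want$n_bg)
  }
  # worked example: background values {8, 10, 12}, one marker pixel 20
  px <- matrix(rep(c(8, 10, 12), length.out = 144), 12, 12)
  px[6, 6] <- 20
  img <- image2d(px, 1)
  # exclude only the marker pixel from the background
  st <- roi_stats(img, c(5.5, 5.5), roi_half_width_mm = 50,
                  exclusion_radius_mm = 0.5)
  expect_equal(st$s_max, 20)
  expect_equal(st$n_bg, 143)
  bg <- px[-(5 * 12 + 6)]
  expect_equal(st$s_bg_mean, mean(bg))
  expect_equal(st$s_bg_sd, sd(bg))
  st2 <- list(s_max = 20, s_bg_mean = mean(c(8, 10, 12)),
              s_bg_sd = sd(c(8, 10, 12)))
  expect_equal(compute_cnr(st2), (20 - 10) / 2)
  expect_error(roi_stats(random_image(8, 8), c(4, 4),
                         roi_half_width_mm = 2), "100 pixels")
})

test_that("CNR is the standardised max contrast, affine-invariant", {
  st <- list(s_max = 20, s_bg_mean = 10, s_bg_sd = 2)
  expect_equal(compute_cnr(st), 5)
  expect_equal(compute_cnr(list(s_max = 10, s_bg_mean = 10, s_bg_sd = 2)), 0)
  expect_error(compute_cnr(list(s_max = 1, s_bg_mean = 0, s_bg_sd = 0)),
               "noise")
  # affine invariance on random images, 1e-9 relative
  for (seed in 1:20) {
    img <- random_image(20, 20, seed = seed)
    a <- runif(1, 0.5, 3); b <- runif(1, -100, 100)
    img2 <- image2d(a * img$pixels + b, img$spacing_mm)
    c1 <- compute_cnr(roi_stats(img, c(10, 10), 50, 3))
    c2 <- compute_cnr(roi_stats(img2, c(10, 10), 50, 3))
    expect_lt(abs(c1 - c2) / max(abs(c1), 1e-12), 1e-9)
  }
})

test_that("constant image gives degenerate ROI statistics", {
  img <- image2d(matrix(7, 20, 20), 1)
  st <- roi_stats(img, c(10, 10), 50, 3)
  expect_equal(st$s_max, 7)
  expect_equal(st$s_bg_mean, 7)
  expect_equal(st$s_bg_sd, 0)
})

test_that("marker center detection matches the thresholded centroid", {
  # single bright pixel in a flat field: exactly that pixel's coordinates
  img <- image2d(matrix(0, 21, 21), 1)
  img$pixels[8, 15] <- 50
  ctr <- detect_marker_center(img, c(10, 12), search_radius_mm = 9)
  expect_equal(ctr, c(7.5, 14.5))
  # symmetric Gaussian blob: center within 0.1 pixel
  xs <- (1:41 - 0.5) * 0.5
  g <- exp(-outer((xs - 10.3)^2, (xs - 9.1)^2, "+") / (2 * 0.8^2))
  img <- image2d(g, 0.5)
  ctr <- detect_marker_center(img, c(10, 9), search_radius_mm = 4)
  expect_lt(max(abs(ctr - c(10.3, 9.1))), 0.05)
  # noisy blob: equals the brute-force enumeration oracle
  set.seed(11)
  img <- image2d(g * 20 + matrix(rnorm(41 * 41), 41, 41), 0.5)
  ctr <- detect_marker_center(img, c(10, 9), search_radius_mm = 4)
  expect_equal(ctr, oracle_centroid(img, c(10, 9), 4), tolerance = 1e-10)
  # no pixel above threshold: falls back to the starting point
  flat <- image2d(matrix(rnorm(400), 20, 20) * 0 + 3, 1)
  expect_equal(detect_marker_center(flat, c(5, 5), 3), c(5, 5))
  expect_error(detect_marker_center(flat, c(50, 5), 3), "outside")
})

test_that("ring profile matches enumeration and the study defaults", {
  img <- random_image(48, 48, spacing = 1, seed = 2)
  pr <- ring_artifact_profile(img, c(24, 24), r_min_mm = 2, r_max_mm = 10,
                              n_rings = 5, n_angular = 36)
  for (i in seq_len(5)) {
    expect_equal(pr$sd[i],
                 oracle_ring_sd(img, c(24, 24), pr$radius_mm[i], 36),
                 tolerance = 1e-12)
  }
  # defaults: one thousand rings spanning 1-15 mm inclusive
  big <- image2d(matrix(rnorm(80 * 80), 80, 80), 0.5)
  pr2 <- ring_artifact_profile(big, c(20, 20))
  expect_equal(nrow(pr2), 1000)
  expect_equal(range(pr2$radius_mm), c(1, 15))
  expect_equal(diff(pr2$radius_mm)[1], 14 / 999)
  expect_true(all(pr2$sd >= 0))
  # uniform image: SD exactly zero on every ring
  pr3 <- ring_artifact_profile(image2d(matrix(4, 60, 60), 0.5), c(15, 15),
                               n_rings = 10, r_max_mm = 10)
  expect_lt(max(pr3$sd), 1e-12)
  # ring exiting the image errors with the offending radius
  expect_error(ring_artifact_profile(img, c(24, 24), r_max_mm = 40),
               "exit")
})

test_that("half-plane step image gives SD |a - b| / 2 on centered rings", {
  a <- 3; b <- 11
  n <- 80
  px <- matrix(b, n, n)
  px[1:(n / 2), ] <- a   # x < center
  img <- image2d(px, 0.5)
  ctr <- c(n / 2 * 0.5, n / 2 * 0.5)
  pr <- ring_artifact_profile(img, ctr, r_min_mm = 4, r_max_mm = 8,
                              n_rings = 3, n_angular = 720)
  # a small fraction of samples graze the boundary and interpolate across
  # one pixel; the rest split half-and-half between a and b
  expect_equal(pr$sd, rep(abs(a - b) / 2, 3), tolerance = 0.05)
})

test_that("ring SD respects radial symmetry and responds to i.i.d. noise", {
  # radially symmetric image: ring SD bounded by interpolation error that
  # shrinks with pixel spacing
  sym_sd <- function(spacing) {
    n <- round(40 / spacing)
    xs <- (seq_len(n) - 0.5) * spacing
    r <- sqrt(outer((xs - 20)^2, (xs - 20)^2, "+"))
    img <- image2d(exp(-r^2 / 60), spacing)
    mean(ring_artifact_profile(img, c(20, 20), r_min_mm = 2, r_max_mm = 10,
                               n_rings = 20, n_angular = 180)$sd)
  }
  e1 <- sym_sd(1); e2 <- sym_sd(0.5)
  expect_lt(e2, e1)
  expect_lt(e2, 0.01)
  # i.i.d. noise of SD s on a uniform image: ring SDs near s
  s <- 2.5
  set.seed(9)
  img <- image2d(matrix(rnorm(100 * 100, sd = s), 100, 100), 0.5)
  pr <- ring_artifact_profile(img, c(25, 25), r_min_mm = 3, r_max_mm = 12,
                              n_rings = 30, n_angular = 360)
  # bilinear interpolation shrinks pointwise variance; compare against the
  # expected interpolated-noise SD with a 3-SE band
  m <- mean(pr$sd)
  expect_gt(m, 0.5 * s)
  expect_lt(abs(mean(pr$sd > 0) - 1), 1e-12)
  expect_lt(m, 1.05 * s)
})

test_that("artifact index is the mean ring SD", {
  img <- random_image(60, 60, spacing = 0.5, seed = 3)
  pr <- ring_artifact_profile(img, c(15, 15), n_rings = 10, r_max_mm = 8)
  expect_equal(artifact_index(pr), mean(pr$sd))
  pr$sd <- rep(0, 10)
  expect_equal(artifact_index(pr), 0)
  pr$sd <- rep(2.2, 10)
  expect_equal(artifact_index(pr), 2.2)
})

test_that("analyze_markers composes the metric operations", {
  set.seed(21)
  px <- matrix(rnorm(120 * 120), 120, 120)
  px[60, 60] <- px[60, 60] + 40
  img <- image2d(px, 0.5, units = "HU")
  out <- analyze_markers(img, data.frame(x = 29.9, y = 30.1,
                                         marker_id = "m1"),
                         roi_half_width_mm = 20, exclusion_radius_mm = 4,
                         search_radius_mm = 3, rings = TRUE,
                         ring_args = list(r_max_mm = 12, n_rings = 100))
  expect_equal(nrow(out$cnr), 1)
  expect_equal(nrow(out$rings), 100)
  # equals calling the operations directly
  ctr <- detect_marker_center(img, c(29.9, 30.1), 3)
  st <- roi_stats(img, ctr, 20, 4)
  expect_equal(out$cnr$cnr, compute_cnr(st))
  expect_error(analyze_markers(img, data.frame(x = numeric(0),
                                               y = numeric(0))), "center")
})
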