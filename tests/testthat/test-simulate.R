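test_that("planar simulation: uniform phantom, determinism, Poisson scaling", {
  ph0 <- phantom_spec(extent_cm = c(6, 6, 4))
  pr <- imaging_protocol("kv_planar", kvp = 80, mas = 200, seed = 3)
  img <- simulate_planar(ph0, pr, noise = FALSE)
  # noise off, no markers: spatially constant
  expect_equal(max(img$pixels) - min(img$pixels), 0)
  expect_identical(img$units, "attenuation")
  # same seed twice: identical images
  n1 <- simulate_planar(ph0, pr, noise = TRUE)
  n2 <- simulate_planar(ph0, pr, noise = TRUE)
  expect_identical(n1$pixels, n2$pixels)
  # quadrupling mAs halves the relative background SD (Poisson scaling)
  rel_sd <- function(mas, seed) {
    p <- imaging_protocol("kv_planar", kvp = 80, mas = mas, seed = seed)
    counts <- exp(-simulate_planar(ph0, p, noise = TRUE)$pixels)
    sd(counts) / mean(counts)
  }
  ratios <- sapply(1:10, function(s) rel_sd(200, s) / rel_sd(50, s + 100))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
  expect_error(simulate_planar(ph0, fast_ct_protocol()), "modality")
})

test_that("planar marker signal equals the closed-form path attenuation", {
  # marker centered on a pixel center so every sub-pixel ray crosses the
  # full cylinder length
  ph <- tiny_phantom("polymer", diameter = 1, length = 5,
                     center = c(30.25, 30.25, 20))
  pr <- imaging_protocol("kv_planar", kvp = 80, mas = 200, seed = 1,
                         pixel_spacing_mm = 0.5)
  img <- simulate_planar(ph, pr, noise = FALSE)
  spec <- protocol_spectrum(pr)
  t_marker <- polychromatic_transmission(
    cbind(soft_tissue = 40 - 5, polymer = 5), spec)
  t_bg <- polychromatic_transmission(cbind(soft_tissue = 40), spec)
  ax <- fidviz:::.image_axes(img)
  ix <- which.min(abs(ax$x - 30.25)); iy <- which.min(abs(ax$y - 30.25))
  expect_equal(img$pixels[ix, iy] - img$pixels[2, 2],
               -log(t_marker) + log(t_bg), tolerance = 1e-6)
})

test_that("CT of a uniform phantom is calibrated and quiet", {
  ph0 <- phantom_spec(extent_cm = c(8, 8, 4))
  pr <- fast_ct_protocol(seed = 5)
  img <- simulate_ct_slice(ph0, pr, fov_n = 48, noise = FALSE)
  # HU within +/-40 of the soft-tissue value (0) away from the edge ring
  expect_lt(max(abs(img$pixels)), 40)
  # coefficient of variation of reconstructed mu < 1%
  mu_w <- attenuation_coefficient("soft_tissue",
                                  effective_energy(protocol_spectrum(pr)))
  mu_hat <- img$pixels / 1000 * mu_w + mu_w
  expect_lt(sd(mu_hat) / mean(mu_hat), 0.01)
  # determinism under a fixed seed
  a <- simulate_ct_slice(ph0, pr, fov_n = 32, noise = TRUE)
  b <- simulate_ct_slice(ph0, pr, fov_n = 32, noise = TRUE)
  expect_identical(a$pixels, b$pixels)
  expect_error(simulate_ct_slice(ph0, pr, z_center_mm = 500), "outside")
})

test_that("beam hardening streaks need a polychromatic beam", {
  # a moderate-Z insert large enough to harden the beam without photon
  # starvation or extreme edge ringing; huge count budgets disable the
  # detector floor so the spectral mechanism is isolated
  ph <- phantom_spec(extent_cm = c(8, 8, 4),
                     markers = marker_spec("aluminum", 8, 8, c(40, 40, 20)))
  pr <- imaging_protocol("ct", kvp = 120, slice_thickness_mm = 1.25,
                         n_views = 180, detector_bin_mm = 0.5, seed = 1,
                         counts_ref = 1e12)
  poly <- simulate_ct_slice(ph, pr, fov_n = 96, noise = FALSE)
  eff <- effective_energy(protocol_spectrum(pr))
  mono_pr <- imaging_protocol("mvct", energy_kev = eff, n_views = 180,
                              detector_bin_mm = 0.5, seed = 1,
                              counts_ref = 1e12)
  mono <- simulate_ct_slice(ph, mono_pr, fov_n = 96, noise = FALSE)
  ring_idx <- function(img) {
    artifact_index(ring_artifact_profile(img, c(40, 40), r_min_mm = 6,
                                         r_max_mm = 11, n_rings = 50,
                                         n_angular = 360))
  }
  # structured artifact around the insert: present polychromatically,
  # absent (to interpolation error) monochromatically
  expect_gt(ring_idx(poly), 3 * ring_idx(mono))

  # gold under a clinical kV beam: bright marker with deep undershoots
  phg <- tiny_phantom("gold", center = c(30, 30, 20))
  img_g <- simulate_ct_slice(phg, fast_ct_protocol(), fov_n = 64,
                             noise = FALSE)
  expect_gt(max(img_g$pixels), 1000)
  expect_lt(min(img_g$pixels), -200)
})

test_that("partial volume: noise-off peak falls once slice outgrows the marker", {
  ph <- tiny_phantom("carbon", diameter = 1, length = 3,
                     center = c(30, 30, 20))
  peak <- sapply(c(2.5, 3.75, 5), function(t) {
    img <- simulate_ct_slice(ph, fast_ct_protocol(slice = t), fov_n = 48,
                             noise = FALSE)
    max(img$pixels)
  })
  expect_true(all(diff(peak) < 0))
})

test_that("sparse CT projector agrees with the dense pixel-map projector", {
  # one carbon marker in a small phantom, monochromatic beam: the internal
  # sparse path (analytic slab + fine marker samples) must match an
  # independent dense Radon of the voxelized mu map
  ph <- tiny_phantom("carbon", diameter = 1.5, length = 3,
                     center = c(30, 30, 20))
  en <- 60
  pr <- imaging_protocol("mvct", energy_kev = en, n_views = 90,
                         detector_bin_mm = 0.5, slice_thickness_mm = 0.4,
                         seed = 1)
  img <- simulate_ct_slice(ph, pr, fov_n = 64, noise = FALSE)
  mu_w <- attenuation_coefficient("soft_tissue", en)
  mu_hat <- img$pixels / 1000 * mu_w + mu_w

  vox <- 0.25
  n <- 240
  mu_map <- matrix(mu_w, n, n)
  xs <- (seq_len(n) - 0.5) * vox
  r2 <- outer((xs - 30)^2, (xs - 30)^2, "+")
  mu_map[r2 <= 0.75^2] <- attenuation_coefficient("carbon", en)
  sg <- forward_sinogram(mu_map, angles_deg = (seq_len(90) - 0.5) * 2,
                         pixel_mm = vox, detector_bin_mm = 0.5)
  rec <- fbp_reconstruct(sg, n = 64, pixel_mm = 0.25)
  # same geometry reconstructed two ways: peak and background agree
  expect_lt(abs(max(mu_hat) - max(rec)) / max(rec), 0.08)
  expect_lt(abs(mean(mu_hat[1:10, 1:10]) - mean(rec[1:10, 1:10])) / mu_w,
            0.02)
})

test_that("CBCT adds scatter that depresses contrast", {
  ph <- tiny_phantom("carbon", diameter = 1, length = 3,
                     center = c(30, 30, 20))
  base <- imaging_protocol("ct", kvp = 100, slice_thickness_mm = 2.5,
                           n_views = 180, detector_bin_mm = 0.5, seed = 1)
  cb <- imaging_protocol("cbct", kvp = 100, slice_thickness_mm = 2.5,
                         n_views = 180, detector_bin_mm = 0.5, seed = 1,
                         counts_ref = base$counts_ref)
  i1 <- simulate_ct_slice(ph, base, fov_n = 48, noise = FALSE)
  i2 <- simulate_ct_slice(ph, cb, fov_n = 48, noise = FALSE)
  expect_lt(max(i2$pixels), max(i1$pixels))
})
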