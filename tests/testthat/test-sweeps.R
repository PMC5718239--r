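# sweeps use a small single-marker phantom to stay fast
sweep_phantom <- function() {
  phantom_spec(extent_cm = c(6, 6, 4),
               markers = rbind(
                 marker_spec("gold", 0.9, 3, c(20, 30, 20)),
                 marker_spec("carbon", 1, 3, c(40, 30, 20))))
}

test_that("degenerate sweep equals a direct single simulation", {
  ph <- sweep_phantom()
  sw <- run_sweep(ph, modality = "kv_planar", axis = "mas", values = 100,
                  fixed = list(kvp = 80), n_realizations = 1, base_seed = 5,
                  crop_half_mm = 10, exclusion_radius_mm = 4)
  expect_equal(nrow(sw$samples), 2)   # one marker of each material
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$mean_cnr,
               sw$samples$cnr[match(sw$summary$material,
                                    sw$samples$material)])
  # reproduce the gold cell by hand with the recorded child seed
  row <- sw$samples[sw$samples$material == "gold", ]
  ph_g <- phantom_spec(extent_cm = c(6, 6, 4),
                       markers = ph$markers[ph$markers$material == "gold", ])
  pr <- imaging_protocol("kv_planar", kvp = 80, mas = 100, seed = row$seed)
  full <- simulate_planar(ph_g, pr)
  crop <- fidviz:::.crop_image(full, c(20, 30), 10)
  ctr <- detect_marker_center(crop, c(20, 30), 3)
  st <- roi_stats(crop, ctr, 75, 4)
  expect_equal(row$cnr, compute_cnr(st))
  expect_equal(c(row$s_max, row$s_bg_sd), c(st$s_max, st$s_bg_sd))
})

test_that("sweep is reproducible and deterministic given the base seed", {
  ph <- sweep_phantom()
  sw1 <- run_sweep(ph, modality = "kv_planar", axis = "mas",
                   values = c(50, 200), fixed = list(kvp = 80),
                   n_realizations = 2, base_seed = 7, crop_half_mm = 10,
                   exclusion_radius_mm = 4)
  sw2 <- run_sweep(ph, modality = "kv_planar", axis = "mas",
                   values = c(50, 200), fixed = list(kvp = 80),
                   n_realizations = 2, base_seed = 7, crop_half_mm = 10,
                   exclusion_radius_mm = 4)
  expect_identical(sw1$samples, sw2$samples)
  sw3 <- run_sweep(ph, modality = "kv_planar", axis = "mas",
                   values = c(50, 200), fixed = list(kvp = 80),
                   n_realizations = 2, base_seed = 8, crop_half_mm = 10,
                   exclusion_radius_mm = 4)
  expect_false(identical(sw1$samples$cnr, sw3$samples$cnr))
  # every cell carries exactly n_realizations samples per marker
  counts <- table(sw1$samples$material, sw1$samples$value)
  expect_true(all(counts == 2))
})

test_that("child seeds are stable, order-independent scalars", {
  s1 <- child_seed(42, "a", 1)
  expect_identical(s1, child_seed(42, "a", 1))
  expect_false(s1 == child_seed(42, "a", 2))
  expect_false(s1 == child_seed(43, "a", 1))
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_type(s1, "integer")
})

test_that("invalid axis/modality pairings are protocol errors", {
  ph <- sweep_phantom()
  expect_error(run_sweep(ph, modality = "mv_planar", axis = "kvp",
                         values = c(60, 80)), "not sweepable")
  expect_error(run_sweep(ph, modality = "ct", axis = "mu", values = 1),
               "not sweepable")
  expect_error(run_sweep(ph, modality = "ct", axis = "kvp",
                         values = numeric(0)), "non-empty")
})

test_that("visibility report applies the Rose criterion", {
  fake <- structure(list(
    summary = tibble::tibble(material = c("a", "b"), value = 1,
                             mean_cnr = c(0, 6.5), sd_cnr = 0, n = 5),
    axis = "mu", modality = "mv_planar", values = 1),
    class = "fid_sweep")
  vr <- visibility_report(fake)
  expect_identical(vr$visible, c(FALSE, TRUE))
  # nothing visible at zero CNR regardless of threshold
  vr0 <- visibility_report(fake, threshold = 1e-9)
  expect_identical(vr0$visible, c(FALSE, TRUE))
  expect_error(visibility_report(fake, threshold = 0), "threshold")
})

test_that("trend summary: slopes, peaks, tie-breaks", {
  mk_sweep <- function(vals, cnr_by_mat) {
    structure(list(
      summary = tibble::tibble(
        material = rep(names(cnr_by_mat), each = length(vals)),
        value = rep(vals, length(cnr_by_mat)),
        mean_cnr = unlist(cnr_by_mat), sd_cnr = 0, n = 5),
      axis = "kvp", modality = "ct", values = vals), class = "fid_sweep")
  }
  sw <- mk_sweep(c(1, 2, 3), list(up = c(1, 2, 3), flat = c(2, 2, 2)))
  ts <- trend_summary(sw)
  expect_equal(ts$slope_sign[ts$material == "up"], 1)
  expect_equal(ts$peak_value[ts$material == "up"], 3)
  # equal cells: slope 0, peak at the first value by the tie rule
  expect_equal(ts$slope[ts$material == "flat"], 0)
  expect_equal(ts$peak_value[ts$material == "flat"], 1)
  expect_equal(ts$rel_range[ts$material == "flat"], 0)
  expect_error(trend_summary(mk_sweep(c(1, 2), list(a = c(1, 2)))),
               "3 numeric")
})

test_that("write_report emits per-sweep CSVs, figures, and a manifest", {
  ph <- sweep_phantom()
  sw <- run_sweep(ph, modality = "kv_planar", axis = "mas",
                  values = c(50, 200), fixed = list(kvp = 80),
                  n_realizations = 2, base_seed = 7, crop_half_mm = 10,
                  exclusion_radius_mm = 4)
  out <- withr::local_tempdir()
  write_report(list(obi = sw), out)
  expect_true(file.exists(file.path(out, "obi_samples.csv")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  got <- read.csv(file.path(out, "obi_samples.csv"))
  # row count: materials x values x realizations (one marker per material)
  expect_equal(nrow(got), 2 * 2 * 2)
  # idempotent: rerun writes byte-identical CSVs
  bytes1 <- readBin(file.path(out, "obi_samples.csv"), "raw", 1e6)
  write_report(list(obi = sw), out)
  bytes2 <- readBin(file.path(out, "obi_samples.csv"), "raw", 1e6)
  expect_identical(bytes1, bytes2)
  # empty result list: manifest only
  out2 <- withr::local_tempdir()
  write_report(list(), out2)
  expect_identical(list.files(out2), "manifest.yaml")
})

test_that("tidy, glance, and autoplot work on sweep results", {
  ph <- sweep_phantom()
  sw <- run_sweep(ph, modality = "kv_planar", axis = "mas", values = 100,
                  fixed = list(kvp = 80), n_realizations = 1, base_seed = 5,
                  crop_half_mm = 10, exclusion_radius_mm = 4)
  expect_identical(tidy(sw), sw$samples)
  gl <- glance(sw)
  expect_true(all(c("mean_cnr", "modality", "axis") %in% names(gl)))
  expect_s3_class(autoplot(sw), "ggplot")
  img <- random_image(16, 16)
  expect_s3_class(autoplot(img), "ggplot")
  pr <- ring_artifact_profile(random_image(60, 60, 0.5, seed = 2),
                              c(15, 15), n_rings = 10, r_max_mm = 8)
  expect_s3_class(autoplot(pr), "ggplot")
  expect_equal(nrow(tidy(pr)), 10)
})
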