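# Protocol sweeps: simulate - locate - score across a parameter grid, with
# deterministic child seeds per (axis value, realization).

# Deterministic child seed: fold the textual key into a 31-bit hash with the
# classic polynomial-rolling scheme. Stable across platforms and execution
# order; documented so runs can be reproduced piecemeal.
child_seed <- function(base_seed, ...) {
  key <- paste(c(format(base_seed), vapply(list(...), format, character(1))),
               collapse = "|")
  h <- as.double(base_seed) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

.sweep_axes <- list(
  ct = c("kvp", "slice_thickness_mm", "mas"),
  cbct = c("kvp", "slice_thickness_mm"),
  kv_planar = c("kvp", "mas"),
  mv_planar = c("mu"),
  mvct = c("scan_mode")
)

# crop a sub-image of half-width `half_mm` around a center
.crop_image <- function(img, center_mm, half_mm) {
  ax <- .image_axes(img)
  ix <- which(abs(ax$x - center_mm[1]) <= half_mm)
  iy <- which(abs(ax$y - center_mm[2]) <= half_mm)
  image2d(img$pixels[ix, iy, drop = FALSE], img$spacing_mm,
          units = img$units,
          origin_mm = c(ax$x[ix[1]], ax$y[iy[1]]) - img$spacing_mm / 2,
          protocol = img$protocol, seed = img$seed)
}

# simulate one protocol and return one image per marker (ROI views for 3D
# modalities, crops of the full radiograph for planar ones)
.per_marker_images <- function(phantom, protocol, fov_n, fov_pixel_mm,
                               crop_half_mm, noise, materials, k_pe) {
  mk <- phantom$markers
  if (protocol$modality %in% c("ct", "cbct", "mvct")) {
    fovs <- lapply(seq_len(nrow(mk)), function(i) {
      list(center_mm = c(mk$x_mm[i], mk$y_mm[i]), n = fov_n,
           pixel_mm = fov_pixel_mm)
    })
    .simulate_ct_multifov(phantom, protocol,
                          z_center_mm = phantom$extent_mm[3] / 2,
                          fovs = fovs, noise = noise, materials = materials,
                          k_pe = k_pe)
  } else {
    full <- simulate_planar(phantom, protocol, noise = noise,
                            materials = materials, k_pe = k_pe)
    lapply(seq_len(nrow(mk)), function(i) {
      .crop_image(full, c(mk$x_mm[i], mk$y_mm[i]), crop_half_mm)
    })
  }
}

#' Run a parameter sweep
#'
#' For each grid value and noise realization: simulate the phantom under the
#' protocol, locate every marker, and compute its contrast-to-noise ratio on
#' a per-marker region of interest; results are aggregated per material.
#' Child seeds derive deterministically from `base_seed`, the realization
#' index, and the simulated material set, so any cell can be reproduced in
#' isolation and re-running the sweep with the same `base_seed` reproduces
#' every number exactly. Within one realization all grid values share a
#' noise stream (common random numbers, realised by inversion-sampled
#' Poisson noise), which sharpens estimated parameter trends without
#' biasing them.
#'
#' Metrics are evaluated on a per-marker sub-image (CT: a reconstructed ROI
#' centered on the marker; planar: a crop of the radiograph), so each
#' marker's statistics reflect its own surroundings; the nominal 15 cm
#' square profile is clipped to that sub-image.
#'
#' @param phantom A [phantom_spec()]; defaults to [default_phantom()].
#' @param modality Imaging modality, see [imaging_protocol()].
#' @param axis Protocol parameter to sweep (`"kvp"`, `"mas"`,
#'   `"slice_thickness_mm"`, `"mu"`, `"scan_mode"`); must be valid for the
#'   modality.
#' @param values Non-empty grid of axis values.
#' @param fixed Named list of other [imaging_protocol()] arguments held
#'   fixed.
#' @param n_realizations Noise realizations per grid value.
#' @param base_seed Base RNG seed.
#' @param fov_n,fov_pixel_mm Per-marker reconstruction grid (3D modalities).
#' @param crop_half_mm Half-width of per-marker crops (planar modalities)
#'   and of the clipped metric profile.
#' @param exclusion_radius_mm Background exclusion disk for [roi_stats()].
#' @param isolate_materials Simulate each marker material in its own copy of
#'   the phantom (default)? This keeps one material's artifact (gold streaks
#'   reach several centimetres at low kVp) out of another material's
#'   background statistics, so each trend reflects that marker's own physics.
#'   Set to `FALSE` to image all markers together.
#' @param materials,k_pe Physics configuration.
#' @return A `fid_sweep` object: `samples` (one row per marker, value,
#'   realization), `summary` (mean and SD of CNR per material and value),
#'   plus the sweep configuration. See [trend_summary()],
#'   [visibility_report()], [autoplot.fid_sweep()].
#' @examples
#' \donttest{
#' sw <- run_sweep(modality = "kv_planar", axis = "mas",
#'                 values = c(50, 100, 200), n_realizations = 2,
#'                 base_seed = 7)
#' sw$summary
#' }
#' @export
run_sweep <- function(phantom = default_phantom(), modality, axis, values,
                      fixed = list(), n_realizations = 5, base_seed = 1,
                      fov_n = 128, fov_pixel_mm = 0.25, crop_half_mm = 16,
                      exclusion_radius_mm = 7.5, isolate_materials = TRUE,
                      materials = material_table(),
                      k_pe = k_pe_default(materials)) {
  modality <- match.arg(modality, .modalities)
  if (length(values) < 1) stop("`values` must be non-empty", call. = FALSE)
  if (!axis %in% .sweep_axes[[modality]]) {
    stop(sprintf("axis '%s' is not sweepable for modality '%s'", axis,
                 modality), call. = FALSE)
  }
  if (nrow(phantom$markers) == 0) stop("phantom has no markers",
                                       call. = FALSE)
  phantoms <- if (isolate_materials) {
    lapply(unique(phantom$markers$material), function(m) {
      phantom_spec(extent_cm = phantom$extent_mm / 10,
                   layer_thickness_cm = phantom$layer_thickness_mm / 10,
                   background_material = phantom$background_material,
                   markers = phantom$markers[phantom$markers$material == m,
                                             , drop = FALSE],
                   materials = materials)
    })
  } else list(phantom)
  samples <- purrr::map_dfr(seq_along(values), function(vi) {
    purrr::map_dfr(seq_len(n_realizations), function(ri) {
      args <- c(list(modality = modality), fixed)
      args[[axis]] <- values[[vi]]
      purrr::map_dfr(phantoms, function(ph) {
        mk <- ph$markers
        # seed depends on the realization but NOT the axis value: grid cells
        # of one realization share their noise stream (common random
        # numbers), so estimated trends difference the quantum noise out
        args$seed <- child_seed(base_seed, ri,
                                paste(unique(mk$material), collapse = "+"))
        protocol <- do.call(imaging_protocol, args)
        imgs <- .per_marker_images(ph, protocol, fov_n, fov_pixel_mm,
                                   crop_half_mm, noise = TRUE, materials,
                                   k_pe)
        purrr::map_dfr(seq_len(nrow(mk)), function(i) {
          ctr <- detect_marker_center(imgs[[i]],
                                      c(mk$x_mm[i], mk$y_mm[i]),
                                      search_radius_mm = 3)
          st <- roi_stats(imgs[[i]], ctr,
                          roi_half_width_mm = 75,
                          exclusion_radius_mm = exclusion_radius_mm)
          tibble::tibble(material = mk$material[i],
                         marker_id = mk$marker_id[i],
                         value = if (is.numeric(values)) values[[vi]] else
                           as.character(values[[vi]]),
                         realization = ri, seed = protocol$seed,
                         s_max = st$s_max, s_bg_mean = st$s_bg_mean,
                         s_bg_sd = st$s_bg_sd, cnr = compute_cnr(st))
        })
      })
    })
  })
  summary <- samples |>
    dplyr::group_by(.data$material, .data$value) |>
    dplyr::summarise(mean_cnr = mean(.data$cnr),
                     sd_cnr = stats::sd(.data$cnr),
                     n = dplyr::n(), .groups = "drop")
  structure(list(samples = samples, summary = summary, axis = axis,
                 modality = modality, values = values, fixed = fixed,
                 n_realizations = n_realizations, base_seed = base_seed),
            class = "fid_sweep")
}

#' @export
print.fid_sweep <- function(x, ...) {
  cat(sprintf("<fid_sweep> %s over %s (%d values x %d realizations), seed %s\n",
              x$modality, x$axis, length(x$values), x$n_realizations,
              format(x$base_seed)))
  print(x$summary)
  invisible(x)
}

#' Study presets
#'
#' The parameter grids of the phantom study: CT kVp and slice-thickness
#' series, planar kV tube-voltage and mAs series, CBCT kV series, planar MV,
#' and helical MV CT fine/normal modes. Presets use a 360-view, 0.5 mm
#' detector-bin acquisition reconstructed on a 128^2 grid of 0.25 mm pixels
#' per marker.
#'
#' @param name Preset name: `"ct-kvp"`, `"ct-slice"`, `"obi-kvp"`,
#'   `"obi-mas"`, `"cbct-kv"`, `"mv"`, `"mvct"`.
#' @param base_seed,n_realizations,phantom,... Passed to [run_sweep()].
#' @return A `fid_sweep`.
#' @export
sweep_preset <- function(name, base_seed = 1, n_realizations = 5,
                         phantom = default_phantom(), ...) {
  cfg <- .sweep_preset_config(name)
  run_sweep(phantom = phantom, modality = cfg$modality, axis = cfg$axis,
            values = cfg$values, fixed = cfg$fixed,
            n_realizations = n_realizations, base_seed = base_seed, ...)
}

.sweep_preset_config <- function(name) {
  ct_fix <- list(n_views = 360, detector_bin_mm = 0.5)
  switch(match.arg(name, c("ct-kvp", "ct-slice", "obi-kvp",
                           "obi-mas", "cbct-kv", "mv", "mvct")),
    "ct-kvp" = list(modality = "ct", axis = "kvp",
                    values = c(80, 100, 120, 140),
                    fixed = c(list(slice_thickness_mm = 2.5), ct_fix)),
    "ct-slice" = list(modality = "ct", axis = "slice_thickness_mm",
                      values = c(0.625, 1.25, 2.5, 3.75, 5),
                      fixed = c(list(kvp = 120), ct_fix)),
    "obi-kvp" = list(modality = "kv_planar", axis = "kvp",
                     values = c(60, 70, 75, 80, 90, 100, 110, 120),
                     fixed = list(mas = 200)),
    "obi-mas" = list(modality = "kv_planar", axis = "mas",
                     values = c(50, 63, 80, 100, 125, 160, 200),
                     fixed = list(kvp = 80)),
    "cbct-kv" = list(modality = "cbct", axis = "kvp",
                     values = c(60, 90, 100, 125),
                     fixed = c(list(slice_thickness_mm = 2.5), ct_fix)),
    "mv" = list(modality = "mv_planar", axis = "mu", values = c(1, 2),
                fixed = list()),
    "mvct" = list(modality = "mvct", axis = "scan_mode",
                  values = c("fine", "normal"), fixed = ct_fix))
}

#' Visibility report
#'
#' Classifies each material as visible or not at each grid value by the Rose
#' criterion: mean CNR at or above `threshold` (default 4).
#'
#' @param result A `fid_sweep`.
#' @param threshold Visibility threshold (> 0).
#' @return Tibble: material, value, mean_cnr, visible.
#' @export
visibility_report <- function(result, threshold = 4) {
  stopifnot(inherits(result, "fid_sweep"), threshold > 0)
  dplyr::mutate(result$summary, threshold = threshold,
                visible = .data$mean_cnr >= threshold)
}

#' Trend summary
#'
#' Per-material least-squares slope of mean CNR against the (numeric) axis
#' value, its sign, the grid value at which mean CNR peaks (ties broken
#' toward the smaller value), and the relative range
#' (max - min) / mean of the per-value means.
#'
#' @param result A `fid_sweep` with at least 3 numeric grid values.
#' @return Tibble: material, slope, slope_sign, peak_value, rel_range.
#' @export
trend_summary <- function(result) {
  stopifnot(inherits(result, "fid_sweep"))
  if (length(result$values) < 3 || !is.numeric(result$summary$value)) {
    stop("trend_summary needs >= 3 numeric grid values", call. = FALSE)
  }
  result$summary |>
    dplyr::group_by(.data$material) |>
    dplyr::arrange(.data$value, .by_group = TRUE) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(mean_cnr ~ value,
                                    data = dplyr::pick(dplyr::everything())
                                    ))[["value"]],
      slope_sign = sign(.data$slope),
      peak_value = .data$value[which.max(.data$mean_cnr)],
      rel_range = (max(.data$mean_cnr) - min(.data$mean_cnr)) /
        mean(.data$mean_cnr),
      .groups = "drop")
}

#' Ring-artifact profiles of the phantom markers
#'
#' Noise-free acquisition of the central slice under a protocol, followed by
#' a ring artifact profile around the central marker of each material. With
#' noise disabled the per-ring SD isolates structured artifact (streaks,
#' cupping) from quantum mottle.
#'
#' @param phantom A [phantom_spec()].
#' @param protocol A 3D-modality [imaging_protocol()].
#' @param noise Poisson noise flag (default `FALSE`).
#' @param fov_n,fov_pixel_mm Per-marker reconstruction grid.
#' @param n_rings,n_angular,r_min_mm,r_max_mm Ring sampling, see
#'   [ring_artifact_profile()].
#' @param isolate_materials Image each material in its own phantom copy
#'   (default), as in [run_sweep()].
#' @param materials,k_pe Physics configuration.
#' @return Tibble: material, marker_id, radius_mm, sd.
#' @export
marker_artifact_profiles <- function(phantom, protocol, noise = FALSE,
                                     fov_n = 128, fov_pixel_mm = 0.25,
                                     n_rings = 1000, n_angular = 720,
                                     r_min_mm = 1, r_max_mm = 15,
                                     isolate_materials = TRUE,
                                     materials = material_table(),
                                     k_pe = k_pe_default(materials)) {
  mk <- phantom$markers
  # central marker of each material (closest to the phantom axis)
  dd <- (mk$x_mm - phantom$extent_mm[1] / 2)^2
  sel <- mk[vapply(split(seq_len(nrow(mk)), mk$material),
                   function(ii) ii[which.min(dd[ii])], integer(1)), ,
            drop = FALSE]
  purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    ph_i <- if (isolate_materials) {
      phantom_spec(extent_cm = phantom$extent_mm / 10,
                   layer_thickness_cm = phantom$layer_thickness_mm / 10,
                   background_material = phantom$background_material,
                   markers = mk[mk$material == sel$material[i], ,
                                drop = FALSE],
                   materials = materials)
    } else phantom
    img <- .simulate_ct_multifov(ph_i, protocol,
                                 z_center_mm = phantom$extent_mm[3] / 2,
                                 fovs = list(list(
                                   center_mm = c(sel$x_mm[i], sel$y_mm[i]),
                                   n = fov_n, pixel_mm = fov_pixel_mm)),
                                 noise = noise, materials = materials,
                                 k_pe = k_pe)[[1]]
    pr <- ring_artifact_profile(img, c(sel$x_mm[i], sel$y_mm[i]),
                                r_min_mm, r_max_mm, n_rings, n_angular)
    tibble::tibble(material = sel$material[i], marker_id = sel$marker_id[i],
                   radius_mm = pr$radius_mm, sd = pr$sd)
  })
}

#' Write sweep reports
#'
#' One CSV of per-sample results and one of per-cell summaries per sweep,
#' one trend figure per sweep, and a YAML manifest recording seeds, grids,
#' and the package version. Deterministic inputs give byte-identical CSVs.
#'
#' @param results Named list of `fid_sweep` objects (may be empty: the
#'   manifest is still written).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results))) {
    names(results) <- vapply(results, function(r) {
      paste(r$modality, r$axis, sep = "-")
    }, character(1))
  }
  for (nm in names(results)) {
    r <- results[[nm]]
    utils::write.csv(r$samples, file.path(out_dir,
                                          paste0(nm, "_samples.csv")),
                     row.names = FALSE)
    utils::write.csv(r$summary, file.path(out_dir,
                                          paste0(nm, "_summary.csv")),
                     row.names = FALSE)
    gg <- autoplot.fid_sweep(r)
    ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), gg,
                    width = 6, height = 4, dpi = 150)
  }
  manifest <- list(
    package = "fidviz",
    version = as.character(utils::packageVersion("fidviz")),
    sweeps = lapply(results, function(r) {
      list(modality = r$modality, axis = r$axis,
           values = as.vector(r$values), base_seed = r$base_seed,
           n_realizations = r$n_realizations)
    }))
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
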