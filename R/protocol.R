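.modalities <- c("ct", "cbct", "kv_planar", "mv_planar", "mvct")

# Detector count budgets (documented calibration constants).
#
# Planar kV follows the explicit budget: 1e5 incident counts per detector
# pixel at 200 mAs, linear in mAs. The 3D kV modalities model auto-exposure
# (the clinical scanners adapt tube current to a noise target, and the study
# protocols specify kV and slice thickness but no CT mAs): the *detected*
# count budget behind the phantom is held at a reference value, scaled
# proportionally to slice thickness. MV budgets reflect the poor contrast
# conditions of megavoltage detectors and were calibrated once so the default
# MV presets land at clinically reported operating points (gold CNR ~ 6 on a
# 2 MU portal image, ~ 20 on fine-mode helical MV CT).
.fid_budgets <- list(
  kv_planar_counts_at_200mas = 6e5,   # incident, per pixel
  mv_planar_counts_per_mu    = 22000, # incident, per pixel
  ct_detected_ref            = 800,   # detected per ray at 2.5 mm slice
  cbct_detected_ref          = 300,   # detected per ray at 2.5 mm slice
  mvct_detected_fine         = 660,   # detected per ray, fine mode
  mvct_detected_normal       = 750    # detected per ray, normal mode
)
# The two MV CT budgets are effective per-mode constants (detected fluence
# per reconstructed slice after pitch, slice width, and reconstruction
# filters): the normal mode's thicker slice loses more gold signal to
# partial volume than its coarser pitch costs in fluence, so the calibrated
# budgets come out similar.

#' Imaging protocol
#'
#' Bundles modality, beam quality, exposure, and geometry for one acquisition.
#' Kilovoltage modalities take a peak tube voltage `kvp` (polychromatic
#' spectrum); megavoltage modalities are modelled as monoenergetic at
#' `energy_kev` (Compton-dominated contrast). Exposure semantics per modality:
#' planar kV scales incident counts with `mas`; planar MV with `mu`; the 3D
#' modalities use an auto-exposure model in which the detected count budget
#' behind the phantom is `counts_ref` scaled by slice thickness (see
#' Details in the package vignette).
#'
#' @param modality One of `"ct"`, `"cbct"`, `"kv_planar"`, `"mv_planar"`,
#'   `"mvct"`.
#' @param kvp Peak tube voltage (kV), kV modalities only.
#' @param energy_kev Effective beam energy (keV) for MV modalities
#'   (default 2000 planar MV, 1000 MV CT).
#' @param mas Tube current-time product, planar kV.
#' @param mu Monitor units, planar MV.
#' @param slice_thickness_mm Slice thickness, 3D modalities.
#' @param scan_mode `"fine"` or `"normal"`, MV CT only (sets slice thickness
#'   2 / 4 mm and the detected-count budget).
#' @param pixel_spacing_mm Image pixel spacing.
#' @param detector_bin_mm Detector bin width (3D modalities); defaults to
#'   `pixel_spacing_mm`.
#' @param n_views Projection count over 180 degrees (3D modalities).
#' @param filtration_mm_al Aluminum-equivalent tube filtration, kV beams.
#' @param scatter_fraction Flat additive scatter fraction (CBCT default 0.2,
#'   otherwise 0).
#' @param counts_ref Count budget; `NULL` picks the modality default.
#' @param seed RNG seed recorded in every output's provenance.
#' @return An `imaging_protocol` object.
#' @examples
#' imaging_protocol("ct", kvp = 120, slice_thickness_mm = 1.25, seed = 1)
#' imaging_protocol("mv_planar", mu = 2, seed = 1)
#' @export
imaging_protocol <- function(modality, kvp = NULL, energy_kev = NULL,
                             mas = NULL, mu = NULL,
                             slice_thickness_mm = NULL, scan_mode = NULL,
                             pixel_spacing_mm = NULL, detector_bin_mm = NULL,
                             n_views = 720, filtration_mm_al = 2.5,
                             scatter_fraction = NULL, counts_ref = NULL,
                             seed = 1L) {
  modality <- match.arg(modality, .modalities)
  is_mv <- modality %in% c("mv_planar", "mvct")
  is_3d <- modality %in% c("ct", "cbct", "mvct")
  if (is_mv) {
    if (!is.null(kvp)) stop("MV modalities take `energy_kev`, not `kvp`",
                            call. = FALSE)
    if (is.null(energy_kev)) {
      energy_kev <- if (modality == "mv_planar") 2000 else 1000
    }
  } else {
    if (is.null(kvp)) stop("kV modalities need `kvp`", call. = FALSE)
    stopifnot(kvp > 0)
  }
  if (modality == "mvct") {
    scan_mode <- match.arg(scan_mode %||% "fine", c("fine", "normal"))
    if (is.null(slice_thickness_mm)) {
      slice_thickness_mm <- if (scan_mode == "fine") 2 else 4
    }
  }
  if (is_3d) {
    if (is.null(slice_thickness_mm)) slice_thickness_mm <- 2.5
    stopifnot(slice_thickness_mm > 0, n_views >= 2)
  }
  if (modality == "kv_planar" && is.null(mas)) mas <- 200
  if (modality == "mv_planar" && is.null(mu)) mu <- 2
  if (!is.null(mas) && mas <= 0) stop("`mas` must be > 0", call. = FALSE)
  if (!is.null(mu) && mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- switch(modality, kv_planar = 0.4, mv_planar = 1.27,
                               0.25)
  }
  if (is.null(detector_bin_mm)) detector_bin_mm <- pixel_spacing_mm
  if (is.null(scatter_fraction)) {
    scatter_fraction <- if (modality == "cbct") 0.2 else 0
  }
  if (is.null(counts_ref)) {
    counts_ref <- switch(modality,
      kv_planar = .fid_budgets$kv_planar_counts_at_200mas,
      mv_planar = .fid_budgets$mv_planar_counts_per_mu,
      ct        = .fid_budgets$ct_detected_ref,
      cbct      = .fid_budgets$cbct_detected_ref,
      mvct      = if (scan_mode == "fine") .fid_budgets$mvct_detected_fine
                  else .fid_budgets$mvct_detected_normal)
  }
  structure(list(modality = modality, kvp = kvp, energy_kev = energy_kev,
                 mas = mas, mu = mu, slice_thickness_mm = slice_thickness_mm,
                 scan_mode = scan_mode, pixel_spacing_mm = pixel_spacing_mm,
                 detector_bin_mm = detector_bin_mm, n_views = n_views,
                 filtration_mm_al = filtration_mm_al,
                 scatter_fraction = scatter_fraction,
                 counts_ref = counts_ref, seed = as.integer(seed)),
            class = "imaging_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.imaging_protocol <- function(x, ...) {
  beam <- if (is.null(x$kvp)) sprintf("%g keV (MV)", x$energy_kev)
          else sprintf("%g kVp", x$kvp)
  expo <- if (!is.null(x$mas)) sprintf(", %g mAs", x$mas)
          else if (!is.null(x$mu)) sprintf(", %g MU", x$mu) else ""
  sl <- if (!is.null(x$slice_thickness_mm))
    sprintf(", slice %g mm", x$slice_thickness_mm) else ""
  cat(sprintf("<imaging_protocol> %s, %s%s%s, seed %d\n", x$modality, beam,
              expo, sl, x$seed))
  invisible(x)
}

#' Beam spectrum of a protocol
#'
#' @param protocol An [imaging_protocol()].
#' @param bin_width_kev Bin width for polychromatic spectra.
#' @param materials,k_pe Physics configuration.
#' @return A `fid_spectrum`: polychromatic for kV modalities, monoenergetic
#'   for MV modalities.
#' @export
protocol_spectrum <- function(protocol, bin_width_kev = 1,
                              materials = material_table(),
                              k_pe = k_pe_default(materials)) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  if (protocol$modality %in% c("mv_planar", "mvct")) {
    mono_spectrum(protocol$energy_kev)
  } else {
    xray_spectrum(protocol$kvp, protocol$filtration_mm_al, bin_width_kev,
                  materials = materials, k_pe = k_pe)
  }
}

# Sub-slice sampling positions across the slice: odd count so the central
# plane is sampled; step ~0.1 mm, capped at 51.
.sub_slice_offsets <- function(thickness_mm) {
  n <- max(3, ceiling(thickness_mm / 0.1))
  n <- min(n, 51)
  if (n %% 2 == 0) n <- n + 1
  seq(-thickness_mm / 2, thickness_mm / 2, length.out = n + 2)[-c(1, n + 2)]
}
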