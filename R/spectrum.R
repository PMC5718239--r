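#' X-ray tube spectrum
#'
#' Polychromatic bremsstrahlung spectrum of a tungsten-anode tube at peak
#' voltage `kvp`, using the Kramers shape (unfiltered photon fluence per bin
#' proportional to \eqn{(kVp - E)/E}), hardened by an aluminum-equivalent
#' filter via Beer-Lambert attenuation, then renormalised to unit total
#' weight. Characteristic lines are omitted; bins start at a low-energy
#' cutoff below which the filtered fluence is negligible.
#'
#' @param kvp Peak tube voltage in kV (> `bin_width_kev`).
#' @param filtration_mm_al Aluminum-equivalent filtration in mm (>= 0).
#' @param bin_width_kev Energy bin width in keV.
#' @param cutoff_kev Low-energy cutoff in keV.
#' @param materials Material table (supplies aluminum attenuation).
#' @param k_pe Photoelectric scale constant.
#' @return A `fid_spectrum`: tibble with columns `energy_kev` (strictly
#'   increasing bin centers) and `weight` (non-negative, sums to 1), with the
#'   generating parameters as attributes.
#' @examples
#' s <- xray_spectrum(120)
#' effective_energy(s)
#' @export
xray_spectrum <- function(kvp, filtration_mm_al = 2.5, bin_width_kev = 1,
                          cutoff_kev = 10, materials = material_table(),
                          k_pe = k_pe_default(materials)) {
  if (kvp <= bin_width_kev) stop("`kvp` must exceed `bin_width_kev`",
                                 call. = FALSE)
  if (filtration_mm_al < 0) stop("`filtration_mm_al` must be >= 0",
                                 call. = FALSE)
  edges <- seq(cutoff_kev, kvp, by = bin_width_kev)
  if (edges[length(edges)] < kvp) edges <- c(edges, kvp)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- (kvp - centers) / centers
  if (filtration_mm_al > 0) {
    mu_al <- attenuation_coefficient("aluminum", centers, materials, k_pe)
    w <- w * exp(-mu_al * filtration_mm_al / 10)
  }
  new_spectrum(centers, w, kvp = kvp, filtration_mm_al = filtration_mm_al)
}

#' Monoenergetic spectrum
#'
#' Single-bin spectrum, used for megavoltage beams (modelled at a configurable
#' effective energy, Compton-dominated) and for monochromatic reference
#' reconstructions.
#'
#' @param energy_kev Photon energy in keV.
#' @return A `fid_spectrum` with one bin of weight 1.
#' @export
mono_spectrum <- function(energy_kev) {
  stopifnot(length(energy_kev) == 1L, energy_kev > 0)
  new_spectrum(energy_kev, 1, kvp = energy_kev, filtration_mm_al = 0)
}

new_spectrum <- function(energy_kev, weight, kvp = NA_real_,
                         filtration_mm_al = NA_real_) {
  if (length(energy_kev) == 0L) stop("empty spectrum", call. = FALSE)
  if (any(diff(energy_kev) <= 0)) {
    stop("spectrum energies must be strictly increasing", call. = FALSE)
  }
  if (any(weight < 0)) stop("spectrum weights must be >= 0", call. = FALSE)
  tot <- sum(weight)
  if (tot <= 0) stop("spectrum has zero total weight", call. = FALSE)
  out <- tibble::tibble(energy_kev = as.numeric(energy_kev),
                        weight = as.numeric(weight) / tot)
  structure(out, kvp = kvp, filtration_mm_al = filtration_mm_al,
            class = c("fid_spectrum", class(out)))
}

.assert_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "fid_spectrum") || nrow(spectrum) == 0L) {
    stop("`spectrum` must be a non-empty fid_spectrum", call. = FALSE)
  }
  invisible(spectrum)
}

#' Fluence-weighted effective energy of a spectrum
#'
#' @param spectrum A [xray_spectrum()] / [mono_spectrum()] object.
#' @return Mean energy \eqn{\sum w_i E_i} in keV; lies within the spectrum's
#'   energy range. Used as the single energy for the reconstruction-side
#'   Hounsfield calibration (the monochromatic assumption whose mismatch with
#'   polychromatic data produces beam-hardening artifact).
#' @export
effective_energy <- function(spectrum) {
  .assert_spectrum(spectrum)
  sum(spectrum$weight * spectrum$energy_kev)
}

#' @export
print.fid_spectrum <- function(x, ...) {
  cat(sprintf("<fid_spectrum> %d bins, %.1f-%.1f keV, effective %.2f keV\n",
              nrow(x), min(x$energy_kev), max(x$energy_kev),
              effective_energy(x)))
  invisible(x)
}
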