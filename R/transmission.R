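# Energy-integrating detector weights: photon fluence weight x energy,
# normalised so an unattenuated beam reads 1.
.detector_weights <- function(spectrum) {
  v <- spectrum$weight * spectrum$energy_kev
  v / sum(v)
}

#' Polychromatic transmission along rays
#'
#' Detected signal fraction of an energy-integrating detector behind given
#' per-material path lengths:
#' \deqn{T = \sum_i w_i E_i \exp(-\sum_m \mu_m(E_i) L_m) / \sum_i w_i E_i.}
#' For a single-bin spectrum through thickness L of one material this reduces
#' exactly to \eqn{\exp(-\mu L)}.
#'
#' @param path_lengths_mm Numeric matrix, rays in rows, one column per
#'   material (columns named with registered material names), path lengths in
#'   mm. A bare vector is taken as a single ray.
#' @param spectrum A `fid_spectrum`.
#' @param materials,k_pe Physics configuration.
#' @return Transmission fraction per ray, in (0, 1].
#' @examples
#' polychromatic_transmission(
#'   cbind(soft_tissue = c(0, 100, 200)), mono_spectrum(70))
#' @export
polychromatic_transmission <- function(path_lengths_mm, spectrum,
                                       materials = material_table(),
                                       k_pe = k_pe_default(materials)) {
  .assert_spectrum(spectrum)
  if (is.null(dim(path_lengths_mm))) {
    path_lengths_mm <- matrix(path_lengths_mm, nrow = 1,
                              dimnames = list(NULL,
                                              names(path_lengths_mm)))
  }
  if (is.null(colnames(path_lengths_mm))) {
    stop("`path_lengths_mm` columns must be named with material names",
         call. = FALSE)
  }
  if (any(path_lengths_mm < 0)) stop("path lengths must be >= 0",
                                     call. = FALSE)
  mu <- .mu_matrix(colnames(path_lengths_mm), spectrum$energy_kev,
                   materials, k_pe)                      # nE x nmat
  v <- .detector_weights(spectrum)
  # optical depth per (ray, energy): L [mm] / 10 -> cm
  od <- (path_lengths_mm / 10) %*% t(mu)
  as.vector(exp(-od) %*% v)
}

# Lookup table T(L) for rays through a single (background) material:
# piecewise-linear interpolation on a fine path-length grid.
.transmission_table <- function(material, spectrum, materials, k_pe,
                                l_max_mm, n = 600) {
  mu <- attenuation_coefficient(material, spectrum$energy_kev, materials,
                                k_pe)
  v <- .detector_weights(spectrum)
  grid <- seq(0, l_max_mm, length.out = n)
  tvals <- as.vector(exp(-outer(grid / 10, mu)) %*% v)
  list(grid = grid, tvals = tvals,
       fun = function(l) {
         stats::approx(grid, tvals, xout = l, rule = 2)$y
       })
}
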