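# Physical constants (CGS-ish units: cm, g, keV)
.re_cm <- 2.8179403262e-13      # classical electron radius
.mec2_kev <- 510.99895          # electron rest energy
.avogadro <- 6.02214076e23

#' Thomson scattering cross-section
#'
#' Low-energy limit of the Klein-Nishina total cross-section,
#' \eqn{(8\pi/3) r_e^2}.
#'
#' @return Cross-section per electron in cm^2.
#' @export
thomson_cross_section <- function() {
  8 * pi / 3 * .re_cm^2
}

#' Klein-Nishina total cross-section
#'
#' Total Compton-scattering cross-section per electron at photon energy E,
#' from the closed-form integral of the Klein-Nishina differential
#' cross-section over solid angle, with reduced energy
#' \eqn{\alpha = E / m_e c^2}.
#'
#' The closed form suffers catastrophic cancellation as \eqn{\alpha \to 0};
#' below 1 keV the series expansion
#' \eqn{\sigma_T (1 - 2\alpha + 26\alpha^2/5 - 133\alpha^3/10)} is used,
#' which agrees with the Thomson value to better than 0.1% in that range.
#'
#' @param energy_kev Photon energy in keV (vectorised, must be > 0).
#' @return Cross-section per electron in cm^2; strictly positive and strictly
#'   decreasing in energy.
#' @examples
#' klein_nishina_cross_section(100) / thomson_cross_section()
#' @export
klein_nishina_cross_section <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0)) {
    stop("`energy_kev` must be finite and > 0", call. = FALSE)
  }
  a <- energy_kev / .mec2_kev
  sig_t <- thomson_cross_section()
  out <- numeric(length(a))
  small <- a < (1 / .mec2_kev)  # below 1 keV
  if (any(small)) {
    s <- a[small]
    out[small] <- sig_t * (1 - 2 * s + 26 / 5 * s^2 - 133 / 10 * s^3)
  }
  if (any(!small)) {
    s <- a[!small]
    out[!small] <- 2 * pi * .re_cm^2 * (
      (1 + s) / s^2 * (2 * (1 + s) / (1 + 2 * s) - log1p(2 * s) / s) +
        log1p(2 * s) / (2 * s) - (1 + 3 * s) / (1 + 2 * s)^2
    )
  }
  out
}

# Default material constants. Effective Z drives the photoelectric Z^3 term;
# electron density rho * N_A * (Z/A) drives the Compton term. Marker
# compositions are not published by the vendor, so the table encodes what the
# devices physically are: pyrolytic carbon (rho ~ 2.2) and a radiopacified
# polymer (fillers raise Z_eff above tissue's 7.4 -- a plain rho ~ 1.2 polymer
# would be invisible on planar kV imaging). All values are overridable.
.default_materials <- function() {
  tibble::tibble(
    name         = c("gold", "carbon", "polymer", "soft_tissue", "air",
                     "aluminum"),
    z_eff        = c(79, 6, 8.5, 7.4, 7.64, 13),
    mass_density = c(19.3, 2.2, 1.50, 1.0, 1.205e-3, 2.699),
    z_a_ratio    = c(0.40108, 0.4995, 0.52, 0.55, 0.499, 0.4818)
  )
}

#' Material table
#'
#' Registered materials with the physical constants that drive the attenuation
#' model: effective atomic number (photoelectric \eqn{Z^3} term), mass density,
#' and electron density \eqn{\rho N_A (Z/A)} (Compton term). The default table
#' registers gold, carbon, polymer, soft_tissue, air, and aluminum (used for
#' tube filtration).
#'
#' @param overrides Optional data frame with column `name` plus any of
#'   `z_eff`, `mass_density`, `z_a_ratio` to replace defaults or add materials.
#' @return A tibble with columns `name`, `z_eff`, `mass_density`, `z_a_ratio`,
#'   `electron_density` (electrons/cm^3).
#' @examples
#' material_table()
#' material_table(data.frame(name = "steel", z_eff = 26,
#'                           mass_density = 7.9, z_a_ratio = 0.466))
#' @export
material_table <- function(overrides = NULL) {
  tab <- .default_materials()
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    if (!"name" %in% names(overrides)) {
      stop("`overrides` must have a `name` column", call. = FALSE)
    }
    for (i in seq_len(nrow(overrides))) {
      row <- overrides[i, ]
      j <- match(row$name, tab$name)
      if (is.na(j)) {
        need <- c("z_eff", "mass_density", "z_a_ratio")
        if (!all(need %in% names(row)) || anyNA(row[need])) {
          stop("new material '", row$name, "' needs z_eff, mass_density, ",
               "and z_a_ratio", call. = FALSE)
        }
        tab <- dplyr::bind_rows(tab, row[c("name", need)])
      } else {
        for (f in intersect(names(row), c("z_eff", "mass_density",
                                          "z_a_ratio"))) {
          if (!is.na(row[[f]])) tab[[f]][j] <- row[[f]]
        }
      }
    }
  }
  bad <- tab$z_eff < 1 | tab$mass_density <= 0 | tab$z_a_ratio <= 0
  if (any(bad)) {
    stop("unphysical material constants for: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  }
  tab$electron_density <- tab$mass_density * .avogadro * tab$z_a_ratio
  tab
}

.lookup_material <- function(material, materials) {
  i <- match(material, materials$name)
  if (anyNA(i)) {
    stop("unknown material(s): ",
         paste(unique(material[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

#' Photoelectric scale constant
#'
#' Scale of the \eqn{k_{pe} \, n_e Z^3 / E^3} photoelectric term, calibrated
#' once so that for soft tissue the photoelectric and Compton contributions are
#' equal at 26 keV. This pins the model's diagnostic-energy balance to
#' soft-tissue-like behaviour without external attenuation tables.
#'
#' @param materials Material table (for the soft-tissue effective Z).
#' @return Constant in cm^2 keV^3 per electron.
#' @export
k_pe_default <- function(materials = material_table()) {
  z <- materials$z_eff[.lookup_material("soft_tissue", materials)]
  klein_nishina_cross_section(26) * 26^3 / z^3
}

#' Linear attenuation coefficient
#'
#' Two-term model
#' \eqn{\mu(E) = n_e \sigma_{KN}(E) + k_{pe} n_e Z_{eff}^3 / E^3}:
#' Compton scattering proportional to electron density, photoelectric
#' absorption proportional to \eqn{Z^3/E^3}. Exponents are exactly 3 (the
#' simplest model consistent with the photoelectric energy/Z scaling that
#' drives high-Z marker contrast).
#'
#' @param material Material name (single string) registered in `materials`.
#' @param energy_kev Photon energy in keV (vectorised, > 0).
#' @param materials Material table, see [material_table()].
#' @param k_pe Photoelectric scale constant, see [k_pe_default()].
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @examples
#' attenuation_coefficient("gold", 60)
#' attenuation_coefficient("soft_tissue", c(40, 80, 120))
#' @export
attenuation_coefficient <- function(material, energy_kev,
                                    materials = material_table(),
                                    k_pe = k_pe_default(materials)) {
  stopifnot(length(material) == 1L)
  if (k_pe < 0) stop("`k_pe` must be >= 0", call. = FALSE)
  i <- .lookup_material(material, materials)
  ne <- materials$electron_density[i]
  z <- materials$z_eff[i]
  ne * (klein_nishina_cross_section(energy_kev) + k_pe * z^3 / energy_kev^3)
}

# mu(E) for several materials at once: rows = energies, cols = materials
.mu_matrix <- function(material_names, energy_kev, materials, k_pe) {
  out <- vapply(material_names, function(m) {
    attenuation_coefficient(m, energy_kev, materials, k_pe)
  }, numeric(length(energy_kev)))
  matrix(out, nrow = length(energy_kev),
         dimnames = list(NULL, material_names))
}
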