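#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sweep result
#'
#' @param x A `fid_sweep`.
#' @param ... Unused.
#' @return The per-sample tibble: one row per marker, grid value, and
#'   realization, with ROI statistics and CNR.
#' @export
tidy.fid_sweep <- function(x, ...) x$samples

#' One-row-per-cell summary of a sweep
#'
#' @param x A `fid_sweep`.
#' @param ... Unused.
#' @return Tibble of per (material, value) mean and SD of CNR, annotated
#'   with the sweep configuration.
#' @export
glance.fid_sweep <- function(x, ...) {
  dplyr::mutate(x$summary, modality = x$modality, axis = x$axis,
                n_realizations = x$n_realizations, base_seed = x$base_seed)
}

#' Tidy a ring profile
#'
#' @param x A `ring_profile`.
#' @param ... Unused.
#' @return Tibble with `radius_mm` and `sd`.
#' @export
tidy.ring_profile <- function(x, ...) {
  tibble::tibble(radius_mm = x$radius_mm, sd = x$sd)
}
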