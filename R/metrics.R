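# Marker visibility and artifact statistics.
#
# Two statistics summarise each marker: the contrast-to-noise ratio
# CNR = (S_max - mean(S_bg)) / sd(S_bg), with S_max the maximum intensity in
# a square profile around the marker (the most visible part of the marker),
# and the standard deviation of bilinearly interpolated pixel values along
# rings of increasing radius around the marker center (artifact profile).
# Sample SD (n - 1 denominator) is used throughout.

#' Locate a marker center at sub-pixel precision
#'
#' Intensity-weighted centroid of pixels brighter than
#' background mean + 3 background SD within a search disk; the background
#' statistics are taken over the disk itself. Falls back to `approx_center_mm`
#' when no pixel passes the threshold.
#'
#' @param image A `fid_image`.
#' @param approx_center_mm Starting guess (x, y) in mm; must lie inside the
#'   image.
#' @param search_radius_mm Radius of the search disk (> 0).
#' @return Numeric length-2 refined center (mm).
#' @export
detect_marker_center <- function(image, approx_center_mm,
                                 search_radius_mm = 5) {
  stopifnot(inherits(image, "fid_image"), search_radius_mm > 0)
  ax <- .image_axes(image)
  if (approx_center_mm[1] < min(ax$x) - image$spacing_mm[1] / 2 ||
      approx_center_mm[1] > max(ax$x) + image$spacing_mm[1] / 2 ||
      approx_center_mm[2] < min(ax$y) - image$spacing_mm[2] / 2 ||
      approx_center_mm[2] > max(ax$y) + image$spacing_mm[2] / 2) {
    stop("`approx_center_mm` lies outside the image", call. = FALSE)
  }
  dx <- outer(ax$x - approx_center_mm[1], rep(1, length(ax$y)))
  dy <- outer(rep(1, length(ax$x)), ax$y - approx_center_mm[2])
  in_disk <- dx^2 + dy^2 <= search_radius_mm^2
  if (!any(in_disk)) return(as.numeric(approx_center_mm))
  vals <- image$pixels[in_disk]
  thr <- mean(vals) + 3 * stats::sd(vals)
  hot <- in_disk & image$pixels > thr
  if (!any(hot)) return(as.numeric(approx_center_mm))
  w <- image$pixels[hot] - mean(vals)
  xs <- (dx + approx_center_mm[1])[hot]
  ys <- (dy + approx_center_mm[2])[hot]
  c(sum(w * xs) / sum(w), sum(w * ys) / sum(w))
}

#' ROI statistics around a marker
#'
#' Square profile of half-width `roi_half_width_mm` centered on the marker,
#' clipped to the image. `s_max` is the maximum over the full profile;
#' background mean and SD are computed over profile pixels farther than
#' `exclusion_radius_mm` from the center, so the marker and its near-field
#' artifact do not inflate the noise estimate (set the exclusion to 0 for a
#' literal whole-profile reading).
#'
#' @param image A `fid_image`.
#' @param center_mm Marker center (x, y) in mm.
#' @param roi_half_width_mm Profile half-width; default 75 (a 15 x 15 cm
#'   square).
#' @param exclusion_radius_mm Radius of the central disk excluded from
#'   background statistics; default 7.5 covers the artifact range probed by
#'   the ring profile.
#' @return One-row tibble: `s_max`, `s_bg_mean`, `s_bg_sd`, `n_bg`.
#' @export
roi_stats <- function(image, center_mm, roi_half_width_mm = 75,
                      exclusion_radius_mm = 7.5) {
  stopifnot(inherits(image, "fid_image"))
  ax <- .image_axes(image)
  ix <- which(abs(ax$x - center_mm[1]) <= roi_half_width_mm)
  iy <- which(abs(ax$y - center_mm[2]) <= roi_half_width_mm)
  if (length(ix) * length(iy) < 100) {
    stop("ROI clipped to the image retains fewer than 100 pixels",
         call. = FALSE)
  }
  roi <- image$pixels[ix, iy, drop = FALSE]
  r2 <- outer((ax$x[ix] - center_mm[1])^2, rep(1, length(iy))) +
    outer(rep(1, length(ix)), (ax$y[iy] - center_mm[2])^2)
  bg <- roi[r2 > exclusion_radius_mm^2]
  if (length(bg) < 2) stop("degenerate ROI: no background pixels",
                           call. = FALSE)
  tibble::tibble(s_max = max(roi), s_bg_mean = mean(bg),
                 s_bg_sd = stats::sd(bg), n_bg = length(bg))
}

#' Contrast-to-noise ratio
#'
#' \eqn{CNR = (S_{max} - \bar{S}_{bg}) / \sigma_{bg}}; invariant under
#' affine intensity maps \eqn{x \mapsto ax + b} with \eqn{a > 0}.
#'
#' @param stats A one-row tibble from [roi_stats()] (or any list with
#'   `s_max`, `s_bg_mean`, `s_bg_sd`).
#' @return Dimensionless CNR.
#' @export
compute_cnr <- function(stats) {
  if (stats$s_bg_sd <= 0) {
    stop("background SD is zero: CNR is undefined on a noise-free image ",
         "(enable noise in the simulation)", call. = FALSE)
  }
  as.numeric((stats$s_max - stats$s_bg_mean) / stats$s_bg_sd)
}

#' Ring artifact profile
#'
#' Standard deviation of pixel values along rings of increasing radius around
#' a marker: `n_rings` radii uniformly spaced from `r_min_mm` to `r_max_mm`
#' inclusive; each ring is sampled at `n_angular` equally spaced angles with
#' bilinear interpolation. Defaults mirror the study protocol: one thousand
#' rings from 1 to 15 mm.
#'
#' @param image A `fid_image`.
#' @param center_mm Ring center (x, y) in mm.
#' @param r_min_mm,r_max_mm Radius range (mm).
#' @param n_rings Number of rings (>= 2).
#' @param n_angular Angular samples per ring (default 720, i.e. 0.5
#'   degrees).
#' @return A `ring_profile` tibble with columns `radius_mm`, `sd`; the
#'   center is stored as an attribute. Errors if any ring leaves the image,
#'   naming the first offending radius.
#' @export
ring_artifact_profile <- function(image, center_mm, r_min_mm = 1,
                                  r_max_mm = 15, n_rings = 1000,
                                  n_angular = 720) {
  stopifnot(inherits(image, "fid_image"), n_rings >= 2, n_angular >= 4,
            r_min_mm > 0, r_max_mm > r_min_mm)
  ax <- .image_axes(image)
  margin <- c(center_mm[1] - min(ax$x), max(ax$x) - center_mm[1],
              center_mm[2] - min(ax$y), max(ax$y) - center_mm[2])
  if (min(margin) < r_max_mm) {
    first_bad <- min(margin)
    stop(sprintf("rings with radius > %.3f mm exit the image (r_max = %g)",
                 first_bad, r_max_mm), call. = FALSE)
  }
  radii <- seq(r_min_mm, r_max_mm, length.out = n_rings)
  th <- (seq_len(n_angular) - 1) * 2 * pi / n_angular
  ct <- cos(th); st <- sin(th)
  sds <- vapply(radii, function(r) {
    stats::sd(.bilinear(image, center_mm[1] + r * ct,
                        center_mm[2] + r * st, "ring sample"))
  }, numeric(1))
  out <- tibble::tibble(radius_mm = radii, sd = sds)
  structure(out, center_mm = as.numeric(center_mm),
            units = image$units,
            class = c("ring_profile", class(out)))
}

#' Scalar artifact index
#'
#' Mean of the per-ring SDs of a [ring_artifact_profile()]; zero iff every
#' ring SD is zero. Used to compare artifact burden across materials and
#' modalities.
#'
#' @param profile A `ring_profile`.
#' @return Dimensionless scalar (same units as the image intensity).
#' @export
artifact_index <- function(profile) {
  stopifnot(inherits(profile, "ring_profile"))
  mean(profile$sd)
}

#' Analyze markers in an image
#'
#' Full per-marker assessment: refine each approximate center, compute ROI
#' statistics and CNR, and (optionally) the ring artifact profile. This is
#' the composition used by the sweep driver and the command-line `analyze`
#' entry point.
#'
#' @param image A `fid_image`.
#' @param centers_mm Matrix or data frame of approximate centers, columns
#'   x/y in mm; row names or a `marker_id` column label the markers.
#' @param roi_half_width_mm,exclusion_radius_mm Passed to [roi_stats()].
#' @param search_radius_mm Passed to [detect_marker_center()].
#' @param rings Compute ring profiles as well?
#' @param ring_args List of arguments for [ring_artifact_profile()].
#' @return List with `cnr` (tibble: marker_id, center coordinates, ROI
#'   statistics, cnr) and `rings` (tibble: marker_id, radius_mm, sd; `NULL`
#'   unless `rings = TRUE`).
#' @export
analyze_markers <- function(image, centers_mm, roi_half_width_mm = 75,
                            exclusion_radius_mm = 7.5, search_radius_mm = 5,
                            rings = FALSE, ring_args = list()) {
  stopifnot(inherits(image, "fid_image"))
  centers_mm <- as.data.frame(centers_mm)
  if (nrow(centers_mm) == 0) stop("no marker centers supplied",
                                  call. = FALSE)
  if (!all(c("x", "y") %in% names(centers_mm))) {
    names(centers_mm)[1:2] <- c("x", "y")
  }
  ids <- centers_mm$marker_id %||% rownames(centers_mm)
  rows <- purrr::map_dfr(seq_len(nrow(centers_mm)), function(i) {
    ctr <- detect_marker_center(image,
                                c(centers_mm$x[i], centers_mm$y[i]),
                                search_radius_mm)
    st <- roi_stats(image, ctr, roi_half_width_mm, exclusion_radius_mm)
    tibble::tibble(marker_id = ids[i], x_mm = ctr[1], y_mm = ctr[2],
                   !!!st, cnr = compute_cnr(st))
  })
  ring_tbl <- NULL
  if (rings) {
    ring_tbl <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      pr <- do.call(ring_artifact_profile,
                    c(list(image, c(rows$x_mm[i], rows$y_mm[i])), ring_args))
      dplyr::mutate(tibble::as_tibble(pr), marker_id = rows$marker_id[i],
                    .before = 1)
    })
  }
  list(cnr = rows, rings = ring_tbl)
}
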