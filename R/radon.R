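# Parallel-beam projection and filtered back-projection.
#
# Geometry: rays at angle theta (degrees) have direction
# (-sin(theta), cos(theta)) and are indexed by signed offset s along
# (cos(theta), sin(theta)) from the rotation center. Detector bins are
# uniform in s and centered on s = 0.

.deg2rad <- function(d) d * pi / 180

# Deposit weighted points into detector bins with linear interpolation
# (pixel-driven projection). pts_t: signed offsets; w: deposited value per
# point; returns a length-nbins vector.
.bin_deposit <- function(pts_t, w, nbins, ds) {
  u <- pts_t / ds + (nbins + 1) / 2
  i0 <- floor(u)
  f <- u - i0
  idx <- c(i0, i0 + 1)
  val <- c(w * (1 - f), w * f)
  keep <- idx >= 1 & idx <= nbins
  idx <- idx[keep]; val <- val[keep]
  out <- numeric(nbins)
  if (length(idx)) {
    agg <- rowsum(val, idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Forward sinogram
#'
#' Parallel-beam projection of an attenuation map. With a monochromatic input
#' (a single matrix of linear attenuation coefficients) this is the classical
#' Radon transform \eqn{\int \mu \, dl}. With per-energy maps and a spectrum,
#' each sinogram entry is \eqn{-\ln} of the polychromatic transmission along
#' the ray, which is what a real (monochromatic-assumption) reconstruction
#' receives and is the origin of beam-hardening artifact.
#'
#' @param mu Either a numeric matrix of attenuation values (1/cm), or for
#'   polychromatic projection a list with elements `basis` (list of matrices
#'   of per-pixel partial occupancy in \[0,1\], one per material component)
#'   and `mu_energy` (matrix of attenuation values, spectrum bins in rows,
#'   one column per basis component).
#' @param angles_deg Projection angles in degrees (at least 2 for tomography;
#'   a single angle is allowed for testing).
#' @param pixel_mm Pixel size of `mu`.
#' @param spectrum Required for the polychromatic form.
#' @param detector_bin_mm Detector bin width; defaults to `pixel_mm`.
#' @return A `fid_sinogram`: list with `p` (bins x angles matrix of line
#'   integrals / -log transmissions), `s_mm`, `angles_deg`,
#'   `detector_bin_mm`.
#' @export
forward_sinogram <- function(mu, angles_deg, pixel_mm, spectrum = NULL,
                             detector_bin_mm = pixel_mm) {
  if (length(angles_deg) < 1L) stop("empty angle list", call. = FALSE)
  poly <- is.list(mu) && !is.null(mu$basis)
  maps <- if (poly) mu$basis else list(mu)
  dims <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), dims))
  if (poly) {
    .assert_spectrum(spectrum)
    stopifnot(ncol(mu$mu_energy) == length(maps),
              nrow(mu$mu_energy) == nrow(spectrum))
  }
  nx <- dims[1]; ny <- dims[2]
  ds <- detector_bin_mm
  diag_mm <- sqrt(sum((dims * pixel_mm)^2))
  nbins <- 2 * ceiling(diag_mm / (2 * ds)) + 3
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_mm
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_mm
  # 2x2 sub-pixel sampling suppresses the angular aliasing of pixel-driven
  # projection at oblique angles
  off <- c(-0.25, 0.25) * pixel_mm
  px <- as.vector(outer(rep(xs, times = ny), rep(off, each = 2), "+"))
  py <- as.vector(outer(rep(ys, each = nx), rep(off, times = 2), "+"))
  # path length represented by one sub-pixel sample deposited over a bin
  wlen <- pixel_mm^2 / 4 / ds / 10   # cm
  p <- matrix(0, nbins, length(angles_deg))
  v <- if (poly) .detector_weights(spectrum) else NULL
  for (k in seq_along(angles_deg)) {
    th <- .deg2rad(angles_deg[k])
    tt <- px * cos(th) + py * sin(th)
    if (poly) {
      paths <- vapply(maps, function(m) {
        .bin_deposit(tt, rep(as.vector(m), 4) * wlen, nbins, ds)
      }, numeric(nbins))                       # nbins x nbasis, cm
      trans <- exp(-paths %*% t(mu$mu_energy)) %*% v
      p[, k] <- -log(pmax(trans, .Machine$double.xmin))
    } else {
      p[, k] <- .bin_deposit(tt, rep(as.vector(maps[[1]]), 4) * wlen,
                             nbins, ds)
    }
  }
  if (!all(is.finite(p))) stop("non-finite sinogram entries", call. = FALSE)
  structure(list(p = p, s_mm = (seq_len(nbins) - (nbins + 1) / 2) * ds,
                 angles_deg = angles_deg, detector_bin_mm = ds),
            class = "fid_sinogram")
}

# Ramp-filter a bins x views sinogram matrix (no apodization), using the
# band-limited Ram-Lak kernel assembled in the spatial domain (the pure
# frequency-domain |f| filter loses the DC term and biases the interior of
# large objects low). Returns filtered projections ready for backprojection
# with mu = (pi / n_views) * sum_k q_k.
.ramp_filter <- function(p, ds) {
  nbins <- nrow(p)
  npad <- 2^ceiling(log2(2 * nbins))
  pp <- rbind(p, matrix(0, npad - nbins, ncol(p)))
  h <- numeric(npad)
  h[1] <- 1 / (4 * ds^2)
  n_odd <- seq(1, npad / 2, by = 2)
  h[1 + n_odd] <- -1 / (pi^2 * n_odd^2 * ds^2)
  h[npad + 1 - n_odd] <- -1 / (pi^2 * n_odd^2 * ds^2)
  hf <- Re(stats::fft(h))
  q <- Re(stats::mvfft(stats::mvfft(pp) * hf, inverse = TRUE)) / npad * ds
  q[seq_len(nbins), , drop = FALSE]
}

# Backproject filtered projections at physical points (x, y in mm relative
# to rotation center). q: nbins x nviews; returns values at points.
.backproject_points <- function(q, angles_deg, ds, x, y) {
  nbins <- nrow(q)
  acc <- numeric(length(x))
  for (k in seq_along(angles_deg)) {
    th <- .deg2rad(angles_deg[k])
    u <- (x * cos(th) + y * sin(th)) / ds + (nbins + 1) / 2
    i0 <- pmin(pmax(floor(u), 1L), nbins - 1L)
    f <- pmin(pmax(u - i0, 0), 1)
    col <- q[, k]
    acc <- acc + col[i0] * (1 - f) + col[i0 + 1] * f
  }
  acc * pi / length(angles_deg)
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered (no apodization) back-projection with linear interpolation,
#' a linear operator in the sinogram. Reconstructing the analytic sinogram of
#' a uniform disk recovers its attenuation value at the center to within a
#' few percent for a few hundred views.
#'
#' @param sinogram A `fid_sinogram`, or a bins x angles matrix.
#' @param angles_deg Projection angles (required if `sinogram` is a matrix).
#' @param detector_bin_mm Bin width (required if `sinogram` is a matrix).
#' @param n Output image size in pixels (n x n).
#' @param pixel_mm Output pixel size; defaults to the detector bin width.
#' @param center_mm Offset of the reconstruction-grid center from the
#'   rotation center, length 2 (mm). Reconstructing a small grid away from
#'   the iso-center gives a region-of-interest view.
#' @return A numeric n x n matrix of reconstructed attenuation (1/cm for a
#'   sinogram in line-integral units with lengths in cm).
#' @export
fbp_reconstruct <- function(sinogram, angles_deg = NULL,
                            detector_bin_mm = NULL, n = NULL,
                            pixel_mm = NULL, center_mm = c(0, 0)) {
  if (inherits(sinogram, "fid_sinogram")) {
    angles_deg <- sinogram$angles_deg
    detector_bin_mm <- sinogram$detector_bin_mm
    p <- sinogram$p
  } else {
    p <- as.matrix(sinogram)
    if (is.null(angles_deg) || is.null(detector_bin_mm)) {
      stop("matrix input needs `angles_deg` and `detector_bin_mm`",
           call. = FALSE)
    }
  }
  if (anyNA(p) || !all(is.finite(p))) {
    stop("sinogram contains NaN or non-finite values", call. = FALSE)
  }
  if (is.null(n)) n <- nrow(p)
  if (is.null(pixel_mm)) pixel_mm <- detector_bin_mm
  q <- .ramp_filter(p, detector_bin_mm)
  g <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  x <- rep(g, times = n) + center_mm[1]
  y <- rep(g, each = n) + center_mm[2]
  # filtered projections are per-mm; path lengths were in cm
  matrix(.backproject_points(q, angles_deg, detector_bin_mm, x, y) * 10,
         n, n)
}
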