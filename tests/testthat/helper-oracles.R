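# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately re-derive every quantity from first principles
# (explicit loops over pixels / sample points), independent of the package's
# vectorised implementations.

# small random image with physical metadata
random_image <- function(nx = 32, ny = 32, spacing = 1, seed = 1,
                         units = "HU") {
  set.seed(seed)
  image2d(matrix(rnorm(nx * ny), nx, ny), spacing, units = units)
}

# a small phantom that keeps simulations fast: 6 x 6 x 4 cm with one marker
tiny_phantom <- function(material = "gold", diameter = 0.9, length = 3,
                         center = c(30, 30, 20), axis = c(0, 0, 1)) {
  phantom_spec(extent_cm = c(6, 6, 4), layer_thickness_cm = 2,
               markers = marker_spec(material, diameter, length, center,
                                     axis))
}

fast_ct_protocol <- function(kvp = 120, slice = 1.25, seed = 1, ...) {
  imaging_protocol("ct", kvp = kvp, slice_thickness_mm = slice,
                   n_views = 180, detector_bin_mm = 0.5, seed = seed, ...)
}

# brute-force ROI statistics: explicit pixel loop
oracle_roi_stats <- function(img, center, half_width, excl) {
  nx <- nrow(img$pixels); ny <- ncol(img$pixels)
  vals_all <- c(); vals_bg <- c()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      x <- img$origin_mm[1] + (i - 0.5) * img$spacing_mm[1]
      y <- img$origin_mm[2] + (j - 0.5) * img$spacing_mm[2]
      if (abs(x - center[1]) <= half_width &&
          abs(y - center[2]) <= half_width) {
        vals_all <- c(vals_all, img$pixels[i, j])
        if ((x - center[1])^2 + (y - center[2])^2 > excl^2) {
          vals_bg <- c(vals_bg, img$pixels[i, j])
        }
      }
    }
  }
  list(s_max = max(vals_all), s_bg_mean = mean(vals_bg),
       s_bg_sd = sd(vals_bg), n_bg = length(vals_bg))
}

# brute-force bilinear interpolation at one physical point
oracle_bilinear <- function(img, x, y) {
  u <- (x - img$origin_mm[1]) / img$spacing_mm[1] - 0.5
  v <- (y - img$origin_mm[2]) / img$spacing_mm[2] - 0.5
  i0 <- floor(u); j0 <- floor(v)
  i0 <- min(max(i0, 0), nrow(img$pixels) - 2)
  j0 <- min(max(j0, 0), ncol(img$pixels) - 2)
  fu <- u - i0; fv <- v - j0
  p <- img$pixels
  p[i0 + 1, j0 + 1] * (1 - fu) * (1 - fv) +
    p[i0 + 2, j0 + 1] * fu * (1 - fv) +
    p[i0 + 1, j0 + 2] * (1 - fu) * fv +
    p[i0 + 2, j0 + 2] * fu * fv
}

# brute-force ring SD: explicit loop over angular samples
oracle_ring_sd <- function(img, center, r, n_angular) {
  vals <- numeric(n_angular)
  for (k in seq_len(n_angular)) {
    th <- (k - 1) * 2 * pi / n_angular
    vals[k] <- oracle_bilinear(img, center[1] + r * cos(th),
                               center[2] + r * sin(th))
  }
  sd(vals)
}

# brute-force thresholded centroid
oracle_centroid <- function(img, approx, radius) {
  nx <- nrow(img$pixels); ny <- ncol(img$pixels)
  xs <- img$origin_mm[1] + (seq_len(nx) - 0.5) * img$spacing_mm[1]
  ys <- img$origin_mm[2] + (seq_len(ny) - 0.5) * img$spacing_mm[2]
  vals <- c(); px <- c(); py <- c()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if ((xs[i] - approx[1])^2 + (ys[j] - approx[2])^2 <= radius^2) {
      vals <- c(vals, img$pixels[i, j]); px <- c(px, xs[i]); py <- c(py, ys[j])
    }
  }
  thr <- mean(vals) + 3 * sd(vals)
  hot <- vals > thr
  if (!any(hot)) return(approx)
  w <- vals[hot] - mean(vals)
  c(sum(w * px[hot]) / sum(w), sum(w * py[hot]) / sum(w))
}

# numerical quadrature of the differential Klein-Nishina cross-section over
# solid angle (independent oracle for the closed form)
oracle_kn_quadrature <- function(energy_kev) {
  re <- 2.8179403262e-13
  a <- energy_kev / 510.99895
  f <- function(theta) {
    r <- 1 / (1 + a * (1 - cos(theta)))
    dcs <- 0.5 * re^2 * r^2 * (r + 1 / r - sin(theta)^2)
    dcs * 2 * pi * sin(theta)
  }
  integrate(f, 0, pi, rel.tol = 1e-10)$value
}

# minimal explicit-VR little-endian DICOM writer, crafted byte by byte
# (independent of the package's reader)
craft_dicom <- function(path, pixels, spacing = c(0.5, 0.5), slope = 2,
                        intercept = -1000) {
  # pixels: matrix [x, y]; stored row-major from the top row (x fastest,
  # largest y first)
  rows <- ncol(pixels); cols <- nrow(pixels)
  raw_vals <- as.integer(pixels[, rev(seq_len(rows))])
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  elem_short <- function(group, el, vr, value_raw) {
    u16(group); u16(el)
    writeBin(charToRaw(vr), con)
    u16(length(value_raw))
    writeBin(value_raw, con)
  }
  elem_ow <- function(group, el, value_raw) {
    u16(group); u16(el)
    writeBin(charToRaw("OW"), con); u16(0)
    writeBin(as.integer(length(value_raw)), con, size = 4,
             endian = "little")
    writeBin(value_raw, con)
  }
  us_raw <- function(x) {
    r <- raw(2); r[1] <- as.raw(x %% 256); r[2] <- as.raw(x %/% 256); r
  }
  ds_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  elem_short(0x0028, 0x0010, "US", us_raw(rows))
  elem_short(0x0028, 0x0011, "US", us_raw(cols))
  elem_short(0x0028, 0x0030, "DS",
             ds_raw(sprintf("%g\\%g", spacing[2], spacing[1])))
  elem_short(0x0028, 0x0100, "US", us_raw(16))
  elem_short(0x0028, 0x0103, "US", us_raw(0))
  elem_short(0x0028, 0x1052, "DS", ds_raw(format(intercept)))
  elem_short(0x0028, 0x1053, "DS", ds_raw(format(slope)))
  px_raw <- writeBin(raw_vals, raw(), size = 2, endian = "little")
  elem_ow(0x7fe0, 0x0010, px_raw)
  invisible(path)
}
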