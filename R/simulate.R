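# Forward simulation of planar radiographs and CT slices.
#
# The CT path is built for speed without losing the physics that matters:
# the uniform phantom background is projected analytically (ray-rectangle
# intersection), markers are projected from fine sub-voxel samples of their
# cross-sections, and the polychromatic Beer-Lambert sum is evaluated
# exactly on marker-affected rays and via a fine lookup table on
# background-only rays. Beam hardening, photon starvation, partial volume,
# and Poisson noise all emerge from this model rather than being painted on.

# Poisson noise by inversion of a uniform stream. Unlike rejection-based
# sampling, inversion keeps the underlying uniform draws aligned between
# simulations that share a seed but differ in mean signal, so sweeps run
# under common random numbers: parameter trends difference out the shared
# quantum noise instead of being buried in it.
.poisson_inversion <- function(mean_sig) {
  stats::qpois(stats::runif(length(mean_sig)), as.vector(mean_sig))
}

# Path length (mm) of rays (offset s, angle th) through the rectangle
# [0, ex] x [0, ey]; iso is the rotation center.
.ray_rect_length <- function(s, th, extent_xy, iso) {
  ox <- iso[1] + s * cos(th); oy <- iso[2] + s * sin(th)
  vx <- -sin(th); vy <- cos(th)
  tmin <- rep(-Inf, length(s)); tmax <- rep(Inf, length(s))
  clip <- function(o, v, lo, hi, tmin, tmax) {
    if (abs(v) < 1e-12) {
      out <- o < lo | o > hi
      tmin[out] <- Inf
    } else {
      t1 <- (lo - o) / v; t2 <- (hi - o) / v
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
    list(tmin = tmin, tmax = tmax)
  }
  cl <- clip(ox, vx, 0, extent_xy[1], tmin, tmax)
  cl <- clip(oy, vy, 0, extent_xy[2], cl$tmin, cl$tmax)
  pmax(0, cl$tmax - cl$tmin)
}

# Fine in-plane sample points of a marker's cross-section at height z (mm).
# Returns NULL when the plane misses the marker.
.marker_plane_points <- function(marker, z) {
  g <- min(0.1, marker$diameter_mm / 9)
  half <- (max(marker$diameter_mm, marker$length_mm) + g) / 2
  xs <- seq(marker$x_mm - half, marker$x_mm + half, by = g)
  ys <- seq(marker$y_mm - half, marker$y_mm + half, by = g)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z)
  keep <- .in_cylinder(pts, marker)
  if (!any(keep)) return(NULL)
  list(x = pts[keep, 1], y = pts[keep, 2], area = g^2)
}

# Distinct sub-slice geometries (markers cut by each sub-plane), with
# multiplicities. Geometry is z-invariant for markers aligned with +z, which
# collapses most sub-slices onto one representative.
.slice_geometries <- function(phantom, z_positions) {
  mk <- phantom$markers
  keys <- vapply(z_positions, function(z) {
    parts <- vapply(seq_len(nrow(mk)), function(i) {
      m <- mk[i, ]
      dz <- abs(z - m$z_mm)
      axial <- abs(m$az) > 1 - 1e-9
      hit <- if (axial) dz <= m$length_mm / 2 else TRUE
      if (!hit) "-" else if (axial) "z" else sprintf("%.4f", z)
    }, character(1))
    paste(parts, collapse = "|")
  }, character(1))
  split_idx <- split(seq_along(z_positions), keys)
  lapply(split_idx, function(ii) {
    list(z = z_positions[ii[1]], weight = length(ii))
  })
}

# Core CT slice engine: returns list of HU images, one per requested FOV.
.simulate_ct_multifov <- function(phantom, protocol, z_center_mm, fovs,
                                  noise = TRUE, materials = material_table(),
                                  k_pe = k_pe_default(materials),
                                  bin_width_kev = 1) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(protocol, "imaging_protocol"))
  if (!protocol$modality %in% c("ct", "cbct", "mvct")) {
    stop("protocol modality must be ct, cbct, or mvct", call. = FALSE)
  }
  ext <- phantom$extent_mm
  if (z_center_mm < 0 || z_center_mm > ext[3]) {
    stop("z_center_mm outside the phantom", call. = FALSE)
  }
  spec <- protocol_spectrum(protocol, bin_width_kev, materials, k_pe)
  v <- .detector_weights(spec)
  t_mm <- protocol$slice_thickness_mm
  iso <- ext[1:2] / 2
  ds <- protocol$detector_bin_mm
  half_diag <- sqrt(sum(ext[1:2]^2)) / 2
  nbins <- 2 * ceiling(half_diag / ds) + 3
  nv <- protocol$n_views
  th <- (seq_len(nv) - 0.5) * pi / nv
  svec <- (seq_len(nbins) - (nbins + 1) / 2) * ds

  mat_names <- unique(c(phantom$background_material,
                        phantom$markers$material))
  mu_e <- .mu_matrix(mat_names, spec$energy_kev, materials, k_pe) # nE x nmat
  bg_col <- 1L
  tab <- .transmission_table(phantom$background_material, spec, materials,
                             k_pe, l_max_mm = 2 * half_diag + 10)

  # distinct sub-slice geometries with fine marker sample points
  zs <- z_center_mm + .sub_slice_offsets(t_mm)
  geoms <- .slice_geometries(phantom, zs)
  n_sub <- length(zs)
  geom_pts <- lapply(geoms, function(g) {
    mk <- phantom$markers
    if (nrow(mk) == 0) return(NULL)
    out <- purrr::map_dfr(seq_len(nrow(mk)), function(i) {
      pp <- .marker_plane_points(mk[i, ], g$z)
      if (is.null(pp)) return(NULL)
      tibble::tibble(x = pp$x - iso[1], y = pp$y - iso[2],
                     w = pp$area / ds,
                     mat = match(mk$material[i], mat_names))
    })
    if (nrow(out) == 0) NULL else out
  })

  # transmission sinogram, sub-slice averaged
  tbar <- matrix(0, nbins, nv)
  for (k in seq_len(nv)) {
    lbg <- .ray_rect_length(svec, th[k], ext[1:2], iso)
    t_bg <- tab$fun(lbg)
    trow <- t_bg * n_sub
    for (gi in seq_along(geoms)) {
      gp <- geom_pts[[gi]]
      wgt <- geoms[[gi]]$weight
      if (is.null(gp)) next
      tt <- gp$x * cos(th[k]) + gp$y * sin(th[k])
      u <- tt / ds + (nbins + 1) / 2
      i0 <- floor(u); fr <- u - i0
      idx <- c(i0, i0 + 1L)
      val <- c(gp$w * (1 - fr), gp$w * fr)
      mats <- c(gp$mat, gp$mat)
      keep <- idx >= 1 & idx <= nbins
      key <- (mats[keep] - 1L) * nbins + idx[keep]
      agg <- rowsum(val[keep], key)
      kk <- as.integer(rownames(agg))
      aff_bin <- unique((kk - 1L) %% nbins + 1L)
      lm <- matrix(0, length(aff_bin), length(mat_names))
      lm[cbind(match((kk - 1L) %% nbins + 1L, aff_bin),
               (kk - 1L) %/% nbins + 1L)] <- agg[, 1]
      lm[, bg_col] <- pmax(lbg[aff_bin] - rowSums(lm), 0)
      t_aff <- as.vector(exp(-(lm / 10) %*% t(mu_e)) %*% v)
      trow[aff_bin] <- trow[aff_bin] + wgt * (t_aff - t_bg[aff_bin])
    }
    tbar[, k] <- trow / n_sub
  }

  # exposure: incident counts per ray
  l_ref <- mean(ext[1:2])
  t_ref <- tab$fun(l_ref)
  n0 <- if (protocol$modality %in% c("ct", "cbct") &&
            !is.null(protocol$mas)) {
    .fid_budgets$kv_planar_counts_at_200mas * (protocol$mas / 200) *
      (t_mm / 2.5)
  } else if (protocol$modality == "mvct") {
    protocol$counts_ref / t_ref
  } else {
    # auto-exposure: detected budget scales with sqrt(thickness) -- thin
    # slices get a tube-current boost that partially offsets fluence loss,
    # as clinical protocols do
    protocol$counts_ref * sqrt(t_mm / 2.5) / t_ref
  }
  sf <- protocol$scatter_fraction
  mean_sig <- n0 * (tbar + sf * t_ref)
  counts <- if (noise) {
    .with_seed(protocol$seed,
               matrix(.poisson_inversion(mean_sig), nbins, nv))
  } else mean_sig
  p <- -log(pmax(counts, 0.5) / n0)

  # water-equivalent beam-hardening precorrection: map each measured -log
  # transmission to the monochromatic equivalent of the background material
  # at the effective energy. This linearizes the uniform background exactly
  # (as clinical water corrections do); high-Z markers violate the water
  # assumption, and that residual is what produces their streaks.
  mu_w <- attenuation_coefficient(phantom$background_material,
                                  effective_energy(spec), materials, k_pe)
  bhc <- .transmission_table(phantom$background_material, spec, materials,
                             k_pe, l_max_mm = 2000, n = 2001)
  p_of_l <- -log(pmax(bhc$tvals, .Machine$double.xmin))
  p[] <- stats::approx(p_of_l, bhc$grid, xout = as.vector(p),
                       rule = 2)$y * mu_w / 10

  # reconstruction under the monochromatic assumption
  q <- .ramp_filter(p, ds)
  lapply(fovs, function(fv) {
    n <- fv$n
    g <- (seq_len(n) - (n + 1) / 2) * fv$pixel_mm
    x <- rep(g, times = n) + fv$center_mm[1] - iso[1]
    y <- rep(g, each = n) + fv$center_mm[2] - iso[2]
    mu_hat <- matrix(.backproject_points(q, th / pi * 180, ds, x, y) * 10,
                     n, n)
    hu <- 1000 * (mu_hat - mu_w) / mu_w
    image2d(hu, fv$pixel_mm, units = "HU",
            origin_mm = fv$center_mm - n * fv$pixel_mm / 2,
            protocol = protocol, seed = protocol$seed)
  })
}

#' Simulate a CT slice
#'
#' Polychromatic parallel-beam acquisition of one axial slice of the phantom,
#' reconstructed by filtered back-projection under the monochromatic
#' assumption and calibrated to Hounsfield units at the spectrum's effective
#' energy. Partial volume across the slice thickness is modelled by
#' averaging the detector fluence of sub-slice samples (step ~0.1 mm, odd
#' count, capped at 51); quantum noise is Poisson on detected counts, with
#' counts floored at 0.5 (detector floor -- rays through gold starve).
#'
#' Exposure: protocols that state an explicit `mas` use an incident budget of
#' 1e5 counts/ray at 200 mAs and 2.5 mm, scaled by mAs and slice thickness;
#' otherwise an auto-exposure model holds detected counts behind the phantom
#' at the modality's reference budget, scaled by slice thickness (CT/CBCT).
#' CBCT adds a flat scatter fraction (default 20%) to every ray.
#'
#' @param phantom A [phantom_spec()].
#' @param protocol An [imaging_protocol()] with a 3D modality.
#' @param z_center_mm Slice center along z; defaults to the phantom center.
#' @param fov_center_mm Center of the reconstructed field of view (x, y mm);
#'   defaults to the phantom center.
#' @param fov_n Reconstruction grid size (pixels).
#' @param noise Apply Poisson noise (seeded from the protocol seed)?
#' @param materials,k_pe Physics configuration.
#' @param bin_width_kev Spectrum bin width.
#' @return A `fid_image` in HU.
#' @examples
#' \donttest{
#' ph <- default_phantom()
#' pr <- imaging_protocol("ct", kvp = 120, slice_thickness_mm = 1.25,
#'                        n_views = 360, detector_bin_mm = 0.5, seed = 7)
#' img <- simulate_ct_slice(ph, pr, fov_center_mm = c(150, 105), fov_n = 128)
#' }
#' @export
simulate_ct_slice <- function(phantom, protocol, z_center_mm = NULL,
                              fov_center_mm = NULL, fov_n = 128,
                              noise = TRUE, materials = material_table(),
                              k_pe = k_pe_default(materials),
                              bin_width_kev = 1) {
  if (is.null(z_center_mm)) z_center_mm <- phantom$extent_mm[3] / 2
  if (is.null(fov_center_mm)) fov_center_mm <- phantom$extent_mm[1:2] / 2
  .simulate_ct_multifov(phantom, protocol, z_center_mm,
                        list(list(center_mm = fov_center_mm, n = fov_n,
                                  pixel_mm = protocol$pixel_spacing_mm)),
                        noise, materials, k_pe, bin_width_kev)[[1]]
}

# Path length (mm) along +z through a cylinder, for rays at (x, y).
# Closed form from the quadratic radial-distance condition, clipped to the
# axial extent.
.z_path_through_cylinder <- function(x, y, marker) {
  ax <- c(marker$ax, marker$ay, marker$az)
  wx <- x - marker$x_mm; wy <- y - marker$y_mm; wz <- -marker$z_mm
  wa <- wx * ax[1] + wy * ax[2] + wz * ax[3]
  # squared radial distance of p(z) = (x, y, z) from the axis is quadratic:
  # A z^2 + 2 B z + C + r^2, roots bound the in-cylinder interval
  A <- 1 - ax[3]^2
  B <- wz - wa * ax[3]
  C <- wx^2 + wy^2 + wz^2 - wa^2 - (marker$diameter_mm / 2)^2
  r <- numeric(length(x))
  if (A < 1e-12) {
    # axis parallel to z: radial distance independent of z
    inside <- C <= 0
    r[inside] <- marker$length_mm
    return(r)
  }
  disc <- B^2 - A * C
  ok <- disc > 0
  if (!any(ok)) return(r)
  sq <- sqrt(disc[ok])
  z1 <- (-B[ok] - sq) / A
  z2 <- (-B[ok] + sq) / A
  # axial clip: |wa + z az| <= L/2
  if (abs(ax[3]) > 1e-12) {
    za <- (-marker$length_mm / 2 - wa[ok]) / ax[3]
    zb <- (marker$length_mm / 2 - wa[ok]) / ax[3]
    lo <- pmin(za, zb); hi <- pmax(za, zb)
    z1 <- pmax(z1, lo); z2 <- pmin(z2, hi)
  } else if (any(abs(wa[ok]) > marker$length_mm / 2)) {
    bad <- abs(wa[ok]) > marker$length_mm / 2
    z2[bad] <- z1[bad]
  }
  r[ok] <- pmax(0, z2 - z1)
  r
}

#' Simulate a planar radiograph
#'
#' Parallel-ray projection along z through the phantom onto a detector grid.
#' Pixel values are radiological path (-log of the polychromatic detected
#' signal fraction), so markers are the bright feature as on an inverted
#' clinical radiograph; Poisson noise is applied to per-pixel photon counts.
#' Incident counts scale with mAs (kV; 1e5/ray at 200 mAs) or MU (MV).
#' Marker edges are anti-aliased by 3x3 sub-pixel ray sampling.
#'
#' @param phantom A [phantom_spec()].
#' @param protocol An [imaging_protocol()] with modality `kv_planar` or
#'   `mv_planar`.
#' @param noise Apply Poisson noise?
#' @param materials,k_pe Physics configuration.
#' @param bin_width_kev Spectrum bin width.
#' @return A `fid_image` with units `"attenuation"` covering the full
#'   phantom face.
#' @export
simulate_planar <- function(phantom, protocol, noise = TRUE,
                            materials = material_table(),
                            k_pe = k_pe_default(materials),
                            bin_width_kev = 1) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(protocol, "imaging_protocol"))
  if (!protocol$modality %in% c("kv_planar", "mv_planar")) {
    stop("protocol modality must be kv_planar or mv_planar", call. = FALSE)
  }
  spec <- protocol_spectrum(protocol, bin_width_kev, materials, k_pe)
  v <- .detector_weights(spec)
  ext <- phantom$extent_mm
  dp <- protocol$pixel_spacing_mm
  nx <- ceiling(ext[1] / dp); ny <- ceiling(ext[2] / dp)
  xs <- (seq_len(nx) - 0.5) * dp
  ys <- (seq_len(ny) - 0.5) * dp

  mat_names <- unique(c(phantom$background_material,
                        phantom$markers$material))
  mu_e <- .mu_matrix(mat_names, spec$energy_kev, materials, k_pe)
  t_bg <- sum(v * exp(-mu_e[, 1] * ext[3] / 10))
  tmat <- matrix(t_bg, nx, ny)

  mk <- phantom$markers
  sub <- c(-1, 0, 1) / 3 * dp
  for (i in seq_len(nrow(mk))) {
    m <- mk[i, ]
    half <- (max(m$diameter_mm, m$length_mm)) / 2 + dp
    ix <- which(abs(xs - m$x_mm) <= half)
    iy <- which(abs(ys - m$y_mm) <= half)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    tacc <- numeric(length(px))
    for (ox in sub) for (oy in sub) {
      l_m <- .z_path_through_cylinder(px + ox, py + oy, m)
      od <- outer(l_m, mu_e[, match(m$material, mat_names)]) / 10 +
        outer(ext[3] - l_m, mu_e[, 1]) / 10
      tacc <- tacc + as.vector(exp(-od) %*% v)
    }
    tmat[cbind(rep(ix, times = length(iy)), rep(iy, each = length(ix)))] <-
      tacc / length(sub)^2
  }

  n0 <- if (protocol$modality == "kv_planar") {
    protocol$counts_ref * protocol$mas / 200
  } else {
    protocol$counts_ref * protocol$mu
  }
  mean_sig <- n0 * tmat
  counts <- if (noise) {
    .with_seed(protocol$seed,
               matrix(.poisson_inversion(mean_sig), nx, ny))
  } else mean_sig
  p <- -log(pmax(counts, 0.5) / n0)
  image2d(p, dp, units = "attenuation", origin_mm = c(0, 0),
          protocol = protocol, seed = protocol$seed)
}
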