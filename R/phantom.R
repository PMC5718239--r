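# Coordinate conventions: right-handed, millimetres, origin at the phantom
# corner. A voxel's position is its center; indices are 1-based in R but the
# first voxel center sits at origin + voxel_size/2. CT slices are x-y planes
# at fixed z; planar radiographs project along z.

#' Marker specification
#'
#' One cylindrical fiducial marker.
#'
#' @param material Registered material name.
#' @param diameter_mm,length_mm Cylinder dimensions in mm (> 0).
#' @param center Numeric length-3, center in mm (phantom coordinates).
#' @param axis Numeric length-3 direction of the cylinder axis (normalised
#'   internally; must be non-zero). Default +z: markers are implanted along
#'   the scan axis, so a CT slice crosses the marker's length, not its
#'   diameter.
#' @return One-row tibble describing the marker.
#' @export
marker_spec <- function(material, diameter_mm, length_mm, center,
                        axis = c(0, 0, 1)) {
  stopifnot(length(center) == 3L, length(axis) == 3L)
  if (diameter_mm <= 0 || length_mm <= 0) {
    stop("marker dimensions must be > 0", call. = FALSE)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("marker axis must be non-zero", call. = FALSE)
  axis <- axis / nrm
  tibble::tibble(
    material = material, diameter_mm = diameter_mm, length_mm = length_mm,
    x_mm = center[1], y_mm = center[2], z_mm = center[3],
    ax = axis[1], ay = axis[2], az = axis[3]
  )
}

#' Phantom specification
#'
#' Declarative geometry of a layered uniform phantom with embedded cylindrical
#' markers. Layers are geometric bookkeeping only: the background material is
#' uniform (the bolus slabs the phantom emulates are near-constant density).
#'
#' @param extent_cm Numeric length-3 phantom extent in cm (all > 0).
#' @param layer_thickness_cm Slab thickness in cm.
#' @param background_material Registered material name for the bulk.
#' @param markers Tibble of markers (rows from [marker_spec()]), may be empty.
#' @param materials Material table used to validate names.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(extent_cm = c(30, 31, 15), layer_thickness_cm = 2,
                         background_material = "soft_tissue",
                         markers = NULL, materials = material_table()) {
  stopifnot(length(extent_cm) == 3L)
  if (any(extent_cm <= 0) || layer_thickness_cm <= 0) {
    stop("phantom extents must be > 0", call. = FALSE)
  }
  if (is.null(markers)) {
    markers <- marker_spec("gold", 1, 1, c(1, 1, 1))[0, ]
  }
  markers <- tibble::as_tibble(markers)
  if (nrow(markers) > 0) {
    .lookup_material(markers$material, materials)
    if (!"marker_id" %in% names(markers)) {
      markers$marker_id <- sprintf("%s_%d", markers$material,
                                   stats::ave(seq_len(nrow(markers)),
                                              markers$material,
                                              FUN = seq_along))
    }
    extent_mm <- extent_cm * 10
    inside <- markers$x_mm > 0 & markers$x_mm < extent_mm[1] &
      markers$y_mm > 0 & markers$y_mm < extent_mm[2] &
      markers$z_mm > 0 & markers$z_mm < extent_mm[3]
    if (!all(inside)) {
      stop("marker center(s) outside phantom extent: ",
           paste(markers$marker_id[!inside], collapse = ", "), call. = FALSE)
    }
    if (nrow(markers) > 1) {
      ctr <- as.matrix(markers[, c("x_mm", "y_mm", "z_mm")])
      rad <- pmax(markers$diameter_mm, markers$length_mm) / 2
      d <- as.matrix(stats::dist(ctr))
      lim <- outer(rad, rad, "+")
      diag(d) <- Inf
      if (any(d < lim)) stop("markers overlap", call. = FALSE)
    }
  }
  .lookup_material(background_material, materials)
  structure(list(extent_mm = extent_cm * 10,
                 layer_thickness_mm = layer_thickness_cm * 10,
                 background_material = background_material,
                 markers = markers),
            class = "phantom_spec")
}

#' Default bolus phantom
#'
#' The study phantom: a 30 x 31 x 15 cm^3 uniform soft-tissue-equivalent block
#' built from 2 cm layers, with three markers of each material (gold 0.9 x 3
#' mm, carbon 1 x 3 mm, polymer 1 x 5 mm) in the central layer, arranged on a
#' 3 x 3 grid with 5 cm nearest-neighbour spacing (one row per material).
#' Marker axes point along +z (the scan axis).
#'
#' @param materials Material table.
#' @return A `phantom_spec`.
#' @examples
#' ph <- default_phantom()
#' ph$markers
#' @export
default_phantom <- function(materials = material_table()) {
  dims <- list(gold = c(0.9, 3), carbon = c(1, 3), polymer = c(1, 5))
  cx <- c(100, 150, 200)          # 5 cm apart along x
  cy <- c(gold = 105, carbon = 155, polymer = 205)  # one row per material
  markers <- purrr::map_dfr(names(dims), function(m) {
    purrr::map_dfr(seq_along(cx), function(i) {
      marker_spec(m, dims[[m]][1], dims[[m]][2], c(cx[i], cy[[m]], 75))
    })
  })
  phantom_spec(extent_cm = c(30, 31, 15), layer_thickness_cm = 2,
               background_material = "soft_tissue", markers = markers,
               materials = materials)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %g x %g x %g mm, background %s, %d marker(s)\n",
              x$extent_mm[1], x$extent_mm[2], x$extent_mm[3],
              x$background_material, nrow(x$markers)))
  invisible(x)
}

# Squared radial distance from, and axial projection onto, a marker axis,
# for an n x 3 matrix of points (mm). Returns logical inside-cylinder mask.
.in_cylinder <- function(pts, marker) {
  d <- cbind(pts[, 1] - marker$x_mm, pts[, 2] - marker$y_mm,
             pts[, 3] - marker$z_mm)
  ax <- c(marker$ax, marker$ay, marker$az)
  t_ax <- d %*% ax
  r2 <- rowSums(d^2) - t_ax^2
  abs(t_ax) <= marker$length_mm / 2 & r2 <= (marker$diameter_mm / 2)^2
}

#' Voxelize a phantom
#'
#' Rasterises the phantom onto a regular grid: a voxel takes a marker's
#' material iff its center lies inside that marker's cylinder, otherwise the
#' background material. Grid dimensions are `ceiling(extent / voxel_size)`
#' per axis.
#'
#' @param phantom A [phantom_spec()].
#' @param voxel_size_mm Isotropic voxel size in mm; must not exceed half the
#'   smallest marker diameter, so markers are resolved.
#' @return A `material_volume`: list with `labels` (3D integer array),
#'   `materials` (label level names), `voxel_size_mm`, `origin_mm`.
#' @export
voxelize <- function(phantom, voxel_size_mm) {
  stopifnot(inherits(phantom, "phantom_spec"), voxel_size_mm > 0)
  mk <- phantom$markers
  if (nrow(mk) > 0) {
    dmin <- min(mk$diameter_mm)
    if (voxel_size_mm > dmin / 2) {
      worst <- mk$marker_id[which.min(mk$diameter_mm)]
      stop(sprintf(paste0("voxel_size_mm = %g is too coarse to resolve ",
                          "marker '%s' (diameter %g mm); need <= %g mm"),
                   voxel_size_mm, worst, dmin, dmin / 2), call. = FALSE)
    }
  }
  dims <- ceiling(phantom$extent_mm / voxel_size_mm)
  levels <- unique(c(phantom$background_material, mk$material))
  labels <- array(1L, dim = dims)
  xs <- (seq_len(dims[1]) - 0.5) * voxel_size_mm
  ys <- (seq_len(dims[2]) - 0.5) * voxel_size_mm
  zs <- (seq_len(dims[3]) - 0.5) * voxel_size_mm
  for (i in seq_len(nrow(mk))) {
    m <- mk[i, ]
    half <- max(m$diameter_mm, m$length_mm) / 2 + voxel_size_mm
    ix <- which(abs(xs - m$x_mm) <= half)
    iy <- which(abs(ys - m$y_mm) <= half)
    iz <- which(abs(zs - m$z_mm) <= half)
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
    inside <- .in_cylinder(pts, m)
    if (any(inside)) {
      idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
      labels[idx] <- match(m$material, levels)
    }
  }
  structure(list(labels = labels, materials = levels,
                 voxel_size_mm = voxel_size_mm, origin_mm = c(0, 0, 0)),
            class = "material_volume")
}

#' @export
print.material_volume <- function(x, ...) {
  cat(sprintf("<material_volume> %s voxels @ %g mm, materials: %s\n",
              paste(dim(x$labels), collapse = " x "), x$voxel_size_mm,
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Write / read a phantom specification as YAML
#'
#' @param phantom A `phantom_spec`.
#' @param path File path.
#' @return `write_phantom_yaml` returns `path` invisibly; `read_phantom_yaml`
#'   returns a `phantom_spec`.
#' @export
write_phantom_yaml <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  obj <- list(extent_cm = as.numeric(phantom$extent_mm) / 10,
              layer_thickness_cm = phantom$layer_thickness_mm / 10,
              background_material = phantom$background_material,
              markers = lapply(seq_len(nrow(phantom$markers)), function(i) {
                as.list(phantom$markers[i, ])
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @param materials Material table used for validation.
#' @export
read_phantom_yaml <- function(path, materials = material_table()) {
  obj <- yaml::read_yaml(path)
  markers <- if (length(obj$markers)) {
    purrr::map_dfr(obj$markers, tibble::as_tibble)
  } else NULL
  phantom_spec(extent_cm = as.numeric(obj$extent_cm),
               layer_thickness_cm = obj$layer_thickness_cm,
               background_material = obj$background_material,
               markers = markers, materials = materials)
}
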