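# Image and configuration I/O. Physical pixel spacing is mandatory metadata
# everywhere (ring radii and ROI widths are metric): readers refuse to guess.

.sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read an image
#'
#' Reads NIfTI (`.nii`, `.nii.gz`), TIFF (`.tif`, `.tiff`), or single-frame
#' uncompressed DICOM (`.dcm`) images. Pixel spacing is taken from the
#' header (NIfTI pixdim, TIFF resolution tags, DICOM PixelSpacing) or, for
#' TIFF files written by [write_image()], from the YAML sidecar; a missing
#' spacing is an error, never a silent default. DICOM rescale slope and
#' intercept are applied, so CT values come back in HU.
#'
#' @param path File path.
#' @return A `fid_image` for 2D inputs; for a 3D NIfTI stack, a list of
#'   `fid_image` slices (along the third axis).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    .read_nifti(path)
  } else if (grepl("\\.tiff?$", lower)) {
    .read_tiff(path)
  } else if (grepl("\\.dcm$", lower)) {
    .read_dicom(path)
  } else {
    stop("unknown image format: ", path,
         " (expect .nii, .nii.gz, .tif, .tiff, .dcm)", call. = FALSE)
  }
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (any(pd[1:2] <= 0)) stop("NIfTI header has no usable pixel spacing",
                              call. = FALSE)
  meta <- .read_sidecar(path)
  units <- meta$units %||% "detector_signal"
  if (length(dim(arr)) == 2) {
    image2d(arr, pd[1:2], units = units)
  } else if (length(dim(arr)) == 3) {
    lapply(seq_len(dim(arr)[3]), function(k) {
      image2d(arr[, , k], pd[1:2], units = units)
    })
  } else {
    stop("unsupported NIfTI dimensionality: ", length(dim(arr)),
         call. = FALSE)
  }
}

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (file.exists(sc)) yaml::read_yaml(sc) else NULL
}

.read_tiff <- function(path) {
  raw <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  meta <- .read_sidecar(path)
  spacing <- NULL
  xres <- attr(raw, "x.resolution")
  if (!is.null(xres) && is.numeric(xres) && xres > 0) {
    unit <- attr(raw, "resolution.unit") %||% "inch"
    per_mm <- switch(unit, inch = xres / 25.4, cm = xres / 10, xres / 25.4)
    yres <- attr(raw, "y.resolution") %||% xres
    spacing <- c(1 / per_mm,
                 1 / (switch(unit, inch = yres / 25.4, cm = yres / 10,
                             yres / 25.4)))
  }
  if (is.null(spacing)) spacing <- meta$spacing_mm
  if (is.null(spacing)) {
    stop("TIFF has no resolution tags and no sidecar: pixel spacing ",
         "unknown (refusing to guess)", call. = FALSE)
  }
  m <- raw
  attributes(m) <- list(dim = dim(raw))
  vals <- m / 65535
  if (!is.null(meta$scale)) {
    vals <- m * meta$scale$step + meta$scale$min
  }
  # TIFF stores row-major from the top row: transpose to [x, y]
  image2d(t(vals[rev(seq_len(nrow(vals))), , drop = FALSE]),
          spacing, units = meta$units %||% "detector_signal")
}

#' Write an image
#'
#' NIfTI output is lossless 32/64-bit float with the spacing in the header.
#' TIFF output is 16-bit with linear quantization over the data range; the
#' quantization scale, spacing, and units go to a YAML sidecar
#' (`<path>.meta.yaml`) that [read_image()] uses to restore values.
#'
#' @param image A `fid_image`.
#' @param path Output path ending in `.nii`, `.nii.gz`, `.tif`, or `.tiff`.
#' @param force Overwrite an existing file? Default `FALSE`: refuse.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, force = FALSE) {
  stopifnot(inherits(image, "fid_image"))
  if (file.exists(path) && !force) {
    stop("refusing to overwrite existing file (use force = TRUE): ", path,
         call. = FALSE)
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    hdr <- RNifti::niftiHeader(list(
      dim = c(2, dim(image$pixels), 1, 1, 1, 1, 1),
      pixdim = c(-1, image$spacing_mm, 1, 0, 0, 0, 0)))
    arr <- RNifti::asNifti(image$pixels, hdr)
    RNifti::writeNifti(arr, path, datatype = "double")
    yaml::write_yaml(list(units = image$units,
                          spacing_mm = as.numeric(image$spacing_mm),
                          seed = image$seed),
                     .sidecar_path(path))
  } else if (grepl("\\.tiff?$", lower)) {
    rng <- range(image$pixels)
    step <- if (diff(rng) > 0) diff(rng) / 65535 else 1
    q <- round((image$pixels - rng[1]) / step)
    # back to row-major top-first layout
    m <- t(q)[rev(seq_len(ncol(q))), , drop = FALSE]
    storage.mode(m) <- "integer"
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
    yaml::write_yaml(list(units = image$units,
                          spacing_mm = as.numeric(image$spacing_mm),
                          scale = list(min = rng[1], step = step),
                          seed = image$seed),
                     .sidecar_path(path))
  } else {
    stop("unsupported output extension (use .nii/.nii.gz/.tif/.tiff): ",
         path, call. = FALSE)
  }
  invisible(path)
}

# --- minimal DICOM reader -------------------------------------------------
# Single-frame, uncompressed, explicit-VR little-endian only: enough for the
# read contract (pixel array, PixelSpacing, rescale slope/intercept). No R
# DICOM reader is available in the package's dependency set, so this much is
# implemented directly.

.read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  if (length(preamble) < 132 ||
      rawToChar(preamble[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1])
  u32 <- function(r, i) {
    as.numeric(r[i]) + 256 * as.numeric(r[i + 1]) +
      65536 * as.numeric(r[i + 2]) + 16777216 * as.numeric(r[i + 3])
  }
  tags <- list()
  repeat {
    head <- readBin(con, "raw", 8)
    if (length(head) < 8) break
    group <- u16(head, 1); elem <- u16(head, 3)
    vr <- rawToChar(head[5:6])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      lenraw <- readBin(con, "raw", 4)
      len <- u32(lenraw, 1)
    } else {
      len <- u16(head, 7)
    }
    key <- sprintf("%04x%04x", group, elem)
    if (len == 0xFFFFFFFF) stop("undefined-length DICOM elements are not ",
                                "supported", call. = FALSE)
    val <- readBin(con, "raw", len)
    tags[[key]] <- list(vr = vr, val = val)
    if (key == "7fe00010") break
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM missing ", what, call. = FALSE)
    tags[[key]]
  }
  ds_num <- function(key) {
    as.numeric(strsplit(trimws(rawToChar(tags[[key]]$val)), "\\\\")[[1]])
  }
  rows <- u16(need("00280010", "Rows")$val, 1)
  cols <- u16(need("00280011", "Columns")$val, 1)
  if (is.null(tags[["00280030"]])) {
    stop("DICOM missing PixelSpacing: refusing to guess", call. = FALSE)
  }
  sp <- ds_num("00280030")          # row spacing, column spacing (mm)
  spacing <- c(sp[2], sp[1])
  bits <- if (!is.null(tags[["00280100"]])) {
    u16(tags[["00280100"]]$val, 1)
  } else 16
  signed <- !is.null(tags[["00280103"]]) &&
    u16(tags[["00280103"]]$val, 1) == 1
  if (bits != 16) stop("only 16-bit DICOM pixel data is supported",
                       call. = FALSE)
  px <- need("7fe00010", "PixelData")$val
  vals <- readBin(px, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
  if (!signed) vals[vals < 0] <- vals[vals < 0] + 65536
  slope <- if (!is.null(tags[["00281053"]])) ds_num("00281053")[1] else 1
  inter <- if (!is.null(tags[["00281052"]])) ds_num("00281052")[1] else 0
  vals <- slope * vals + inter
  has_rescale <- !is.null(tags[["00281053"]]) || !is.null(tags[["00281052"]])
  # row-major, first row on top; store as [x, y] with y increasing upward
  m <- matrix(vals, nrow = cols)
  m <- m[, rev(seq_len(rows)), drop = FALSE]
  image2d(m, spacing, units = if (has_rescale) "HU" else "detector_signal")
}

#' Run configuration
#'
#' Loads a YAML configuration with optional keys `materials` (per-material
#' overrides of `z_eff`, `mass_density`, `z_a_ratio`), `k_pe`, `phantom`
#' (path to a phantom YAML), `seed`, and `out_dir`. Every key is defaulted:
#' an empty (or absent) file reproduces the default study configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return List with `materials` (tibble), `k_pe`, `phantom`
#'   (`phantom_spec`), `seed`, `out_dir`.
#' @export
run_config <- function(path = NULL) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
    yaml::read_yaml(path) %||% list()
  } else list()
  overrides <- NULL
  if (!is.null(cfg$materials)) {
    overrides <- purrr::map_dfr(names(cfg$materials), function(nm) {
      tibble::as_tibble(c(list(name = nm), cfg$materials[[nm]]))
    })
  }
  materials <- material_table(overrides)
  k_pe <- cfg$k_pe %||% k_pe_default(materials)
  phantom <- if (!is.null(cfg$phantom)) {
    read_phantom_yaml(cfg$phantom, materials)
  } else {
    default_phantom(materials)
  }
  list(materials = materials, k_pe = k_pe, phantom = phantom,
       seed = as.integer(cfg$seed %||% 1L),
       out_dir = cfg$out_dir %||% "fidviz_out")
}
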