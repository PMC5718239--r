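#' 2D image with physical metadata
#'
#' Pixel array plus the physical metadata every downstream statistic needs:
#' spacing in mm (mandatory -- ring radii and ROI widths are metric), a value
#' unit tag, and acquisition provenance. `pixels[i, j]` sits at physical
#' position `origin_mm + (c(i, j) - 0.5) * spacing_mm` (first index x, second
#' y; a pixel's position is its center).
#'
#' @param pixels Numeric matrix of finite values.
#' @param spacing_mm Pixel spacing, length 1 or 2, > 0.
#' @param units Value units, e.g. `"HU"`, `"detector_signal"`,
#'   `"attenuation"`, `"mu"`.
#' @param origin_mm Physical position of the image corner (mm), length 2.
#' @param protocol Optional [imaging_protocol()] provenance.
#' @param seed RNG seed used to generate the image, if any.
#' @return A `fid_image` object.
#' @export
image2d <- function(pixels, spacing_mm, units = "detector_signal",
                    origin_mm = c(0, 0), protocol = NULL, seed = NULL) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 2)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0", call. = FALSE)
  structure(list(pixels = pixels, spacing_mm = spacing_mm, units = units,
                 origin_mm = as.numeric(origin_mm)[1:2], protocol = protocol,
                 seed = seed),
            class = "fid_image")
}

#' @export
print.fid_image <- function(x, ...) {
  cat(sprintf("<fid_image> %d x %d px @ %g x %g mm [%s]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1],
              x$spacing_mm[2], x$units))
  invisible(x)
}

#' @export
dim.fid_image <- function(x) dim(x$pixels)

# Physical center coordinates of pixels along each axis
.image_axes <- function(img) {
  list(x = img$origin_mm[1] + (seq_len(nrow(img$pixels)) - 0.5) *
         img$spacing_mm[1],
       y = img$origin_mm[2] + (seq_len(ncol(img$pixels)) - 0.5) *
         img$spacing_mm[2])
}

# Bilinear interpolation of image values at physical points (mm).
# Points must lie within the pixel-center hull; outside points error.
.bilinear <- function(img, x_mm, y_mm, what = "sample point") {
  u <- (x_mm - img$origin_mm[1]) / img$spacing_mm[1] - 0.5
  v <- (y_mm - img$origin_mm[2]) / img$spacing_mm[2] - 0.5
  nx <- nrow(img$pixels); ny <- ncol(img$pixels)
  if (any(u < 0 | u > nx - 1 | v < 0 | v > ny - 1)) {
    stop(what, " falls outside the image", call. = FALSE)
  }
  i0 <- pmin(floor(u), nx - 2); j0 <- pmin(floor(v), ny - 2)
  fu <- u - i0; fv <- v - j0
  p <- img$pixels
  idx <- function(i, j) p[cbind(i + 1L, j + 1L)]
  idx(i0, j0) * (1 - fu) * (1 - fv) + idx(i0 + 1, j0) * fu * (1 - fv) +
    idx(i0, j0 + 1) * (1 - fu) * fv + idx(i0 + 1, j0 + 1) * fu * fv
}

#' Tidy an image into a long tibble
#'
#' @param x A `fid_image`.
#' @param ... Unused.
#' @return Tibble with columns `x_mm`, `y_mm`, `value`.
#' @export
tidy.fid_image <- function(x, ...) {
  ax <- .image_axes(x)
  tibble::tibble(x_mm = rep(ax$x, times = length(ax$y)),
                 y_mm = rep(ax$y, each = length(ax$x)),
                 value = as.vector(x$pixels))
}

#' @importFrom generics tidy
NULL

# run RNG-dependent code under a protocol seed without disturbing the
# caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
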