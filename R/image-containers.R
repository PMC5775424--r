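#' Two-photon image containers
#'
#' Lightweight containers for single-channel intensity rasters and binary
#' masks. A [channel_image] holds a non-negative intensity grid (a matrix for
#' 2D maximum-intensity projections, a 3D array for z-stacks) together with
#' the channel identity and the physical pixel size; a [binary_mask] holds a
#' logical grid of the same shape. All downstream statistics consume these
#' two types.
#'
#' Channels follow the reporter conventions of intravital bone imaging:
#' `"cyan"` for mature osteoblasts (Col2.3-ECFP), `"red"` for mature
#' osteoclasts (TRAP-tdTomato), `"probe"` for the pH-sensing chemical probe,
#' and `"shg"` for the second-harmonic bone-matrix signal.
#'
#' @param pixels Numeric matrix (2D) or 3D array of non-negative intensities.
#' @param channel One of `"cyan"`, `"red"`, `"probe"`, `"shg"`.
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (in-plane). Must be positive.
#' @param voxel_depth_um Z-step in micrometres for 3D stacks; ignored for 2D.
#'
#' @return `channel_image()` returns an object of class `"channel_image"`;
#'   `binary_mask()` returns an object of class `"binary_mask"`. Both are
#'   lists with elements `pixels`/`bits`, `channel`, `pixel_size_um`, and
#'   (for stacks) `voxel_depth_um`.
#' @examples
#' img <- channel_image(matrix(c(0, 10, 200, 220), 2, 2), "cyan")
#' mask <- binarize(img, otsu_threshold(img))
#' mask_area_um2(mask)
#' @export
channel_image <- function(pixels, channel = c("cyan", "red", "probe", "shg"),
                          pixel_size_um = 1, voxel_depth_um = NULL) {
  channel <- match.arg(channel)
  if (!is.numeric(pixels) || is.null(dim(pixels)) ||
      !(length(dim(pixels)) %in% c(2L, 3L))) {
    abort("`pixels` must be a numeric matrix or 3D array.")
  }
  if (any(dim(pixels) < 1L)) abort("image dimensions must all be >= 1")
  if (anyNA(pixels) || any(pixels < 0)) {
    abort(sprintf("channel '%s': intensities must be finite and >= 0", channel))
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  is_3d <- length(dim(pixels)) == 3L
  if (is_3d && (is.null(voxel_depth_um) || voxel_depth_um <= 0)) {
    abort("3D stacks require a positive `voxel_depth_um`.")
  }
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size_um = as.numeric(pixel_size_um),
         voxel_depth_um = if (is_3d) as.numeric(voxel_depth_um)),
    class = "channel_image"
  )
}

#' @rdname channel_image
#' @param bits Logical matrix (2D) or 3D array marking foreground pixels.
#' @export
binary_mask <- function(bits, channel = c("cyan", "red", "probe", "shg"),
                        pixel_size_um = 1, voxel_depth_um = NULL) {
  channel <- match.arg(channel)
  if (!is.logical(bits) || is.null(dim(bits)) ||
      !(length(dim(bits)) %in% c(2L, 3L))) {
    abort("`bits` must be a logical matrix or 3D array.")
  }
  if (anyNA(bits)) abort("mask bits must not contain NA")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  is_3d <- length(dim(bits)) == 3L
  if (is_3d && (is.null(voxel_depth_um) || voxel_depth_um <= 0)) {
    abort("3D masks require a positive `voxel_depth_um`.")
  }
  structure(
    list(bits = bits, channel = channel,
         pixel_size_um = as.numeric(pixel_size_um),
         voxel_depth_um = if (is_3d) as.numeric(voxel_depth_um)),
    class = "binary_mask"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  d <- paste(dim(x$pixels), collapse = " x ")
  cat(sprintf("<channel_image> %s, %s, %.3g um/px, range [%g, %g]\n",
              x$channel, d, x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- paste(dim(x$bits), collapse = " x ")
  cat(sprintf("<binary_mask> %s, %s, %.3g um/px, %d foreground (%.4g um^2)\n",
              x$channel, d, x$pixel_size_um, sum(x$bits), mask_area_um2(x)))
  invisible(x)
}

#' Foreground area of a 2D mask in square micrometres
#'
#' @param mask A [binary_mask].
#' @return Foreground pixel count times the squared pixel size.
#' @export
mask_area_um2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$bits) * mask$pixel_size_um^2
}

#' Read and write grayscale rasters
#'
#' Thin wrappers over the \pkg{tiff} and \pkg{png} readers that return a
#' [channel_image] on the native integer intensity scale (0--255 for 8-bit
#' files, 0--65535 for 16-bit). Multi-page TIFFs are returned as a list of
#' frames by `read_stack()`.
#'
#' @param path File path; `.tif`/`.tiff` or `.png`.
#' @inheritParams channel_image
#' @return A [channel_image] (`read_channel_image`), a list of them
#'   (`read_stack`), or the path invisibly (writers).
#' @export
read_channel_image <- function(path, channel = "cyan", pixel_size_um = 1,
                               voxel_depth_um = NULL) {
  px <- read_raster(path)
  channel_image(px, channel, pixel_size_um, voxel_depth_um)
}

#' @rdname read_channel_image
#' @export
read_stack <- function(path, channel = "cyan", pixel_size_um = 1,
                       voxel_depth_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(pages, function(p) {
    channel_image(drop_to_gray(p), channel, pixel_size_um, voxel_depth_um)
  })
}

#' @rdname read_channel_image
#' @param image A [channel_image] (or list of them for multi-page output).
#' @param bits_per_sample 8 or 16.
#' @export
write_channel_image <- function(image, path, bits_per_sample = 16L) {
  imgs <- if (inherits(image, "channel_image")) list(image) else image
  maxv <- 2^bits_per_sample - 1
  mats <- lapply(imgs, function(im) {
    m <- pmin(pmax(im$pixels, 0), maxv) / maxv
    m
  })
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stopifnot(length(mats) == 1L)
    png::writePNG(mats[[1]], path)
  } else {
    tiff::writeTIFF(mats, path, bits.per.sample = bits_per_sample)
  }
  invisible(path)
}

#' @rdname read_channel_image
#' @param mask A [binary_mask]; written as 0/255 grayscale.
#' @export
write_mask <- function(mask, path) {
  m <- mask$bits * 1
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(path)
}

read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path, info = TRUE)
    depth <- attr(px, "info")$bit.depth %||% 8L
    px <- drop_to_gray(px) * (2^depth - 1)
    attributes(px) <- list(dim = dim(px))
    px
  } else {
    drop_to_gray(tiff::readTIFF(path, as.is = TRUE))
  }
}

# Collapse an RGB(A) plane to gray by taking the first channel; grayscale
# files come back unchanged.
drop_to_gray <- function(px) {
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px
}
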