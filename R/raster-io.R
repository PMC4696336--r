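#' @include AllGenerics.R
NULL

#' Construct an 8-bit image
#'
#' @param x numeric matrix with integer values in [0, 255].
#' @return an \linkS4class{Image8}.
#' @examples
#' img <- Image8(matrix(255L, 8, 8))
#' @export
Image8 <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("Image8 requires a numeric matrix")
  if (anyNA(x)) stop("Image8 intensities must not contain NA")
  if (any(x != round(x)))
    stop("Image8 intensities must be integer-valued")
  storage.mode(x) <- "integer"
  new("Image8", x)
}

#' Construct an RGB image
#'
#' @param x height x width x 3 numeric array with values in [0, 255].
#' @return an \linkS4class{ImageRGB}.
#' @export
ImageRGB <- function(x) new("ImageRGB", x)

#' Construct a binary mask
#'
#' @param x logical matrix, or numeric matrix interpreted as nonzero = member.
#' @return a \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(x) {
  if (!is.logical(x)) {
    x <- x != 0
  }
  new("BinaryMask", x)
}

## internal: accept Image8 / integer matrix interchangeably
as_image8 <- function(img) {
  if (is(img, "Image8")) return(img)
  if (is.matrix(img)) return(Image8(img))
  stop("expected an Image8 or a 2-D intensity matrix")
}

as_mask <- function(mask) {
  if (is(mask, "BinaryMask")) return(mask)
  if (is.matrix(mask)) return(BinaryMask(mask))
  stop("expected a BinaryMask or a 2-D matrix")
}

## internal: read a PNG/TIFF into a [0,1] array + bit depth, rejecting > 8 bit
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    a <- png::readPNG(path, info = TRUE)
    depth <- attr(a, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(a, "bits.per.sample")
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  if (!is.null(depth) && any(depth > 8))
    stop("unsupported bit depth: ", max(depth),
         " bits/channel; fixed intensity thresholds are defined on 8-bit data",
         " and 16-bit inputs are rejected rather than silently rescaled")
  a
}

#' Load an image from a PNG or TIFF file
#'
#' Grayscale files load directly as \linkS4class{Image8}; colour files load
#' as \linkS4class{ImageRGB} (a trailing alpha channel, if present, is
#' dropped). Inputs deeper than 8 bits/channel are rejected, because the
#' fixed intensity thresholds (150 mouse, 100 human) are defined on the
#' 8-bit scale.
#'
#' @param path path to a PNG or TIFF file.
#' @return an \linkS4class{Image8} or \linkS4class{ImageRGB}.
#' @export
loadImage <- function(path) {
  a <- read_raster(path)
  v <- round(a * 255)
  if (length(dim(v)) == 2L) return(Image8(v))
  d <- dim(v)
  if (d[3L] <= 2L)                                 # gray (+ alpha)
    return(Image8(matrix(v[, , 1L], d[1L], d[2L])))
  ImageRGB(v[, , 1:3, drop = FALSE])               # RGB or RGBA
}

#' Load a binary mask from a raster file
#'
#' Membership is encoded as nonzero pixels; colour rasters are collapsed by
#' maximum over channels before binarisation.
#'
#' @param path path to a PNG or TIFF file.
#' @return a \linkS4class{BinaryMask}.
#' @export
loadMask <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), max)
  BinaryMask(a != 0)
}

#' Write an image or mask to a PNG or TIFF file
#'
#' 8-bit rasters round-trip losslessly through either format.
#'
#' @param img an \linkS4class{Image8}, \linkS4class{ImageRGB} or
#'   \linkS4class{BinaryMask}.
#' @param path destination path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeImage <- function(img, path) {
  if (is(img, "BinaryMask")) {
    a <- matrix(as.numeric(img@.Data), nrow(img@.Data), ncol(img@.Data))
  } else if (is(img, "Image8") || is(img, "ImageRGB")) {
    a <- img@.Data / 255
  } else if (is.matrix(img) || is.array(img)) {
    a <- img / 255
  } else {
    stop("cannot write object of class ", class(img)[1L])
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  invisible(path)
}

#' @describeIn toGray8 weighted channel mean, rounded and clipped to [0, 255].
#' @export
setMethod("toGray8", "ImageRGB", function(img, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3L || any(!is.finite(weights)))
    stop("weights must be three finite numbers")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  a <- img@.Data
  g <- weights[1L] * a[, , 1L] + weights[2L] * a[, , 2L] + weights[3L] * a[, , 3L]
  g <- matrix(g, dim(a)[1L], dim(a)[2L])   # guard against 1-pixel drop
  Image8(pmin(pmax(round_half_up(g), 0), 255))
})

#' @describeIn toGray8 method for plain arrays.
#' @export
setMethod("toGray8", "array", function(img, weights = c(1, 1, 1) / 3) {
  toGray8(ImageRGB(img), weights)
})

setMethod("show", "Image8", function(object) {
  d <- dim(object@.Data)
  cat(sprintf("Image8: %d x %d pixels, intensity range [%d, %d]\n",
              d[1L], d[2L], min(object@.Data), max(object@.Data)))
})

setMethod("show", "ImageRGB", function(object) {
  d <- dim(object@.Data)
  cat(sprintf("ImageRGB: %d x %d pixels, 3 channels\n", d[1L], d[2L]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@.Data)
  cat(sprintf("BinaryMask: %d x %d pixels, %d member pixels (%.1f%%)\n",
              d[1L], d[2L], sum(object@.Data),
              100 * mean(object@.Data)))
})
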