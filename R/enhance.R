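#' @include AllGenerics.R
NULL

#' Unsharp-mask parameters
#'
#' Defaults follow the published analysis settings: radius (Gaussian sigma)
#' 1 pixel, mask weight 0.60.
#'
#' @param radius Gaussian sigma in pixels (> 0).
#' @param weight mask weight in [0, 1).
#' @return an \linkS4class{EnhanceParams}.
#' @export
EnhanceParams <- function(radius = 1, weight = 0.60) {
  new("EnhanceParams", radius = radius, weight = weight)
}

setMethod("show", "EnhanceParams", function(object) {
  cat(sprintf("EnhanceParams: unsharp mask, radius (sigma) %g px, weight %g\n",
              object@radius, object@weight))
})

## internal: round half up (floor(x + 0.5)), the conventional pixel
## quantisation; base round() is half-to-even, which would map e.g.
## 0.30 * 255 = 76.5 to 76 instead of 77
round_half_up <- function(x) floor(x + 0.5)

## internal: discrete 1-D Gaussian kernel, truncated at 3*sigma
## (minimum half-width 1), normalised to sum 1
gauss_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## internal: 1-D convolution of a matrix along one dimension with
## replicate-edge padding; dim = 1 convolves down columns (across rows)
conv_replicate <- function(m, kernel, dim) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(kernel)) {
    off <- s - h - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)      # replicate edges
    out <- out + kernel[s] * (if (dim == 1L) m[idx, , drop = FALSE]
                              else m[, idx, drop = FALSE])
  }
  out
}

## internal: separable Gaussian smoothing with replicate-edge padding,
## in double precision (no intermediate rounding)
gaussian_smooth <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  conv_replicate(conv_replicate(m, k, 1L), k, 2L)
}

#' Unsharp-mask an 8-bit image
#'
#' Sharpens the image before thresholding using the classical unsharp
#' formula: each output pixel is `(I - w * G_sigma(I)) / (1 - w)`, computed
#' in real arithmetic, where `G_sigma` is Gaussian smoothing with sigma =
#' `radius` (kernel truncated at 3 sigma, replicate-edge padding) and `w` is
#' the mask weight. The result is rounded and clipped to [0, 255]. At
#' `w = 0` the filter is the identity; constant images are fixed points for
#' any parameters.
#'
#' @param img an \linkS4class{Image8} or intensity matrix.
#' @param params an \linkS4class{EnhanceParams}.
#' @return an \linkS4class{Image8}.
#' @examples
#' img <- Image8(matrix(100L, 9, 9))
#' unsharpMask(img)          # constant image is unchanged
#' @export
unsharpMask <- function(img, params = EnhanceParams()) {
  img <- as_image8(img)
  stopifnot(is(params, "EnhanceParams"))
  m <- img@.Data
  storage.mode(m) <- "double"
  w <- params@weight
  if (w == 0) return(img)
  g <- gaussian_smooth(m, params@radius)
  out <- (m - w * g) / (1 - w)
  Image8(pmin(pmax(round_half_up(out), 0), 255))
}
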