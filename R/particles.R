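#' @include enhance.R
NULL

#' Particle scoring parameters
#'
#' Defaults reproduce the published mouse-brain analysis: intensity threshold
#' 150 with dark-positive polarity (DAB-positive staining is dark on a light
#' background), particle size window 0-30 pixel^2, circularity window
#' 0.50-1.00 (inclusive bounds), 8-connectivity. The human vessel variant
#' uses `threshold = 100` (see [vesselMaskedScore()]).
#'
#' Perimeters are measured as the crack boundary (the count of exposed unit
#' pixel edges, including hole boundaries), which is exact and reproducible;
#' tools that use a weighted boundary approximation yield slightly different
#' circularities, which is why `circMin` is exposed as a parameter.
#'
#' @param threshold intensity threshold in [0, 255].
#' @param polarity "dark" (member iff intensity <= threshold) or "bright"
#'   (member iff intensity >= threshold).
#' @param sizeMin,sizeMax inclusive area window, pixel^2 (uncalibrated).
#' @param circMin,circMax inclusive circularity window in [0, 1].
#' @param connectivity 4 or 8.
#' @return a \linkS4class{ScoreParams}.
#' @export
ScoreParams <- function(threshold = 150, polarity = c("dark", "bright"),
                        sizeMin = 0, sizeMax = 30,
                        circMin = 0.50, circMax = 1.00,
                        connectivity = 8L) {
  polarity <- match.arg(polarity)
  new("ScoreParams", threshold = threshold, polarity = polarity,
      sizeMin = sizeMin, sizeMax = sizeMax, circMin = circMin,
      circMax = circMax, connectivity = as.integer(connectivity))
}

setMethod("show", "ScoreParams", function(object) {
  cat(sprintf(
    "ScoreParams: threshold %g (%s-positive), size %g-%g px^2, circularity %.2f-%.2f, %d-connectivity\n",
    object@threshold, object@polarity, object@sizeMin, object@sizeMax,
    object@circMin, object@circMax, object@connectivity))
})

#' Threshold an image into a positive-pixel mask
#'
#' @param img an \linkS4class{Image8} or intensity matrix.
#' @param params a \linkS4class{ScoreParams}; only `threshold` and
#'   `polarity` are used.
#' @return a \linkS4class{BinaryMask} of threshold-positive pixels.
#' @export
thresholdMask <- function(img, params = ScoreParams()) {
  img <- as_image8(img)
  stopifnot(is(params, "ScoreParams"))
  m <- img@.Data
  BinaryMask(if (params@polarity == "dark") m <= params@threshold
             else m >= params@threshold)
}

## internal: shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  ok_r <- rs >= 1L & rs <= H; ok_c <- cs >= 1L & cs <= W
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

neighbour_offsets <- function(connectivity) {
  orth <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4L) return(orth)
  c(orth, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

#' Label connected components of a binary mask
#'
#' Two member pixels share a label iff they are connected under the chosen
#' adjacency. Labels are 1..K in deterministic raster-scan order (row by
#' row, left to right, by each component's first pixel), so output is
#' reproducible byte-for-byte.
#'
#' Implemented as vectorised iterative minimum-label propagation: each member
#' pixel starts with its raster index and repeatedly takes the minimum over
#' its neighbourhood until a fixed point, which is exact for any mask.
#'
#' @param mask a \linkS4class{BinaryMask} or logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return an integer matrix of the mask's dimensions; 0 = background,
#'   1..K = component labels.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  b <- mask@.Data
  H <- nrow(b); W <- ncol(b)
  if (!any(b)) return(matrix(0L, H, W))
  ## raster (row-major) index, so the final minimum per component is the
  ## raster index of its first pixel
  rix <- (row(b) - 1) * W + col(b)
  cur <- ifelse(b, rix, Inf)
  offs <- neighbour_offsets(connectivity)
  repeat {
    nb <- cur
    for (o in offs) nb <- pmin(nb, shift_mat(cur, o[1L], o[2L], Inf))
    nb[!b] <- Inf
    if (identical(nb, cur)) break
    cur <- nb
  }
  u <- sort(unique(cur[b]))
  lab <- matrix(0L, H, W)
  lab[b] <- match(cur[b], u)
  lab
}

#' Measure labelled particles
#'
#' Computes, per component: area (member pixel count; holes are not filled),
#' crack-boundary perimeter (count of unit pixel edges adjacent to a
#' non-member pixel or the image border, hole boundaries included),
#' circularity `min(1, 4*pi*area / perimeter^2)`, centroid (mean row/col,
#' 1-based), and half-open bounding box.
#'
#' @param labels integer label matrix from [labelComponents()].
#' @return a data.frame with one row per particle, ordered by label.
#' @export
measureParticles <- function(labels) {
  stopifnot(is.matrix(labels))
  member <- labels > 0L
  K <- if (any(member)) max(labels) else 0L
  if (K == 0L) {
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), circularity = numeric(),
                      centroidRow = numeric(), centroidCol = numeric(),
                      bboxTop = integer(), bboxLeft = integer(),
                      bboxBottom = integer(), bboxRight = integer()))
  }
  ## exposed edges: 4-adjacent member pixels always belong to the same
  ## component (under both 4- and 8-connectivity), so exposure can be
  ## computed from the membership mask alone
  nmem <- shift_mat(member, -1L, 0L, FALSE) + shift_mat(member, 1L, 0L, FALSE) +
          shift_mat(member, 0L, -1L, FALSE) + shift_mat(member, 0L, 1L, FALSE)
  exposed <- 4 - nmem
  lab <- labels[member]
  area <- as.numeric(tabulate(lab, nbins = K))
  perim <- as.numeric(rowsum(as.numeric(exposed[member]), lab)[, 1L])
  rr <- row(labels)[member]; cc <- col(labels)[member]
  data.frame(
    label = seq_len(K),
    area = area,
    perimeter = perim,
    circularity = pmin(1, 4 * pi * area / perim^2),
    centroidRow = as.numeric(rowsum(as.numeric(rr), lab)[, 1L]) / area,
    centroidCol = as.numeric(rowsum(as.numeric(cc), lab)[, 1L]) / area,
    bboxTop = as.integer(tapply(rr, lab, min)),
    bboxLeft = as.integer(tapply(cc, lab, min)),
    bboxBottom = as.integer(tapply(rr, lab, max)) + 1L,
    bboxRight = as.integer(tapply(cc, lab, max)) + 1L
  )
}

#' Apply the size and circularity filters
#'
#' A particle is retained iff `sizeMin <= area <= sizeMax` and
#' `circMin <= circularity <= circMax`, all bounds inclusive.
#'
#' @param particles data.frame from [measureParticles()].
#' @param params a \linkS4class{ScoreParams}.
#' @return the input data.frame with a logical `retained` column.
#' @export
filterParticles <- function(particles, params = ScoreParams()) {
  stopifnot(is(params, "ScoreParams"))
  particles$retained <-
    particles$area >= params@sizeMin & particles$area <= params@sizeMax &
    particles$circularity >= params@circMin &
    particles$circularity <= params@circMax
  particles
}

## internal: score a mask that has already been thresholded
score_mask <- function(mask, params) {
  labels <- labelComponents(mask, params@connectivity)
  pt <- filterParticles(measureParticles(labels), params)
  new("ScoreResult",
      score = sum(pt$area[pt$retained]),
      nTotal = nrow(pt),
      nRetained = sum(pt$retained),
      particles = pt,
      params = params)
}

#' @describeIn notch3Score score an 8-bit image.
#' @export
setMethod("notch3Score", "Image8", function(img, enhance = EnhanceParams(),
                                            params = ScoreParams()) {
  stopifnot(is(params, "ScoreParams"))
  if (!is.null(enhance)) img <- unsharpMask(img, enhance)
  score_mask(thresholdMask(img, params), params)
})

#' @describeIn notch3Score score a plain intensity matrix.
#' @export
setMethod("notch3Score", "matrix", function(img, enhance = EnhanceParams(),
                                            params = ScoreParams()) {
  notch3Score(as_image8(img), enhance, params)
})

#' @describeIn notch3Score load an image file (colour files are converted
#'   with [toGray8()] default weights) and score it.
#' @export
setMethod("notch3Score", "character", function(img, enhance = EnhanceParams(),
                                               params = ScoreParams()) {
  x <- loadImage(img)
  if (is(x, "ImageRGB")) x <- toGray8(x)
  notch3Score(x, enhance, params)
})

#' @describeIn score total retained particle area of a per-image result.
#' @export
setMethod("score", "ScoreResult", function(object) object@score)

#' @describeIn particles per-particle table, optionally filtered.
#' @export
setMethod("particles", "ScoreResult", function(object, retainedOnly = FALSE) {
  pt <- object@particles
  if (retainedOnly) pt[pt$retained, , drop = FALSE] else pt
})

#' @describeIn nParticles particle counts.
#' @export
setMethod("nParticles", "ScoreResult", function(object, retained = TRUE) {
  if (retained) object@nRetained else object@nTotal
})

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf(
    "NOTCH3 score: %g px^2 (%d of %d particles retained)\n",
    object@score, object@nRetained, object@nTotal))
})
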