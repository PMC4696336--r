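#' @include particles.R
NULL

#' Vessel-restricted NOTCH3 score (human variant)
#'
#' Computes the score inside a CD31-defined vessel region: the positive area
#' is the count of pixels that are both vessel-mask members and
#' threshold-positive (default threshold 100, dark-positive), and the score
#' is reported as the percentage of the vessel area that is positive. The
#' percentage normalisation makes the score independent of how generously
#' the vessel ROI was drawn; the raw positive area is always reported
#' alongside.
#'
#' By default no unsharp mask and no particle filtering are applied (the
#' human procedure states neither); both can be switched on for sensitivity
#' analyses.
#'
#' @param img an \linkS4class{Image8} or intensity matrix.
#' @param vessel a \linkS4class{BinaryMask} with the image's dimensions and
#'   at least one member pixel.
#' @param params a \linkS4class{ScoreParams}; defaults to threshold 100,
#'   dark-positive.
#' @param enhance optional \linkS4class{EnhanceParams}; `NULL` (default)
#'   skips enhancement.
#' @param particleFilter logical; when TRUE, size/circularity filtering from
#'   `params` is applied to the positive pixels within the vessel before
#'   counting.
#' @return a \linkS4class{VesselScoreResult}.
#' @export
vesselMaskedScore <- function(img, vessel,
                              params = ScoreParams(threshold = 100),
                              enhance = NULL, particleFilter = FALSE) {
  img <- as_image8(img)
  vessel <- as_mask(vessel)
  if (!identical(dim(img@.Data), dim(vessel@.Data)))
    stop("vessel mask dimensions (", paste(dim(vessel@.Data), collapse = " x "),
         ") do not match image dimensions (",
         paste(dim(img@.Data), collapse = " x "), ")")
  vesselArea <- sum(vessel@.Data)
  if (vesselArea == 0)
    stop("vessel mask is empty; the score is undefined (division by zero)")
  if (!is.null(enhance)) img <- unsharpMask(img, enhance)
  pos <- thresholdMask(img, params)@.Data & vessel@.Data
  if (particleFilter) {
    res <- score_mask(BinaryMask(pos), params)
    positiveArea <- res@score
  } else {
    positiveArea <- sum(pos)
  }
  new("VesselScoreResult", vesselArea = as.numeric(vesselArea),
      positiveArea = as.numeric(positiveArea),
      score = 100 * positiveArea / vesselArea)
}

#' @describeIn score percentage score of a vessel-restricted result.
#' @export
setMethod("score", "VesselScoreResult", function(object) object@score)

setMethod("show", "VesselScoreResult", function(object) {
  cat(sprintf(
    "Vessel NOTCH3 score: %.3f%% (positive %g of %g px^2 vessel area)\n",
    object@score, object@positiveArea, object@vesselArea))
})

#' Per-subject aggregation of image scores
#'
#' The per-subject value is the arithmetic mean over that subject's images
#' (four images per individual in the human procedure); the sample SD is
#' reported when at least two images are available and is NA for a single
#' image.
#'
#' @param scores numeric vector of per-image scores, or a list of
#'   \linkS4class{VesselScoreResult} / \linkS4class{ScoreResult} objects.
#' @return a data.frame with columns n, mean, sd.
#' @examples
#' perSubjectScore(c(1, 3))   # mean 2, sd sqrt(2)
#' @export
perSubjectScore <- function(scores) {
  if (is.list(scores)) scores <- vapply(scores, score, numeric(1))
  if (length(scores) == 0) stop("need at least one image score")
  data.frame(n = length(scores), mean = mean(scores),
             sd = if (length(scores) >= 2) stats::sd(scores) else NA_real_)
}
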