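#' @include AllClasses.R
NULL

#' Convert a colour image to the 8-bit grayscale working representation
#'
#' @param img an \linkS4class{ImageRGB} (or height x width x 3 array).
#' @param weights length-3 non-negative channel weights summing to 1; the
#'   default is the unweighted channel mean, the standard 8-bit conversion of
#'   an RGB micrograph.
#' @return an \linkS4class{Image8}.
#' @export
setGeneric("toGray8", function(img, weights = c(1, 1, 1) / 3)
  standardGeneric("toGray8"))

#' Compute the per-image NOTCH3 score
#'
#' Runs the mouse-variant scoring pipeline: unsharp-mask enhancement,
#' intensity thresholding, connected-particle extraction, size/circularity
#' filtering, and summation of retained particle areas.
#'
#' @param img an \linkS4class{Image8}, integer matrix, or path to an image
#'   file.
#' @param enhance an \linkS4class{EnhanceParams}; `NULL` skips enhancement.
#' @param params a \linkS4class{ScoreParams}.
#' @return a \linkS4class{ScoreResult}.
#' @export
setGeneric("notch3Score", function(img, enhance = EnhanceParams(),
                                   params = ScoreParams())
  standardGeneric("notch3Score"))

#' Render a synthetic stained field
#'
#' @param spec a \linkS4class{FieldSpec}.
#' @return a \linkS4class{SyntheticField}.
#' @export
setGeneric("renderField", function(spec) standardGeneric("renderField"))

#' Simulate a synthetic strain x age cohort
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param outDir optional directory; when given, field images and truth masks
#'   are written as PNG files and tables as CSV.
#' @return a list with elements `design` (per-field data.frame including the
#'   rendered images as a list column when `outDir` is NULL, file paths
#'   otherwise), `truth` (per-field truth table) and `expected` (per
#'   strain x age cell expected deposit load).
#' @export
setGeneric("simulateCohort", function(spec, outDir = NULL)
  standardGeneric("simulateCohort"))

## --- accessors --------------------------------------------------------------

#' Extract the numeric score from a result object
#' @param object a \linkS4class{ScoreResult} or \linkS4class{VesselScoreResult}.
#' @export
setGeneric("score", function(object) standardGeneric("score"))

#' Per-particle measurement table of a \linkS4class{ScoreResult}
#' @param object a \linkS4class{ScoreResult}.
#' @param retainedOnly logical; keep only particles passing the filters.
#' @export
setGeneric("particles", function(object, retainedOnly = FALSE)
  standardGeneric("particles"))

#' Number of particles before/after filtering
#' @param object a \linkS4class{ScoreResult}.
#' @param retained logical; count retained (TRUE) or all (FALSE) particles.
#' @export
setGeneric("nParticles", function(object, retained = TRUE)
  standardGeneric("nParticles"))

#' Ground-truth total deposit area of a \linkS4class{SyntheticField}
#' @param object a \linkS4class{SyntheticField}.
#' @export
setGeneric("truthArea", function(object) standardGeneric("truthArea"))

#' Tidy per-subject score table of a \linkS4class{CohortScores}
#' @param object a \linkS4class{CohortScores}.
#' @export
setGeneric("subjectScores", function(object) standardGeneric("subjectScores"))

#' Per (group, age) summaries of a \linkS4class{CohortScores}
#' @param object a \linkS4class{CohortScores}.
#' @export
setGeneric("groupSummaries", function(object) standardGeneric("groupSummaries"))
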