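#' @import methods
NULL

## ---------------------------------------------------------------------------
## Image containers
##
## Images are stored as base matrices/arrays (row = image row, column = image
## column, origin top-left) wrapped in thin S4 classes so that validity is
## checked once at construction and dispatch stays clean.  Intensities are
## integer 0-255; this is the working representation every scoring stage
## operates on, mirroring an 8-bit converted micrograph.
## ---------------------------------------------------------------------------

#' 8-bit grayscale image
#'
#' An integer matrix of intensities in [0, 255], row-major with origin at the
#' top-left. This is the working raster for all scoring operations.
#'
#' @slot .Data integer matrix of intensities.
#' @export
setClass("Image8", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (length(dim(m)) != 2L) return("Image8 must be a 2-D matrix")
  if (nrow(m) < 1L || ncol(m) < 1L) return("Image8 must have positive dimensions")
  if (!is.numeric(m)) return("Image8 intensities must be numeric")
  if (anyNA(m)) return("Image8 intensities must not contain NA")
  if (any(m != round(m))) return("Image8 intensities must be integer-valued")
  if (min(m) < 0 || max(m) > 255) return("Image8 intensities must lie in [0, 255]")
  TRUE
})

#' RGB colour image
#'
#' A height x width x 3 array of channel intensities in [0, 255], as read from
#' a colour micrograph before 8-bit conversion.
#'
#' @slot .Data numeric array with third dimension of extent 3.
#' @export
setClass("ImageRGB", contains = "array", validity = function(object) {
  a <- object@.Data
  if (length(dim(a)) != 3L || dim(a)[3L] != 3L)
    return("ImageRGB must be a height x width x 3 array")
  if (dim(a)[1L] < 1L || dim(a)[2L] < 1L)
    return("ImageRGB must have positive dimensions")
  if (anyNA(a)) return("ImageRGB intensities must not contain NA")
  if (min(a) < 0 || max(a) > 255) return("ImageRGB intensities must lie in [0, 255]")
  TRUE
})

#' Binary pixel mask
#'
#' A logical matrix marking pixel membership (e.g. threshold-positive pixels,
#' a manually drawn vessel region, or synthetic ground-truth deposits).
#'
#' @slot .Data logical matrix.
#' @export
setClass("BinaryMask", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (length(dim(m)) != 2L) return("BinaryMask must be a 2-D matrix")
  if (!is.logical(m)) return("BinaryMask must be logical")
  if (anyNA(m)) return("BinaryMask must not contain NA")
  TRUE
})

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Unsharp-mask parameters
#'
#' @slot radius Gaussian scale (sigma) in pixels; must be > 0.
#' @slot weight mask weight w in [0, 1); the filter computes
#'   (I - w * G_sigma(I)) / (1 - w).
#' @export
setClass("EnhanceParams",
  representation(radius = "numeric", weight = "numeric"),
  validity = function(object) {
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
      return("radius must be a single positive number")
    if (length(object@weight) != 1L || !is.finite(object@weight) ||
        object@weight < 0 || object@weight >= 1)
      return("weight must be a single number in [0, 1)")
    TRUE
  })

#' Particle scoring parameters
#'
#' Threshold, polarity, size window, circularity window and connectivity used
#' by the particle-analysis stage.
#'
#' @slot threshold intensity threshold in [0, 255].
#' @slot polarity "dark" (positive iff intensity <= threshold; DAB is dark on
#'   a light background) or "bright" (>= threshold).
#' @slot sizeMin,sizeMax inclusive particle area window in pixel^2.
#' @slot circMin,circMax inclusive circularity window in [0, 1].
#' @slot connectivity pixel adjacency, 4 or 8.
#' @export
setClass("ScoreParams",
  representation(threshold = "numeric", polarity = "character",
                 sizeMin = "numeric", sizeMax = "numeric",
                 circMin = "numeric", circMax = "numeric",
                 connectivity = "integer"),
  validity = function(object) {
    if (object@threshold < 0 || object@threshold > 255)
      return("threshold must lie in [0, 255]")
    if (!object@polarity %in% c("dark", "bright"))
      return("polarity must be \"dark\" or \"bright\"")
    if (object@sizeMin < 0 || object@sizeMin > object@sizeMax)
      return("need 0 <= sizeMin <= sizeMax")
    if (object@circMin < 0 || object@circMin > object@circMax ||
        object@circMax > 1)
      return("need 0 <= circMin <= circMax <= 1")
    if (!object@connectivity %in% c(4L, 8L))
      return("connectivity must be 4 or 8")
    TRUE
  })

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Per-image particle score
#'
#' @slot score total retained particle area (pixel^2) -- the NOTCH3 score.
#' @slot nTotal,nRetained particle counts before/after filtering.
#' @slot particles data.frame of per-particle measurements with a logical
#'   `retained` column.
#' @slot params the \linkS4class{ScoreParams} used.
#' @export
setClass("ScoreResult",
  representation(score = "numeric", nTotal = "integer", nRetained = "integer",
                 particles = "data.frame", params = "ScoreParams"),
  validity = function(object) {
    if (object@score < 0) return("score must be non-negative")
    if (object@nRetained > object@nTotal)
      return("retained count cannot exceed total count")
    TRUE
  })

#' Vessel-restricted score (human variant)
#'
#' @slot vesselArea vessel mask area in pixel^2.
#' @slot positiveArea threshold-positive area within the vessel, pixel^2.
#' @slot score 100 * positiveArea / vesselArea (percentage of vessel area).
#' @export
setClass("VesselScoreResult",
  representation(vesselArea = "numeric", positiveArea = "numeric",
                 score = "numeric"),
  validity = function(object) {
    if (object@vesselArea < 1) return("vessel area must be >= 1 pixel")
    if (object@positiveArea < 0 || object@positiveArea > object@vesselArea)
      return("need 0 <= positiveArea <= vesselArea")
    TRUE
  })

#' Group summary statistics
#'
#' @slot label group label (strain, age or diagnosis).
#' @slot n group size.
#' @slot mean,sd summary statistics in score units (sd is NA when n = 1).
#' @export
setClass("GroupSummary",
  representation(label = "character", n = "integer", mean = "numeric",
                 sd = "numeric"),
  validity = function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
    if (object@n >= 2L && is.na(object@sd)) return("sd required when n >= 2")
    TRUE
  })

#' Hypothesis-test result
#'
#' @slot statistic test statistic (t or F).
#' @slot df degrees of freedom (length 1 for t, length 2 for F).
#' @slot pValue two-sided p-value.
#' @slot method short description of the test performed.
#' @slot details optional data.frame of auxiliary results (e.g. the Fisher
#'   LSD pairwise table, or the interaction estimate of a slope comparison).
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character", details = "data.frame"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("p-value must lie in [0, 1]")
    TRUE
  })

#' Linear progression fit
#'
#' @slot slope,intercept ordinary least-squares estimates (score units per
#'   week, score units).
#' @slot slopeSE standard error of the slope.
#' @slot df residual degrees of freedom.
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", slopeSE = "numeric",
                 df = "numeric"),
  validity = function(object) {
    if (object@slopeSE < 0) return("slopeSE must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## Synthetic-data classes
## ---------------------------------------------------------------------------

#' Recipe for one synthetic stained field
#'
#' Describes a DAB-like brightfield field: a light tissue background, a
#' vessel-wall ring, and dark granular deposits placed on the wall.
#'
#' @slot width,height field size in pixels.
#' @slot backgroundMean,backgroundSD background intensity and additive
#'   Gaussian pixel noise SD (noise applied to the whole field, clipped).
#' @slot center vessel ring centre (row, col), 1-based.
#' @slot innerRadius,outerRadius vessel wall annulus radii in pixels.
#' @slot wallIntensity vessel wall intensity (lighter than deposits, darker
#'   than background).
#' @slot nDeposits number of deposits to place.
#' @slot depositRadii candidate deposit radii (pixels); each deposit draws one
#'   uniformly.
#' @slot depositIntensityMean,depositIntensitySD per-deposit intensity
#'   distribution (clamped to [60, 120] so deposits stay threshold-positive).
#' @slot minGap minimum edge-to-edge gap between deposits in pixels.
#' @slot seed RNG seed (NA for current RNG state).
#' @export
setClass("FieldSpec",
  representation(width = "integer", height = "integer",
                 backgroundMean = "numeric", backgroundSD = "numeric",
                 center = "numeric", innerRadius = "numeric",
                 outerRadius = "numeric", wallIntensity = "numeric",
                 nDeposits = "integer", depositRadii = "numeric",
                 depositIntensityMean = "numeric",
                 depositIntensitySD = "numeric",
                 minGap = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@width < 8L || object@height < 8L)
      return("field must be at least 8 x 8 pixels")
    if (object@outerRadius <= object@innerRadius)
      return("outerRadius must exceed innerRadius")
    if (length(object@center) != 2L) return("center must be (row, col)")
    r <- object@outerRadius
    if (object@center[1L] - r < 1 || object@center[1L] + r > object@height ||
        object@center[2L] - r < 1 || object@center[2L] + r > object@width)
      return("vessel ring must fit inside the frame")
    if (object@nDeposits < 0L) return("nDeposits must be >= 0")
    if (any(object@depositRadii <= 0)) return("deposit radii must be positive")
    if (object@backgroundSD < 0) return("backgroundSD must be >= 0")
    if (object@minGap < 0) return("minGap must be >= 0")
    if (object@depositIntensityMean >= object@backgroundMean)
      return("deposits must be darker than the background")
    TRUE
  })

#' A rendered synthetic field with ground truth
#'
#' @slot image the rendered \linkS4class{Image8}.
#' @slot truthMask \linkS4class{BinaryMask} marking exactly the deposit pixels.
#' @slot deposits data.frame with one row per deposit (centre, radius,
#'   rasterised pixel area, intensity).
#' @slot totalDepositArea total true deposit area in pixel^2.
#' @export
setClass("SyntheticField",
  representation(image = "Image8", truthMask = "BinaryMask",
                 deposits = "data.frame", totalDepositArea = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@truthMask)))
      return("image and truth mask dimensions must match")
    if (object@totalDepositArea != sum(object@truthMask@.Data))
      return("totalDepositArea must equal the truth-mask member count")
    TRUE
  })

#' Recipe for a synthetic strain x age cohort
#'
#' The expected number of deposits per field follows the accumulation-load
#' model L(age, e) = rate * e * max(0, age - onset(e)), where e is the
#' relative transgene expression multiplier and onset(e) decreases with
#' expression (higher expression, earlier onset). Per-field deposit counts
#' are Poisson with mean L.
#'
#' @slot strains data.frame with columns label, expression, onsetWeeks.
#' @slot ages ages in weeks at which mice are sampled.
#' @slot micePerGroup mice per strain x age cell.
#' @slot fieldsPerMouse images per mouse.
#' @slot rate deposits per week per unit expression.
#' @slot fieldSpec template \linkS4class{FieldSpec} for each rendered field
#'   (its nDeposits and seed are overridden per field).
#' @slot seed RNG seed for the whole cohort.
#' @export
setClass("CohortSpec",
  representation(strains = "data.frame", ages = "numeric",
                 micePerGroup = "integer", fieldsPerMouse = "integer",
                 rate = "numeric", fieldSpec = "FieldSpec", seed = "numeric"),
  validity = function(object) {
    need <- c("label", "expression", "onsetWeeks")
    if (!all(need %in% names(object@strains)))
      return("strains must have columns label, expression, onsetWeeks")
    s <- object@strains[order(object@strains$expression), ]
    if (is.unsorted(rev(s$onsetWeeks)))
      return("onset must be non-increasing in expression level")
    if (object@micePerGroup < 1L || object@fieldsPerMouse < 1L)
      return("need at least one mouse and one field per mouse")
    if (object@rate < 0) return("rate must be >= 0")
    TRUE
  })

#' Scored cohort
#'
#' Container returned by [runCohort()]: tidy per-image and per-subject score
#' tables, per (group, age) summaries, recorded failures and the parameters
#' used (a provenance record sufficient to regenerate every downstream
#' statistic).
#'
#' @slot imageTable data.frame with one row per scored image.
#' @slot subjectTable data.frame with one row per subject
#'   (subject, group, age_weeks, n_images, score).
#' @slot groupTable data.frame of per (group, age) summaries (n, mean, sd).
#' @slot failures data.frame of images that could not be scored.
#' @slot params list recording scoring parameters and aggregation rule.
#' @export
setClass("CohortScores",
  representation(imageTable = "data.frame", subjectTable = "data.frame",
                 groupTable = "data.frame", failures = "data.frame",
                 params = "list"))
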