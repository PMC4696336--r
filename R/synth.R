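#' @include particles.R
NULL

## Default study conditions for the synthetic generator. Intensities are
## chosen so that, after the default unsharp mask (sigma 1, weight 0.6), the
## threshold-150 positive set equals the deposit set exactly in the
## noise-free case: background 235 and wall 215 stay well above 150 even
## with edge overshoot, deposits (clamped to [60, 120]) stay below it.
## Deposit radii {1.5, 2.5} rasterise (with centres snapped to pixel
## centres) to fixed digital shapes of area 9 and 21 whose crack-boundary
## circularities (0.785, 0.659) pass the default 0.50-1.00 window, so
## ground-truth recovery is exact rather than approximate.
DEPOSIT_INTENSITY_RANGE <- c(60, 120)

#' Synthetic field recipe
#'
#' Constructor for \linkS4class{FieldSpec} with the package's default study
#' conditions: a 256 x 256 field, background 235 with additive Gaussian
#' noise SD 8, a vessel-wall ring (inner radius 80, outer 96) at intensity
#' 215, and dark granular deposits (radii drawn from {1.5, 2.5} px,
#' intensity ~ N(90, 8) clamped to [60, 120]) placed uniformly on the wall
#' with a minimum edge-to-edge gap of 2 px.
#'
#' @param width,height field size in pixels.
#' @param nDeposits number of deposits to place.
#' @param backgroundMean,backgroundSD background intensity and noise SD.
#' @param center ring centre (row, col); defaults to the field centre.
#' @param innerRadius,outerRadius wall annulus radii.
#' @param wallIntensity wall intensity.
#' @param depositRadii candidate deposit radii.
#' @param depositIntensityMean,depositIntensitySD deposit intensity model.
#' @param minGap minimum edge-to-edge deposit gap, pixels.
#' @param seed RNG seed (NA = use current RNG state).
#' @return a \linkS4class{FieldSpec}.
#' @export
FieldSpec <- function(width = 256L, height = 256L, nDeposits = 20L,
                      backgroundMean = 235, backgroundSD = 8,
                      center = c((height + 1) / 2, (width + 1) / 2),
                      innerRadius = 80, outerRadius = 96,
                      wallIntensity = 215,
                      depositRadii = c(1.5, 2.5),
                      depositIntensityMean = 90, depositIntensitySD = 8,
                      minGap = 2, seed = NA_real_) {
  new("FieldSpec", width = as.integer(width), height = as.integer(height),
      backgroundMean = backgroundMean, backgroundSD = backgroundSD,
      center = center, innerRadius = innerRadius, outerRadius = outerRadius,
      wallIntensity = wallIntensity, nDeposits = as.integer(nDeposits),
      depositRadii = depositRadii,
      depositIntensityMean = depositIntensityMean,
      depositIntensitySD = depositIntensitySD,
      minGap = minGap, seed = as.numeric(seed))
}

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf(
    "FieldSpec: %d x %d px, %d deposits on ring r = [%g, %g], noise SD %g\n",
    object@height, object@width, object@nDeposits, object@innerRadius,
    object@outerRadius, object@backgroundSD))
})

setMethod("show", "SyntheticField", function(object) {
  cat(sprintf(
    "SyntheticField: %d deposits, true total area %g px^2\n",
    nrow(object@deposits), object@totalDepositArea))
  show(object@image)
})

#' @describeIn truthArea true total deposit area.
#' @export
setMethod("truthArea", "SyntheticField", function(object)
  object@totalDepositArea)

## internal: rasterise a disc of given radius centred on a pixel centre;
## returns linear (column-major) pixel indices
disc_pixels <- function(cy, cx, r, H, W) {
  rr <- floor(r)
  rows <- (cy - rr):(cy + rr)
  cols <- (cx - rr):(cx + rr)
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
  g <- g[keep & g$row >= 1 & g$row <= H & g$col >= 1 & g$col <= W, ]
  (g$col - 1L) * H + g$row
}

render_field_impl <- function(spec) {
  H <- spec@height; W <- spec@width
  cr <- spec@center[1L]; cc <- spec@center[2L]
  base <- matrix(spec@backgroundMean, H, W)
  d <- sqrt((row(base) - cr)^2 + (col(base) - cc)^2)
  base[d >= spec@innerRadius & d <= spec@outerRadius] <- spec@wallIntensity

  n <- spec@nDeposits
  dep <- data.frame(row = integer(), col = integer(), radius = numeric(),
                    area = numeric(), intensity = numeric())
  truth <- matrix(FALSE, H, W)
  if (n > 0L) {
    placedR <- numeric(0); placedC <- numeric(0); placedRad <- numeric(0)
    maxTries <- 500L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        r <- spec@depositRadii[sample.int(length(spec@depositRadii), 1L)]
        theta <- stats::runif(1, 0, 2 * pi)
        lo <- spec@innerRadius + r; hi <- spec@outerRadius - r
        if (hi <= lo) stop("wall too thin for deposit radius ", r)
        rad <- stats::runif(1, lo, hi)
        ## snap centres to pixel centres so each radius rasterises to a
        ## fixed digital shape with known area and circularity
        py <- round(cr + rad * sin(theta))
        px <- round(cc + rad * cos(theta))
        if (py - r < 1 || py + r > H || px - r < 1 || px + r > W) next
        if (length(placedR)) {
          dd <- sqrt((placedR - py)^2 + (placedC - px)^2)
          if (any(dd < placedRad + r + spec@minGap)) next
        }
        placedR <- c(placedR, py); placedC <- c(placedC, px)
        placedRad <- c(placedRad, r)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("deposit placement infeasible after ", maxTries,
             " retries; placed ", i - 1L, " of ", n, " deposits")
    }
    ints <- pmin(pmax(stats::rnorm(n, spec@depositIntensityMean,
                                   spec@depositIntensitySD),
                      DEPOSIT_INTENSITY_RANGE[1L]),
                 DEPOSIT_INTENSITY_RANGE[2L])
    ints <- round(ints)
    areas <- numeric(n)
    for (i in seq_len(n)) {
      px <- disc_pixels(placedR[i], placedC[i], placedRad[i], H, W)
      truth[px] <- TRUE
      base[px] <- ints[i]
      areas[i] <- length(px)
    }
    dep <- data.frame(row = placedR, col = placedC, radius = placedRad,
                      area = areas, intensity = ints)
  }
  if (spec@backgroundSD > 0) {
    base <- base + matrix(stats::rnorm(H * W, 0, spec@backgroundSD), H, W)
  }
  img <- Image8(pmin(pmax(round_half_up(base), 0), 255))
  new("SyntheticField", image = img, truthMask = BinaryMask(truth),
      deposits = dep, totalDepositArea = sum(dep$area))
}

#' @describeIn renderField deterministic for a fixed seed; errors with a
#'   placement report if the requested deposits cannot fit on the wall.
#' @export
setMethod("renderField", "FieldSpec", function(spec) {
  if (is.na(spec@seed)) render_field_impl(spec)
  else withr::with_seed(as.integer(spec@seed), render_field_impl(spec))
})

## ---------------------------------------------------------------------------
## Cohorts
## ---------------------------------------------------------------------------

#' Default strain table
#'
#' Expression multipliers 1.0/1.5/2.0/3.5 (i.e. 100/150/200/350% of
#' endogenous expression) with onsets of first detectable accumulation at
#' 52/22/13/6 weeks: higher expression, earlier onset.
#'
#' @return data.frame with columns label, expression, onsetWeeks.
#' @export
defaultStrains <- function() {
  data.frame(
    label = c("tgN3MUT100", "tgN3MUT150", "tgN3MUT200", "tgN3MUT350"),
    expression = c(1.0, 1.5, 2.0, 3.5),
    onsetWeeks = c(52, 22, 13, 6))
}

#' Synthetic cohort recipe
#'
#' Constructor for \linkS4class{CohortSpec}. Defaults follow the study
#' design being emulated: 4 expression levels, sampling ages 6/24/52/82
#' weeks, 3 mice per strain x age, 10 fields per mouse, and an
#' accumulation-load model L(age, e) = rate * e * max(0, age - onset(e))
#' expected deposits per field with rate = 0.15 deposits/week.
#'
#' @param strains data.frame(label, expression, onsetWeeks).
#' @param ages sampling ages, weeks.
#' @param micePerGroup mice per strain x age cell.
#' @param fieldsPerMouse images per mouse.
#' @param rate deposits per week per unit expression.
#' @param fieldSpec template \linkS4class{FieldSpec}; its nDeposits and seed
#'   are overridden per field.
#' @param seed cohort RNG seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
CohortSpec <- function(strains = defaultStrains(), ages = c(6, 24, 52, 82),
                       micePerGroup = 3L, fieldsPerMouse = 10L, rate = 0.15,
                       fieldSpec = FieldSpec(), seed = NA_real_) {
  new("CohortSpec", strains = strains, ages = as.numeric(ages),
      micePerGroup = as.integer(micePerGroup),
      fieldsPerMouse = as.integer(fieldsPerMouse), rate = rate,
      fieldSpec = fieldSpec, seed = as.numeric(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d strains x %d ages, %d mice x %d fields, rate %g deposits/week\n",
    nrow(object@strains), length(object@ages), object@micePerGroup,
    object@fieldsPerMouse, object@rate))
})

#' Expected deposit load per field
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return data.frame per strain x age cell with the expected deposit count
#'   per field (`expectedLoad`). Monotone non-decreasing in age within each
#'   strain and, at fixed age, non-decreasing in expression.
#' @export
expectedLoad <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  g <- expand.grid(strain = spec@strains$label, age = spec@ages,
                   stringsAsFactors = FALSE)
  i <- match(g$strain, spec@strains$label)
  g$expression <- spec@strains$expression[i]
  g$onsetWeeks <- spec@strains$onsetWeeks[i]
  g$expectedLoad <- spec@rate * g$expression * pmax(0, g$age - g$onsetWeeks)
  g[order(g$strain, g$age), ]
}

simulate_cohort_impl <- function(spec, outDir) {
  loads <- expectedLoad(spec)
  cells <- loads[rep(seq_len(nrow(loads)),
                     each = spec@micePerGroup * spec@fieldsPerMouse), ]
  nPer <- spec@micePerGroup * spec@fieldsPerMouse
  cells$mouse <- rep(rep(seq_len(spec@micePerGroup),
                         each = spec@fieldsPerMouse), nrow(loads))
  cells$field <- rep(seq_len(spec@fieldsPerMouse), nrow(loads) * spec@micePerGroup)
  cells$subject <- sprintf("%s_age%03d_m%d", cells$strain,
                           as.integer(cells$age), as.integer(cells$mouse))
  nF <- nrow(cells)
  cells$nDeposits <- stats::rpois(nF, cells$expectedLoad)
  fieldSeeds <- sample.int(.Machine$integer.max - 1L, nF)
  images <- vector("list", nF)
  truthArea <- numeric(nF)
  writeOut <- !is.null(outDir)
  if (writeOut) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nF)
  for (k in seq_len(nF)) {
    fs <- spec@fieldSpec
    fs@nDeposits <- cells$nDeposits[k]
    fs@seed <- fieldSeeds[k]
    fld <- renderField(fs)
    truthArea[k] <- fld@totalDepositArea
    if (writeOut) {
      base <- sprintf("%s_f%02d", cells$subject[k], cells$field[k])
      paths[k] <- file.path(outDir, paste0(base, ".png"))
      writeImage(fld@image, paths[k])
      writeImage(fld@truthMask, file.path(outDir, paste0(base, "_truth.png")))
    } else {
      images[[k]] <- fld@image
    }
  }
  design <- data.frame(subject = cells$subject, group = cells$strain,
                       age_weeks = cells$age, mouse = cells$mouse,
                       field = cells$field, stringsAsFactors = FALSE)
  if (writeOut) design$image <- paths else design$image <- I(images)
  truth <- cbind(design[c("subject", "group", "age_weeks", "mouse", "field")],
                 data.frame(nDeposits = cells$nDeposits,
                            trueArea = truthArea))
  if (writeOut) {
    tw <- truth
    utils::write.csv(tw, file.path(outDir, "truth.csv"), row.names = FALSE)
  }
  list(design = design, truth = truth, expected = loads)
}

#' @describeIn simulateCohort per-field deposit counts are Poisson with the
#'   model mean; fully reproducible under the cohort seed.
#' @export
setMethod("simulateCohort", "CohortSpec", function(spec, outDir = NULL) {
  if (is.na(spec@seed)) simulate_cohort_impl(spec, outDir)
  else withr::with_seed(as.integer(spec@seed),
                        simulate_cohort_impl(spec, outDir))
})
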