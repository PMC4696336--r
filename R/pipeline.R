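#' @include synth.R vessel.R
NULL

## internal: resolve one design "image" entry (path, Image8, or matrix)
resolve_image <- function(x) {
  if (is.character(x)) {
    img <- loadImage(x)
    if (is(img, "ImageRGB")) img <- toGray8(img)
    img
  } else {
    as_image8(x)
  }
}

#' Score a subject's images
#'
#' Scores each image with [notch3Score()] and aggregates to a per-subject
#' value. The default aggregate is the mean of per-image scores, which keeps
#' subjects with different image counts comparable; the sum is available for
#' strict replication of total-area bookkeeping. Unreadable images are
#' recorded as failures and the run continues; the aggregate is then over
#' the scored images and flagged.
#'
#' @param images list of image paths, \linkS4class{Image8} objects or
#'   intensity matrices (>= 1).
#' @param enhance an \linkS4class{EnhanceParams} or NULL.
#' @param params a \linkS4class{ScoreParams}.
#' @param aggregate "mean" (default) or "sum".
#' @return a list with `perImage` (data.frame: image, score, nParticles),
#'   `aggregate` (per-subject value), `nScored`, `failures` (data.frame:
#'   image, error) and `complete` (TRUE iff no failures).
#' @export
scoreSubject <- function(images, enhance = EnhanceParams(),
                         params = ScoreParams(),
                         aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.character(images)) images <- as.list(images)
  if (!is.list(images)) images <- list(images)
  if (length(images) == 0) stop("need at least one image")
  ids <- names(images)
  if (is.null(ids)) {
    ids <- vapply(seq_along(images), function(i) {
      if (is.character(images[[i]])) images[[i]] else sprintf("image_%02d", i)
    }, character(1))
  }
  rows <- vector("list", length(images))
  fails <- list()
  for (i in seq_along(images)) {
    res <- tryCatch(notch3Score(resolve_image(images[[i]]), enhance, params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(image = ids[i], error = conditionMessage(res))
    } else {
      rows[[i]] <- data.frame(image = ids[i], score = score(res),
                              nParticles = nParticles(res))
    }
  }
  perImage <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(image = character(), error = character())
  if (is.null(perImage) || nrow(perImage) == 0)
    stop("no image could be scored; first error: ", failures$error[1L])
  agg <- if (aggregate == "mean") mean(perImage$score) else sum(perImage$score)
  list(perImage = perImage, aggregate = agg, nScored = nrow(perImage),
       failures = failures, complete = nrow(failures) == 0L)
}

#' Score a whole cohort
#'
#' Runs multi-image, multi-subject scoring (the "10 images per mouse, 3 mice
#' per time point" design) and produces analysis-ready tables: one row per
#' image, one row per subject, and per (group, age) summaries that feed the
#' statistics layer directly.
#'
#' @param design data.frame with columns `subject`, `group`, `age_weeks` and
#'   `image` (file paths, or a list column of \linkS4class{Image8}s, e.g.
#'   from [simulateCohort()]); for `variant = "human"` also `mask` (paths or
#'   \linkS4class{BinaryMask}s).
#' @param variant "mouse" (particle score, default) or "human"
#'   (vessel-masked score).
#' @param enhance an \linkS4class{EnhanceParams} or NULL; the human variant
#'   defaults to no enhancement.
#' @param params a \linkS4class{ScoreParams}; defaults to the variant's
#'   published threshold (150 mouse, 100 human).
#' @param aggregate per-subject aggregation, "mean" or "sum".
#' @return a \linkS4class{CohortScores}.
#' @export
runCohort <- function(design, variant = c("mouse", "human"),
                      enhance = NULL, params = NULL,
                      aggregate = c("mean", "sum")) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  need <- c("subject", "group", "age_weeks", "image")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("design must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(design) == 0) stop("empty cohort design")
  if (variant == "human" && !"mask" %in% names(design))
    stop("the human variant requires a mask per image")
  if (is.null(params))
    params <- if (variant == "mouse") ScoreParams()
              else ScoreParams(threshold = 100)
  if (is.null(enhance) && variant == "mouse") enhance <- EnhanceParams()

  rows <- vector("list", nrow(design))
  fails <- list()
  for (i in seq_len(nrow(design))) {
    res <- tryCatch({
      img <- resolve_image(design$image[[i]])
      if (variant == "mouse") {
        score(notch3Score(img, enhance, params))
      } else {
        msk <- design$mask[[i]]
        msk <- if (is.character(msk)) loadMask(msk) else as_mask(msk)
        score(vesselMaskedScore(img, msk, params, enhance = enhance))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject = design$subject[i], row = i,
        error = conditionMessage(res))
    } else {
      rows[[i]] <- data.frame(subject = design$subject[i],
                              group = design$group[i],
                              age_weeks = design$age_weeks[i],
                              row = i, score = res)
    }
  }
  imageTable <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(subject = character(), row = integer(),
                              error = character())
  if (is.null(imageTable) || nrow(imageTable) == 0)
    stop("no image in the design could be scored")
  imageTable <- imageTable[order(imageTable$subject, imageTable$row), ]
  rownames(imageTable) <- NULL

  aggfun <- if (aggregate == "mean") mean else sum
  sp <- split(imageTable, imageTable$subject)
  subjectTable <- do.call(rbind, lapply(sp, function(d) {
    data.frame(subject = d$subject[1L], group = d$group[1L],
               age_weeks = d$age_weeks[1L], n_images = nrow(d),
               score = aggfun(d$score))
  }))
  subjectTable <- subjectTable[order(subjectTable$group,
                                     subjectTable$age_weeks,
                                     subjectTable$subject), ]
  rownames(subjectTable) <- NULL

  gs <- split(subjectTable, list(subjectTable$group, subjectTable$age_weeks),
              drop = TRUE)
  groupTable <- do.call(rbind, lapply(gs, function(d) {
    data.frame(group = d$group[1L], age_weeks = d$age_weeks[1L],
               n = nrow(d), mean = mean(d$score),
               sd = if (nrow(d) >= 2) stats::sd(d$score) else NA_real_)
  }))
  groupTable <- groupTable[order(groupTable$group, groupTable$age_weeks), ]
  rownames(groupTable) <- NULL

  new("CohortScores", imageTable = imageTable, subjectTable = subjectTable,
      groupTable = groupTable, failures = failures,
      params = list(variant = variant, aggregate = aggregate,
                    enhance = enhance, score = params))
}

#' @describeIn subjectScores per-subject tidy table.
#' @export
setMethod("subjectScores", "CohortScores", function(object)
  object@subjectTable)

#' @describeIn groupSummaries per (group, age) summary table.
#' @export
setMethod("groupSummaries", "CohortScores", function(object)
  object@groupTable)

setMethod("show", "CohortScores", function(object) {
  cat(sprintf(
    "CohortScores: %d images, %d subjects, %d group x age cells (%d failures)\n",
    nrow(object@imageTable), nrow(object@subjectTable),
    nrow(object@groupTable), nrow(object@failures)))
})

#' Turn a group-summary row into a \linkS4class{GroupSummary}
#'
#' Convenience bridge from [groupSummaries()] output to
#' [tTestFromSummary()].
#'
#' @param groupTable a data.frame as returned by [groupSummaries()].
#' @param group,age_weeks cell selector.
#' @return a \linkS4class{GroupSummary}.
#' @export
cellSummary <- function(groupTable, group, age_weeks) {
  r <- groupTable[groupTable$group == group &
                  groupTable$age_weeks == age_weeks, ]
  if (nrow(r) != 1L) stop("cell not found (or not unique) in group table")
  GroupSummary(sprintf("%s@%gw", group, age_weeks), r$n, r$mean, r$sd)
}

#' Write cohort tables to CSV
#'
#' Emits per-image, per-subject and group-summary CSVs; the tidy tables are
#' sufficient to regenerate every group summary and statistical result.
#'
#' @param scores a \linkS4class{CohortScores}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohortTables <- function(scores, dir) {
  stopifnot(is(scores, "CohortScores"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scores@imageTable, file.path(dir, "per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(scores@subjectTable, file.path(dir, "per_subject.csv"),
                   row.names = FALSE)
  utils::write.csv(scores@groupTable, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  if (nrow(scores@failures))
    utils::write.csv(scores@failures, file.path(dir, "failures.csv"),
                     row.names = FALSE)
  invisible(dir)
}
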