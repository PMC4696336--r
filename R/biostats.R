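#' @include AllGenerics.R
NULL

#' Group summary
#'
#' @param label group label.
#' @param n group size (>= 1).
#' @param mean group mean, score units.
#' @param sd sample SD (NA allowed when n = 1).
#' @return a \linkS4class{GroupSummary}.
#' @export
GroupSummary <- function(label, n, mean, sd = NA_real_) {
  new("GroupSummary", label = as.character(label), n = as.integer(n),
      mean = as.numeric(mean), sd = as.numeric(sd))
}

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary '%s': n = %d, mean = %g, sd = %g\n",
              object@label, object@n, object@mean, object@sd))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n  statistic = %.4g, df = %s, p = %.4g\n",
              object@method, object@statistic,
              paste(signif(object@df, 6), collapse = ", "), object@pValue))
  if (nrow(object@details) > 0) {
    cat("  details:\n")
    print(object@details, row.names = FALSE)
  }
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "Progression fit: slope %.4g +/- %.4g (SE) per week, intercept %.4g, residual df %g\n",
    object@slope, object@slopeSE, object@intercept, object@df))
})

#' Two-sample t-test from group summaries
#'
#' Unpaired two-sample t-test computed from (mean, sd, n) summaries.
#' The default is the pooled-variance Student test
#' (df = n_a + n_b - 2); Welch's unequal-variance form is available via
#' `method = "welch"`. Identical to a raw-data `t.test(var.equal = TRUE)`
#' on any data with the same summaries.
#'
#' With the published 20-month summaries (659 +/- 51 vs 1150 +/- 107,
#' n = 3 each) this reproduces t = 7.17 on 4 df, p = 0.002.
#'
#' @param a,b \linkS4class{GroupSummary} objects with n >= 2.
#' @param method "pooled" (default) or "welch".
#' @return a \linkS4class{TestResult} (two-sided p).
#' @examples
#' tTestFromSummary(GroupSummary("tgN3MUT150", 3, 659, 51),
#'                  GroupSummary("tgN3MUT350", 3, 1150, 107))
#' @export
tTestFromSummary <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  stopifnot(is(a, "GroupSummary"), is(b, "GroupSummary"))
  if (a@n < 2L || b@n < 2L)
    stop("both groups need n >= 2 for a two-sample t-test")
  d <- a@mean - b@mean
  if (method == "pooled") {
    df <- a@n + b@n - 2
    sp2 <- ((a@n - 1) * a@sd^2 + (b@n - 1) * b@sd^2) / df
    se <- sqrt(sp2 * (1 / a@n + 1 / b@n))
  } else {
    va <- a@sd^2 / a@n; vb <- b@sd^2 / b@n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a@n - 1) + vb^2 / (b@n - 1))
  }
  tstat <- d / se
  new("TestResult", statistic = tstat, df = df,
      pValue = 2 * stats::pt(-abs(tstat), df),
      method = sprintf("Unpaired two-sample t-test (%s variance), %s vs %s",
                       if (method == "pooled") "pooled" else "Welch",
                       a@label, b@label),
      details = data.frame())
}

#' One-way ANOVA with Fisher's LSD post-hoc comparisons
#'
#' Omnibus one-way ANOVA (via [stats::aov()]) followed by Fisher's least
#' significant difference pairwise tests: for groups i, j,
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` on the residual
#' (MSE) degrees of freedom, with *unadjusted* two-sided p-values -- that is
#' what Fisher's LSD is; interpret the pairwise table only after a
#' significant omnibus F, and note the multiplicity.
#'
#' @param values numeric vector of observations, or a list of numeric
#'   vectors (one per group, `groups` then ignored).
#' @param groups group labels parallel to `values`.
#' @return a \linkS4class{TestResult} holding the omnibus F (df pair) and,
#'   in `@details`, the pairwise LSD table (groupA, groupB, diff, t, df, p).
#' @export
anovaLSD <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    if (!is.null(names(values))) groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dd <- means[i] - means[j]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tt <- dd / se
    data.frame(groupA = lev[i], groupB = lev[j], diff = as.numeric(dd),
               t = as.numeric(tt), df = dfe,
               p = 2 * stats::pt(-abs(tt), dfe))
  }))
  new("TestResult",
      statistic = an["g", "F value"], df = c(an["g", "Df"], dfe),
      pValue = an["g", "Pr(>F)"],
      method = "One-way ANOVA with Fisher's LSD post-hoc (unadjusted pairwise p)",
      details = lsd)
}

#' Fit the progression of a score over age
#'
#' Ordinary least-squares regression of score on age; the slope is the rate
#' of increase of the score per week and its standard error comes from the
#' residual variance.
#'
#' @param ages ages in weeks (>= 3 points, >= 2 distinct ages).
#' @param scores scores, parallel to `ages`.
#' @return a \linkS4class{RegressionFit}.
#' @export
fitProgression <- function(ages, scores) {
  stopifnot(length(ages) == length(scores))
  if (length(ages) < 3L) stop("need at least 3 points")
  if (length(unique(ages)) < 2L)
    stop("all ages identical; the slope is undefined")
  fit <- stats::lm(scores ~ ages)
  ## an exactly linear input is legitimate here (slopeSE = 0), so silence
  ## summary.lm's perfect-fit warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  se <- cf["ages", "Std. Error"]
  if (!is.finite(se)) se <- 0       # exact fit: zero residual variance
  new("RegressionFit", slope = cf["ages", "Estimate"],
      intercept = cf["(Intercept)", "Estimate"],
      slopeSE = se, df = fit$df.residual)
}

#' Compare progression slopes between two groups
#'
#' Tests slope equality through the age x group interaction of a common
#' linear model `score ~ age * group` (pooled residual variance); the
#' reported statistic is the interaction coefficient's t, with a two-sided
#' p. This is the standard ANCOVA-style slope-equality test.
#'
#' @param agesA,scoresA data for group A.
#' @param agesB,scoresB data for group B.
#' @return a \linkS4class{TestResult}; `@details` holds the interaction
#'   estimate (slope difference B - A) and its SE.
#' @export
compareSlopes <- function(agesA, scoresA, agesB, scoresB) {
  stopifnot(length(agesA) == length(scoresA),
            length(agesB) == length(scoresB))
  age <- c(agesA, agesB)
  sc <- c(scoresA, scoresB)
  grp <- factor(rep(c("A", "B"), c(length(agesA), length(agesB))))
  fit <- stats::lm(sc ~ age * grp)
  cf <- summary(fit)$coefficients
  row <- "age:grpB"
  new("TestResult", statistic = cf[row, "t value"], df = fit$df.residual,
      pValue = cf[row, "Pr(>|t|)"],
      method = "Slope comparison via age x group interaction (pooled OLS)",
      details = data.frame(slopeDiff = cf[row, "Estimate"],
                           se = cf[row, "Std. Error"]))
}

#' Sample size for detecting a treatment effect on progression
#'
#' Smallest integer group size n such that a two-sided two-sample t-test has
#' at least the target power to detect a reduction of
#' `effectFraction * baselineProgression` in the endpoint, given a
#' between-animal SD. A normal-approximation start
#' `n0 = 2 (z_{1-alpha/2} + z_{1-beta})^2 sd^2 / delta^2` is refined by
#' exact noncentral-t power iteration ([stats::power.t.test()]).
#'
#' Defaults alpha = 0.05 (two-sided) and power = 0.80 are conventions, not
#' published values; all inputs behind a published "n mice detect an x%
#' effect" style claim (variance source, alpha, power, endpoint definition)
#' are exposed as parameters rather than guessed.
#'
#' @param effectFraction fraction of the baseline progression to detect
#'   (0 < effectFraction <= 1; 0.5 = a 50% effect).
#' @param baselineProgression expected progression in the untreated group,
#'   score units (e.g. slope x treatment duration).
#' @param sd between-animal SD of the endpoint, score units.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return a list with n (per group), achieved power at n, delta, and the
#'   normal-approximation start.
#' @examples
#' sampleSizeProgression(1, baselineProgression = 1, sd = 1)$n   # 17
#' @export
sampleSizeProgression <- function(effectFraction, baselineProgression, sd,
                                  alpha = 0.05, power = 0.80) {
  if (effectFraction <= 0 || effectFraction > 1)
    stop("effectFraction must lie in (0, 1]")
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  delta <- effectFraction * baselineProgression
  if (delta <= 0) stop("effect size must be positive")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n0 <- max(2, ceiling(2 * z^2 * sd^2 / delta^2))
  pow <- function(n) stats::power.t.test(n = n, delta = delta, sd = sd,
                                         sig.level = alpha)$power
  n <- n0
  while (pow(n) < power) n <- n + 1
  while (n > 2 && pow(n - 1) >= power) n <- n - 1
  list(n = as.integer(n), power = pow(n), delta = delta,
       normalApproxN = as.integer(n0), alpha = alpha, targetPower = power)
}
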