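test_that("summary t-test reproduces the published 20-month comparison", {
  a <- GroupSummary("tgN3MUT150", 3, 659, 51)
  b <- GroupSummary("tgN3MUT350", 3, 1150, 107)
  r <- tTestFromSummary(a, b)
  expect_equal(r@df, 4)
  expect_equal(abs(r@statistic), 7.17, tolerance = 0.001)
  expect_equal(round(r@pValue, 3), 0.002)
})

test_that("summary-based t equals the raw-data t-test to >= 10 significant digits", {
  set.seed(51)
  for (i in 1:10) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    x <- sample_with_moments(na, runif(1, 0, 100), runif(1, 1, 20))
    y <- sample_with_moments(nb, runif(1, 0, 100), runif(1, 1, 20))
    r <- tTestFromSummary(GroupSummary("a", na, mean(x), sd(x)),
                          GroupSummary("b", nb, mean(y), sd(y)))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(r@statistic, unname(ref$statistic), tolerance = 1e-11)
    expect_equal(r@pValue, ref$p.value, tolerance = 1e-11)
    w <- tTestFromSummary(GroupSummary("a", na, mean(x), sd(x)),
                          GroupSummary("b", nb, mean(y), sd(y)), "welch")
    refw <- t.test(x, y)
    expect_equal(w@statistic, unname(refw$statistic), tolerance = 1e-11)
    expect_equal(w@pValue, refw$p.value, tolerance = 1e-11)
  }
  ident <- tTestFromSummary(GroupSummary("a", 5, 10, 2),
                            GroupSummary("b", 5, 10, 2))
  expect_equal(ident@statistic, 0)
  expect_equal(ident@pValue, 1)
  expect_error(tTestFromSummary(GroupSummary("a", 1, 5),
                                GroupSummary("b", 3, 5, 1)), "n >= 2")
})

test_that("pooled t-test holds its nominal type-I error under the null", {
  set.seed(52)
  nrep <- 10000
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    x <- rnorm(3); y <- rnorm(3)
    r <- tTestFromSummary(GroupSummary("a", 3, mean(x), sd(x)),
                          GroupSummary("b", 3, mean(y), sd(y)))
    rej[i] <- r@pValue < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("one-way ANOVA with LSD matches hand sums-of-squares and pairwise t", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  r <- anovaLSD(g)
  # independent sums-of-squares arithmetic
  x <- unlist(g); gm <- mean(x)
  means <- sapply(g, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum(sapply(g, function(v) sum((v - mean(v))^2)))
  f <- (ssb / 2) / (ssw / 6)
  expect_equal(r@statistic, f)
  expect_equal(r@df, c(2, 6))
  expect_equal(r@pValue, pf(f, 2, 6, lower.tail = FALSE))
  # LSD pairwise p equal unadjusted pooled-SD pairwise t-tests
  pw <- pairwise.t.test(x, rep(names(g), each = 3), p.adjust.method = "none",
                        pool.sd = TRUE)
  expect_equal(r@details$p[r@details$groupA == "a" & r@details$groupB == "b"],
               pw$p.value["b", "a"])
  expect_equal(r@details$p[r@details$groupA == "a" & r@details$groupB == "c"],
               pw$p.value["c", "a"])
  expect_equal(r@details$p[r@details$groupA == "b" & r@details$groupB == "c"],
               pw$p.value["c", "b"])
})

test_that("two-group ANOVA F equals the squared pooled t with identical p", {
  set.seed(53)
  x <- rnorm(6, 10, 2); y <- rnorm(4, 12, 2)
  r <- anovaLSD(list(x = x, y = y))
  t2 <- tTestFromSummary(GroupSummary("x", 6, mean(x), sd(x)),
                         GroupSummary("y", 4, mean(y), sd(y)))
  expect_equal(r@statistic, t2@statistic^2)
  expect_equal(r@pValue, t2@pValue)
  ident <- anovaLSD(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident@statistic, 0)
  expect_equal(ident@pValue, 1)
  expect_error(anovaLSD(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("progression fits recover exact lines and match the closed form", {
  exact <- fitProgression(c(6, 24, 52, 82), 2 * c(6, 24, 52, 82) + 1)
  expect_equal(exact@slope, 2)
  expect_equal(exact@intercept, 1)
  expect_equal(exact@slopeSE, 0)
  set.seed(54)
  ages <- rep(c(6, 24, 52, 82), each = 3)
  y <- 11.1 * ages + rnorm(12, 0, 30)
  fit <- fitProgression(ages, y)
  # closed-form normal equations
  sxx <- sum((ages - mean(ages))^2)
  slope <- sum((ages - mean(ages)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) + slope * (ages - mean(ages)))
  se <- sqrt(sum(resid^2) / (length(y) - 2) / sxx)
  expect_equal(fit@slope, slope)
  expect_equal(fit@slopeSE, se)
  # duplicating every point keeps the slope but shrinks its SE
  dup <- fitProgression(c(ages, ages), c(y, y))
  expect_equal(dup@slope, fit@slope)
  expect_lt(dup@slopeSE, fit@slopeSE)
  expect_error(fitProgression(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fitProgression(c(1, 2), c(1, 2)), "3 points")
})

test_that("fitted slopes track the programmed progression rates", {
  set.seed(55)
  ages <- rep(c(6, 24, 52, 82), each = 3)
  for (true_slope in c(11.1, 6.2)) {
    err <- se <- numeric(300)
    for (i in 1:300) {
      f <- fitProgression(ages, true_slope * ages + rnorm(12, 0, 60))
      err[i] <- f@slope - true_slope
      se[i] <- f@slopeSE
    }
    expect_lt(abs(mean(err)), 2 * mean(se))
  }
})

test_that("slope comparison matches a design-matrix least-squares oracle", {
  set.seed(56)
  agesA <- rep(c(6, 24, 52, 82), each = 3)
  yA <- 11.1 * agesA + rnorm(12, 0, 40)
  agesB <- agesA
  yB <- 6.2 * agesB + rnorm(12, 0, 40)
  r <- compareSlopes(agesA, yA, agesB, yB)
  gB <- rep(c(0, 1), each = 12)
  X <- cbind(1, c(agesA, agesB), gB, c(agesA, agesB) * gB)
  orc <- oracle_ols(X, c(yA, yB))
  expect_equal(r@statistic, orc$t[4], tolerance = 1e-10)
  expect_equal(r@pValue, orc$p[4], tolerance = 1e-10)
  expect_equal(r@details$slopeDiff, orc$beta[4], tolerance = 1e-10)
  # identical datasets: interaction exactly zero, p = 1
  same <- compareSlopes(agesA, yA, agesA, yA)
  expect_equal(same@details$slopeDiff, 0, tolerance = 1e-12)
  expect_gt(same@pValue, 0.9)
  # steep vs shallow with tiny noise: decisively detected
  set.seed(57)
  steep <- compareSlopes(agesA, 11.1 * agesA + rnorm(12, 0, 1),
                         agesB, 6.2 * agesB + rnorm(12, 0, 1))
  expect_lt(steep@pValue, 0.001)
})

test_that("sample-size computation is exact-t calibrated and Monte-Carlo consistent", {
  r <- sampleSizeProgression(1, baselineProgression = 1, sd = 1)
  expect_equal(r$n, 17L)
  expect_gte(r$power, 0.8)
  # doubling the detectable effect shrinks n roughly four-fold
  r2 <- sampleSizeProgression(0.5, baselineProgression = 2, sd = 1)
  expect_equal(r2$n, 17L)
  big <- sampleSizeProgression(1, baselineProgression = 0.5, sd = 1)
  expect_gt(big$n, 3.5 * r$n)
  expect_lt(big$n, 4.5 * r$n)
  # Monte-Carlo power at the returned n and just below it
  set.seed(58)
  nrep <- 20000
  mc_power <- function(n, delta) {
    x <- matrix(rnorm(nrep * n), nrep)
    y <- matrix(rnorm(nrep * n, mean = delta), nrep)
    mx <- rowMeans(x); my <- rowMeans(y)
    sp2 <- (rowSums((x - mx)^2) + rowSums((y - my)^2)) / (2 * n - 2)
    t <- (my - mx) / sqrt(sp2 * 2 / n)
    mean(2 * pt(-abs(t), 2 * n - 2) < 0.05)
  }
  expect_gte(mc_power(r$n, 1), 0.8 - 0.01)
  expect_lt(mc_power(r$n - 1L, 1), 0.8 + 0.01)
  expect_error(sampleSizeProgression(0, 1, 1), "effectFraction")
  expect_error(sampleSizeProgression(0.5, 1, 0), "sd")
})
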