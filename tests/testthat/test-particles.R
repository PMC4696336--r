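test_that("thresholding matches the per-pixel comparison in both polarities", {
  p <- ScoreParams(threshold = 150)
  expect_equal(sum(thresholdMask(Image8(matrix(255L, 8, 8)), p)@.Data), 0)
  expect_true(all(thresholdMask(Image8(matrix(0L, 8, 8)), p)@.Data))
  set.seed(31)
  m <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  expect_identical(thresholdMask(Image8(m), p)@.Data, m <= 150)
  pb <- ScoreParams(threshold = 150, polarity = "bright")
  expect_identical(thresholdMask(Image8(m), pb)@.Data, m >= 150)
  # boundary value is included under both polarities
  one <- Image8(matrix(150L, 1, 1))
  expect_true(thresholdMask(one, p)@.Data[1, 1])
  expect_true(thresholdMask(one, pb)@.Data[1, 1])
})

test_that("adjacency rules: diagonal pixels merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  lab <- labelComponents(single)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 1)
  expect_equal(max(labelComponents(matrix(FALSE, 4, 4))), 0)
})

test_that("labels are assigned in raster-scan order", {
  m <- matrix(FALSE, 5, 9)
  m[4, 2] <- TRUE          # later row
  m[1, 8] <- TRUE          # first row, right side
  m[2, 4] <- TRUE          # second row
  lab <- labelComponents(m)
  expect_equal(lab[1, 8], 1)
  expect_equal(lab[2, 4], 2)
  expect_equal(lab[4, 2], 3)
})

test_that("hand-countable particles measure exactly", {
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  p1 <- measureParticles(labelComponents(one))
  expect_equal(p1$area, 1)
  expect_equal(p1$perimeter, 4)
  expect_equal(p1$circularity, min(1, 4 * pi / 16))
  sq <- matrix(FALSE, 7, 7); sq[3:5, 3:5] <- TRUE
  p9 <- measureParticles(labelComponents(sq))
  expect_equal(p9$area, 9)
  expect_equal(p9$perimeter, 12)
  expect_equal(p9$circularity, min(1, 4 * pi * 9 / 144))
  expect_equal(p9$centroidRow, 4)
  expect_equal(c(p9$bboxTop, p9$bboxLeft, p9$bboxBottom, p9$bboxRight),
               c(3, 3, 6, 6))
  # a ring: hole boundary counts toward the crack perimeter
  ring <- matrix(FALSE, 6, 6); ring[2:5, 2:5] <- TRUE; ring[3:4, 3:4] <- FALSE
  pr <- measureParticles(labelComponents(ring))
  expect_equal(pr$area, 12)          # holes are not filled
  expect_equal(pr$perimeter, 16 + 8) # outer 4x4 plus inner 2x2 boundary
})

test_that("circularity is capped at 1 and filters use inclusive bounds", {
  set.seed(32)
  for (i in 1:50) {
    m <- matrix(runif(16 * 16) > 0.6, 16, 16)
    pt <- measureParticles(labelComponents(m))
    expect_true(all(pt$circularity <= 1 & pt$circularity >= 0))
  }
  p <- ScoreParams()
  tbl <- data.frame(area = c(31, 30, 29, 1), perimeter = c(24, 20, 20, 4),
                    circularity = c(0.9, 0.50, 0.499, 1))
  out <- filterParticles(tbl, p)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, TRUE))
  # random particle sets match the direct predicate
  set.seed(33)
  rnd <- data.frame(area = sample(0:60, 200, TRUE),
                    circularity = runif(200))
  rnd$perimeter <- 4 * sqrt(rnd$area + 1)
  got <- filterParticles(rnd, p)$retained
  want <- rnd$area >= 0 & rnd$area <= 30 &
    rnd$circularity >= 0.5 & rnd$circularity <= 1
  expect_identical(got, want)
})

test_that("labelling and scoring agree with the flood-fill oracle bit-for-bit", {
  set.seed(34)
  for (i in 1:40) {
    H <- sample(10:48, 1); W <- sample(10:48, 1)
    m <- matrix(runif(H * W) < runif(1, 0.2, 0.6), H, W)
    conn <- sample(c(4L, 8L), 1)
    lab <- labelComponents(m, conn)
    orc <- oracle_score_mask(m, conn)
    expect_identical(lab, orc$labels)
    pt <- filterParticles(measureParticles(lab),
                          ScoreParams(connectivity = conn))
    expect_identical(pt$area, orc$areas)
    expect_identical(pt$perimeter, orc$perimeters)
    expect_equal(pt$circ, orc$circ)
    expect_identical(sum(pt$area[pt$retained]), orc$totalRetainedArea)
  }
})

test_that("full pipeline scores constructed fields via the pixel-count oracle", {
  # blank image scores zero
  blank <- notch3Score(Image8(matrix(255L, 40, 40)))
  expect_equal(score(blank), 0)
  expect_equal(nParticles(blank, retained = FALSE), 0)
  # two well-separated dark blobs that pass the filters: a 3x3 square
  # (area 9, circ 0.785) and the digital disc of radius 2.5 (area 21,
  # circ 0.659); the score is their total pixel count
  m <- white_field(48, 48)
  m <- stamp_rect(m, 8, 8, 3, 3)
  d <- sqrt((row(m) - 30)^2 + (col(m) - 30)^2)
  m[d <= 2.5] <- 80L
  expect_equal(sum(d <= 2.5), 21)
  r <- notch3Score(Image8(m))
  expect_equal(score(r), 9 + 21)
  expect_equal(nParticles(r), 2)
  # particles touching the border are included
  e <- white_field(20, 20); e[1:3, 1:3] <- 80L
  expect_equal(score(notch3Score(Image8(e))), 9)
})

test_that("the size window excludes large blobs as published", {
  m <- stamp_rect(white_field(40, 40), 10, 10, 5, 10)   # area 50 blob
  r <- notch3Score(Image8(m))
  expect_equal(score(r), 0)
  expect_equal(nParticles(r, retained = FALSE), 1)
  wide <- ScoreParams(sizeMax = 100)
  expect_equal(score(notch3Score(Image8(m), params = wide)), 50)
})

test_that("scores are additive across gutter-separated fields", {
  set.seed(35)
  mk <- function() {
    m <- white_field(30, 30)
    m <- stamp_rect(m, sample(5:20, 1), sample(5:20, 1), 3, 3)
    stamp_rect(m, sample(5:24, 1), sample(5:24, 1), 2, 2)
  }
  for (i in 1:10) {
    a <- mk(); b <- mk()
    gutter <- matrix(235L, 30, 3)
    both <- cbind(a, gutter, b)
    expect_equal(score(notch3Score(Image8(both))),
                 score(notch3Score(Image8(a))) + score(notch3Score(Image8(b))))
  }
})

test_that("adding a filter-passing deposit never decreases the score", {
  set.seed(36)
  base <- white_field(40, 40)
  base <- stamp_rect(base, 5, 5, 3, 3)
  s0 <- score(notch3Score(Image8(base)))
  more <- stamp_rect(base, 25, 25, 3, 3)
  s1 <- score(notch3Score(Image8(more)))
  expect_equal(s1, s0 + 9)
  expect_gte(s1, s0)
})

test_that("the score is invariant under rotations and mirroring", {
  set.seed(37)
  m <- white_field(36, 44)
  m <- stamp_rect(m, 6, 6, 3, 3)
  m <- stamp_rect(m, 20, 30, 4, 5)
  d <- sqrt((row(m) - 28)^2 + (col(m) - 12)^2); m[d <= 2.5] <- 75L
  s <- score(notch3Score(Image8(m)))
  rot90 <- t(m)[, nrow(m):1]
  rot180 <- m[nrow(m):1, ncol(m):1]
  mirror <- m[, ncol(m):1]
  for (v in list(rot90, rot180, mirror, t(m)))
    expect_equal(score(notch3Score(Image8(v))), s)
})
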