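# Independent brute-force oracles. These deliberately share no code with the
# package internals: flood fill with an explicit stack, per-pixel edge
# counting, dense (non-separable) convolution, and direct normal-equations
# least squares.

# flood-fill connected-component labelling; labels assigned in raster-scan
# (row-major) order of each component's first pixel
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- matrix(0L, H, W)
  k <- 0L
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    if (mask[r, cl] && lab[r, cl] == 0L) {
      k <- k + 1L
      stack <- matrix(0L, H * W, 2)
      stack[1, ] <- c(r, cl)
      top <- 1L
      lab[r, cl] <- k
      while (top > 0L) {
        p <- stack[top, ]; top <- top - 1L
        for (o in seq_len(nrow(offs))) {
          rr <- p[1] + offs[o, 1]; cc <- p[2] + offs[o, 2]
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- k
            top <- top + 1L
            stack[top, ] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# exposed unit-edge count of one labelled component, by per-pixel inspection
oracle_perimeter <- function(labels, lb) {
  H <- nrow(labels); W <- ncol(labels)
  tot <- 0L
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    if (labels[r, cl] == lb) {
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + o[1]; cc <- cl + o[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W || labels[rr, cc] != lb)
          tot <- tot + 1L
      }
    }
  }
  tot
}

# per-component measurement + filtering + total retained area, all by brute
# force; returns list(areas, perimeters, circ, retained, totalRetainedArea)
oracle_score_mask <- function(mask, connectivity = 8,
                              sizeMin = 0, sizeMax = 30,
                              circMin = 0.5, circMax = 1.0) {
  lab <- oracle_label(mask, connectivity)
  K <- max(lab)
  areas <- perims <- circ <- numeric(K)
  for (k in seq_len(K)) {
    areas[k] <- sum(lab == k)
    perims[k] <- oracle_perimeter(lab, k)
    circ[k] <- min(1, 4 * pi * areas[k] / perims[k]^2)
  }
  retained <- areas >= sizeMin & areas <= sizeMax &
    circ >= circMin & circ <= circMax
  list(labels = lab, areas = areas, perimeters = perims, circ = circ,
       retained = retained, totalRetainedArea = sum(areas[retained]))
}

# dense, explicitly summed Gaussian convolution with replicate-edge padding;
# 2-D kernel built directly (not separably) and truncated at 3*sigma
oracle_gaussian <- function(m, sigma) {
  h <- max(1, ceiling(3 * sigma))
  xs <- -h:h
  k2 <- outer(xs, xs, function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  k2 <- k2 / sum(k2)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    acc <- 0
    for (i in seq_along(xs)) for (j in seq_along(xs)) {
      rr <- min(max(r + xs[i], 1), H)
      cc <- min(max(cl + xs[j], 1), W)
      acc <- acc + k2[i, j] * m[rr, cc]
    }
    out[r, cl] <- acc
  }
  out
}

# full-matrix least squares: coefficient estimates, SEs, t and two-sided p
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * s2))
  t <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = t, df = df,
       p = 2 * pt(-abs(t), df))
}

# draw a sample with mean m and sample SD s exactly
sample_with_moments <- function(n, m, s) {
  z <- rnorm(n)
  as.numeric(m + s * scale(z))
}

# small white field with dark rectangles stamped in; intensities chosen so
# the unsharp mask cannot move any pixel across the threshold
white_field <- function(H, W, bg = 235L) matrix(bg, H, W)

stamp_rect <- function(m, top, left, h, w, value = 80L) {
  m[top:(top + h - 1), left:(left + w - 1)] <- value
  m
}

# compact FieldSpec for fast pipeline tests
small_field_spec <- function(nDeposits, backgroundSD, seed) {
  FieldSpec(width = 96L, height = 96L, nDeposits = nDeposits,
            backgroundSD = backgroundSD, innerRadius = 26, outerRadius = 40,
            seed = seed)
}
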