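# Independent brute-force oracles: plain pixel loops and closed-form
# statistics kept deliberately separate from the package implementations.

# --- mask generation -------------------------------------------------------

# Random connected blob: union of seeded disks along a random walk. The
# walk stays in the central third of the canvas so that centroid rotations
# of the blob never leave the frame (needed for naive rotation oracles).
randomBlob <- function(n = 32, steps = 6, rmax = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  x <- n / 2; y <- n / 2
  lo <- n / 2 - n / 6; hi <- n / 2 + n / 6
  for (s in seq_len(steps)) {
    r <- runif(1, 1.5, rmax)
    for (i in 1:n) for (j in 1:n)
      if ((i - x)^2 + (j - y)^2 <= r^2) m[i, j] <- TRUE
    ang <- runif(1, 0, 2 * pi)
    x <- min(max(x + cos(ang) * r, lo), hi)
    y <- min(max(y + sin(ang) * r, lo), hi)
  }
  m
}

rasterDisk <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  m <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cx)^2 + (j - cy)^2 <= r^2) m[i, j] <- TRUE
  m
}

rasterEllipse <- function(n, a, b) {
  c0 <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n)
    if (((i - c0) / a)^2 + ((j - c0) / b)^2 <= 1) m[i, j] <- TRUE
  m
}

# --- morphometry oracles (pixel loops) -------------------------------------

oraclePerimeterPx <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cnt <- 0
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j]
  for (i in 1:nr) for (j in 1:nc) if (m[i, j]) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      if (!at(i + d[1], j + d[2])) cnt <- cnt + 1
  }
  cnt
}

# Gift-wrapping convex hull over pixel-corner points; area by the shoelace.
oracleHullAreaPx <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  pts <- unique(rbind(
    cbind(idx[, 1] - 0.5, idx[, 2] - 0.5), cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] - 0.5), cbind(idx[, 1] + 0.5, idx[, 2] + 0.5)))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- start; cur <- start
  repeat {
    cand <- if (cur == 1) 2 else 1
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d2c <- sum((pts[cand, ] - pts[cur, ])^2)
      d2k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d2k > d2c)) cand <- k
    }
    if (cand == start) break
    hull <- c(hull, cand); cur <- cand
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nh <- length(hull)
  if (nh < 3) return(0)
  abs(sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)) / 2
}

oracleMoments <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  xc <- mean(idx[, 1]); yc <- mean(idx[, 2])
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (k in seq_len(nrow(idx))) {
    dx <- idx[k, 1] - xc; dy <- idx[k, 2] - yc
    mu20 <- mu20 + dx * dx; mu02 <- mu02 + dy * dy; mu11 <- mu11 + dx * dy
  }
  np <- nrow(idx)
  tr <- (mu20 + mu02) / np
  det <- (mu20 * mu02 - mu11^2) / np^2
  l1 <- as.numeric(tr / 2 + sqrt(max(tr^2 / 4 - det, 0)))
  l2 <- as.numeric(tr / 2 - sqrt(max(tr^2 / 4 - det, 0)))
  list(ecc = sqrt(1 - max(l2, 0) / l1), iso = max(l2, 0) / l1)
}

# Surround a mask with background so naive rotation never clips: rotated
# content stays within the centroid-centred disk of radius rmax, so padding
# by rmax is always sufficient.
padMask <- function(m, k = NULL) {
  if (is.null(k)) {
    idx <- which(m, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    k <- ceiling(sqrt(max((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2))) + 3L
  }
  out <- matrix(FALSE, nrow(m) + 2 * k, ncol(m) + 2 * k)
  out[k + seq_len(nrow(m)), k + seq_len(ncol(m))] <- m
  out
}

# Per-pixel inverse-mapped rotation and Jaccard, looped.
oracleRMS <- function(m, k) {
  idx <- which(m, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  nr <- nrow(m); nc <- ncol(m)
  jac <- numeric(k - 1)
  for (j in seq_len(k - 1)) {
    th <- 2 * pi * j / k
    inter <- 0; uni <- 0
    for (i in 1:nr) for (q in 1:nc) {
      sr <- floor(cx + cos(th) * (i - cx) + sin(th) * (q - cy) + 0.5 + 1e-9)
      sc <- floor(cy - sin(th) * (i - cx) + cos(th) * (q - cy) + 0.5 + 1e-9)
      rot <- sr >= 1 && sr <= nr && sc >= 1 && sc <= nc && m[sr, sc]
      if (m[i, q] && rot) inter <- inter + 1
      if (m[i, q] || rot) uni <- uni + 1
    }
    jac[j] <- inter / uni
  }
  mean(jac)
}

# Looped Zhang-Suen thinning.
oracleThin <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(mm, i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mm[i, j]
  pass <- function(mm, sub) {
    del <- matrix(FALSE, nr, nc)
    for (i in 1:nr) for (j in 1:nc) if (mm[i, j]) {
      nb <- c(at(mm, i - 1, j), at(mm, i - 1, j + 1), at(mm, i, j + 1),
              at(mm, i + 1, j + 1), at(mm, i + 1, j), at(mm, i + 1, j - 1),
              at(mm, i, j - 1), at(mm, i - 1, j - 1))
      B <- sum(nb)
      A <- sum(!nb & c(nb[-1], nb[1]))
      ok <- B >= 2 && B <= 6 && A == 1
      if (ok) {
        if (sub == 1) ok <- !(nb[1] && nb[3] && nb[5]) && !(nb[3] && nb[5] && nb[7])
        else ok <- !(nb[1] && nb[3] && nb[7]) && !(nb[1] && nb[5] && nb[7])
      }
      if (ok) del[i, j] <- TRUE
    }
    mm & !del
  }
  repeat {
    m1 <- pass(m, 1)
    m2 <- pass(m1, 2)
    if (identical(m2, m)) return(m2)
    m <- m2
  }
}

oracleSkeletonLength <- function(sk) {
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  orth <- 0; diag <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    chk <- function(di, dj) {
      ii <- i + di; jj <- j + dj
      ii >= 1 && ii <= nrow(sk) && jj >= 1 && jj <= ncol(sk) && sk[ii, jj]
    }
    if (chk(1, 0)) orth <- orth + 1
    if (chk(0, 1)) orth <- orth + 1
    if (chk(1, 1)) diag <- diag + 1
    if (chk(1, -1)) diag <- diag + 1
  }
  # connected pieces by naive flood fill (8-connectivity)
  lab <- matrix(0L, nrow(sk), ncol(sk)); nextl <- 0L
  for (k in seq_len(nrow(idx))) {
    if (lab[idx[k, 1], idx[k, 2]] > 0) next
    nextl <- nextl + 1L
    queue <- list(idx[k, ])
    lab[idx[k, 1], idx[k, 2]] <- nextl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nrow(sk) && jj >= 1 && jj <= ncol(sk) &&
            sk[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- nextl
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  orth + sqrt(2) * diag + nextl
}

# --- statistics oracles ----------------------------------------------------

oracleTTest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# OLS via explicit normal equations on a model matrix.
oracleOLS <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# --- logistic loss oracle --------------------------------------------------

# Mean logistic loss (no penalty) and its numerical gradient.
logLossAt <- function(Xs, y, w, b) {
  eta <- drop(Xs %*% w) + b
  mean(log(1 + exp(-(2 * y - 1) * eta)))
}

numericalGradient <- function(Xs, y, w, b, h = 1e-6) {
  g <- numeric(length(w))
  for (j in seq_along(w)) {
    wp <- w; wm <- w
    wp[j] <- wp[j] + h; wm[j] <- wm[j] - h
    g[j] <- (logLossAt(Xs, y, wp, b) - logLossAt(Xs, y, wm, b)) / (2 * h)
  }
  gb <- (logLossAt(Xs, y, w, b + h) - logLossAt(Xs, y, w, b - h)) / (2 * h)
  list(gw = g, gb = gb)
}

# --- shared fixtures -------------------------------------------------------

# Minimal trait table holding one trait per plant-day for a whole design.
designTable <- function(design, days = -1:7) {
  p <- plants(design)
  grid <- expand.grid(i = seq_len(nrow(p)), das = days)
  TraitTable(data.frame(
    plant_id = p$plant_id[grid$i], genotype = p$genotype[grid$i],
    treatment = p$treatment[grid$i], das = as.integer(grid$das),
    trait = "area", value = seq_len(nrow(grid))))
}

# A small fluorescence-only trait table used by several stats/classify tests.
smallTraitTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- buildDesign(8, seed = 7)
      cache <<- simulateTraitTable(d, SimulationParams(), seed = 7,
                                   morphology = FALSE)
    }
    cache
  }
})
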