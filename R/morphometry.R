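# Rosette morphometry from binary top-view masks.
#
# Conventions (fixed so that every count is bit-exact and testable):
#  - components use 8-connectivity, cracks (perimeter) 4-neighbour edges;
#  - perimeter is the crack length: number of exposed pixel edges x scale;
#  - the convex hull is taken over pixel corners, so a filled rectangle has
#    hull area equal to its pixel area and compactness exactly 1;
#  - all dimensionless traits are computed in pixel units and are therefore
#    invariant under changes of the mm/px scale.

# 8-connected labelling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
label8 <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  lut <- c(0L, match(root, sort(unique(root))))
  matrix(lut[lab + 1L], nr, nc)
}

#' Clean a raw binary mask into a single-rosette mask
#'
#' Fills interior holes and keeps the largest 8-connected component, the
#' standard post-processing between colour segmentation and trait
#' extraction.
#'
#' @param raw binary matrix (0/1 or logical), nonzero = plant.
#' @param scale mm per pixel.
#' @return a [RosetteMask-class].
#' @export
cleanMask <- function(raw, scale = 1) {
  if (is(raw, "RosetteMask")) { scale <- raw@scale; raw <- raw@mask }
  m <- if (is.logical(raw)) raw else {
    if (!all(raw %in% c(0, 1))) stop("raster must be binary-valued")
    raw > 0
  }
  if (!any(m)) stop("empty mask: no foreground pixels")
  filled <- EBImage::imageData(EBImage::fillHull(m * 1)) > 0
  lab <- label8(filled)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  RosetteMask(lab == keep, scale)
}

# Count of exposed 4-neighbour pixel edges (crack perimeter, in pixels).
crackPerimeterPx <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  adjV <- sum(m[-nr, , drop = FALSE] & m[-1, , drop = FALSE])
  adjH <- sum(m[, -nc, drop = FALSE] & m[, -1, drop = FALSE])
  4 * sum(m) - 2 * (adjV + adjH)
}

# Convex hull area over pixel corners, in px^2 (shoelace).
hullAreaPx <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  # corners of every foreground pixel; boundary pixels suffice but corners of
  # all pixels are cheap enough and unambiguous
  x <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  y <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  if (n < 3) return(length(unique(paste(x, y))) * 0)  # degenerate line: area 0
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
}

#' Basic size and outline traits of a rosette mask
#'
#' Area (foreground pixel count x scale^2), crack perimeter, convex hull
#' area, compactness (area / hull area) and roundness
#' (4 pi area / perimeter^2, clipped to at most 1).
#'
#' @param m a [RosetteMask-class].
#' @return named list: `area` (mm^2), `perimeter` (mm), `convex_hull_area`
#'   (mm^2), `compactness`, `roundness`.
#' @examples
#' sq <- RosetteMask(matrix(TRUE, 10, 10))
#' basicGeometry(sq)  # area 100, perimeter 40, compactness 1
#' @export
basicGeometry <- function(m) {
  stopifnot(is(m, "RosetteMask"))
  mask <- m@mask; s <- m@scale
  apx <- sum(mask)
  if (apx == 0) stop("empty mask")
  ppx <- crackPerimeterPx(mask)
  hpx <- hullAreaPx(mask)
  list(area = apx * s^2,
       perimeter = ppx * s,
       convex_hull_area = hpx * s^2,
       compactness = if (hpx > 0) min(apx / hpx, 1) else 1,
       roundness = min(4 * pi * apx / ppx^2, 1))
}

#' Second-moment shape of a rosette mask
#'
#' Builds the 2x2 inertia tensor from the central second moments of the
#' foreground pixel centres; with eigenvalues lambda1 >= lambda2,
#' eccentricity = sqrt(1 - lambda2/lambda1) (ellipse-equivalent) and
#' isotropy = lambda2/lambda1. The ellipse-equivalent axis lengths
#' (4 sqrt(lambda)) are returned in mm.
#'
#' @param m a [RosetteMask-class] with at least 3 foreground pixels.
#' @return named list: `eccentricity`, `isotropy`, `major_axis`,
#'   `minor_axis`, `aspect_ratio`, `degenerate` (TRUE when the pixels are
#'   collinear, in which case eccentricity takes its limit value 1).
#' @export
momentShape <- function(m) {
  stopifnot(is(m, "RosetteMask"))
  idx <- which(m@mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("momentShape needs at least 3 foreground pixels")
  x <- idx[, 1] - mean(idx[, 1]); y <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)$values
  l1 <- max(ev[1], 0); l2 <- max(ev[2], 0)
  degen <- l2 <= .Machine$double.eps * l1
  ratio <- if (degen) 0 else l2 / l1
  list(eccentricity = sqrt(1 - ratio),
       isotropy = ratio,
       major_axis = 4 * sqrt(l1) * m@scale,
       minor_axis = 4 * sqrt(l2) * m@scale,
       aspect_ratio = if (degen) Inf else sqrt(l1 / l2),
       degenerate = degen)
}

# Crop a logical matrix to its foreground bounding box plus a margin
# (traits are translation invariant; cropping only saves work).
cropForeground <- function(mask, margin = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  r1 <- max(1L, min(idx[, 1]) - margin); r2 <- min(nrow(mask), max(idx[, 1]) + margin)
  c1 <- max(1L, min(idx[, 2]) - margin); c2 <- min(ncol(mask), max(idx[, 2]) + margin)
  mask[r1:r2, c1:c2, drop = FALSE]
}

# Rotate a mask by theta (radians) about (cx, cy) with nearest-neighbour
# inverse mapping; returns a logical matrix of the same shape.
rotateMaskNN <- function(mask, theta, cx, cy) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- rep(seq_len(nr), times = nc); c <- rep(seq_len(nc), each = nr)
  # inverse rotation of each target pixel centre; half-up rounding with a
  # tiny bias is translation invariant (unlike round()'s half-to-even) and
  # keeps exact .5 ties stable against last-ulp centroid differences, so
  # the result is independent of the canvas framing
  dx <- r - cx; dy <- c - cy
  sr <- floor(cx + cos(theta) * dx + sin(theta) * dy + 0.5 + 1e-9)
  sc <- floor(cy - sin(theta) * dx + cos(theta) * dy + 0.5 + 1e-9)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- logical(nr * nc)
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  matrix(out, nr, nc)
}

#' Rotational mass symmetry of a rosette mask
#'
#' Mean Jaccard overlap between the mask and its rotations by 360 j / k
#' degrees (j = 1..k-1) about the binary centroid, using nearest-neighbour
#' resampling. 1 for a perfectly rotation-symmetric rosette; drops when
#' leaves move or grow asymmetrically.
#'
#' @param m a [RosetteMask-class].
#' @param k number of rotations (default 8; must be >= 2).
#' @return scalar RMS in (0, 1].
#' @export
rotationalMassSymmetry <- function(m, k = 8) {
  stopifnot(is(m, "RosetteMask"), k >= 2)
  mask <- m@mask
  if (!any(mask)) stop("empty mask")
  # re-frame on a canvas centred near the centroid and large enough to hold
  # every rotation of the content, so no rotated pixel is ever clipped
  bb <- which(mask, arr.ind = TRUE)
  ctr <- round(c(mean(bb[, 1]), mean(bb[, 2])))
  half <- ceiling(sqrt(max((bb[, 1] - ctr[1])^2 + (bb[, 2] - ctr[2])^2))) + 3L
  side <- 2L * half + 1L
  frame <- matrix(FALSE, side, side)
  frame[cbind(bb[, 1] - ctr[1] + half + 1L,
              bb[, 2] - ctr[2] + half + 1L)] <- TRUE
  mask <- frame
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  jac <- vapply(seq_len(k - 1), function(j) {
    rot <- rotateMaskNN(mask, 2 * pi * j / k, cx, cy)
    sum(mask & rot) / sum(mask | rot)
  }, numeric(1))
  mean(jac)
}

# One Zhang-Suen thinning pass (vectorised); sub = 1 or 2 selects the
# subiteration. Returns the updated mask.
zsPass <- function(m, sub) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, nr, nc)
  for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
  if (sub == 1) {
    cond <- m & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- m & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  m & !cond
}

# Topological thinning (Zhang-Suen) to a one-pixel-wide skeleton.
thinMask <- function(m) {
  repeat {
    m1 <- zsPass(m, 1)
    m2 <- zsPass(m1, 2)
    if (identical(m2, m)) return(m2)
    m <- m2
  }
}

# Skeleton length in pixel units: one unit per 4-neighbour link, sqrt(2) per
# diagonal link, plus one per connected piece (so an n-pixel straight run
# has length n and an isolated pixel length 1).
skeletonLengthPx <- function(sk) {
  if (!any(sk)) return(0)
  nr <- nrow(sk); nc <- ncol(sk)
  orth <- sum(sk[-nr, , drop = FALSE] & sk[-1, , drop = FALSE]) +
          sum(sk[, -nc, drop = FALSE] & sk[, -1, drop = FALSE])
  diag1 <- sum(sk[-nr, -nc, drop = FALSE] & sk[-1, -1, drop = FALSE])
  diag2 <- sum(sk[-nr, -1, drop = FALSE] & sk[-1, -nc, drop = FALSE])
  ncomp <- max(label8(sk))
  orth + sqrt(2) * (diag1 + diag2) + ncomp
}

#' Slenderness of leaves (SOL)
#'
#' Skeleton-based elongation measure: the rosette mask is thinned to its
#' topological skeleton (Zhang-Suen) and SOL = (skeleton length)^2 /
#' foreground area, both in pixel units, making the trait dimensionless and
#' scale-invariant. Long thin leaves give a long skeleton relative to their
#' area (high SOL); a disk collapses to a short skeleton (SOL well below 1).
#' A single-pixel mask has SOL 1 by convention.
#'
#' @param m a [RosetteMask-class].
#' @return scalar SOL >= 0.
#' @export
slendernessOfLeaves <- function(m) {
  stopifnot(is(m, "RosetteMask"))
  mask <- m@mask
  apx <- sum(mask)
  if (apx == 0) stop("empty mask")
  len <- skeletonLengthPx(thinMask(cropForeground(mask)))
  len^2 / apx
}

#' Mean rosette surface temperature
#'
#' Arithmetic mean of the thermal raster over the mask foreground — the
#' mask-guided extraction of leaf temperature from an infrared image.
#'
#' @param m a [RosetteMask-class].
#' @param t a [ThermalRaster-class] of the same shape.
#' @return mean temperature in degrees C.
#' @export
rosetteTemperature <- function(m, t) {
  stopifnot(is(m, "RosetteMask"), is(t, "ThermalRaster"))
  if (!identical(dim(m@mask), dim(t@grid)))
    stop("mask and thermal raster shapes differ")
  if (!any(m@mask)) stop("empty mask")
  mean(t@grid[m@mask])
}

#' All morphology traits of a mask (plus optional temperature)
#'
#' Convenience wrapper running [basicGeometry()], [momentShape()],
#' [rotationalMassSymmetry()], [slendernessOfLeaves()] and, when a thermal
#' raster is supplied, [rosetteTemperature()].
#'
#' @param m a [RosetteMask-class] (already cleaned).
#' @param thermal optional [ThermalRaster-class].
#' @param k rotations for the rotational-mass-symmetry trait.
#' @return named list of trait values using the [traitVocabulary()] names.
#' @export
maskTraits <- function(m, thermal = NULL, k = 8) {
  g <- basicGeometry(m)
  s <- momentShape(m)
  out <- c(g, s[c("eccentricity", "isotropy", "major_axis", "minor_axis",
                  "aspect_ratio")],
           list(RMS = rotationalMassSymmetry(m, k),
                SOL = slendernessOfLeaves(m)))
  if (!is.null(thermal)) out$temperature <- rosetteTemperature(m, thermal)
  out
}
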