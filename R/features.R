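# Feature extraction: shape index, auto-alignment via the longest boundary
# chord, axis and width-strip measurements, boundary-chain perimeter, and
# the polar Fourier texture descriptor compressed by PCA. All geometric
# features are measured on the horizontally aligned mask so they are
# invariant to the object's orientation in the micrograph.

asSegObj <- function(x) {
  if (is(x, "SegmentedObject")) return(x)
  if (is.matrix(x)) return(SegmentedObject(1L, x))
  stop("expected a SegmentedObject or a 0/1 mask matrix")
}

#' Angle between two slopes
#'
#' The inclination formula \eqn{\theta = \tan^{-1}((m_1 - m_2)/(1 + m_1 m_2))}
#' in degrees; antisymmetric in its arguments. With a horizontal reference
#' line (\code{m2 = 0}) this is simply the inclination of a line of slope
#' \code{m1}.
#'
#' @param m1,m2 Line slopes (dimensionless).
#' @return Angle in degrees.
#' @export
inclinationTheta <- function(m1, m2 = 0) {
  atan((m1 - m2) / (1 + m1 * m2)) * 180 / pi
}

#' Longest boundary chord and inclination angle
#'
#' Finds the pair of boundary pixels at maximal Euclidean distance (the
#' object's longest chord) by exhaustive search over all boundary-pixel
#' pairs. Pairs within half a pixel of the maximum length are near-ties —
#' a rasterization artifact of blunted tips — so the reported inclination
#' is the circular mean of their (undirected) chord directions, which is
#' unbiased when the tip pixels scatter symmetrically about the true axis.
#' The representative endpoint pair is the near-tie with smallest
#' inclination magnitude, then lexicographically smallest endpoints
#' (row, then column). The inclination is measured
#' against a horizontal reference line, so it is translation invariant, and
#' normalized to (-90, 90\] degrees (90 for a vertical chord).
#'
#' @param obj A [SegmentedObject-class] or 0/1 mask with >= 2 boundary
#'   pixels.
#' @return List with \code{p1}, \code{p2} (each \code{c(x, y)} = column,
#'   row), \code{m1} (chord slope, Inf if vertical), \code{m2} (reference
#'   slope, 0), \code{theta} (degrees), \code{length} (px).
#' @export
inclinationAngle <- function(obj) {
  obj <- asSegObj(obj)
  pts <- boundaryPixels(objMask(obj))
  if (nrow(pts) < 2) stop("mask must have at least 2 boundary pixels")
  n <- nrow(pts)
  ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  dx <- pts[ij[, 2], "x"] - pts[ij[, 1], "x"]
  dy <- pts[ij[, 2], "y"] - pts[ij[, 1], "y"]
  d2 <- dx * dx + dy * dy     # integer coordinates: exact
  theta <- ifelse(dx == 0, 90, atan(dy / dx) * 180 / pi)
  near <- which(sqrt(d2) >= sqrt(max(d2)) - 0.5)
  # circular mean of undirected directions via angle doubling
  th2 <- theta[near] * pi / 90
  thetaHat <- atan2(mean(sin(th2)), mean(cos(th2))) * 90 / pi
  if (thetaHat <= -90) thetaHat <- thetaHat + 180
  best <- near
  if (length(best) > 1) {
    best <- best[order(abs(theta[best]),
                       pts[ij[best, 1], "y"], pts[ij[best, 1], "x"],
                       pts[ij[best, 2], "y"], pts[ij[best, 2], "x"])[1]]
  }
  a <- pts[ij[best, 1], ]; b <- pts[ij[best, 2], ]
  # order endpoints lexicographically by (row, col)
  if (b["y"] < a["y"] || (b["y"] == a["y"] && b["x"] < a["x"])) {
    tmp <- a; a <- b; b <- tmp
  }
  list(p1 = unname(a), p2 = unname(b),
       m1 = if (abs(thetaHat) == 90) Inf else tan(thetaHat * pi / 180),
       m2 = 0, theta = thetaHat, length = sqrt(max(d2)))
}

# Rotate mask + colour crop content by `angle` degrees about the mask
# centroid; the canvas is expanded so no foreground is clipped. Bilinear
# resampling for the colour planes and for the mask coverage (thresholded
# back to binary).
rotateContent <- function(mask, crop, angle) {
  a <- angle * pi / 180
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  my <- mean(fg[, 1]); mx <- mean(fg[, 2])
  corners <- rbind(c(1, 1), c(1, w), c(h, 1), c(h, w))
  xc <- corners[, 2] - mx; yc <- corners[, 1] - my
  xr <- xc * cos(a) - yc * sin(a); yr <- xc * sin(a) + yc * cos(a)
  wOut <- 2L * ceiling(max(abs(xr))) + 3L
  hOut <- 2L * ceiling(max(abs(yr))) + 3L
  cx <- (wOut + 1) / 2; cy <- (hOut + 1) / 2
  xo <- matrix(rep(seq_len(wOut) - cx, each = hOut), hOut, wOut)
  yo <- matrix(rep(seq_len(hOut) - cy, wOut), hOut, wOut)
  xs <- xo * cos(a) + yo * sin(a) + mx
  ys <- -xo * sin(a) + yo * cos(a) + my
  r0 <- floor(ys); c0 <- floor(xs)
  fr <- ys - r0; fc <- xs - c0
  gather <- function(plane, rr, cc) {
    v <- matrix(0, hOut, wOut)
    okk <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v[okk] <- plane[cbind(rr[okk], cc[okk])]
    v
  }
  bilinear <- function(plane)
    gather(plane, r0, c0) * (1 - fr) * (1 - fc) +
    gather(plane, r0 + 1, c0) * fr * (1 - fc) +
    gather(plane, r0, c0 + 1) * (1 - fr) * fc +
    gather(plane, r0 + 1, c0 + 1) * fr * fc
  # bilinear-interpolated coverage, lightly smoothed, then thresholded at
  # 0.5: plain NN sampling staircases the rotated boundary and repeated
  # resampling adds sub-pixel wiggle, both of which inflate chain-code
  # perimeters; stray pixels detached by resampling are dropped by
  # keeping the largest connected component
  cov <- bilinear(mask + 0.0)
  covp <- cov[c(1, seq_len(hOut), hOut), c(1, seq_len(wOut), wOut)]
  kw <- c(1, 2, 1)                  # centre-weighted 3x3, sum 16
  sm <- matrix(0, hOut, wOut)
  for (dr in 0:2) for (dc in 0:2)
    sm <- sm + kw[dr + 1] * kw[dc + 1] *
      covp[dr + seq_len(hOut), dc + seq_len(wOut)]
  maskOut <- asMask(sm / 16 >= 0.5)
  lab <- label8(maskOut)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    maskOut <- asMask(lab == which.max(sizes))
  }
  cropOut <- NULL
  if (!is.null(crop)) {
    cropOut <- array(0, c(hOut, wOut, 3L))
    for (ch in 1:3) cropOut[, , ch] <- bilinear(crop[, , ch])
  }
  list(mask = maskOut, crop = cropOut)
}

#' Rotate an object to horizontal alignment
#'
#' Rotates mask and colour crop by \code{-angle} about the mask centroid
#' (nearest-neighbour / bilinear resampling, canvas expanded so nothing is
#' clipped) and re-crops to the rotated mask's bounding box. With
#' \code{angle} taken from [inclinationAngle()], the longest chord of the
#' result is horizontal to within ~2 degrees.
#'
#' @param obj A [SegmentedObject-class] or 0/1 mask.
#' @param angle Inclination to remove, in degrees; defaults to the object's
#'   own [inclinationAngle()].
#' @return A new [SegmentedObject-class] in its own (aligned) frame; the
#'   bbox covers the new mask extent from the origin.
#' @export
alignHorizontal <- function(obj, angle = inclinationAngle(obj)$theta) {
  obj <- asSegObj(obj)
  if (angle == 0) return(obj)
  out <- rotateOnce(obj, angle)
  # resampling can shift the measured chord by a degree or two; one
  # corrective pass brings the residual inside the contract
  res <- inclinationAngle(out)$theta
  if (abs(res) > 1) out <- rotateOnce(out, res)
  out
}

rotateOnce <- function(obj, angle) {
  rot <- rotateContent(objMask(obj), objCrop(obj), -angle)
  b <- maskBBox(rot$mask)
  mask <- rot$mask[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  crop <- rot$crop[(b[1] + 1):b[3], (b[2] + 1):b[4], , drop = FALSE]
  for (ch in 1:3) crop[, , ch] <- clamp01(crop[, , ch] * mask)
  SegmentedObject(objIndex(obj), mask, colorCrop = crop,
                  overlapping = isOverlapping(obj))
}

# Per-column vertical foreground extent (0 where a column is empty).
columnExtents <- function(mask) {
  vapply(seq_len(ncol(mask)), function(j) {
    r <- which(mask[, j] != 0)
    if (length(r) == 0) 0L else max(r) - min(r) + 1L
  }, integer(1))
}

#' Major and minor axes of an aligned object
#'
#' For a horizontally aligned object the major axis is the horizontal extent
#' between the extreme foreground columns (the longest-chord length) and the
#' minor axis is the maximum vertical foreground extent over all columns
#' (the maximum width perpendicular to the major axis).
#'
#' @param obj Aligned [SegmentedObject-class] or 0/1 mask.
#' @return Named numeric \code{c(major, minor)} in pixels.
#' @export
majorMinorAxes <- function(obj) {
  mask <- objMask(asSegObj(obj))
  ext <- columnExtents(mask)
  nz <- which(ext > 0)
  c(major = max(nz) - min(nz) + 1, minor = max(ext))
}

#' Width-factor profile of an aligned object
#'
#' Slices the object's horizontal span into \code{nStrips} equal-width
#' vertical strips; within each strip the width \eqn{W_c} is the maximum
#' vertical foreground extent, and the width factor is the ratio
#' \eqn{R_c = W_c / L} with \eqn{L} the major-axis length. Strips are
#' ordered left to right.
#'
#' @param obj Aligned [SegmentedObject-class] or 0/1 mask.
#' @param nStrips Number of strips (default 5).
#' @return List with \code{strips} (the ratios \eqn{R_c}), \code{widths}
#'   (\eqn{W_c}, px), \code{objectLength} (\eqn{L}, px), \code{nStrips}.
#' @export
widthProfile <- function(obj, nStrips = 5L) {
  mask <- objMask(asSegObj(obj))
  ext <- columnExtents(mask)
  nz <- which(ext > 0)
  cmin <- min(nz); cmax <- max(nz)
  L <- cmax - cmin + 1
  breaks <- seq(cmin - 0.5, cmax + 0.5, length.out = nStrips + 1)
  band <- findInterval(nz, breaks, rightmost.closed = TRUE)
  widths <- vapply(seq_len(nStrips), function(b) {
    cols <- nz[band == b]
    if (length(cols) == 0) 0 else max(ext[cols])
  }, numeric(1))
  list(strips = widths / L, widths = widths, objectLength = L,
       nStrips = as.integer(nStrips))
}

#' Object area
#'
#' The exact count of foreground ('1') pixels inside the object boundary.
#'
#' @param obj [SegmentedObject-class] or 0/1 mask.
#' @return Area in px^2.
#' @export
regionArea <- function(obj) sum(objMask(asSegObj(obj)))

# Moore-neighbour boundary trace of a connected 0/1 mask. Returns the
# closed chain of boundary pixel coordinates (row, col). Termination uses
# a lookahead criterion: the trace stops when it re-enters the start pixel
# and the following step would reproduce the second chain pixel, which is
# robust for contours pinched at the start pixel.
traceBoundary <- function(mask) {
  mask <- asMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1L, arr.ind = TRUE)   # column-major: min col first
  start <- fg[1, ]
  if (nrow(fg) == 1) return(matrix(start, 1, 2))
  offs <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
                 ncol = 2, byrow = TRUE)    # E SE S SW W NW N NE (clockwise)
  # one Moore step: scan neighbours clockwise from the backtrack; returns
  # c(row, col, new backtrack index) or NULL for an isolated pixel
  stepFrom <- function(P, backIdx) {
    for (s in 1:8) {
      idx <- (backIdx + s - 1L) %% 8L + 1L
      r <- P[1] + offs[idx, 1]; c <- P[2] + offs[idx, 2]
      if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] == 1L) {
        prevIdx <- (idx - 2L) %% 8L + 1L    # last background cell scanned
        bR <- P[1] + offs[prevIdx, 1] - r; bC <- P[2] + offs[prevIdx, 2] - c
        bk <- which(offs[, 1] == bR & offs[, 2] == bC)
        return(c(r, c, bk))
      }
    }
    NULL
  }
  chain <- matrix(0L, 8L * nrow(fg) + 8L, 2L)
  chain[1, ] <- start
  nchain <- 1L
  P <- start; backIdx <- 5L                 # backtrack west of the start
  repeat {
    st <- stepFrom(P, backIdx)
    if (is.null(st)) break                  # isolated pixel
    P <- st[1:2]; backIdx <- st[3]
    if (P[1] == start[1] && P[2] == start[2] && nchain >= 2L) {
      nxt <- stepFrom(P, backIdx)
      if (!is.null(nxt) && nxt[1] == chain[2, 1] && nxt[2] == chain[2, 2])
        break
    }
    nchain <- nchain + 1L
    if (nchain > nrow(chain)) {             # safety: malformed mask
      nchain <- nrow(chain)
      break
    }
    chain[nchain, ] <- P
  }
  chain[seq_len(nchain), , drop = FALSE]
}

#' Object perimeter
#'
#' Traces the outer boundary as a closed 8-connected chain and sums the step
#' lengths between adjoining boundary pixels: 1 for axial moves, sqrt(2) for
#' diagonal moves (including the closing step back to the start).
#'
#' @param obj [SegmentedObject-class] or connected 0/1 mask.
#' @return Perimeter in px (0 for a single-pixel mask).
#' @export
regionPerimeter <- function(obj) {
  chain <- traceBoundary(objMask(asSegObj(obj)))
  n <- nrow(chain)
  if (n < 2) return(0)
  steps <- rbind(diff(chain), chain[1, ] - chain[n, ])
  sum(sqrt(rowSums(steps^2)))
}

#' Shape-category index
#'
#' A coarse three-way shape label fed to the classifier as feature F1:
#' 0 for circular outlines, 1 for spiral/elongated ones, -1 for irregular
#' shapes. The rule uses circularity \eqn{C = 4\pi A / P^2} and elongation
#' \eqn{E} = major/minor of the aligned object: circular when
#' \eqn{C \ge} \code{circularity}, else elongated when \eqn{E \ge}
#' \code{elongation}, else irregular.
#'
#' @param obj [SegmentedObject-class] or 0/1 mask.
#' @param circularity,elongation Rule thresholds (defaults 0.75 and 2.8).
#' @return Integer in \{0, 1, -1\}.
#' @export
classifyShape <- function(obj, circularity = 0.75, elongation = 2.8) {
  obj <- asSegObj(obj)
  aligned <- alignHorizontal(obj)
  axes <- majorMinorAxes(aligned)
  shapeIndexFromStats(regionArea(aligned), regionPerimeter(aligned),
                      axes["major"], axes["minor"], circularity, elongation)
}

shapeIndexFromStats <- function(area, perim, major, minor,
                                circularity = 0.75, elongation = 2.8) {
  circ <- if (perim > 0) 4 * pi * area / perim^2 else 1
  if (circ >= circularity) return(0L)
  if (max(major, minor) / min(major, minor) >= elongation) return(1L)
  -1L
}

#' Polar Fourier texture descriptor
#'
#' Resamples the masked grayscale crop to a fixed \code{size} x \code{size}
#' square, applies a Hann window, takes the 2-D power spectrum with the DC
#' bin zeroed, and accumulates it into polar bins \eqn{S(r, \phi)}:
#' \code{nRadial} radial bins up to the Nyquist frequency and
#' \code{nAngular} angular bins over \[0, pi) (the spectrum of a real image
#' is symmetric). The radial marginal \eqn{P_1(r)} summarizes the energy
#' distribution over frequency; the angular marginal \eqn{P_2(\phi)}
#' captures directionality. Both are normalized to unit sum and
#' concatenated into the raw texture descriptor (length
#' \code{nRadial + nAngular}); a constant crop, having only DC energy,
#' yields the zero descriptor.
#'
#' @param obj [SegmentedObject-class] (the colour crop is used) or a gray
#'   matrix.
#' @param size Resampled square side (default 64 px).
#' @param nRadial,nAngular Polar bin counts (defaults 16 and 16).
#' @return List with \code{S} (\code{nRadial x nAngular}), \code{radial}
#'   (\eqn{P_1}), \code{angular} (\eqn{P_2}), \code{descriptor},
#'   \code{rawDim}.
#' @export
fourierSpectrum <- function(obj, size = 64L, nRadial = 16L, nAngular = 16L) {
  g <- if (is.matrix(obj)) obj else {
    o <- asSegObj(obj)
    toGray(objCrop(o)) * objMask(o)
  }
  g64 <- EBImage::resize(EBImage::Image(g), w = size, h = size,
                         filter = "bilinear")
  g64 <- matrix(as.numeric(g64), size, size)
  # remove the mean before windowing: the window would otherwise leak the
  # DC offset into the lowest-frequency bins and swamp the marginals
  g64 <- g64 - mean(g64)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(size) - 1) / (size - 1)))
  P <- Mod(stats::fft(g64 * outer(hann, hann)))^2
  P[1, 1] <- 0
  f <- c(0:(size / 2 - 1), -(size / 2):-1) / size
  r <- sqrt(outer(f^2, f^2, "+"))
  phi <- atan2(matrix(f, size, size), matrix(f, size, size, byrow = TRUE)) %% pi
  keep <- r > 0 & r <= 0.5
  rbin <- pmin(nRadial, ceiling(r[keep] / 0.5 * nRadial))
  abin <- pmin(nAngular, floor(phi[keep] / pi * nAngular) + 1L)
  S <- matrix(0, nRadial, nAngular)
  acc <- rowsum(P[keep], group = (abin - 1L) * nRadial + rbin)
  S[as.integer(rownames(acc))] <- acc
  p1 <- rowSums(S); p2 <- colSums(S)
  if (sum(p1) > 1e-12) p1 <- p1 / sum(p1) else p1 <- p1 * 0
  if (sum(p2) > 1e-12) p2 <- p2 / sum(p2) else p2 <- p2 * 0
  list(S = S, radial = p1, angular = p2, descriptor = c(p1, p2),
       rawDim = nRadial + nAngular)
}

#' Fit a PCA compression of the texture descriptors
#'
#' Mean-centers the training descriptors, eigendecomposes their covariance,
#' and retains the top \code{k} components by eigenvalue, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). Fitted on the training split only and frozen for
#' prediction.
#'
#' @param descriptors Numeric matrix, one descriptor per row (>= k + 1 rows).
#' @param k Number of retained components (default 8).
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(descriptors, k = 8L) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < k + 1)
    stop("need at least k + 1 = ", k + 1, " descriptors to fit PCA")
  mu <- colMeans(descriptors)
  e <- eigen(stats::cov(descriptors), symmetric = TRUE)
  comps <- t(e$vectors[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  new("PCAModel", center = mu, components = comps,
      eigenvalues = pmax(e$values[seq_len(k)], 0))
}

#' Project a descriptor onto fitted principal components
#'
#' @param model A [PCAModel-class].
#' @param descriptor Numeric vector of length \code{rawDim}, or a matrix
#'   with one descriptor per row.
#' @return Numeric k-vector (or n x k matrix) of component scores.
#' @export
projectPCA <- function(model, descriptor) {
  stopifnot(is(model, "PCAModel"))
  if (is.matrix(descriptor)) {
    if (ncol(descriptor) != length(model@center))
      stop("descriptor length does not match the fitted dimension")
    return(sweep(descriptor, 2, model@center) %*% t(model@components))
  }
  if (length(descriptor) != length(model@center))
    stop("descriptor length does not match the fitted dimension")
  drop(model@components %*% (descriptor - model@center))
}

# Orientation-invariant part of the feature vector plus the raw texture
# descriptor (F14-F21 need a fitted PCA, added in assembleFeatures).
# `align = FALSE` skips auto-alignment for objects already horizontal.
extractRawFeatures <- function(obj, nStrips = 5L, circularity = 0.75,
                               elongation = 2.8, align = TRUE) {
  obj <- asSegObj(obj)
  aligned <- if (align) alignHorizontal(obj) else obj
  axes <- majorMinorAxes(aligned)
  if (align && axes["minor"] > axes["major"]) {
    # near-square outlines can come out of chord alignment taller than
    # wide; a quarter turn restores the major >= minor convention
    aligned <- rotateOnce(aligned, 90)
    axes <- majorMinorAxes(aligned)
  }
  area <- regionArea(aligned)
  perim <- regionPerimeter(aligned)
  wp <- widthProfile(aligned, nStrips)
  geom <- c(
    shapeIndexFromStats(area, perim, axes["major"], axes["minor"],
                        circularity, elongation),
    unname(axes["major"]), unname(axes["minor"]), area, perim,
    unname(axes["minor"] / axes["major"]),
    unname(area / axes["major"]),
    unname(perim / axes["major"]),
    wp$strips
  )
  names(geom) <- paste0("F", seq_along(geom))
  list(geom = geom, descriptor = fourierSpectrum(aligned)$descriptor)
}

#' Assemble the 21-dimensional feature vector
#'
#' Computes, in fixed order: F1 shape index; F2 major axis; F3 minor axis;
#' F4 area; F5 perimeter; F6 minor/major; F7 area/major; F8 perimeter/major;
#' F9-F13 the five width-factor strips; F14-F21 the PCA projection of the
#' polar Fourier texture descriptor. Geometric features are measured on the
#' auto-aligned mask.
#'
#' @param obj A [SegmentedObject-class].
#' @param pca A fitted [PCAModel-class] for the texture block.
#' @param nStrips,circularity,elongation Passed to the component extractors.
#' @param align Auto-align by the longest chord first (default TRUE); set
#'   FALSE for objects already horizontal.
#' @return Named numeric vector of length 21 (\code{F1}..\code{F21}).
#' @export
assembleFeatures <- function(obj, pca, nStrips = 5L, circularity = 0.75,
                             elongation = 2.8, align = TRUE) {
  raw <- extractRawFeatures(obj, nStrips, circularity, elongation, align)
  out <- c(raw$geom, projectPCA(pca, raw$descriptor))
  names(out) <- paste0("F", seq_along(out))
  out
}
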