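# Seeded synthetic micrograph generator. Emulates bright-field frames of
# the five study genera: a bright, slightly graded, noisy background
# carrying dark objects whose morphology follows each genus archetype:
#   Navicula     - elongated lens/boat outline, fine transverse striations
#   Scenedesmus  - four ellipsoidal cells side by side
#   Microcystis  - near-circular blob packed with small dark granules
#   Oscillatoria - long straight filament with regular transverse septa
#   Chroococcus  - a dividing pair of hemispherical cells in one sheath
#   Debris       - irregular lobed fragment with flat, aperiodic texture
# All stochastic parameters flow from one explicit seed; no global RNG
# state leaks. Contrast defaults (background mean ~210/255, object mean
# <= ~120/255, noise sd 8/255) keep Otsu binarization and Canny edges well
# inside their working range, emulating a well-exposed micrograph.

#' Genus archetype parameters
#'
#' Parameter ranges for the synthetic morphologies: object sizes in pixels,
#' aspect ranges, texture period/contrast, and RGB tints. All areas are
#' comfortably above the 50-px segmentation floor.
#'
#' @return Named list of archetype parameter lists.
#' @export
genusArchetypes <- function() {
  list(
    Navicula = list(length = c(95, 140), aspect = c(3, 6),
                    base = 0.42, stripePeriod = c(4, 7), stripeAmp = 0.12,
                    tint = c(1.00, 0.80, 0.48)),
    Scenedesmus = list(cellHalfHeight = c(16, 24), cellAspect = c(0.32, 0.42),
                       cells = 4L, spacing = 0.7, base = 0.40,
                       tint = c(0.55, 1.00, 0.50)),
    Microcystis = list(radius = c(28, 42), lobing = c(0.02, 0.05),
                       base = 0.52, granule = 0.22, granuleR = c(1.5, 3),
                       granuleDensity = 1 / 50, tint = c(0.55, 0.95, 0.75)),
    Oscillatoria = list(halfWidth = c(6, 9), length = c(170, 260),
                        minAspect = 8.4, septaPeriod = c(6, 9),
                        base = 0.42, septa = 0.26, tint = c(0.50, 0.95, 0.50)),
    Chroococcus = list(cellRadius = c(18, 25), cellGap = c(0.8, 1.0),
                       sheathPad = 3, sheath = 0.55, cell = 0.33,
                       tint = c(0.60, 0.95, 0.85)),
    Debris = list(radius = c(16, 40), stretch = c(0.6, 2.2),
                  lobing = c(0.10, 0.25), base = 0.45, blotch = 0.08,
                  tint = c(0.85, 0.75, 0.60))
  )
}

runif1 <- function(rng2) stats::runif(1, rng2[1], rng2[2])

# Local coordinate grids centred on 0.
localGrid <- function(halfH, halfW) {
  h <- 2L * ceiling(halfH) + 5L
  w <- 2L * ceiling(halfW) + 5L
  list(x = matrix(rep(seq_len(w) - (w + 1) / 2, each = h), h, w),
       y = matrix(rep(seq_len(h) - (h + 1) / 2, w), h, w))
}

#' Draw one synthetic object
#'
#' Renders a single object of the requested archetype at a random size,
#' texture phase and orientation, using the current RNG state (callers
#' seed it; [generateScene()] does so explicitly). The colour patch is the
#' per-pixel intensity map times the genus tint.
#'
#' @param label Archetype name (see [genusArchetypes()]).
#' @param params Archetype parameter list (defaults to the named entry).
#' @param rotate Randomly rotate the object (default TRUE).
#' @return List with \code{mask} (0/1 matrix cropped to content),
#'   \code{color} (matching h x w x 3 array) and \code{label}.
#' @export
drawObject <- function(label, params = genusArchetypes()[[label]],
                       rotate = TRUE) {
  if (is.null(params)) stop("unknown archetype: ", label)
  d <- switch(label,
    Navicula = drawNavicula(params),
    Scenedesmus = drawScenedesmus(params),
    Microcystis = drawMicrocystis(params),
    Oscillatoria = drawOscillatoria(params),
    Chroococcus = drawChroococcus(params),
    Debris = drawDebris(params),
    stop("unknown archetype: ", label)
  )
  color <- tintPatch(d$intensity, params$tint, d$mask)
  if (rotate) {
    rot <- rotateContent(d$mask, color, stats::runif(1, 0, 180))
    d$mask <- rot$mask; color <- rot$crop
  }
  b <- maskBBox(d$mask)
  mask <- d$mask[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  color <- color[(b[1] + 1):b[3], (b[2] + 1):b[4], , drop = FALSE]
  for (ch in 1:3) color[, , ch] <- clamp01(color[, , ch] * mask)
  list(mask = mask, color = color, label = label)
}

tintPatch <- function(intensity, tint, mask) {
  out <- array(0, c(dim(intensity), 3L))
  for (ch in 1:3) out[, , ch] <- clamp01(intensity * tint[ch]) * mask
  out
}

drawNavicula <- function(p) {
  L <- runif1(p$length); A <- runif1(p$aspect)
  a <- L / 2; b <- L / (2 * A)
  R <- (a^2 + b^2) / (2 * b)         # lens = intersection of two circles
  g <- localGrid(b, a)
  off <- R - b
  mask <- asMask(g$x^2 + (g$y - off)^2 <= R^2 &
                 g$x^2 + (g$y + off)^2 <= R^2)
  period <- runif1(p$stripePeriod)
  phase <- stats::runif(1, 0, 2 * pi)
  intensity <- p$base + p$stripeAmp * sin(2 * pi * g$x / period + phase)
  list(mask = mask, intensity = intensity)
}

drawScenedesmus <- function(p) {
  hv <- runif1(p$cellHalfHeight); hw <- hv * runif1(p$cellAspect)
  k <- p$cells
  centers <- (seq_len(k) - (k + 1) / 2) * p$spacing * 2 * hw
  g <- localGrid(hv, max(abs(centers)) + hw)
  mask <- matrix(0L, nrow(g$x), ncol(g$x))
  rho2 <- matrix(Inf, nrow(g$x), ncol(g$x))
  for (cx in centers) {
    r2 <- ((g$x - cx) / hw)^2 + (g$y / hv)^2
    mask[r2 <= 1] <- 1L
    rho2 <- pmin(rho2, r2)
  }
  # cells lighter at the centre, darker toward their wall
  intensity <- p$base + 0.12 * (1 - pmin(rho2, 1))
  list(mask = mask, intensity = intensity)
}

drawMicrocystis <- function(p) {
  R0 <- runif1(p$radius)
  amp <- stats::runif(3, p$lobing[1], p$lobing[2])
  ph <- stats::runif(3, 0, 2 * pi)
  g <- localGrid(R0 * 1.3, R0 * 1.3)
  phi <- atan2(g$y, g$x)
  rb <- R0 * (1 + amp[1] * cos(2 * phi + ph[1]) +
                  amp[2] * cos(3 * phi + ph[2]) +
                  amp[3] * cos(4 * phi + ph[3]))
  mask <- asMask(sqrt(g$x^2 + g$y^2) <= rb)
  intensity <- matrix(p$base, nrow(mask), ncol(mask))
  fg <- which(mask == 1L)
  n <- max(8L, round(length(fg) * p$granuleDensity))
  centers <- fg[sample.int(length(fg), min(n, length(fg)))]
  h <- nrow(mask)
  for (idx in centers) {
    r <- runif1(p$granuleR)
    cr <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    rr <- max(1, cr - 3):min(h, cr + 3)
    cc2 <- max(1, cc - 3):min(ncol(mask), cc + 3)
    sub <- outer((rr - cr)^2, (cc2 - cc)^2, "+") <= r^2
    intensity[rr, cc2][sub] <- p$granule
  }
  list(mask = mask, intensity = intensity)
}

drawOscillatoria <- function(p) {
  hw <- runif1(p$halfWidth)
  L <- max(runif1(p$length), p$minAspect * 2 * hw * 1.02)
  g <- localGrid(hw, L / 2)
  core <- abs(g$x) <= L / 2 - hw & abs(g$y) <= hw
  capL <- (g$x - (-(L / 2 - hw)))^2 + g$y^2 <= hw^2
  capR <- (g$x - (L / 2 - hw))^2 + g$y^2 <= hw^2
  mask <- asMask(core | capL | capR)
  period <- runif1(p$septaPeriod)
  phase <- stats::runif(1, 0, period)
  septa <- ((g$x + phase) %% period) < 1.8
  intensity <- matrix(p$base, nrow(mask), ncol(mask))
  intensity[septa] <- p$septa
  list(mask = mask, intensity = intensity)
}

# A dividing pair: two hemispherical cells side by side inside a shared
# mucilaginous sheath (the canonical Chroococcus aspect), giving a gently
# waisted, peanut-like outline.
drawChroococcus <- function(p) {
  rc <- runif1(p$cellRadius)
  d <- runif1(p$cellGap) * rc              # centre separation
  rs <- rc + p$sheathPad                   # sheath radius per cell
  g <- localGrid(rs, d / 2 + rs)
  left2 <- (g$x + d / 2)^2 + g$y^2
  right2 <- (g$x - d / 2)^2 + g$y^2
  mask <- asMask(left2 <= rs^2 | right2 <= rs^2)
  intensity <- matrix(p$sheath, nrow(mask), ncol(mask))
  for (r2 in list(left2 / rc^2, right2 / rc^2)) {
    inside <- r2 <= 1
    intensity[inside] <- p$cell + 0.08 * (1 - r2[inside])
  }
  list(mask = mask, intensity = intensity)
}

drawDebris <- function(p) {
  R0 <- runif1(p$radius)
  sx <- runif1(p$stretch)
  amp <- stats::runif(4, p$lobing[1], p$lobing[2])
  ph <- stats::runif(4, 0, 2 * pi)
  g <- localGrid(R0 * 1.6, R0 * 1.6 * max(1, sx))
  xs <- g$x / sx
  phi <- atan2(g$y, xs)
  rb <- R0 * (1 + amp[1] * cos(2 * phi + ph[1]) + amp[2] * cos(3 * phi + ph[2]) +
                  amp[3] * cos(5 * phi + ph[3]) + amp[4] * cos(6 * phi + ph[4]))
  mask <- asMask(sqrt(xs^2 + g$y^2) <= rb)
  if (sum(mask) < 200) {                    # deep lobes can hollow it out
    mask <- asMask(sqrt(xs^2 + g$y^2) <= R0)
  }
  blotch <- gaussianSmooth(matrix(stats::rnorm(length(mask)), nrow(mask)), 4)
  blotch <- blotch / max(abs(blotch), 1e-9)
  intensity <- p$base + p$blotch * blotch
  list(mask = mask, intensity = intensity)
}

#' Generate one synthetic scene
#'
#' A bright background (mean ~210/255) with a smooth random illumination
#' gradient and Gaussian pixel noise (sd 8/255), carrying the requested
#' objects at rejection-sampled non-touching positions. With
#' \code{overlap = TRUE} the first two objects are instead placed so their
#' masks intersect by roughly 30\%, producing one merged component for the
#' overlap-separation stage to split.
#'
#' @param labels Character vector of archetype names, one object each.
#' @param canvas Integer \code{c(height, width)}; default \code{c(512, 640)}.
#' @param seed Integer seed; the scene is fully reproducible from it.
#' @param overlap Force the first two objects to overlap (default FALSE).
#' @param background Mean background intensity (default 210/255).
#' @param noiseSD Gaussian noise standard deviation (default 8/255).
#' @param archetypes Archetype parameter set (default [genusArchetypes()]).
#' @return A [SyntheticScene-class].
#' @export
generateScene <- function(labels, canvas = c(512L, 640L), seed = 1L,
                          overlap = FALSE, background = 210 / 255,
                          noiseSD = 8 / 255,
                          archetypes = genusArchetypes()) {
  h <- canvas[1]; w <- canvas[2]
  withr::with_seed(as.integer(seed), {
    gx <- stats::runif(1, -0.06, 0.06); gy <- stats::runif(1, -0.06, 0.06)
    bg <- background +
      gx * (matrix(rep(seq_len(w), each = h), h, w) / w - 0.5) +
      gy * (matrix(rep(seq_len(h), w), h, w) / h - 0.5)
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- bg

    placed <- list()
    occupied <- matrix(0L, h, w)
    margin <- 12L
    for (li in seq_along(labels)) {
      d <- drawObject(labels[li], archetypes[[labels[li]]])
      oh <- nrow(d$mask); ow <- ncol(d$mask)
      if (oh > h - 2 * margin || ow > w - 2 * margin)
        stop("object larger than canvas")
      pos <- NULL
      if (overlap && li == 2L && length(placed) == 1L) {
        pos <- overlapPosition(d, placed[[1]], h, w, margin)
      }
      if (is.null(pos)) {
        for (att in seq_len(1000L)) {
          r0 <- sample.int(h - oh - 2L * margin, 1L) + margin
          c0 <- sample.int(w - ow - 2L * margin, 1L) + margin
          rows <- r0:(r0 + oh - 1L); cols <- c0:(c0 + ow - 1L)
          grow <- max(1, r0 - margin):min(h, r0 + oh - 1L + margin)
          gcol <- max(1, c0 - margin):min(w, c0 + ow - 1L + margin)
          if (!any(occupied[grow, gcol])) { pos <- c(r0, c0); break }
        }
        if (is.null(pos)) stop("could not place object after 1000 attempts")
      }
      r0 <- pos[1]; c0 <- pos[2]
      rows <- r0:(r0 + oh - 1L); cols <- c0:(c0 + ow - 1L)
      sel <- d$mask == 1L
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[sel] <- d$color[, , ch][sel]
        img[rows, cols, ch] <- plane
      }
      occupied[rows, cols] <- pmax(occupied[rows, cols], d$mask)
      fg <- which(sel, arr.ind = TRUE)
      placed[[li]] <- list(label = d$label, mask = d$mask,
                           bbox = c(r0 - 1L, c0 - 1L, r0 + oh - 1L,
                                    c0 + ow - 1L),
                           area = sum(d$mask),
                           centroidR = r0 - 1 + mean(fg[, 1]) - 0.5,
                           centroidC = c0 - 1 + mean(fg[, 2]) - 0.5)
    }
    img <- clamp01(img + array(stats::rnorm(length(img), sd = noiseSD),
                               dim(img)))
  })
  truth <- if (length(placed) == 0) {
    data.frame(label = character(0), r0 = integer(0), c0 = integer(0),
               r1 = integer(0), c1 = integer(0), area = integer(0),
               centroidR = numeric(0), centroidC = numeric(0))
  } else {
    data.frame(
      label = vapply(placed, `[[`, character(1), "label"),
      r0 = vapply(placed, function(p) p$bbox[1], numeric(1)),
      c0 = vapply(placed, function(p) p$bbox[2], numeric(1)),
      r1 = vapply(placed, function(p) p$bbox[3], numeric(1)),
      c1 = vapply(placed, function(p) p$bbox[4], numeric(1)),
      area = vapply(placed, `[[`, numeric(1), "area"),
      centroidR = vapply(placed, `[[`, numeric(1), "centroidR"),
      centroidC = vapply(placed, `[[`, numeric(1), "centroidC"))
  }
  new("SyntheticScene", image = img, truth = truth,
      masks = lapply(placed, `[[`, "mask"), seed = as.integer(seed))
}

# Position the second object so its mask intersects the first by ~30%.
overlapPosition <- function(d, first, h, w, margin) {
  oh <- nrow(d$mask); ow <- ncol(d$mask)
  fb <- first$bbox
  fc <- c((fb[1] + fb[3]) / 2, (fb[2] + fb[4]) / 2)
  r1 <- sqrt(first$area / pi); r2 <- sqrt(sum(d$mask) / pi)
  for (att in seq_len(400L)) {
    ang <- stats::runif(1, 0, 2 * pi)
    dist <- stats::runif(1, 0.55, 0.95) * (r1 + r2)
    ctr <- fc + dist * c(sin(ang), cos(ang))
    r0 <- round(ctr[1] - oh / 2); c0 <- round(ctr[2] - ow / 2)
    if (r0 <= margin || c0 <= margin ||
        r0 + oh - 1 > h - margin || c0 + ow - 1 > w - margin) next
    a <- uncropMask(first$mask, first$bbox, h, w)
    b <- uncropMask(d$mask, c(r0 - 1L, c0 - 1L, r0 + oh - 1L, c0 + ow - 1L),
                    h, w)
    frac <- sum(a & b) / min(first$area, sum(d$mask))
    if (frac >= 0.2 && frac <= 0.4) return(c(r0, c0))
  }
  NULL
}

#' Generate a labelled train/test image set
#'
#' Single-alga scenes for each of the five genera: by default 40 training
#' and 50 test images per genus, the study's benchmark sizes. Per-scene
#' seeds are drawn from one master seed with disjoint draws for the two
#' splits, so the whole dataset is reproducible from \code{seed} alone.
#'
#' @param nTrainPerClass,nTestPerClass Images per genus in each split.
#' @param seed Master seed.
#' @param canvas Scene size \code{c(height, width)}.
#' @param debrisPerSplit Optional count of extra unlabelled-debris scenes
#'   appended to each split (default 0).
#' @return List with \code{train} and \code{test}: lists of
#'   [SyntheticScene-class], class-balanced and interleaved.
#' @export
generateDataset <- function(nTrainPerClass = 40L, nTestPerClass = 50L,
                            seed = 1L, canvas = c(512L, 640L),
                            debrisPerSplit = 0L) {
  sds <- datasetSeeds(nTrainPerClass, nTestPerClass, seed, debrisPerSplit)
  mkSplit <- function(plan)
    lapply(seq_len(nrow(plan)), function(i)
      generateScene(plan$label[i], canvas = canvas, seed = plan$seed[i]))
  list(train = mkSplit(sds$train), test = mkSplit(sds$test))
}

# Per-scene labels and seeds for a dataset, derived from one master seed
# with disjoint draws for the two splits. Shared by generateDataset() and
# the streaming benchmark so both see byte-identical scenes.
datasetSeeds <- function(nTrainPerClass, nTestPerClass, seed,
                         debrisPerSplit = 0L) {
  genera <- c("Navicula", "Scenedesmus", "Microcystis", "Oscillatoria",
              "Chroococcus")
  trainLabels <- c(rep(genera, nTrainPerClass), rep("Debris", debrisPerSplit))
  testLabels <- c(rep(genera, nTestPerClass), rep("Debris", debrisPerSplit))
  nTrain <- length(trainLabels); nTest <- length(testLabels)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(2147483646L, nTrain + nTest))
  list(train = data.frame(label = trainLabels, seed = seeds[seq_len(nTrain)]),
       test = data.frame(label = testLabels,
                         seed = seeds[nTrain + seq_len(nTest)]))
}
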