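test_that("the slope-angle formula gives 45 degrees for unit slope and is antisymmetric", {
  expect_equal(inclinationTheta(1, 0), 45)
  withr::with_seed(2, {
    m <- stats::runif(20, -3, 3)
    m2 <- stats::runif(20, -3, 3)
    expect_equal(inclinationTheta(m, m2), -inclinationTheta(m2, m))
  })
})

test_that("the longest chord equals exhaustive all-pairs search on small masks", {
  masks <- list(
    ellipseMask(20, 8),
    ellipseMask(18, 7, angleDeg = 30),
    barMask(5, 30),
    diskMask(9)
  )
  withr::with_seed(8, {
    blob <- medianFilter3(matrix(rbinom(225, 1, 0.6), 15, 15))
    lab <- algascope:::label8(blob)
    if (max(lab) >= 1) {
      sizes <- tabulate(lab[lab > 0])
      masks <- c(masks, list(matrix(as.integer(lab == which.max(sizes)),
                                    15, 15)))
    }
  })
  for (m in masks) {
    got <- inclinationAngle(m)
    want <- bruteChord(m)
    expect_identical(got$p1, want$p1)
    expect_identical(got$p2, want$p2)
    expect_equal(got$length, sqrt(want$d2))
    expect_equal(got$theta, want$th)
  }
})

test_that("inclination of axis-aligned and rotated ellipses matches their geometry", {
  expect_lt(abs(inclinationAngle(ellipseMask(50, 20))$theta), 1)
  th <- inclinationAngle(ellipseMask(50, 20, angleDeg = 30))$theta
  expect_lt(abs(abs(th) - 30), 2)
})

test_that("alignment makes the longest chord horizontal and preserves area", {
  obj <- asMaskObj <- SegmentedObject(1L, ellipseMask(50, 20, angleDeg = 30))
  expect_identical(alignHorizontal(obj, 0), obj)   # identity rotation

  al <- alignHorizontal(obj)
  expect_lte(abs(inclinationAngle(al)$theta), 2)
  expect_lt(abs(regionArea(al) - regionArea(obj)) / regionArea(obj), 0.03)

  withr::with_seed(19, {
    for (ang in stats::runif(3, -80, 80)) {
      m <- ellipseMask(40, 15, angleDeg = ang)
      al <- alignHorizontal(SegmentedObject(1L, m))
      expect_lte(abs(inclinationAngle(al)$theta), 2)
      expect_lt(abs(regionArea(al) - sum(m)) / sum(m), 0.03)
    }
  })
})

test_that("major/minor axes recover rectangle, disk and filament dimensions", {
  ax <- majorMinorAxes(barMask(40, 100))
  expect_equal(unname(ax), c(100, 40))

  ax <- majorMinorAxes(diskMask(30))
  expect_lt(abs(ax["major"] - 60), 2.5)
  expect_lt(abs(ax["minor"] - 60), 2.5)

  withr::with_seed(4, {
    p <- genusArchetypes()$Oscillatoria
    d <- drawObject("Oscillatoria", p, rotate = FALSE)
    ax <- majorMinorAxes(objMask(alignHorizontal(SegmentedObject(1L, d$mask))))
    expect_gte(ax["major"] / ax["minor"], 8)
  })
})

test_that("width-factor strips follow the analytic profiles of simple shapes", {
  wp <- widthProfile(barMask(40, 100))
  expect_equal(wp$strips, rep(0.4, 5))
  expect_equal(wp$objectLength, 100)
  expect_equal(wp$nStrips, 5L)

  wp <- widthProfile(diskMask(50))
  expect_equal(wp$strips[1], wp$strips[5], tolerance = 0.02)
  expect_equal(wp$strips[2], wp$strips[4], tolerance = 0.02)
  expect_gt(wp$strips[3], wp$strips[1])
  expect_equal(wp$strips[3], 1.0, tolerance = 0.02)
  # analytic chord widths of a circle, maximized per strip
  r <- 50; L <- 2 * r + 1
  analytic <- vapply(1:5, function(b) {
    xl <- -r + (b - 1) / 5 * L; xr <- -r + b / 5 * L
    x <- if (xl <= 0 && xr >= 0) 0 else if (abs(xl) < abs(xr)) xl else xr
    (2 * sqrt(r^2 - x^2) + 1) / L
  }, numeric(1))
  expect_equal(wp$strips, analytic, tolerance = 0.03)

  # isoceles triangle, apex right: strictly decreasing profile
  tri <- matrix(0L, 120, 120)
  for (c in 10:109) {
    half <- round(50 * (109 - c) / 99)
    tri[(60 - half):(60 + half), c] <- 1L
  }
  wp <- widthProfile(tri)
  expect_true(all(diff(wp$strips) < 0))
})

test_that("area is the exact foreground count", {
  expect_equal(regionArea(barMask(10, 10)), 100)
  two <- matrix(0L, 5, 5); two[2, 2] <- 1L; two[4, 4] <- 1L
  expect_equal(regionArea(two), 2)
  a <- regionArea(diskMask(20))
  expect_gte(a, 1218); expect_lte(a, 1295)     # pi * 20^2 within 3%
})

test_that("perimeter is the chain length of the traced boundary", {
  expect_equal(regionPerimeter(barMask(10, 10)), 36)
  expect_equal(regionPerimeter(barMask(1, 50)), 98)
  p <- regionPerimeter(diskMask(30))
  expect_gte(p, 2 * pi * 30 * 0.95)
  expect_lte(p, 2 * pi * 30 * 1.15)
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_equal(regionPerimeter(one), 0)
})

test_that("the shape index separates circular, elongated and irregular outlines", {
  expect_equal(classifyShape(diskMask(40)), 0L)
  expect_equal(classifyShape(barMask(12, 200)), 1L)
  L <- matrix(0L, 100, 100)
  L[10:89, 10:39] <- 1L
  L[60:89, 10:89] <- 1L                         # two 80x30 bars joined
  expect_equal(classifyShape(L), -1L)
})

test_that("the polar spectrum localizes gratings and shifts under rotation", {
  expect_equal(sum(fourierSpectrum(matrix(0.5, 40, 40))$descriptor), 0)

  n <- 64L; k <- 8 / 64
  g <- matrix(rep(0.5 + 0.4 * sin(2 * pi * seq_len(n) * k), each = n), n, n)
  sp <- fourierSpectrum(g)
  expect_equal(which.max(sp$radial), ceiling(k / 0.5 * 16))
  expect_equal(which.max(sp$angular), 1L)       # normal along the x axis
  expect_true(all(sp$S >= 0))
  expect_equal(unname(rowSums(sp$S) / sum(sp$S)), sp$radial, tolerance = 1e-9)

  sp90 <- fourierSpectrum(t(g))                 # the same texture rotated 90
  expect_lt(max(abs(sp90$radial - sp$radial)) / max(sp$radial), 0.05)
  shifted <- sp$angular[((seq_len(16) - 1 + 8) %% 16) + 1]
  expect_equal(which.max(sp90$angular), which.max(shifted))
})

test_that("PCA retains orthonormal descending components and reconstructs training data", {
  withr::with_seed(23, {
    # rank-2 data: eigenvalues 3..8 vanish
    basis <- matrix(stats::rnorm(2 * 32), 2, 32)
    X <- matrix(stats::rnorm(100 * 2), 100, 2) %*% basis
    p <- fitPCA(X, k = 8)
    expect_lt(max(p@eigenvalues[3:8]), 1e-10)
    expect_lt(max(abs(p@components %*% t(p@components) - diag(8))), 1e-8)
    expect_true(all(diff(p@eigenvalues) <= 1e-12))

    # isotropic data: all eigenvalues near 1 (Marchenko-Pastur edges at
    # (1 +/- sqrt(32/n))^2, well inside [0.7, 1.3] for n = 4000)
    Xi <- matrix(stats::rnorm(4000 * 32), 4000, 32)
    pi8 <- fitPCA(Xi, k = 8)
    expect_true(all(pi8@eigenvalues > 0.7 & pi8@eigenvalues < 1.3))

    # captured variance identity
    scores <- projectPCA(pi8, Xi)
    recon <- scores %*% pi8@components
    centered <- sweep(Xi, 2, pi8@center)
    lost <- sum((centered - recon)^2) / sum(centered^2)
    ev <- eigen(stats::cov(Xi), symmetric = TRUE)$values
    expect_equal(lost, 1 - sum(ev[1:8]) / sum(ev), tolerance = 1e-8)
  })
  expect_error(fitPCA(matrix(0, 5, 32), k = 8), "at least")
})

test_that("PCA projection matches direct matrix arithmetic", {
  withr::with_seed(6, {
    X <- matrix(stats::rnorm(50 * 32), 50, 32)
    p <- fitPCA(X, k = 8)
    expect_equal(projectPCA(p, p@center), rep(0, 8))
    expect_equal(projectPCA(p, p@center + p@components[1, ]),
                 c(1, rep(0, 7)), tolerance = 1e-10)
    x <- stats::rnorm(32)
    expect_lt(max(abs(projectPCA(p, x) -
                      drop(p@components %*% (x - p@center)))), 1e-10)
  })
  expect_error(projectPCA(fitPCA(diag(32)[1:10, ], 8), stats::rnorm(5)),
               "length")
})

test_that("the assembled vector has 21 features with the documented composition", {
  withr::with_seed(30, {
    descr <- matrix(stats::runif(20 * 32), 20, 32)
    pca <- fitPCA(descr, 8)
    mkrect <- function() {
      m <- matrix(1L, 40, 100)      # tight bbox, as segmentation produces
      crop <- array(0.5, c(dim(m), 3))
      SegmentedObject(1L, m, colorCrop = crop)
    }
    # the rectangle is already horizontal; its longest chord is a diagonal,
    # so auto-alignment is skipped to measure it in its stated pose
    f <- assembleFeatures(mkrect(), pca, align = FALSE)
    expect_length(f, 21L)
    expect_named(f, paste0("F", 1:21))
    expect_equal(unname(f["F6"]), 0.4)
    expect_equal(unname(f[paste0("F", 9:13)]), rep(0.4, 5))
    expect_equal(unname(f["F6"]), unname(f["F3"] / f["F2"]))
    expect_equal(unname(f["F7"]), unname(f["F4"] / f["F2"]))
    expect_equal(unname(f["F8"]), unname(f["F5"] / f["F2"]))
    # flat texture: raw descriptor is zero, so F14..F21 is the projection
    # of the zero descriptor
    expect_equal(unname(f[paste0("F", 14:21)]),
                 unname(projectPCA(pca, rep(0, 32))))
  })
})

test_that("geometric features are invariant to object orientation", {
  # shapes whose axes span >= ~25 px, so the 5% band is more than one
  # pixel of quantization
  # the same object rasterized at two different orientations must give
  # matching features after auto-alignment; axes span >= ~45 px so the 5%
  # band comfortably exceeds one pixel of quantization
  withr::with_seed(17, {
    for (rep in 1:3) {
      angs <- stats::runif(2, 10, 80)
      copies <- lapply(angs, function(a)
        SegmentedObject(1L, ellipseMask(120, 45, angleDeg = a)))
      raw0 <- algascope:::extractRawFeatures(copies[[1]])
      raw1 <- algascope:::extractRawFeatures(copies[[2]])
      expect_equal(raw1$geom["F1"], raw0$geom["F1"])
      rel <- abs(raw1$geom[2:13] - raw0$geom[2:13]) /
        pmax(abs(raw0$geom[2:13]), 1e-9)
      expect_lt(max(rel), 0.05)
    }
    # a more elongated outline, same property
    for (rep in 1:3) {
      angs <- stats::runif(2, 10, 80)
      copies <- lapply(angs, function(a)
        SegmentedObject(1L, ellipseMask(90, 25, angleDeg = a)))
      raw0 <- algascope:::extractRawFeatures(copies[[1]])
      raw1 <- algascope:::extractRawFeatures(copies[[2]])
      expect_equal(raw1$geom["F1"], raw0$geom["F1"])
      rel <- abs(raw1$geom[2:13] - raw0$geom[2:13]) /
        pmax(abs(raw0$geom[2:13]), 1e-9)
      expect_lt(max(rel), 0.05)
    }
  })
})

test_that("features scale as lengths, areas and dimensionless ratios", {
  big <- ellipseMask(100, 40)
  small <- ellipseMask(50, 20)
  rb <- algascope:::extractRawFeatures(SegmentedObject(1L, big))
  rs <- algascope:::extractRawFeatures(SegmentedObject(1L, small))
  for (f in c("F2", "F3", "F5"))
    expect_equal(unname(rb$geom[f] / rs$geom[f]), 2, tolerance = 0.03)
  expect_equal(unname(rb$geom["F4"] / rs$geom["F4"]), 4, tolerance = 0.05)
  expect_equal(unname(rb$geom["F6"]), unname(rs$geom["F6"]), tolerance = 0.05)
  rel <- abs(rb$geom[9:13] - rs$geom[9:13]) / pmax(rs$geom[9:13], 1e-9)
  expect_lt(max(rel), 0.05)
})
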