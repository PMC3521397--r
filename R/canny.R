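#' Canny detector parameters
#'
#' @param sigma Gaussian standard deviation in pixels used for smoothing.
#' @param low,high Hysteresis thresholds as fractions of the maximum gradient
#'   magnitude; weak pixels (between them) are kept only when 8-connected,
#'   transitively, to a strong pixel (above \code{high}).
#' @return A validated list of class \code{"cannyParams"}.
#' @export
cannyParams <- function(sigma = 1.4, low = 0.1, high = 0.25) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!(0 < low && low < high && high < 1))
    stop("thresholds must satisfy 0 < low < high < 1")
  structure(list(sigma = sigma, low = low, high = high),
            class = "cannyParams")
}

#' Gaussian smoothing
#'
#' Convolves a grayscale image with a normalized 2-D Gaussian, implemented
#' separably; the kernel is truncated at 3 sigma and borders are replicated,
#' so dimensions are preserved and a constant image passes unchanged.
#'
#' @param img Gray matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Smoothed matrix of identical dimensions.
#' @export
gaussianSmooth <- function(img, sigma) {
  stopifnotGray(img)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  sepConvolve(img, k / sum(k))
}

#' First-derivative gradient field
#'
#' Computes horizontal and vertical derivatives with 3x3 Sobel kernels
#' (columns increase rightward, rows downward), then the gradient magnitude
#' \eqn{g = (G_x^2 + G_y^2)^{1/2}} and direction at each pixel. The
#' direction is stored as \code{atan2(gy, gx)} for non-maximal-suppression
#' sector quantization and is 0 where both derivatives vanish.
#'
#' @param img Gray matrix with both dimensions >= 3.
#' @return List with matrices \code{gx}, \code{gy}, \code{magnitude},
#'   \code{direction} (radians).
#' @export
gradientField <- function(img) {
  stopifnotGray(img)
  if (min(dim(img)) < 3L) stop("image must be at least 3 x 3")
  h <- nrow(img); w <- ncol(img)
  mp <- padReplicate(img, 1L)
  sm <- function(dr, dc) shiftView(mp, 1L, dr, dc, h, w)
  # Sobel: smooth [1 2 1] across, difference [-1 0 1] along
  gx <- (sm(-1, 1) + 2 * sm(0, 1) + sm(1, 1)) -
        (sm(-1, -1) + 2 * sm(0, -1) + sm(1, -1))
  gy <- (sm(1, -1) + 2 * sm(1, 0) + sm(1, 1)) -
        (sm(-1, -1) + 2 * sm(-1, 0) + sm(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  dir <- matrix(0, h, w)
  nz <- mag > 0
  dir[nz] <- atan2(gy[nz], gx[nz])
  list(gx = gx, gy = gy, magnitude = mag, direction = dir)
}

#' Edge direction as the ratio arc-tangent
#'
#' The direction angle written as \eqn{\alpha = \tan^{-1}(G_x / G_y)}; kept
#' as a standalone formula (radians) for checking the gradient identities.
#' Returns 0 where both derivatives are zero.
#'
#' @param gx,gy Derivative values (scalars or equal-shaped arrays).
#' @return Angle(s) in radians in \[-pi/2, pi/2\].
#' @export
edgeDirection <- function(gx, gy) {
  out <- ifelse(gx == 0 & gy == 0, 0, atan(gx / gy))
  out[gy == 0 & gx > 0] <- pi / 2
  out[gy == 0 & gx < 0] <- -pi / 2
  out
}

#' Canny edge detection
#'
#' Smooth with a Gaussian, take Sobel gradients, thin by non-maximal
#' suppression along the quantized gradient direction (4 sectors at 0, 45,
#' 90, 135 degrees), double-threshold the surviving magnitudes, and link by
#' hysteresis: weak pixels are retained iff 8-connected, transitively, to a
#' strong pixel. Returns a 1-px-wide edge mask; a constant image yields an
#' empty mask.
#'
#' @param img Gray matrix.
#' @param params A [cannyParams()] list.
#' @return Integer 0/1 edge mask of the same dimensions.
#' @export
cannyEdges <- function(img, params = cannyParams()) {
  stopifnotGray(img)
  stopifnot(inherits(params, "cannyParams"))
  h <- nrow(img); w <- ncol(img)
  g <- gradientField(gaussianSmooth(img, params$sigma))
  mag <- g$magnitude
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0L, h, w))

  # quantize direction (mod pi) into 4 sectors; compare against the two
  # neighbours along that direction, using zero-padded shifted views
  ang <- g$direction %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  mp <- matrix(0, h + 2L, w + 2L)
  mp[2:(h + 1), 2:(w + 1)] <- mag
  sv <- function(dr, dc) mp[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    o <- offs[[as.character(s)]]
    n1[sel] <- sv(o[1], o[2])[sel]
    n2[sel] <- sv(-o[1], -o[2])[sel]
  }
  # strict comparison on one side breaks plateau ties (a symmetric step
  # would otherwise yield a 2-px line)
  ridge <- mag > n1 & mag >= n2 & mag > 0

  strong <- ridge & mag >= params$high * mmax
  weak <- ridge & mag >= params$low * mmax
  if (!any(strong)) return(matrix(0L, h, w))
  lab <- label8(weak)
  keep <- sort(unique(lab[strong]))
  asMask(matrix(lab %in% keep, h, w))
}
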