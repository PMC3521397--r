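#' Read a micrograph from disk
#'
#' Reads a PNG, TIFF or JPEG file into an RGB array. Grayscale files are
#' promoted to three identical channels; an alpha channel, if present, is
#' dropped. Intensities are kept as floats in \[0,1\]; quantization to 8 bits
#' happens only at file I/O.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return Numeric \code{H x W x 3} array in \[0,1\].
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = , tiff = tiff::readTIFF(path),
      # fall back to EBImage for jpeg and anything else it can decode
      EBImage::imageData(EBImage::transpose(EBImage::readImage(path)))
    ),
    error = function(e) stop("cannot decode image file ", path, ": ",
                             conditionMessage(e))
  )
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("unsupported channel layout in ", path)
  if (any(dim(img)[1:2] < 1L)) stop("zero-sized image: ", path)
  clamp01(img)
}

#' Write an image or mask to disk
#'
#' Gray matrices and RGB arrays are written as 8-bit PNG or TIFF according to
#' the file extension; 0/1 masks are written as \{0, 255\} grayscale.
#'
#' @param img Numeric matrix or H x W x 3 array in \[0,1\], or a 0/1 mask.
#' @param path Output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(img, path) {
  if (is.matrix(img) && all(img %in% c(0, 1))) img <- img * 1.0
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

#' Histogram equalization
#'
#' Maps pixel intensities through the cumulative distribution of a 256-bin
#' histogram so that the output histogram is approximately uniform. For RGB
#' input the value channel (per-pixel channel maximum) is equalized and the
#' three channels rescaled proportionally, which enhances contrast without
#' distorting hue. The mapping is monotone, so pixel ordering is preserved;
#' a constant image maps to itself.
#'
#' @param img Gray matrix or RGB array in \[0,1\].
#' @param levels Number of histogram bins (default 256, the 8-bit raster
#'   resolution of the source imagery).
#' @return Image of the same shape and mode.
#' @export
equalizeContrast <- function(img, levels = 256L) {
  if (is.matrix(img)) return(equalizeGray(img, levels))
  stopifnotRGB(img)
  v <- pmax(img[, , 1], img[, , 2], img[, , 3])
  v2 <- equalizeGray(v, levels)
  gain <- ifelse(v > 0, v2 / v, 0)
  out <- img
  for (ch in 1:3) out[, , ch] <- clamp01(img[, , ch] * gain)
  out
}

equalizeGray <- function(m, levels = 256L) {
  q <- pmin(as.integer(levels) - 1L, floor(m * levels))
  counts <- tabulate(q + 1L, nbins = levels)
  cdf <- cumsum(counts)
  n <- length(m)
  cmin <- cdf[which(counts > 0)[1]]
  if (cmin == n) return(m)  # single occupied bin: constant image unchanged
  mapped <- (cdf - cmin) / (n - cmin)
  matrix(mapped[q + 1L], nrow(m), ncol(m))
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114). A matrix
#' input is assumed to be gray already and is returned unchanged.
#'
#' @param img RGB array (or gray matrix) in \[0,1\].
#' @return Numeric matrix in \[0,1\].
#' @export
toGray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnotRGB(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Binarize a grayscale image and take its complement
#'
#' Computes Otsu's global threshold, thresholds the image, and complements
#' the result so that dark objects on the bright field become foreground
#' (1, white) and the background becomes 0 (black). A constant image has no
#' threshold; an all-background mask is returned with a warning. Otsu's
#' split is only meaningful for a genuinely bimodal histogram: when the two
#' class means it produces differ by less than \code{minContrast} the image
#' is treated as object-free (thresholding inside a unimodal noise
#' distribution would otherwise fabricate foreground out of half the
#' background).
#'
#' @param img Gray matrix in \[0,1\].
#' @param minContrast Minimum separation of the two Otsu class means, as a
#'   fraction of full intensity range (default 0.15; sensor noise spans a
#'   few hundredths, real object/background contrast several tenths).
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
binarizeComplement <- function(img, minContrast = 0.15) {
  stopifnotGray(img)
  if (max(img) - min(img) < .Machine$double.eps^0.5) {
    warning("constant image: no threshold exists, returning all-background mask")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  dark <- img <= thr
  if (mean(img[!dark]) - mean(img[dark]) < minContrast)
    return(matrix(0L, nrow(img), ncol(img)))
  asMask(dark)  # complement folded in: dark pixels become 1
}

#' 3x3 median filter on a binary mask
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood (borders
#' replicated), which removes isolated salt noise while preserving solid
#' regions up to 1-px boundary smoothing. For a binary image the median is 1
#' exactly when at least 5 of the 9 neighbourhood pixels are 1.
#'
#' @param mask Integer 0/1 matrix.
#' @return Filtered 0/1 matrix of the same dimensions.
#' @export
medianFilter3 <- function(mask) {
  mask <- asMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  mp <- padReplicate(mask, 1L)
  s <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1)
    s <- s + shiftView(mp, 1L, dr, dc, h, w)
  asMask(s >= 5L)
}
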