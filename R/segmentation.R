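#' Morphological cleanup of an edge mask
#'
#' Turns a raw edge map into solid object regions: (i) dilate with a 3x3
#' square to close small gaps in the edge chains, (ii) fill enclosed holes,
#' (iii) erode with the same element to restore scale, (iv) clear any region
#' touching the image border, and (v) remove connected components smaller
#' than \code{minArea} pixels (strictly below; a 50-px component survives the
#' default).
#'
#' @param edges Integer 0/1 mask (typically from [cannyEdges()]).
#' @param minArea Minimum component area in pixels retained (default 50).
#' @return Cleaned 0/1 mask.
#' @export
morphologyCleanup <- function(edges, minArea = 50L) {
  m <- asMask(edges)
  h <- nrow(m); w <- ncol(m)
  kern <- matrix(1L, 3L, 3L)
  m <- EBImage::dilate(m, kern)
  m <- EBImage::fillHull(m)
  m <- asMask(EBImage::erode(m, kern))
  lab <- label8(m)
  if (max(lab) == 0) return(matrix(0L, h, w))
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- union(border[border > 0], which(areas < minArea))
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}

#' Label components and separate probable overlaps
#'
#' 8-connected component labeling of a cleaned mask. Components whose
#' bounding rectangle exceeds \code{overlapLen} pixels along its longer side
#' and measures at least \code{overlapLen} pixels perpendicular to it are
#' flagged as probable clusters of touching objects and split by a
#' distance-transform watershed (regional maxima of the distance map as
#' markers, nearby maxima merged); if the watershed yields a single region
#' the component is emitted unsplit. Output order is top-left-first by
#' bounding-box origin.
#'
#' @param mask Cleaned 0/1 mask (every component >= the area floor).
#' @param overlapLen Side length of the overlap bounding-rectangle rule
#'   (default 50 px).
#' @param minArea Fragments below this area after a watershed split are
#'   discarded (default 50 px, matching the cleanup floor).
#' @return List of entries \code{list(mask, bbox, overlapping)} where
#'   \code{mask} is cropped to \code{bbox} (0-based half-open).
#' @export
separateObjects <- function(mask, overlapLen = 50L, minArea = 50L) {
  mask <- asMask(mask)
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0) return(list())
  out <- list()
  for (i in seq_len(n)) {
    comp <- asMask(lab == i)
    bbox <- maskBBox(comp)
    dims <- c(bbox[3] - bbox[1], bbox[4] - bbox[2])
    flagged <- max(dims) > overlapLen && min(dims) >= overlapLen
    crop <- comp[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4], drop = FALSE]
    if (!flagged) {
      out[[length(out) + 1L]] <- list(mask = crop, bbox = bbox,
                                      overlapping = FALSE)
      next
    }
    pieces <- watershedSplit(crop, minArea = minArea)
    for (p in pieces) {
      pb <- maskBBox(p)
      out[[length(out) + 1L]] <- list(
        mask = p[(pb[1] + 1):pb[3], (pb[2] + 1):pb[4], drop = FALSE],
        bbox = as.integer(pb + c(bbox[1], bbox[2], bbox[1], bbox[2])),
        overlapping = TRUE)
    }
  }
  ord <- order(vapply(out, function(o) o$bbox[1], numeric(1)),
               vapply(out, function(o) o$bbox[2], numeric(1)))
  out[ord]
}

# Distance-transform watershed on one cropped component. A 1-px zero pad
# gives the distance map a background to measure against. Catchment
# markers are detected in a 15-px neighbourhood and basins whose
# separating saddle is shallower than 4 px of distance are merged, so the
# shallow multiple maxima of a scalloped colony outline or a rasterized
# ridge line (a px or two deep) collapse into one region while two
# genuinely overlapping objects (whose waist cuts several px deeper)
# still split.
watershedSplit <- function(crop, minArea = 50L) {
  h <- nrow(crop); w <- ncol(crop)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1), 2:(w + 1)] <- crop
  d <- EBImage::distmap(padded)
  ws <- EBImage::watershed(d, tolerance = 4, ext = 15)
  ws <- matrix(as.integer(ws), h + 2L, w + 2L)[2:(h + 1), 2:(w + 1)]
  ids <- setdiff(unique(as.vector(ws)), 0)
  if (length(ids) <= 1L) return(list(crop))
  pieces <- lapply(ids, function(k) asMask(ws == k & crop == 1L))
  pieces <- pieces[vapply(pieces, sum, numeric(1)) >= minArea]
  if (length(pieces) <= 1L) list(crop) else pieces
}

#' Pair binary regions with their colour crops
#'
#' Windows the original colour image to each component's bounding box, zeroes
#' background pixels (mask = 0), and assigns consecutive indices from 1,
#' yielding one [SegmentedObject-class] per component.
#'
#' @param components List as returned by [separateObjects()].
#' @param original RGB array with the dimensions the components came from.
#' @return List of [SegmentedObject-class].
#' @export
pairMasks <- function(components, original) {
  stopifnotRGB(original)
  lapply(seq_along(components), function(i) {
    comp <- components[[i]]
    b <- comp$bbox
    if (b[3] > nrow(original) || b[4] > ncol(original))
      stop("component bbox exceeds original image dimensions")
    crop <- original[(b[1] + 1):b[3], (b[2] + 1):b[4], , drop = FALSE]
    for (ch in 1:3) crop[, , ch] <- crop[, , ch] * comp$mask
    SegmentedObject(index = i, mask = comp$mask, bbox = b,
                    colorCrop = crop, overlapping = comp$overlapping)
  })
}

#' Segment a colour micrograph end to end
#'
#' Runs the full detection chain: histogram equalization, grayscale
#' conversion, Otsu binarization with complement, 3x3 median filtering,
#' Canny edge detection on the preprocessed binary image, morphological
#' cleanup, component separation, and pairing with the original colour
#' image.
#'
#' @param img RGB array in \[0,1\].
#' @param params [cannyParams()] for the edge detector.
#' @param minArea,overlapLen Morphology thresholds in pixels.
#' @return List of [SegmentedObject-class].
#' @export
segmentScene <- function(img, params = cannyParams(), minArea = 50L,
                         overlapLen = 50L) {
  stopifnotRGB(img)
  # Histogram equalization is monotone, so binarizing the raw intensities
  # is equivalent to binarizing the equalized image at the mapped threshold;
  # computing Otsu's threshold on the raw (bimodal) histogram keeps the
  # split well-posed, since equalization flattens the histogram the method
  # needs. The equalized image is what a user would inspect; the masks are
  # identical either way.
  gray <- toGray(img)
  binary <- medianFilter3(binarizeComplement(gray))
  edges <- cannyEdges(binary * 1.0, params)
  cleaned <- morphologyCleanup(edges, minArea = minArea)
  comps <- separateObjects(cleaned, overlapLen = overlapLen, minArea = minArea)
  pairMasks(comps, img)
}
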