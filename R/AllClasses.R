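#' @import methods
NULL

#' Segmented object: one detected region of a micrograph
#'
#' Couples a binary mask (cropped to the object's bounding box) with the
#' corresponding window of the original colour image, as produced by
#' [segmentScene()] / [pairMasks()]. Background pixels of the colour crop are
#' zeroed so that downstream texture features see only the object.
#'
#' @slot index Integer id, consecutive from 1 within a scene.
#' @slot mask Integer matrix over \{0,1\}; 1 = object.
#' @slot bbox Integer length-4 vector \code{(r0, c0, r1, c1)}, 0-based
#'   half-open, in source-image coordinates (rows increase downward).
#' @slot colorCrop Numeric \code{h x w x 3} array in \[0,1\], same height and
#'   width as \code{mask}.
#' @slot overlapping Logical; \code{TRUE} when the region was flagged by the
#'   50-px bounding-rectangle rule as a probable cluster of touching objects.
#'
#' @export
setClass("SegmentedObject",
  representation(
    index = "integer",
    mask = "matrix",
    bbox = "integer",
    colorCrop = "array",
    overlapping = "logical"
  )
)

setValidity("SegmentedObject", function(object) {
  m <- object@mask
  if (!all(m %in% c(0L, 1L))) return("mask values must be 0/1")
  if (sum(m) < 1) return("mask must contain at least one foreground pixel")
  if (length(object@bbox) != 4L) return("bbox must have length 4")
  b <- object@bbox
  if (b[3] - b[1] != nrow(m) || b[4] - b[2] != ncol(m))
    return("bbox extent must match mask dimensions")
  d <- dim(object@colorCrop)
  if (length(d) != 3L || d[3] != 3L || d[1] != nrow(m) || d[2] != ncol(m))
    return("colorCrop must be an h x w x 3 array matching the mask")
  TRUE
})

#' Construct a SegmentedObject
#'
#' @param index integer id.
#' @param mask 0/1 matrix.
#' @param bbox integer (r0, c0, r1, c1), 0-based half-open; defaults to the
#'   mask extent placed at the origin.
#' @param colorCrop h x w x 3 array in \[0,1\]; defaults to the mask replicated
#'   over three channels.
#' @param overlapping logical flag.
#' @return A [SegmentedObject-class] instance.
#' @export
SegmentedObject <- function(index, mask,
                            bbox = c(0L, 0L, nrow(mask), ncol(mask)),
                            colorCrop = NULL, overlapping = FALSE) {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (is.null(colorCrop))
    colorCrop <- array(rep(as.numeric(mask), 3), c(dim(mask), 3L))
  new("SegmentedObject", index = as.integer(index), mask = mask,
      bbox = as.integer(bbox), colorCrop = colorCrop,
      overlapping = isTRUE(overlapping))
}

#' @describeIn SegmentedObject Accessor for the binary mask.
#' @param object,x a \code{SegmentedObject}.
#' @export
objMask <- function(x) x@mask

#' @describeIn SegmentedObject Accessor for the colour crop.
#' @export
objCrop <- function(x) x@colorCrop

#' @describeIn SegmentedObject Accessor for the bounding box.
#' @export
objBBox <- function(x) x@bbox

#' @describeIn SegmentedObject Accessor for the object index.
#' @export
objIndex <- function(x) x@index

#' @describeIn SegmentedObject Accessor for the overlap flag.
#' @export
isOverlapping <- function(x) x@overlapping

setMethod("show", "SegmentedObject", function(object) {
  cat(sprintf("SegmentedObject #%d: %d x %d px, area %d px^2%s\n",
              object@index, nrow(object@mask), ncol(object@mask),
              sum(object@mask),
              if (object@overlapping) " [overlap-flagged]" else ""))
})

#' Principal-component model for the polar Fourier texture descriptor
#'
#' Fitted by [fitPCA()] on training descriptors only and frozen thereafter;
#' [projectPCA()] maps a raw descriptor to its k retained components.
#'
#' @slot center Numeric mean vector of the training descriptors.
#' @slot components Numeric k x d matrix of orthonormal loading rows, sorted
#'   by decreasing explained variance.
#' @slot eigenvalues Numeric length-k vector of component variances,
#'   descending.
#' @export
setClass("PCAModel",
  representation(center = "numeric", components = "matrix",
                 eigenvalues = "numeric")
)

setValidity("PCAModel", function(object) {
  k <- nrow(object@components)
  if (length(object@eigenvalues) != k)
    return("one eigenvalue per component required")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted descending")
  if (any(object@eigenvalues < -1e-10))
    return("eigenvalues must be non-negative")
  g <- object@components %*% t(object@components)
  if (max(abs(g - diag(k))) > 1e-8)
    return("component rows must be orthonormal")
  if (ncol(object@components) != length(object@center))
    return("center length must equal descriptor dimension")
  TRUE
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("PCAModel: %d components over %d-dim descriptors\n",
              nrow(object@components), length(object@center)))
  cat("  eigenvalues:", paste(signif(ev, 3), collapse = " "), "\n")
})

#' Multilayer-perceptron classifier
#'
#' A single-hidden-layer feed-forward network with hyperbolic-tangent
#' activations on both layers, sized 21-8-5 by default: 21 input features,
#' 8 hidden units, one output per genus. Inputs are standardized by the
#' training-set mean and standard deviation stored with the model; targets
#' are coded +1 for the true class and -1 elsewhere to match the tanh range.
#'
#' @slot W1,b1 Hidden-layer weights (hidden x input) and biases.
#' @slot W2,b2 Output-layer weights (output x hidden) and biases.
#' @slot labels Character vector of class names, one per output unit.
#' @slot center,scale Feature standardizer (training mean / sd).
#' @slot unknownThreshold Maximum-activation cutoff below which a prediction
#'   is rejected as \code{"Unidentified"} (foreign objects, debris).
#' @export
setClass("MLPModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 labels = "character", center = "numeric", scale = "numeric",
                 unknownThreshold = "numeric")
)

setValidity("MLPModel", function(object) {
  if (nrow(object@W2) != length(object@labels))
    return("one output unit per label required")
  if (ncol(object@W2) != nrow(object@W1))
    return("W2 columns must equal W1 rows (hidden size)")
  if (length(object@b1) != nrow(object@W1) ||
      length(object@b2) != nrow(object@W2))
    return("bias lengths must match layer sizes")
  if (anyDuplicated(object@labels)) return("labels must be distinct")
  if (length(object@center) != ncol(object@W1) ||
      length(object@scale) != ncol(object@W1))
    return("standardizer length must equal input size")
  TRUE
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d-%d-%d tanh network\n",
              ncol(object@W1), nrow(object@W1), nrow(object@W2)))
  cat("  classes:", paste(object@labels, collapse = ", "), "\n")
  cat(sprintf("  rejection threshold: %g\n", object@unknownThreshold))
})

#' Training trace of an MLP fit
#'
#' @slot epochs Number of epochs actually run.
#' @slot trainRMSE,valRMSE Per-epoch root-mean-squared error on the training
#'   and the held-out cross-validation split.
#' @slot stoppedEarly TRUE when validation RMSE rose for \code{patience}
#'   consecutive epochs before \code{maxEpochs}.
#' @slot bestEpoch Epoch whose validation RMSE was lowest; the returned
#'   weights are those of this epoch.
#' @export
setClass("TrainingState",
  representation(epochs = "integer", trainRMSE = "numeric",
                 valRMSE = "numeric", stoppedEarly = "logical",
                 bestEpoch = "integer")
)

setValidity("TrainingState", function(object) {
  if (length(object@trainRMSE) != object@epochs ||
      length(object@valRMSE) != object@epochs)
    return("RMSE traces must have one entry per epoch")
  if (any(object@trainRMSE < 0) || any(object@valRMSE < 0))
    return("RMSE must be non-negative")
  TRUE
})

setMethod("show", "TrainingState", function(object) {
  cat(sprintf("TrainingState: %d epochs%s, best validation RMSE %.4f at epoch %d\n",
              object@epochs,
              if (object@stoppedEarly) " (early stop)" else "",
              if (object@epochs > 0) min(object@valRMSE) else NA_real_,
              object@bestEpoch))
})

#' Synthetic micrograph with ground truth
#'
#' One generated scene: a bright noisy background carrying dark algae-like
#' objects of the five genus archetypes (plus optional debris), together with
#' the per-object truth needed to score every pipeline stage.
#'
#' @slot image Numeric H x W x 3 array in \[0,1\].
#' @slot truth data.frame with one row per object: \code{label},
#'   bounding box \code{r0,c0,r1,c1} (0-based half-open), \code{area},
#'   \code{centroidR}, \code{centroidC}.
#' @slot masks List of 0/1 matrices, one per truth row, cropped to its bbox.
#' @slot seed Integer seed the scene was generated from.
#' @export
setClass("SyntheticScene",
  representation(image = "array", truth = "data.frame", masks = "list",
                 seed = "integer")
)

setValidity("SyntheticScene", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
  if (nrow(object@truth) != length(object@masks))
    return("one mask per truth row required")
  if (nrow(object@truth) > 0) {
    b <- object@truth
    if (any(b$r0 < 0) || any(b$c0 < 0) || any(b$r1 > d[1]) || any(b$c1 > d[2]))
      return("truth bboxes must lie within the image")
  }
  TRUE
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticScene: %d x %d px, %d object(s) [seed %d]\n",
              d[1], d[2], nrow(object@truth), object@seed))
  if (nrow(object@truth) > 0)
    cat("  labels:", paste(object@truth$label, collapse = ", "), "\n")
})

#' @describeIn SyntheticScene Accessor for the RGB image array.
#' @param x a \code{SyntheticScene}.
#' @export
sceneImage <- function(x) x@image

#' @describeIn SyntheticScene Accessor for the ground-truth table.
#' @export
sceneTruth <- function(x) x@truth

#' @describeIn SyntheticScene Accessor for the list of true object masks.
#' @export
sceneMasks <- function(x) x@masks
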