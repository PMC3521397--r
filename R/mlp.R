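#' Training configuration for the MLP
#'
#' Defaults follow the study protocol: learning rate 0.05, momentum 0.05,
#' at most 400 epochs, 10\% of the data held out for cross-validation, and
#' training stopped when the validation RMSE has risen for \code{patience}
#' consecutive epochs (a single noisy uptick should not stop training).
#'
#' @param learningRate Step size for the per-presentation weight updates.
#' @param momentum Fraction of the previous update added to the current one.
#' @param maxEpochs Epoch cap.
#' @param validationFraction Fraction of the data held out (stratified).
#' @param patience Consecutive epochs of rising validation RMSE tolerated.
#' @param seed RNG seed for initialization, the validation split and the
#'   per-epoch presentation order.
#' @return Validated list of class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(learningRate = 0.05, momentum = 0.05,
                           maxEpochs = 400L, validationFraction = 0.10,
                           patience = 10L, seed = 1L) {
  if (learningRate <= 0) stop("learningRate must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (validationFraction <= 0 || validationFraction >= 0.5)
    stop("validationFraction must be in (0, 0.5)")
  structure(list(learningRate = learningRate, momentum = momentum,
                 maxEpochs = as.integer(maxEpochs),
                 validationFraction = validationFraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "trainingConfig")
}

#' Initialize an MLP
#'
#' Weights are drawn uniformly in \[-1/sqrt(fan-in), +1/sqrt(fan-in)\] from
#' the seeded RNG; biases start at zero. Deterministic given the seed.
#'
#' @param seed Integer RNG seed.
#' @param layerSizes Integer vector (input, hidden, output); default
#'   \code{c(21, 8, 5)}.
#' @param labels Class names, one per output unit.
#' @param unknownThreshold Maximum-activation cutoff for rejection
#'   (default 0 on tanh outputs).
#' @return An [MLPModel-class].
#' @export
initMLP <- function(seed = 1L, layerSizes = c(21L, 8L, 5L),
                    labels = c("Navicula", "Scenedesmus", "Microcystis",
                               "Oscillatoria", "Chroococcus"),
                    unknownThreshold = 0) {
  stopifnot(length(layerSizes) == 3, length(labels) == layerSizes[3])
  d <- layerSizes
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::runif(d[2] * d[1], -1, 1) / sqrt(d[1]), d[2], d[1])
    W2 <- matrix(stats::runif(d[3] * d[2], -1, 1) / sqrt(d[2]), d[3], d[2])
  })
  new("MLPModel", W1 = W1, b1 = rep(0, d[2]), W2 = W2, b2 = rep(0, d[3]),
      labels = labels, center = rep(0, d[1]), scale = rep(1, d[1]),
      unknownThreshold = unknownThreshold)
}

#' Forward pass
#'
#' \eqn{h = \tanh(W_1 x + b_1)}, \eqn{y = \tanh(W_2 h + b_2)}. The input is
#' standardized by the model's stored training mean and standard deviation.
#'
#' @param model An [MLPModel-class].
#' @param x Numeric feature vector of the model's input length.
#' @param standardize Apply the stored standardizer first (default TRUE).
#' @return Numeric vector of output activations in (-1, 1).
#' @export
mlpForward <- function(model, x, standardize = TRUE) {
  if (length(x) != ncol(model@W1))
    stop("input length must be ", ncol(model@W1))
  if (standardize) x <- (x - model@center) / model@scale
  h <- tanh(drop(model@W1 %*% x) + model@b1)
  tanh(drop(model@W2 %*% h) + model@b2)
}

# Gradient of the half squared error 0.5 * sum((y - t)^2) for one sample
# (standardized input). Returns the four weight/bias gradients.
mlpGradient <- function(model, x, target) {
  a1 <- drop(model@W1 %*% x) + model@b1
  h <- tanh(a1)
  y <- tanh(drop(model@W2 %*% h) + model@b2)
  d2 <- (y - target) * (1 - y^2)
  d1 <- drop(t(model@W2) %*% d2) * (1 - h^2)
  list(W1 = outer(d1, x), b1 = d1, W2 = outer(d2, h), b2 = d2, y = y)
}

mlpRMSE <- function(model, X, targets) {
  Y <- t(apply(X, 1, function(x) mlpForward(model, x, standardize = FALSE)))
  sqrt(mean((Y - targets)^2))
}

targetMatrix <- function(labels, classNames) {
  idx <- match(labels, classNames)
  if (anyNA(idx)) stop("label outside the model's label map")
  t(vapply(idx, function(i) { v <- rep(-1, length(classNames)); v[i] <- 1; v },
           numeric(length(classNames))))
}

#' Train the MLP by momentum backpropagation
#'
#' Online (per-presentation) backpropagation of the squared error with a
#' momentum term: \eqn{\Delta w(t) = -\eta \, \partial E/\partial w +
#' \mu \, \Delta w(t-1)}. Targets are coded +1 for the true class and -1
#' elsewhere. Inputs are standardized by the training-split mean/sd (stored
#' with the model); a stratified \code{validationFraction} split is held out
#' and training stops at \code{maxEpochs} or once the validation RMSE has
#' risen for \code{patience} consecutive epochs, restoring the weights of
#' the best validation epoch.
#'
#' @param model An initialized [MLPModel-class].
#' @param X Numeric matrix, one 21-feature row per sample.
#' @param labels Character vector of true classes (must all appear in the
#'   model's label map, each class present at least twice).
#' @param config A [trainingConfig()].
#' @return List with the trained \code{model} and a
#'   [TrainingState-class] \code{state}.
#' @export
trainMLP <- function(model, X, labels, config = trainingConfig()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) < 20) stop("need at least 20 training pairs")
  classNames <- model@labels
  targets <- targetMatrix(labels, classNames)

  withr::with_seed(config$seed, {
    # stratified validation split
    valIdx <- unlist(lapply(classNames, function(cl) {
      i <- which(labels == cl)
      if (length(i) == 0) return(integer(0))
      i[sample.int(length(i),
                   max(1L, round(length(i) * config$validationFraction)))]
    }))
    trainIdx <- setdiff(seq_len(nrow(X)), valIdx)
    if (!all(classNames %in% labels[trainIdx]))
      stop("degenerate split: a class is absent from the training portion")

    mu <- colMeans(X[trainIdx, , drop = FALSE])
    sg <- apply(X[trainIdx, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    model@center <- mu; model@scale <- sg
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    Xtr <- Xs[trainIdx, , drop = FALSE]; Ttr <- targets[trainIdx, , drop = FALSE]
    Xva <- Xs[valIdx, , drop = FALSE]; Tva <- targets[valIdx, , drop = FALSE]

    vel <- list(W1 = model@W1 * 0, b1 = model@b1 * 0,
                W2 = model@W2 * 0, b2 = model@b2 * 0)
    trainTrace <- valTrace <- numeric(0)
    best <- list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
                 rmse = Inf, epoch = 0L)
    rising <- 0L
    stopped <- FALSE
    epoch <- 0L
    while (epoch < config$maxEpochs) {
      epoch <- epoch + 1L
      for (i in sample(nrow(Xtr))) {
        g <- mlpGradient(model, Xtr[i, ], Ttr[i, ])
        vel$W1 <- -config$learningRate * g$W1 + config$momentum * vel$W1
        vel$b1 <- -config$learningRate * g$b1 + config$momentum * vel$b1
        vel$W2 <- -config$learningRate * g$W2 + config$momentum * vel$W2
        vel$b2 <- -config$learningRate * g$b2 + config$momentum * vel$b2
        model@W1 <- model@W1 + vel$W1; model@b1 <- model@b1 + vel$b1
        model@W2 <- model@W2 + vel$W2; model@b2 <- model@b2 + vel$b2
      }
      trainTrace[epoch] <- mlpRMSE(model, Xtr, Ttr)
      valTrace[epoch] <- mlpRMSE(model, Xva, Tva)
      if (valTrace[epoch] < best$rmse) {
        best <- list(W1 = model@W1, b1 = model@b1, W2 = model@W2,
                     b2 = model@b2, rmse = valTrace[epoch], epoch = epoch)
        rising <- 0L
      } else {
        rising <- rising + 1L
        if (rising >= config$patience) { stopped <- TRUE; break }
      }
    }
  })
  if (best$epoch > 0L) {
    model@W1 <- best$W1; model@b1 <- best$b1
    model@W2 <- best$W2; model@b2 <- best$b2
  }
  state <- new("TrainingState", epochs = epoch %||% 0L,
               trainRMSE = trainTrace, valRMSE = valTrace,
               stoppedEarly = stopped,
               bestEpoch = as.integer(best$epoch))
  list(model = model, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict genus labels
#'
#' Argmax over the five output activations; when the maximum activation
#' falls below the model's rejection threshold the object is labelled
#' \code{"Unidentified"} (foreign objects, debris). Ties go to the lowest
#' output index.
#'
#' @param model A trained [MLPModel-class].
#' @param X Feature vector, or matrix with one sample per row.
#' @return Character vector of predicted labels.
#' @export
predictMLP <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  apply(X, 1, function(x) {
    y <- mlpForward(model, x)
    i <- which.max(y)   # which.max takes the first (lowest index) on ties
    if (y[i] < model@unknownThreshold) "Unidentified" else model@labels[i]
  })
}

#' Confusion matrix and accuracy
#'
#' Builds the (k+1) x (k+1) confusion matrix over the genus labels plus the
#' \code{"Unidentified"} class, with true classes in rows and predictions in
#' columns. Per-class accuracy is the diagonal over the row sum; overall
#' accuracy is the diagonal sum over the total count, so an Unidentified
#' prediction counts as an error for a true-genus row.
#'
#' @param predictions,truth Equal-length label vectors.
#' @param labels The k genus names (defaults to those present in
#'   \code{truth}, excluding Unidentified).
#' @return List with \code{confusion}, \code{perClass} (named accuracies),
#'   \code{overall} (fraction in \[0,1\]), \code{n}.
#' @export
evaluateClassification <- function(predictions, truth, labels = NULL) {
  stopifnot(length(predictions) == length(truth))
  if (is.null(labels)) labels <- setdiff(sort(unique(truth)), "Unidentified")
  lev <- c(labels, "Unidentified")
  if (!all(predictions %in% lev)) stop("prediction label outside the label map")
  if (!all(truth %in% lev)) stop("truth label outside the label map")
  cm <- table(factor(truth, levels = lev), factor(predictions, levels = lev))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  rowTot <- rowSums(cm)
  perClass <- ifelse(rowTot > 0, diag(cm) / rowTot, NA_real_)
  list(confusion = cm, perClass = perClass,
       overall = sum(diag(cm)) / length(truth), n = length(truth))
}

#' Serialize an MLP model (with its PCA) to JSON
#'
#' @param model An [MLPModel-class].
#' @param path Output file path.
#' @param pca Optional [PCAModel-class] stored alongside.
#' @param state Optional [TrainingState-class] (RMSE traces).
#' @return \code{path}, invisibly.
#' @export
writeMLPModel <- function(model, path, pca = NULL, state = NULL) {
  obj <- list(
    layerSizes = c(ncol(model@W1), nrow(model@W1), nrow(model@W2)),
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    labels = model@labels, center = model@center, scale = model@scale,
    unknownThreshold = model@unknownThreshold
  )
  if (!is.null(pca))
    obj$pca <- list(center = pca@center, components = pca@components,
                    eigenvalues = pca@eigenvalues)
  if (!is.null(state))
    obj$training <- list(epochs = state@epochs, trainRMSE = state@trainRMSE,
                         valRMSE = state@valRMSE,
                         stoppedEarly = state@stoppedEarly,
                         bestEpoch = state@bestEpoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized MLP model
#'
#' @param path JSON file written by [writeMLPModel()].
#' @return List with \code{model} ([MLPModel-class]) and \code{pca}
#'   ([PCAModel-class] or NULL).
#' @export
readMLPModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- new("MLPModel",
               W1 = matrix(o$W1, o$layerSizes[2], o$layerSizes[1], byrow = FALSE),
               b1 = as.numeric(o$b1),
               W2 = matrix(o$W2, o$layerSizes[3], o$layerSizes[2], byrow = FALSE),
               b2 = as.numeric(o$b2),
               labels = o$labels, center = as.numeric(o$center),
               scale = as.numeric(o$scale),
               unknownThreshold = o$unknownThreshold)
  pca <- NULL
  if (!is.null(o$pca))
    pca <- new("PCAModel", center = as.numeric(o$pca$center),
               components = as.matrix(o$pca$components),
               eigenvalues = as.numeric(o$pca$eigenvalues))
  list(model = model, pca = pca)
}
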