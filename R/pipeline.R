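# End-to-end orchestration: synth -> extract -> train -> evaluate, with a
# single config object that round-trips through YAML. The feature table is
# the hand-off between stages: extraction writes F1-F13 plus the raw
# 32-dim texture descriptor; training fits the PCA (training rows only)
# and the MLP; evaluation projects test descriptors with the frozen PCA.

#' Pipeline configuration
#'
#' All tunables of the pipeline in one (YAML-serializable) list. Defaults
#' are the study protocol where it states them: 50-px minimum region area,
#' 50-px overlap rectangle rule, 5 width strips, 8 PCA components, learning
#' rate 0.05, momentum 0.05, 400 epochs, 10\% validation.
#'
#' @param sigma,low,high Canny parameters (see [cannyParams()]).
#' @param minArea,overlapLen Morphology thresholds, px.
#' @param nStrips Width-factor strips.
#' @param pcaK Retained PCA components.
#' @param spectrumSize Resampled crop side for the Fourier block, px.
#' @param circularity,elongation Shape-index thresholds.
#' @param learningRate,momentum,maxEpochs,validationFraction,patience
#'   Training parameters (see [trainingConfig()]).
#' @param canvas Synthetic scene size \code{c(height, width)}.
#' @param seed Default seed.
#' @return List of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(sigma = 1.4, low = 0.1, high = 0.25,
                           minArea = 50L, overlapLen = 50L, nStrips = 5L,
                           pcaK = 8L, spectrumSize = 64L,
                           circularity = 0.75, elongation = 2.8,
                           learningRate = 0.05, momentum = 0.05,
                           maxEpochs = 400L, validationFraction = 0.10,
                           patience = 10L, canvas = c(512L, 640L),
                           seed = 1L) {
  stopifnot(minArea > 0, overlapLen > 0, nStrips > 0, pcaK > 0,
            spectrumSize > 0)
  structure(list(
    sigma = sigma, low = low, high = high,
    minArea = as.integer(minArea), overlapLen = as.integer(overlapLen),
    nStrips = as.integer(nStrips), pcaK = as.integer(pcaK),
    spectrumSize = as.integer(spectrumSize),
    circularity = circularity, elongation = elongation,
    learningRate = learningRate, momentum = momentum,
    maxEpochs = as.integer(maxEpochs),
    validationFraction = validationFraction,
    patience = as.integer(patience),
    canvas = as.integer(canvas), seed = as.integer(seed)
  ), class = "pipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipelineConfig()] list.
#' @return \code{readPipelineConfig}: the configuration;
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipelineConfig, v)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeLog <- function(verbose, ...) {
  if (verbose)
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

canonicalGenera <- function() {
  c("Navicula", "Scenedesmus", "Microcystis", "Oscillatoria", "Chroococcus")
}

# Label a detected object by best mask IoU against the scene's truth.
truthLabel <- function(obj, scene, minIoU = 0.3) {
  tr <- sceneTruth(scene)
  if (nrow(tr) == 0) return(NA_character_)
  d <- dim(sceneImage(scene))
  det <- uncropMask(objMask(obj), objBBox(obj), d[1], d[2])
  ious <- vapply(seq_len(nrow(tr)), function(i) {
    tm <- uncropMask(sceneMasks(scene)[[i]],
                     as.integer(unlist(tr[i, c("r0", "c0", "r1", "c1")])),
                     d[1], d[2])
    maskIoU(det, tm)
  }, numeric(1))
  if (max(ious) < minIoU) return(NA_character_)
  tr$label[which.max(ious)]
}

#' Extract the feature table from images
#'
#' Runs preprocessing, segmentation and per-object feature extraction on
#' each input: [SyntheticScene-class] objects (labels assigned from ground
#' truth by mask overlap) or image file paths (no labels). F1-F13 are final;
#' the raw polar-spectrum descriptor is kept in columns \code{S1..S32} so
#' that the PCA behind F14-F21 can be fitted on the training split alone.
#' Per-image failures are logged and skipped; the run fails only if every
#' image fails.
#'
#' @param inputs List of [SyntheticScene-class] and/or character paths.
#' @param config A [pipelineConfig()].
#' @param verbose Log one line per stage per image (default FALSE).
#' @return data.frame: \code{image}, \code{object}, \code{label},
#'   \code{area}, \code{F1..F13}, \code{S1..S32}.
#' @export
runExtract <- function(inputs, config = pipelineConfig(), verbose = FALSE) {
  if (is(inputs, "SyntheticScene") || is.character(inputs) &&
      length(inputs) == 1L && !is.list(inputs)) inputs <- list(inputs)
  params <- cannyParams(config$sigma, config$low, config$high)
  rows <- list()
  failures <- 0L
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      input <- inputs[[i]]
      scene <- NULL
      if (is(input, "SyntheticScene")) {
        img <- sceneImage(input); scene <- input
        id <- sprintf("scene_%03d", i)
      } else {
        img <- loadImage(input)
        id <- as.character(input)
      }
      pipeLog(verbose, "image %s: loaded %d x %d", id, nrow(img), ncol(img))
      objs <- segmentScene(img, params, minArea = config$minArea,
                           overlapLen = config$overlapLen)
      pipeLog(verbose, "image %s: %d object(s) segmented", id, length(objs))
      if (length(objs) == 0) {
        warning("image ", id, ": no objects detected")
        NULL
      } else do.call(rbind, lapply(objs, function(o) {
        raw <- extractRawFeatures(o, config$nStrips, config$circularity,
                                  config$elongation)
        lab <- if (!is.null(scene)) truthLabel(o, scene) else NA_character_
        df <- data.frame(image = id, object = objIndex(o), label = lab,
                         area = regionArea(o))
        df[paste0("F", 1:13)] <- as.list(unname(raw$geom))
        df[paste0("S", seq_along(raw$descriptor))] <-
          as.list(raw$descriptor)
        df
      }))
    }, error = function(e) {
      warning("image ", i, " skipped: ", conditionMessage(e))
      failures <<- failures + 1L
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0 && failures == length(inputs))
    stop("all ", failures, " input image(s) failed")
  if (length(rows) == 0)
    return(data.frame(image = character(0), object = integer(0),
                      label = character(0), area = numeric(0)))
  do.call(rbind, rows)
}

featureColumns <- function(tbl) grep("^F\\d+$", names(tbl), value = TRUE)
descriptorColumns <- function(tbl) grep("^S\\d+$", names(tbl), value = TRUE)

#' Train the classifier from a feature table
#'
#' Fits the texture PCA on the (labelled) training rows, assembles the
#' 21-column design matrix (F1-F13 plus the 8 PCA scores), and trains the
#' 21-8-5 MLP by momentum backpropagation with early stopping. Rows whose
#' label is missing or not a genus (e.g. debris) are excluded.
#'
#' @param features data.frame from [runExtract()] with a \code{label}
#'   column.
#' @param config A [pipelineConfig()].
#' @param seed Training seed (defaults to \code{config$seed}).
#' @return List with \code{model} ([MLPModel-class]), \code{pca}
#'   ([PCAModel-class]), \code{state} ([TrainingState-class]) and
#'   \code{labels}.
#' @export
runTrain <- function(features, config = pipelineConfig(),
                     seed = config$seed) {
  keep <- !is.na(features$label) & features$label %in% canonicalGenera()
  tbl <- features[keep, , drop = FALSE]
  labs <- intersect(canonicalGenera(), unique(tbl$label))
  if (length(labs) < 2) stop("need at least 2 genus classes to train")
  pca <- fitPCA(as.matrix(tbl[descriptorColumns(tbl)]), k = config$pcaK)
  X <- cbind(as.matrix(tbl[paste0("F", 1:13)]),
             projectPCA(pca, as.matrix(tbl[descriptorColumns(tbl)])))
  colnames(X) <- paste0("F", 1:21)
  model <- initMLP(seed = seed, layerSizes = c(ncol(X), 8L, length(labs)),
                   labels = labs)
  cfg <- trainingConfig(learningRate = config$learningRate,
                        momentum = config$momentum,
                        maxEpochs = config$maxEpochs,
                        validationFraction = config$validationFraction,
                        patience = config$patience, seed = seed)
  fit <- trainMLP(model, X, tbl$label, cfg)
  list(model = fit$model, pca = pca, state = fit$state, labels = labs)
}

#' Evaluate the trained pipeline on test images
#'
#' Runs the full chain on every test input; for single-alga benchmark
#' scenes the largest detected object is scored against the scene's truth
#' label, and a scene with no detection counts as an (Unidentified) error.
#' Produces the (5+1) x (5+1) confusion matrix with the Unidentified
#' column, per-class accuracies and overall accuracy.
#'
#' @param bundle List from [runTrain()].
#' @param inputs Test scenes (or image paths with \code{truthLabels}).
#' @param config A [pipelineConfig()].
#' @param truthLabels Optional character vector of true labels, one per
#'   input, overriding scene ground truth.
#' @param verbose Log progress (default FALSE).
#' @return List with \code{confusion}, \code{perClass}, \code{overall}
#'   (fraction), \code{n}, \code{predictions} (data.frame), and
#'   \code{objectCounts} (detections per image).
#' @export
runEvaluate <- function(bundle, inputs, config = pipelineConfig(),
                        truthLabels = NULL, verbose = FALSE) {
  if (is(inputs, "SyntheticScene")) inputs <- list(inputs)
  params <- cannyParams(config$sigma, config$low, config$high)
  n <- length(inputs)
  preds <- character(n); truths <- character(n); counts <- integer(n)
  for (i in seq_len(n)) {
    input <- inputs[[i]]
    if (is(input, "SyntheticScene")) {
      img <- sceneImage(input)
      truths[i] <- if (nrow(sceneTruth(input)) > 0)
        sceneTruth(input)$label[1] else "Unidentified"
    } else {
      img <- loadImage(input)
      truths[i] <- if (!is.null(truthLabels)) truthLabels[i] else
        "Unidentified"
    }
    objs <- tryCatch(
      segmentScene(img, params, minArea = config$minArea,
                   overlapLen = config$overlapLen),
      error = function(e) list())
    counts[i] <- length(objs)
    if (length(objs) == 0) { preds[i] <- "Unidentified"; next }
    main <- objs[[which.max(vapply(objs, regionArea, numeric(1)))]]
    x <- assembleFeatures(main, bundle$pca, config$nStrips,
                          config$circularity, config$elongation)
    preds[i] <- predictMLP(bundle$model, x)
    pipeLog(verbose, "image %d/%d: %d object(s), predicted %s (truth %s)",
            i, n, counts[i], preds[i], truths[i])
  }
  truths[truths == "Debris"] <- "Unidentified"
  ev <- evaluateClassification(preds, truths, labels = bundle$labels)
  c(ev, list(predictions = data.frame(image = seq_len(n), truth = truths,
                                      predicted = preds),
             objectCounts = counts))
}

#' Write an evaluation report to disk
#'
#' Confusion matrix as CSV plus a JSON summary (per-class and overall
#' accuracy, detection counts).
#'
#' @param report List from [runEvaluate()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$confusion, file.path(dir, "confusion.csv"))
  jsonlite::write_json(
    list(overall = report$overall, perClass = as.list(report$perClass),
         n = report$n, objectCounts = report$objectCounts),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a feature table as CSV
#'
#' @param features data.frame from [runExtract()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Run the complete synthetic benchmark
#'
#' Generates the default dataset (40 training and 50 test single-alga
#' images per genus), extracts features, trains the 21-8-5 MLP, and
#' evaluates on the held-out images — the synthetic surrogate of the
#' study's 250-image confusion-matrix benchmark. Fully reproducible from
#' \code{seed}.
#'
#' @param seed Master seed for generation and training.
#' @param nTrainPerClass,nTestPerClass Images per genus (defaults 40 / 50).
#' @param config A [pipelineConfig()].
#' @param verbose Log progress.
#' @return List with \code{report} (from [runEvaluate()]), \code{bundle}
#'   (from [runTrain()]), and \code{features} (training table).
#' @export
runBenchmark <- function(seed = 1L, nTrainPerClass = 40L,
                         nTestPerClass = 50L, config = pipelineConfig(),
                         verbose = FALSE) {
  sds <- datasetSeeds(nTrainPerClass, nTestPerClass, seed)
  # scenes are generated, processed and discarded one at a time; the
  # resulting features and predictions are identical to materializing the
  # whole generateDataset() output at once
  pipeLog(verbose, "extracting features from %d training scenes",
          nrow(sds$train))
  features <- do.call(rbind, lapply(seq_len(nrow(sds$train)), function(i) {
    sc <- generateScene(sds$train$label[i], canvas = config$canvas,
                        seed = sds$train$seed[i])
    tb <- runExtract(list(sc), config)
    if (nrow(tb) > 0) tb$image <- sprintf("train_%03d", i)
    tb
  }))
  pipeLog(verbose, "training on %d objects", nrow(features))
  bundle <- runTrain(features, config, seed = seed)
  pipeLog(verbose, "evaluating on %d test scenes", nrow(sds$test))
  n <- nrow(sds$test)
  preds <- truths <- character(n); counts <- integer(n)
  for (i in seq_len(n)) {
    sc <- generateScene(sds$test$label[i], canvas = config$canvas,
                        seed = sds$test$seed[i])
    r <- runEvaluate(bundle, list(sc), config)
    preds[i] <- r$predictions$predicted
    truths[i] <- r$predictions$truth
    counts[i] <- r$objectCounts
    pipeLog(verbose && i %% 50 == 0, "evaluated %d/%d", i, n)
  }
  ev <- evaluateClassification(preds, truths, labels = bundle$labels)
  report <- c(ev, list(predictions = data.frame(image = seq_len(n),
                                                truth = truths,
                                                predicted = preds),
                       objectCounts = counts))
  list(report = report, bundle = bundle, features = features)
}
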