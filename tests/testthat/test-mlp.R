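test_that("initialization is seeded, deterministic and correctly shaped", {
  a <- initMLP(seed = 7)
  b <- initMLP(seed = 7)
  c <- initMLP(seed = 8)
  expect_identical(a@W1, b@W1)
  expect_identical(a@W2, b@W2)
  expect_false(identical(a@W1, c@W1))
  expect_equal(dim(a@W1), c(8L, 21L))
  expect_equal(dim(a@W2), c(5L, 8L))
  expect_true(all(abs(a@W1) <= 1 / sqrt(21)))
  expect_true(all(a@b1 == 0) && all(a@b2 == 0))
})

test_that("the forward pass matches independent matrix arithmetic", {
  m <- initMLP(seed = 1)
  expect_equal(mlpForward(m, rep(0, 21)), tanh(m@b2 + drop(m@W2 %*% tanh(m@b1))))

  zero <- m; zero@W1[] <- 0; zero@W2[] <- 0
  expect_equal(mlpForward(zero, stats::rnorm(21)), rep(0, 5))

  withr::with_seed(12, {
    for (rep in 1:5) {
      x <- stats::rnorm(21)
      y <- mlpForward(m, x, standardize = FALSE)
      # hand-rolled dot products
      h <- numeric(8)
      for (j in 1:8) h[j] <- tanh(sum(m@W1[j, ] * x) + m@b1[j])
      yo <- numeric(5)
      for (k in 1:5) yo[k] <- tanh(sum(m@W2[k, ] * h) + m@b2[k])
      expect_lt(max(abs(y - yo)), 1e-12)
    }
  })
  expect_error(mlpForward(m, rep(0, 5)), "length")
})

test_that("tanh outputs saturate toward +1 for a strong single path", {
  m <- initMLP(seed = 2)
  m@W1[] <- 0; m@W2[] <- 0
  m@W1[1, 1] <- 5; m@W2[1, 1] <- 5
  y <- mlpForward(m, c(10, rep(0, 20)), standardize = FALSE)
  expect_gt(y[1], 0.99)
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(33, {
    m <- initMLP(seed = 33)
    eps <- 1e-5
    for (rep in 1:3) {
      x <- stats::rnorm(21)
      tgt <- rep(-1, 5); tgt[sample(5, 1)] <- 1
      g <- algascope:::mlpGradient(m, x, tgt)
      loss <- function(mod) 0.5 * sum((mlpForward(mod, x, FALSE) - tgt)^2)
      checkOne <- function(slot, gmat, idx) {
        for (ij in idx) {
          mp <- m; slot(mp, slot)[ij] <- slot(mp, slot)[ij] + eps
          mm <- m; slot(mm, slot)[ij] <- slot(mm, slot)[ij] - eps
          fd <- (loss(mp) - loss(mm)) / (2 * eps)
          expect_equal(gmat[ij], fd, tolerance = 1e-6)
        }
      }
      checkOne("W1", g$W1, sample(length(m@W1), 12))
      checkOne("W2", g$W2, sample(length(m@W2), 12))
      checkOne("b1", g$b1, sample(length(m@b1), 4))
      checkOne("b2", g$b2, sample(length(m@b2), 3))
    }
  })
})

test_that("one small-step epoch without momentum decreases the batch error", {
  withr::with_seed(44, {
    X <- matrix(stats::rnorm(30 * 21), 30, 21)
    labs <- rep(c("Navicula", "Scenedesmus", "Microcystis", "Oscillatoria",
                  "Chroococcus"), 6)
    m <- initMLP(seed = 44)
    tgt <- algascope:::targetMatrix(labs, m@labels)
    fit <- trainMLP(m, X, labs,
                    trainingConfig(learningRate = 0.001, momentum = 0,
                                   maxEpochs = 1, seed = 44))
    Xs <- sweep(sweep(X, 2, fit$model@center), 2, fit$model@scale, "/")
    expect_lt(algascope:::mlpRMSE(fit$model, Xs, tgt),
              algascope:::mlpRMSE(m, Xs, tgt))
  })
})

test_that("training solves a 2-class problem embedded in 21 dimensions", {
  withr::with_seed(55, {
    n <- 200
    X <- matrix(stats::rnorm(n * 21, sd = 0.3), n, 21)
    cls <- sample(0:1, n, replace = TRUE)
    # two informative dimensions, XOR-style quadrant structure
    q <- sample(0:1, n, replace = TRUE)
    X[, 1] <- X[, 1] + ifelse(q == 1, 2, -2)
    X[, 2] <- X[, 2] + ifelse(xor(cls == 1, q == 1), 2, -2)
    labs <- ifelse(cls == 1, "Navicula", "Scenedesmus")
    m <- initMLP(seed = 55, layerSizes = c(21L, 8L, 2L),
                 labels = c("Navicula", "Scenedesmus"))
    fit <- trainMLP(m, X, labs, trainingConfig(seed = 55))
    expect_lt(min(fit$state@trainRMSE), 0.3)
    acc <- mean(predictMLP(fit$model, X) == labs)
    expect_gt(acc, 0.95)
  })
})

test_that("zero-epoch training returns the model unchanged with empty traces", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(40 * 21), 40, 21)
    labs <- rep(c("Navicula", "Scenedesmus"), 20)
    m <- initMLP(seed = 3, layerSizes = c(21L, 8L, 2L),
                 labels = c("Navicula", "Scenedesmus"))
    fit <- trainMLP(m, X, labs, trainingConfig(maxEpochs = 0, seed = 3))
    expect_identical(fit$model@W1, m@W1)
    expect_identical(fit$model@W2, m@W2)
    expect_equal(fit$state@epochs, 0L)
    expect_length(fit$state@trainRMSE, 0L)
  })
})

test_that("early stopping restores the best-validation weights", {
  withr::with_seed(66, {
    # noisy, barely learnable labels force validation RMSE to wander
    X <- matrix(stats::rnorm(60 * 21), 60, 21)
    labs <- sample(c("Navicula", "Scenedesmus"), 60, replace = TRUE)
    m <- initMLP(seed = 66, layerSizes = c(21L, 8L, 2L),
                 labels = c("Navicula", "Scenedesmus"))
    fit <- trainMLP(m, X, labs,
                    trainingConfig(maxEpochs = 150, patience = 5, seed = 66))
    st <- fit$state
    expect_equal(st@bestEpoch, which.min(st@valRMSE))
    # recompute validation RMSE of the returned weights: must equal the best
    cfg <- trainingConfig(maxEpochs = 150, patience = 5, seed = 66)
    valIdx <- withr::with_seed(cfg$seed, unlist(lapply(
      c("Navicula", "Scenedesmus"), function(cl) {
        i <- which(labs == cl)
        i[sample.int(length(i),
                     max(1L, round(length(i) * cfg$validationFraction)))]
      })))
    tgt <- algascope:::targetMatrix(labs, m@labels)
    Xs <- sweep(sweep(X, 2, fit$model@center), 2, fit$model@scale, "/")
    got <- algascope:::mlpRMSE(fit$model, Xs[valIdx, , drop = FALSE],
                               tgt[valIdx, , drop = FALSE])
    expect_equal(got, min(st@valRMSE), tolerance = 1e-12)
    if (st@stoppedEarly) expect_lt(st@epochs, 150L)
  })
})

test_that("prediction takes the argmax and rejects below the threshold", {
  m <- initMLP(seed = 9)
  mk <- function(y) {
    mm <- m
    mm@W1[] <- 0; mm@b1[] <- 0
    mm@W2[] <- 0; mm@b2 <- atanh(y)
    mm
  }
  expect_equal(predictMLP(mk(c(0.9, -0.8, -0.9, -0.7, -0.8)), rep(0, 21)),
               m@labels[1])
  expect_equal(predictMLP(mk(rep(-0.5, 5)), rep(0, 21)), "Unidentified")
  expect_equal(predictMLP(mk(c(0.5, 0.5, -1, -1, -1) * 0.9), rep(0, 21)),
               m@labels[1])   # tie goes to the lowest index
})

test_that("the confusion matrix and accuracies follow their definitions", {
  labs <- c("Navicula", "Scenedesmus", "Microcystis", "Oscillatoria",
            "Chroococcus")
  truth <- rep(labs, each = 50)
  ev <- evaluateClassification(truth, truth, labs)
  expect_equal(ev$overall, 1)
  expect_equal(unname(diag(ev$confusion)[1:5]), rep(50, 5))

  ev0 <- evaluateClassification(rep("Unidentified", 250), truth, labs)
  expect_equal(ev0$overall, 0)

  # printed-style matrix: diagonal (46,43,49,47,49) of 50 each
  diagN <- c(46, 43, 49, 47, 49)
  preds <- unlist(lapply(1:5, function(i)
    c(rep(labs[i], diagN[i]), rep("Unidentified", 50 - diagN[i]))))
  ev2 <- evaluateClassification(preds, truth, labs)
  expect_equal(ev2$overall, 234 / 250)
  expect_equal(unname(ev2$perClass[1:5]), diagN / 50)
  expect_equal(dim(ev2$confusion), c(6L, 6L))

  expect_error(evaluateClassification(c("Volvox"), c("Navicula"), labs),
               "label")
})

test_that("standardization makes predictions invariant to affine feature rescaling", {
  withr::with_seed(77, {
    X <- matrix(stats::rnorm(60 * 21), 60, 21)
    labs <- rep(c("Navicula", "Scenedesmus", "Microcystis"), 20)
    m <- initMLP(seed = 77, layerSizes = c(21L, 8L, 3L),
                 labels = c("Navicula", "Scenedesmus", "Microcystis"))
    fit1 <- trainMLP(m, X, labs, trainingConfig(maxEpochs = 30, seed = 5))
    shift <- stats::rnorm(21); scl <- stats::runif(21, 0.5, 3)
    X2 <- sweep(sweep(X, 2, scl, "*"), 2, shift, "+")
    fit2 <- trainMLP(m, X2, labs, trainingConfig(maxEpochs = 30, seed = 5))
    p1 <- predictMLP(fit1$model, X)
    p2 <- predictMLP(fit2$model, X2)
    expect_identical(p1, p2)
  })
})

test_that("models round-trip through JSON serialization", {
  withr::with_seed(88, {
    m <- initMLP(seed = 88)
    m@center <- stats::rnorm(21); m@scale <- stats::runif(21, 0.5, 2)
    pca <- fitPCA(matrix(stats::rnorm(20 * 32), 20, 32), 8)
    f <- tempfile(fileext = ".json")
    writeMLPModel(m, f, pca = pca)
    back <- readMLPModel(f)
    expect_equal(back$model@W1, m@W1)
    expect_equal(back$model@W2, m@W2)
    expect_equal(back$model@center, m@center)
    expect_identical(back$model@labels, m@labels)
    expect_equal(back$pca@components, pca@components)
    x <- stats::rnorm(21)
    expect_equal(mlpForward(back$model, x), mlpForward(m, x))
    unlink(f)
  })
})
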