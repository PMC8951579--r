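test_that("initialization is deterministic and wired to the schema", {
  reg <- buildDefaultRegistry()
  a <- initModel(modelConfig(seed = 0), reg)
  b <- initModel(modelConfig(seed = 0), reg)
  expect_identical(a@towers, b@towers)
  expect_identical(nrow(a@towers$location$W1), 113L)
  expect_identical(nrow(a@towers$margin$W1), 107L)
  expect_identical(nrow(a@towers$texture$W1), 107L)
  expect_identical(ncol(a@towers$location$W3), 6L)
  expect_identical(ncol(a@towers$texture$W3), 3L)
  expect_identical(ncol(a@towers$margin$W3), 4L)
  expect_identical(a@towers$margin$activation, "relu")
  expect_identical(a@towers$location$activation, "tanh")
  expect_identical(a@towers$location$dropout, c(0.35, 0.25))
  expect_identical(a@towers$texture$dropout, c(0.25, 0.15))
})

test_that("zero parameters give uniform task probabilities; softmax matches closed forms", {
  reg <- buildDefaultRegistry()
  model <- initModel(modelConfig(seed = 0), reg)
  for (task in c("location", "texture", "margin"))
    for (p in c("W1", "b1", "W2", "b2", "W3", "b3"))
      model@towers[[task]][[p]] <- model@towers[[task]][[p]] * 0
  co <- tinyCohort(1L)
  pred <- forwardModel(model, co)
  expect_equal(unname(taskProbabilities(pred, "location")[1, ]), rep(1/6, 6))
  expect_equal(unname(taskProbabilities(pred, "texture")[1, ]), rep(1/3, 3))
  expect_equal(unname(taskProbabilities(pred, "margin")[1, ]), rep(1/4, 4))
  # argmax under uniform probabilities ties toward the first canonical class
  model@trained <- TRUE
  model@standardization <- list(mean = rep(0, 113), sd = rep(1, 113))
  lab <- predictedLabels(predict(model, co))
  expect_identical(as.character(lab$location), "RUL")
  expect_identical(as.character(lab$texture), "Solid")
  expect_identical(as.character(lab$margin), "SharpCircumscribed")
  # softmax of logits (ln 2, 0, 0) is (0.5, 0.25, 0.25)
  P <- lungReporter:::.softmaxRows(matrix(c(log(2), 0, 0), 1))
  expect_equal(unname(P[1, ]), c(0.5, 0.25, 0.25))
})

test_that("cross-entropy loss matches its closed forms", {
  probs <- list(
    location = matrix(1/6, 1, 6, dimnames = list("r", locationLevels())),
    texture = matrix(c(0.5, 0.25, 0.25), 1, 3,
                     dimnames = list("r", textureLevels())),
    margin = matrix(1/4, 1, 4, dimnames = list("r", marginLevels())))
  pred <- lungReporter:::.newPredictions(probs, "r")
  gold <- data.frame(location = "RUL", texture = "Solid",
                     margin = "Lobulated")
  loss <- crossEntropyLoss(pred, gold)
  expect_equal(loss, log(6) + log(2) + log(4), tolerance = 1e-12)
  # a task predicted with probability 0.5 contributes ln 2; uniform 3-class, ln 3
  gold2 <- data.frame(location = "RUL", texture = "Subsolid",
                      margin = "Lobulated")
  expect_equal(crossEntropyLoss(pred, gold2) - loss, log(4) - log(2),
               tolerance = 1e-12)
  uni3 <- lungReporter:::.ceLossMatrix(matrix(1/3, 1, 3),
                                       matrix(c(0, 1, 0), 1), 1e-7)
  expect_equal(uni3, log(3), tolerance = 1e-9)
  # perfect one-hot prediction is bounded by the clipping term
  perfect <- lungReporter:::.ceLossMatrix(matrix(c(1, 0, 0), 1),
                                          matrix(c(1, 0, 0), 1), 1e-7)
  expect_lte(perfect, -log(1 - 1e-7) + 1e-12)
  expect_gte(perfect, 0)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  d <- 5L; K <- 3L; B <- 4L
  tw <- list(W1 = matrix(rnorm(d * 4, sd = 0.3), d, 4), b1 = rnorm(4, sd = 0.1),
             W2 = matrix(rnorm(4 * 3, sd = 0.3), 4, 3), b2 = rnorm(3, sd = 0.1),
             W3 = matrix(rnorm(3 * K, sd = 0.3), 3, K), b3 = rnorm(K, sd = 0.1),
             activation = "tanh", dropout = c(0, 0))
  X <- matrix(rnorm(B * d), B, d)
  Y <- diag(K)[sample(K, B, replace = TRUE), ]
  lossOf <- function(tw) {
    fwd <- lungReporter:::.towerForward(tw, X)
    lungReporter:::.ceLossMatrix(fwd$P, Y, 1e-7)
  }
  for (act in c("tanh", "relu")) {
    tw$activation <- act
    fwd <- lungReporter:::.towerForward(tw, X)
    g <- lungReporter:::.towerBackward(tw, fwd, Y)
    eps <- 1e-5
    for (p in names(g)) {
      for (idx in seq_len(min(6L, length(tw[[p]])))) {
        up <- tw; up[[p]][idx] <- up[[p]][idx] + eps
        dn <- tw; dn[[p]][idx] <- dn[[p]][idx] - eps
        num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
        expect_equal(g[[p]][idx], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss, is deterministic, and can overfit", {
  reg <- buildDefaultRegistry()
  co <- simulateCohort(generatorConfig(n = 20, seed = 0, effect_size = 3))
  cfg <- modelConfig(seed = 0)
  m1 <- trainModel(initModel(cfg, reg), co, cfg)
  expect_lt(tail(trainingLog(m1), 1), trainingLog(m1)[1])
  m2 <- trainModel(initModel(cfg, reg), co, cfg)
  expect_identical(m1@towers, m2@towers)
  # a highly separable cohort is memorized: training-set macro-F1 = 1
  co5 <- simulateCohort(generatorConfig(n = 200, seed = 0, effect_size = 5))
  m5 <- trainModel(initModel(cfg, reg), co5, cfg)
  mr <- metricsReport(predict(m5, co5), semanticLabels(co5))
  for (task in c("location", "texture", "margin"))
    expect_equal(unname(mr$per_task[[task]]$macro["f1"]), 1.0)
})

test_that("training rejects unlabeled records and empty cohorts", {
  reg <- buildDefaultRegistry()
  cfg <- modelConfig(epochs = 1, seed = 0)
  co <- tinyCohort(2L)
  SummarizedExperiment::colData(co)$texture[1L] <- NA
  expect_error(trainModel(initModel(cfg, reg), co, cfg), "unlabeled")
  empty <- simulateCohort(generatorConfig(n = 0, seed = 1))
  expect_error(trainModel(initModel(cfg, reg), empty, cfg), "empty")
  expect_error(predict(initModel(cfg, reg), tinyCohort(1L)), "untrained")
})

test_that("inference is deterministic; training-mode dropout is unbiased (inverted)", {
  reg <- buildDefaultRegistry()
  co <- simulateCohort(generatorConfig(n = 6, seed = 3))
  cfg <- modelConfig(epochs = 2, seed = 1)
  model <- trainModel(initModel(cfg, reg), co, cfg)
  p1 <- predict(model, co); p2 <- predict(model, co)
  expect_identical(taskProbabilities(p1, "location"),
                   taskProbabilities(p2, "location"))
  # E[masked activation] over many draws equals the inference activation
  tw <- model@towers$location
  X <- lungReporter:::.modelInputs(model, co)
  A1 <- lungReporter:::.towerForward(tw, X)$A1
  set.seed(99)
  H <- 0
  reps <- 400L
  for (r in seq_len(reps))
    H <- H + lungReporter:::.towerForward(tw, X, training = TRUE)$H1
  mc_se <- sqrt(mean(A1^2) * (tw$dropout[1] / (1 - tw$dropout[1])) / reps)
  expect_lt(mean(abs(H / reps - A1)), 5 * mc_se + 0.05)
})

test_that("non-finite features raise a numeric error naming the record", {
  reg <- buildDefaultRegistry()
  co <- tinyCohort(2L)
  SummarizedExperiment::assay(co, "features")[1, 2] <- NaN
  cfg <- modelConfig(epochs = 1, seed = 0)
  model <- initModel(cfg, reg)
  expect_error(forwardModel(model, co), "rec_02")
})

test_that("model checkpoints round-trip through JSON", {
  reg <- buildDefaultRegistry()
  co <- simulateCohort(generatorConfig(n = 8, seed = 2))
  cfg <- modelConfig(epochs = 2, seed = 5)
  model <- trainModel(initModel(cfg, reg), co, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  expect_equal(back@towers$location$W1, model@towers$location$W1,
               ignore_attr = TRUE)
  expect_equal(back@standardization$mean, model@standardization$mean)
  p1 <- predict(model, co); p2 <- predict(back, co)
  expect_equal(taskProbabilities(p1, "margin"), taskProbabilities(p2, "margin"))
})
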