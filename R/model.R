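#' @include AllGenerics.R registry.R cohort.R
NULL

#' Model configuration for the multi-objective classifier
#'
#' Hyperparameters of the three-tower dense network. Each tower sees the
#' standardized feature vector (Location all 113 dimensions; Texture and
#' Margin the 107 radiomics dimensions), passes it through two dense layers
#' with dropout, and ends in a softmax output over its own label set.
#' Location and Texture towers use tanh activations, the Margin tower ReLU.
#' Dropout rates default to 0.35/0.25 (Location) and 0.25/0.15 (Texture);
#' the Margin tower reuses the Texture rates. Training is mini-batch
#' RMSprop on the summed three-task cross-entropy.
#'
#' @param hidden Two hidden-layer widths (default 64, 32).
#' @param dropout_location,dropout_texture,dropout_margin Two dropout rates
#'   each, input side first.
#' @param learning_rate,rms_decay RMSprop step size and decay (defaults
#'   1e-3 and 0.9).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 50).
#' @param clip_epsilon Probability clipping bound in the loss (default 1e-7).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param standardize Z-score features using statistics fit on the training
#'   cohort (default TRUE).
#' @return A validated list of class `"ModelConfig"`.
#' @export
modelConfig <- function(hidden = c(64L, 32L),
                        dropout_location = c(0.35, 0.25),
                        dropout_texture = c(0.25, 0.15),
                        dropout_margin = c(0.25, 0.15),
                        learning_rate = 1e-3, rms_decay = 0.9,
                        batch_size = 32L, epochs = 50L,
                        clip_epsilon = 1e-7, seed = 0L,
                        standardize = TRUE) {
  cfg <- list(hidden = as.integer(hidden),
              dropout = list(location = dropout_location,
                             texture = dropout_texture,
                             margin = dropout_margin),
              learning_rate = learning_rate, rms_decay = rms_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              clip_epsilon = clip_epsilon, seed = as.integer(seed),
              standardize = isTRUE(standardize))
  stopifnot(length(cfg$hidden) == 2L, all(cfg$hidden >= 1L),
            cfg$batch_size >= 1L, cfg$epochs >= 1L,
            cfg$learning_rate > 0, cfg$rms_decay > 0, cfg$rms_decay < 1,
            cfg$clip_epsilon > 0, cfg$clip_epsilon < 0.5)
  for (d in cfg$dropout)
    stopifnot(length(d) == 2L, all(d >= 0), all(d < 1))
  class(cfg) <- "ModelConfig"
  cfg
}

setOldClass("ModelConfig")

.TASKS <- c("location", "texture", "margin")

.taskLevels <- function(task) {
  switch(task, location = locationLevels(), texture = textureLevels(),
         margin = marginLevels())
}

.taskActivation <- function(task) {
  # ReLU for the Margin tower; tanh for Location and Texture
  if (task == "margin") "relu" else "tanh"
}

#' NoduleModel: the three-tower semantic classifier
#'
#' Holds the per-tower layer parameters, the fitted standardization
#' statistics, the training log (per-epoch mean total loss) and the
#' configuration. Created untrained by [initModel()] and fitted by
#' [trainModel()].
#'
#' @slot config A `ModelConfig` list.
#' @slot registry The [FeatureRegistry-class] the model was built against.
#' @slot towers Named list (location/texture/margin) of layer parameters.
#' @slot standardization List with `mean` and `sd` (empty until trained).
#' @slot trainingLog Numeric vector of per-epoch mean losses.
#' @slot trained Logical.
#' @aliases NoduleModel
#' @export
setClass("NoduleModel", representation(
  config = "ModelConfig", registry = "FeatureRegistry", towers = "list",
  standardization = "list", trainingLog = "numeric", trained = "logical"
))

setValidity("NoduleModel", function(object) {
  if (!identical(names(object@towers), .TASKS))
    return("towers must be named location, texture, margin")
  for (task in .TASKS) {
    tw <- object@towers[[task]]
    K <- length(.taskLevels(task))
    if (ncol(tw$W3) != K)
      return(sprintf("%s output width must be %d", task, K))
  }
  TRUE
})

setMethod("isTrained", "NoduleModel", function(x) x@trained)
setMethod("trainingLog", "NoduleModel", function(x) x@trainingLog)

setMethod("show", "NoduleModel", function(object) {
  cat(sprintf("NoduleModel (%s): towers %s\n",
              if (object@trained) "trained" else "untrained",
              paste(sprintf("%s[%d->%s->%d]", .TASKS,
                            vapply(object@towers, function(t) nrow(t$W1), 0L),
                            paste(object@config$hidden, collapse = "-"),
                            vapply(object@towers, function(t) ncol(t$W3), 0L)),
                    collapse = ", ")))
  if (length(object@trainingLog))
    cat(sprintf("  final epoch mean loss: %.4f\n",
                utils::tail(object@trainingLog, 1L)))
})

## symmetric fan-based (Glorot-uniform) initialization
.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize an untrained model
#'
#' Builds the three towers with symmetric fan-based (Glorot-uniform)
#' initialization from the seeded generator. The Location tower consumes
#' all 113 features; Texture and Margin consume the 107 radiomics
#' features only.
#'
#' @param config A [modelConfig()].
#' @param registry A [FeatureRegistry-class].
#' @return An untrained [NoduleModel-class].
#' @examples
#' m <- initModel(modelConfig(seed = 1))
#' nrow(m@towers$location$W1)  # 113
#' @export
initModel <- function(config = modelConfig(), registry = buildDefaultRegistry()) {
  stopifnot(inherits(config, "ModelConfig"))
  set.seed(config$seed)
  h <- config$hidden
  towers <- list()
  for (task in .TASKS) {
    d <- if (task == "location") length(featureNames(registry)) else
      length(radiomicsNames(registry))
    if (d < 1L) stop("config error: registry/tower dimension mismatch",
                     call. = FALSE)
    K <- length(.taskLevels(task))
    towers[[task]] <- list(
      W1 = .glorot(d, h[1L]), b1 = numeric(h[1L]),
      W2 = .glorot(h[1L], h[2L]), b2 = numeric(h[2L]),
      W3 = .glorot(h[2L], K), b3 = numeric(K),
      activation = .taskActivation(task),
      dropout = config$dropout[[task]])
  }
  new("NoduleModel", config = config, registry = registry, towers = towers,
      standardization = list(), trainingLog = numeric(0), trained = FALSE)
}

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

.act <- function(Z, kind) if (kind == "relu") pmax(Z, 0) else tanh(Z)
.actGrad <- function(Z, A, kind) if (kind == "relu") (Z > 0) * 1 else 1 - A^2

## Forward pass of one tower on a B x d input matrix. In training mode,
## inverted dropout masks are drawn from the current RNG stream (or taken
## from `masks` when supplied, e.g. for gradient checking).
.towerForward <- function(tw, X, training = FALSE, masks = NULL) {
  drop1 <- tw$dropout[1L]; drop2 <- tw$dropout[2L]
  Z1 <- sweep(X %*% tw$W1, 2L, tw$b1, "+")
  A1 <- .act(Z1, tw$activation)
  M1 <- if (!training || drop1 == 0) 1 else if (!is.null(masks)) masks$M1 else
    matrix(stats::rbinom(length(A1), 1L, 1 - drop1) / (1 - drop1),
           nrow(A1), ncol(A1))
  H1 <- A1 * M1
  Z2 <- sweep(H1 %*% tw$W2, 2L, tw$b2, "+")
  A2 <- .act(Z2, tw$activation)
  M2 <- if (!training || drop2 == 0) 1 else if (!is.null(masks)) masks$M2 else
    matrix(stats::rbinom(length(A2), 1L, 1 - drop2) / (1 - drop2),
           nrow(A2), ncol(A2))
  H2 <- A2 * M2
  Z3 <- sweep(H2 %*% tw$W3, 2L, tw$b3, "+")
  P <- .softmaxRows(Z3)
  list(P = P, X = X, Z1 = Z1, A1 = A1, M1 = M1, H1 = H1,
       Z2 = Z2, A2 = A2, M2 = M2, H2 = H2)
}

## mean over the batch of the per-sample task loss
.ceLossMatrix <- function(P, Y, eps) {
  Pc <- pmin(pmax(P, eps), 1 - eps)
  -sum(Y * log(Pc)) / nrow(P)
}

## Gradients of the batch-mean cross-entropy w.r.t. all tower parameters.
.towerBackward <- function(tw, fwd, Y) {
  B <- nrow(fwd$P)
  dZ3 <- (fwd$P - Y) / B
  dW3 <- crossprod(fwd$H2, dZ3); db3 <- colSums(dZ3)
  dH2 <- tcrossprod(dZ3, tw$W3)
  dZ2 <- dH2 * fwd$M2 * .actGrad(fwd$Z2, fwd$A2, tw$activation)
  dW2 <- crossprod(fwd$H1, dZ2); db2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, tw$W2)
  dZ1 <- dH1 * fwd$M1 * .actGrad(fwd$Z1, fwd$A1, tw$activation)
  dW1 <- crossprod(fwd$X, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

.oneHot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels))
  Y[cbind(seq_along(labels), match(as.character(labels), levels))] <- 1
  Y
}

## standardized n x 113 input matrix (records as rows)
.modelInputs <- function(model, cohort) {
  X <- t(assay(cohort, "features")[featureNames(model@registry), , drop = FALSE])
  if (any(!is.finite(X))) {
    bad <- rownames(X)[which(rowSums(!is.finite(X)) > 0)[1L]]
    stop(sprintf("numeric error: non-finite feature value in record '%s'",
                 bad), call. = FALSE)
  }
  st <- model@standardization
  if (length(st)) X <- sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
  X
}

.towerInput <- function(model, X, task) {
  if (task == "location") X else X[, radiomicsNames(model@registry), drop = FALSE]
}

#' Forward pass over a cohort
#'
#' Runs all three towers on the cohort's (standardized, if the model is
#' trained) feature matrix. In training mode, fresh inverted-dropout masks
#' are drawn from the current RNG stream, so repeated calls differ;
#' inference mode applies no dropout and is deterministic.
#'
#' @param model A [NoduleModel-class].
#' @param cohort A [NoduleCohort-class].
#' @param training Apply dropout (default FALSE).
#' @return A [SemanticPredictions-class].
#' @export
forwardModel <- function(model, cohort, training = FALSE) {
  stopifnot(is(model, "NoduleModel"), is(cohort, "NoduleCohort"))
  X <- .modelInputs(model, cohort)
  probs <- list()
  for (task in .TASKS) {
    fwd <- .towerForward(model@towers[[task]], .towerInput(model, X, task),
                         training = training)
    dimnames(fwd$P) <- list(colnames(cohort), .taskLevels(task))
    probs[[task]] <- fwd$P
  }
  .newPredictions(probs, colnames(cohort))
}

#' Per-record multi-task cross-entropy loss
#'
#' For each record, sums the categorical cross-entropy of the three tasks,
#' with predicted probabilities clipped to `[eps, 1 - eps]`. The batch loss
#' used in training is the mean of these per-record totals.
#'
#' @param pred A [SemanticPredictions-class].
#' @param labels A data.frame with `location`, `texture`, `margin` columns
#'   (e.g. [semanticLabels()] of the cohort).
#' @param clip_epsilon Clipping bound (default 1e-7).
#' @return Numeric vector of per-record total losses.
#' @export
crossEntropyLoss <- function(pred, labels, clip_epsilon = 1e-7) {
  stopifnot(is(pred, "SemanticPredictions"))
  total <- 0
  for (task in .TASKS) {
    P <- pred@probabilities[[task]]
    Y <- .oneHot(labels[[task]], .taskLevels(task))
    Pc <- pmin(pmax(P, clip_epsilon), 1 - clip_epsilon)
    total <- total - rowSums(Y * log(Pc))
  }
  unname(total)
}

#' Train the model by joint mini-batch RMSprop
#'
#' Standardization statistics are fit on the training cohort; each epoch
#' reshuffles the records and performs RMSprop updates of all three towers
#' on the summed cross-entropy of each mini-batch (the towers share no
#' parameters, so the joint summed-loss step updates each tower by its own
#' task gradient). The per-epoch mean total loss is recorded in the
#' training log. Fully deterministic given `config$seed`.
#'
#' @param model An [initModel()] output (or a trained model to continue).
#' @param cohort A fully labeled [NoduleCohort-class].
#' @param config A [modelConfig()]; defaults to the model's own.
#' @return The trained [NoduleModel-class].
#' @export
trainModel <- function(model, cohort, config = model@config) {
  stopifnot(is(model, "NoduleModel"), is(cohort, "NoduleCohort"))
  n <- ncol(cohort)
  if (n == 0L) stop("value error: empty cohort", call. = FALSE)
  lab <- .isLabeled(cohort)
  if (!all(lab))
    stop(sprintf("value error: unlabeled record '%s'",
                 colnames(cohort)[which(!lab)[1L]]), call. = FALSE)
  cd <- colData(cohort)
  if (config$standardize) {
    raw <- t(assay(cohort, "features"))
    mu <- colMeans(raw)
    sdv <- apply(raw, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    model@standardization <- list(mean = mu, sd = sdv)
  } else {
    model@standardization <- list(mean = numeric(nrow(cohort)) * 0,
                                  sd = rep(1, nrow(cohort)))
    names(model@standardization$mean) <- rownames(cohort)
    names(model@standardization$sd) <- rownames(cohort)
  }
  X <- .modelInputs(model, cohort)
  Xt <- lapply(.TASKS, function(task) .towerInput(model, X, task))
  names(Xt) <- .TASKS
  Y <- lapply(.TASKS, function(task) .oneHot(cd[[task]], .taskLevels(task)))
  names(Y) <- .TASKS
  rms <- lapply(model@towers, function(tw)
    lapply(tw[c("W1", "b1", "W2", "b2", "W3", "b3")], function(p) p * 0))
  lr <- config$learning_rate; rho <- config$rms_decay
  eps_rms <- 1e-8; eps_clip <- config$clip_epsilon
  log <- numeric(config$epochs)
  set.seed(config$seed + 1L)  # decoupled from the init stream
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      batch_loss <- 0
      for (task in .TASKS) {
        tw <- model@towers[[task]]
        fwd <- .towerForward(tw, Xt[[task]][idx, , drop = FALSE],
                             training = TRUE)
        Yb <- Y[[task]][idx, , drop = FALSE]
        batch_loss <- batch_loss + .ceLossMatrix(fwd$P, Yb, eps_clip)
        g <- .towerBackward(tw, fwd, Yb)
        for (p in names(g)) {
          rms[[task]][[p]] <- rho * rms[[task]][[p]] + (1 - rho) * g[[p]]^2
          tw[[p]] <- tw[[p]] - lr * g[[p]] / (sqrt(rms[[task]][[p]]) + eps_rms)
        }
        model@towers[[task]] <- tw
      }
      ep_loss <- ep_loss + batch_loss * length(idx)
    }
    log[ep] <- ep_loss / n
  }
  model@trainingLog <- c(model@trainingLog, log)
  model@trained <- TRUE
  validObject(model)
  model
}

#' SemanticPredictions: per-record task probabilities and argmax labels
#'
#' @slot probabilities Named list of probability matrices (records x
#'   classes) for location, texture and margin; each row sums to 1.
#' @slot labels data.frame of argmax labels per record (ties break toward
#'   the first class in canonical order).
#' @aliases SemanticPredictions
#' @export
setClass("SemanticPredictions", representation(
  probabilities = "list", labels = "data.frame"
))

setValidity("SemanticPredictions", function(object) {
  if (!identical(names(object@probabilities), .TASKS))
    return("probabilities must be named location, texture, margin")
  for (task in .TASKS) {
    P <- object@probabilities[[task]]
    if (ncol(P) != length(.taskLevels(task)))
      return(sprintf("%s probability matrix has wrong width", task))
    if (nrow(P) && any(abs(rowSums(P) - 1) > 1e-6))
      return(sprintf("%s probabilities must sum to 1", task))
    if (nrow(P) && any(P < 0)) return("probabilities must be nonnegative")
  }
  TRUE
})

.newPredictions <- function(probs, ids) {
  lab <- data.frame(record_id = if (is.null(ids)) character(nrow(probs[[1]])) else ids,
                    stringsAsFactors = FALSE)
  for (task in .TASKS) {
    lv <- .taskLevels(task)
    lab[[task]] <- factor(lv[apply(probs[[task]], 1L, which.max)],
                          levels = lv)
  }
  new("SemanticPredictions", probabilities = probs, labels = lab)
}

#' @describeIn SemanticPredictions-class the argmax label data.frame.
#' @param x A SemanticPredictions.
#' @export
predictedLabels <- function(x) {
  stopifnot(is(x, "SemanticPredictions"))
  x@labels
}

#' @describeIn SemanticPredictions-class the probability matrix of one task.
#' @param task One of `"location"`, `"texture"`, `"margin"`.
#' @export
taskProbabilities <- function(x, task = .TASKS) {
  stopifnot(is(x, "SemanticPredictions"))
  x@probabilities[[match.arg(task)]]
}

setMethod("show", "SemanticPredictions", function(object) {
  cat(sprintf("SemanticPredictions for %d record(s)\n",
              nrow(object@labels)))
  print(utils::head(object@labels))
})

#' Predict semantic labels for a cohort
#'
#' Inference-mode forward pass (no dropout, deterministic) followed by
#' per-task argmax; ties break toward the lowest class index in canonical
#' order. Requires a trained model (fitted standardization).
#'
#' @param object A trained [NoduleModel-class].
#' @param cohort A [NoduleCohort-class].
#' @return A [SemanticPredictions-class].
#' @export
setMethod("predict", "NoduleModel", function(object, cohort) {
  if (!object@trained)
    stop("state error: model is untrained; call trainModel() first",
         call. = FALSE)
  forwardModel(object, cohort, training = FALSE)
})
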