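## Shared fixtures and independent oracles used across the suite.

## tiny labeled cohort with hand-set features (zeros unless supplied)
tinyCohort <- function(n = 3L, registry = buildDefaultRegistry(),
                       size_mm = rep(10, n), location = rep("RUL", n),
                       texture = rep("Solid", n),
                       margin = rep("Lobulated", n)) {
  m <- matrix(0, nrow = length(featureNames(registry)), ncol = n,
              dimnames = list(featureNames(registry), NULL))
  NoduleCohort(m, size_mm = size_mm, registry = registry,
               location = location, texture = texture, margin = margin,
               record_id = sprintf("rec_%02d", seq_len(n)))
}

## brute-force one-vs-rest confusion oracle: direct pair enumeration
oracleConfusion <- function(gold, predicted, cls) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(gold)) {
    g <- gold[i] == cls; p <- predicted[i] == cls
    if (g && p) tp <- tp + 1L else if (!g && p) fp <- fp + 1L
    else if (g && !p) fn <- fn + 1L else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

## Mann-Whitney AUC oracle: concordant pairs with half credit for ties
oracleAUC <- function(scores, gold) {
  pos <- scores[gold == 1]; neg <- scores[gold == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## Bayes-oracle accuracy for one task on generator output: nearest
## class-conditional prototype (isotropic Gaussian, equal task priors)
bayesOracleAccuracy <- function(cohort, task, config,
                                registry = cohortRegistry(cohort)) {
  lv <- switch(task, location = locationLevels(),
               texture = textureLevels(), margin = marginLevels())
  rad <- radiomicsNames(registry)
  X <- t(SummarizedExperiment::assay(cohort, "features")[rad, , drop = FALSE])
  base <- list(location = "RUL", texture = "Solid",
               margin = "SharpCircumscribed")
  protos <- vapply(lv, function(cls) {
    lab <- base; lab[[task]] <- cls
    classConditionalMean(lab, registry, config)
  }, numeric(length(rad)))
  scores <- X %*% protos - matrix(colSums(protos^2) / 2, nrow(X),
                                  length(lv), byrow = TRUE)
  pred <- lv[apply(scores, 1L, which.max)]
  mean(pred == as.character(semanticLabels(cohort)[[task]]))
}
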