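test_that("generator is deterministic and respects n", {
  cfg <- generatorConfig(n = 25, seed = 11)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_identical(semanticLabels(a), semanticLabels(b))
  expect_identical(sizeMM(a), sizeMM(b))
  expect_identical(ncol(a), 25L)
  expect_identical(ncol(simulateCohort(generatorConfig(n = 0, seed = 1))), 0L)
})

test_that("invalid priors are config errors", {
  expect_error(generatorConfig(location_priors = rep(0.2, 6)), "sum")
  expect_error(generatorConfig(texture_priors = c(0.5, 0.5)), "3")
  bad <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0.5, 0, 0, 0))
  expect_error(generatorConfig(margin_priors_given_texture = bad), "row 3")
})

test_that("label frequencies converge to the priors", {
  co <- simulateCohort(generatorConfig(n = 10000, seed = 5))
  lab <- semanticLabels(co)
  # each location frequency within 4 binomial SEs of 1/6
  p <- 1 / 6; se <- sqrt(p * (1 - p) / 10000)
  freq <- table(lab$location) / 10000
  expect_true(all(abs(freq - p) < 4 * se))
  # chi-square goodness of fit not rejected at alpha = 0.001 for any task
  expect_gt(chisq.test(table(lab$location))$p.value, 0.001)
  expect_gt(chisq.test(table(lab$texture))$p.value, 0.001)
})

test_that("every generated record passes validation; sizes are in (0, 30)", {
  co <- simulateCohort(generatorConfig(n = 200, seed = 2))
  v <- validateCohort(co)
  expect_identical(nrow(v[v$severity == "error", ]), 0L)
  expect_true(all(sizeMM(co) > 0 & sizeMM(co) < 30))
})

test_that("prototypes collapse at delta = 0 and live on disjoint task blocks", {
  reg <- buildDefaultRegistry()
  cfg0 <- generatorConfig(effect_size = 0)
  mu0 <- classConditionalMean(list(location = "LLL", texture = "PureGGO",
                                   margin = "Spiculated"), reg, cfg0)
  expect_identical(unname(mu0), rep(0, 107))
  cfg <- generatorConfig(effect_size = 3)
  a <- classConditionalMean(list(location = "RUL", texture = "Solid",
                                 margin = "Lobulated"), reg, cfg)
  b <- classConditionalMean(list(location = "RUL", texture = "PureGGO",
                                 margin = "Lobulated"), reg, cfg)
  changed <- names(a)[a != b]
  tex_block <- c(registryGroups(reg)$Intensity, registryGroups(reg)$GLCM)
  expect_true(all(changed %in% tex_block))
  # margin and location blocks are untouched by a texture change
  expect_identical(a[registryGroups(reg)$Shape], b[registryGroups(reg)$Shape])
  expect_identical(a[registryGroups(reg)$GLRLM], b[registryGroups(reg)$GLRLM])
})

test_that("Bayes-oracle error is below 1% per task at delta 3, noise 1", {
  cfg <- generatorConfig(n = 4000, seed = 9, effect_size = 3, noise_sd = 1)
  co <- simulateCohort(cfg)
  for (task in c("location", "texture", "margin"))
    expect_gt(bayesOracleAccuracy(co, task, cfg), 0.99)
})

test_that("Bayes-oracle accuracy is monotone in the effect size", {
  acc <- vapply(c(0.2, 0.6, 1.2, 2.5), function(d) {
    cfg <- generatorConfig(n = 800, seed = 31, effect_size = d)
    bayesOracleAccuracy(simulateCohort(cfg), "texture", cfg)
  }, numeric(1L))
  expect_true(all(diff(acc) >= 0))
})

test_that("phantom axial extent follows ceil(size / thickness) and the location band", {
  cfg <- generatorConfig()
  lab <- function(loc) list(location = loc, texture = "Solid",
                            margin = "Lobulated")
  one <- simulatePhantom(lab("RML"), 5, cfg, seed = 1)
  expect_identical(sum(apply(one@mask, 1, sum) > 0), 1L)
  three <- simulatePhantom(lab("RML"), 12, cfg, seed = 1)
  labeled <- which(apply(three@mask, 1, sum) > 0)
  expect_identical(length(labeled), 3L)
  expect_identical(labeled, seq(min(labeled), length.out = 3L))
  # upper vs lower lobe runs occupy disjoint thirds of the stack
  up <- which(apply(simulatePhantom(lab("RUL"), 14, cfg, 4)@mask, 1, sum) > 0)
  low <- which(apply(simulatePhantom(lab("LLL"), 14, cfg, 4)@mask, 1, sum) > 0)
  expect_true(max(up) <= 20 && min(low) >= 41)
  # per-slice areas along the run are unimodal
  areas <- apply(three@mask, 1, sum)[labeled]
  pk <- which.max(areas)
  expect_true(all(diff(areas[seq_len(pk)]) >= 0))
  expect_true(all(diff(areas[pk:length(areas)]) <= 0))
  expect_error(simulatePhantom(lab("RUL"), 500, cfg, 1), "too large")
})
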