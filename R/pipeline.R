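#' @include model.R lungrads.R reporting.R evaluation.R
NULL

#' Save / load a model checkpoint
#'
#' Checkpoints are a single portable JSON file holding the configuration,
#' registry group structure, all tower parameters and standardization
#' statistics at full precision.
#'
#' @param model A [NoduleModel-class].
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly ([saveModel()]); a [NoduleModel-class]
#'   ([loadModel()]).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "NoduleModel"))
  payload <- list(
    format = "lungReporter-model-1",
    config = unclass(model@config),
    registry = registryGroups(model@registry),
    towers = lapply(model@towers, function(tw) list(
      W1 = tw$W1, b1 = tw$b1, W2 = tw$W2, b2 = tw$b2, W3 = tw$W3,
      b3 = tw$b3, activation = tw$activation, dropout = tw$dropout)),
    standardization = model@standardization,
    trainingLog = model@trainingLog,
    trained = model@trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lungReporter-model-1"))
    stop("not a lungReporter model checkpoint", call. = FALSE)
  cfg <- p$config
  cfg$dropout <- lapply(cfg$dropout, as.numeric)
  class(cfg) <- "ModelConfig"
  registry <- new("FeatureRegistry", groups = lapply(p$registry, as.character))
  towers <- lapply(p$towers, function(tw) list(
    W1 = as.matrix(tw$W1), b1 = as.numeric(tw$b1),
    W2 = as.matrix(tw$W2), b2 = as.numeric(tw$b2),
    W3 = as.matrix(tw$W3), b3 = as.numeric(tw$b3),
    activation = tw$activation, dropout = as.numeric(tw$dropout)))
  st <- p$standardization
  if (length(st)) {
    fn <- unlist(p$registry, use.names = FALSE)  # feature order = registry order
    st <- list(mean = stats::setNames(as.numeric(unlist(st$mean)), fn),
               sd = stats::setNames(as.numeric(unlist(st$sd)), fn))
  }
  new("NoduleModel", config = cfg, registry = registry,
      towers = towers[.TASKS], standardization = st,
      trainingLog = as.numeric(p$trainingLog), trained = isTRUE(p$trained))
}

#' Pipeline configuration
#'
#' Collects everything [runEndToEnd()] needs: where the cohort comes from
#' (a CSV path, or the synthetic generator when `cohort_path` is NULL),
#' where the model comes from (a checkpoint path, or training on the input
#' cohort), the rule table and template files, and the output directory.
#' `seed` overrides the generator and model seeds so one integer pins the
#' whole run.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_path Optional cohort CSV; NULL means simulate.
#' @param generator A [generatorConfig()] used when simulating.
#' @param model_config A [modelConfig()] used when training.
#' @param model_path Optional model checkpoint; NULL means train on the
#'   input cohort.
#' @param rule_table_path,template_path Rule/template files (defaults:
#'   shipped).
#' @param template_name Template to render; NULL means the set's default.
#' @param seed Master seed for the run.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(out_dir, cohort_path = NULL,
                           generator = generatorConfig(),
                           model_config = modelConfig(),
                           model_path = NULL,
                           rule_table_path = defaultRuleTablePath(),
                           template_path = defaultTemplatePath(),
                           template_name = NULL, seed = 0L) {
  cfg <- list(out_dir = out_dir, cohort_path = cohort_path,
              generator = generator, model_config = model_config,
              model_path = model_path, rule_table_path = rule_table_path,
              template_path = template_path, template_name = template_name,
              seed = as.integer(seed))
  cfg$generator$seed <- cfg$seed
  cfg$model_config$seed <- cfg$seed
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full pipeline
#'
#' For every input record: predict the three semantic labels, assign the
#' Lung-RADS category from the predicted texture and margin together with
#' the record's measured size, and render the report text. Writes
#' `predictions.csv`, `assignments.csv`, one `reports/<record_id>.txt`
#' per nodule, `metrics.json` (when the cohort has gold labels) and a
#' `manifest.json` that suffices to re-run the pipeline identically
#' (seed, configuration, file inventory; no wall-clock fields, so reruns
#' are byte-identical).
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the cohort, model, predictions,
#'   assignments data.frame, report texts and the manifest.
#' @export
runEndToEnd <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(file.path(config$out_dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- if (is.null(config$cohort_path))
    simulateCohort(config$generator) else readCohort(config$cohort_path)
  model <- if (!is.null(config$model_path)) loadModel(config$model_path)
    else {
      if (!all(.isLabeled(cohort)))
        stop(paste("stage 'train': cohort has unlabeled records and no",
                   "model checkpoint was supplied"), call. = FALSE)
      trainModel(initModel(config$model_config, cohortRegistry(cohort)),
                 cohort, config$model_config)
    }
  pred <- predict(model, cohort)
  table <- loadRuleTable(config$rule_table_path)
  templates <- loadTemplates(config$template_path)
  lab <- predictedLabels(pred)
  sizes <- sizeMM(cohort)
  out <- lab
  out$size_mm <- unname(sizes[lab$record_id])
  out$category <- NA_character_
  reports <- character(nrow(out))
  names(reports) <- out$record_id
  for (i in seq_len(nrow(out))) {
    id <- out$record_id[i]
    out$category[i] <- tryCatch(
      assignCategory(out$texture[i], out$margin[i], out$size_mm[i], table),
      error = function(e) stop(sprintf("stage 'lungrads', record '%s': %s",
                                       id, conditionMessage(e)),
                               call. = FALSE))
    ctx <- reportContext(out$location[i], out$texture[i], out$margin[i],
                         out$size_mm[i], out$category[i], record_id = id)
    reports[id] <- renderReport(ctx, templates, config$template_name)
    writeLines(reports[id], file.path(config$out_dir, "reports",
                                      paste0(id, ".txt")))
  }
  prob_cols <- do.call(cbind, lapply(.TASKS, function(task) {
    m <- taskProbabilities(pred, task)
    colnames(m) <- paste0("p_", task, "_", colnames(m))
    m
  }))
  utils::write.csv(cbind(lab, prob_cols),
                   file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(out, file.path(config$out_dir, "assignments.csv"),
                   row.names = FALSE)
  metrics <- NULL
  if (all(.isLabeled(cohort)) && ncol(cohort) > 0L) {
    metrics <- metricsReport(pred, semanticLabels(cohort))
    jsonlite::write_json(
      list(overall = as.list(metrics$overall),
           per_task = lapply(metrics$per_task, function(t)
             c(as.list(t$macro), list(macro_auc = t$macro_auc)))),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
  }
  cfg_path <- file.path(config$out_dir, "pipeline_config.yaml")
  yaml::write_yaml(.configAsList(config), cfg_path)
  manifest <- list(
    package = "lungReporter",
    version = as.character(utils::packageVersion("lungReporter")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_records = ncol(cohort),
    records = colnames(cohort),
    outputs = c("predictions.csv", "assignments.csv", "pipeline_config.yaml",
                if (!is.null(metrics)) "metrics.json",
                file.path("reports", paste0(out$record_id, ".txt"))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, model = model, predictions = pred,
                 assignments = out, reports = reports, manifest = manifest,
                 metrics = metrics))
}

#' @importFrom tools md5sum
.configAsList <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL  # incidental; kept out of the config hash

  x$generator <- unclass(x$generator)
  x$generator$margin_priors_given_texture <-
    apply(x$generator$margin_priors_given_texture, 1L, as.numeric,
          simplify = FALSE)
  x$model_config <- unclass(x$model_config)
  x
}
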