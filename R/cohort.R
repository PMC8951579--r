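#' @include AllGenerics.R registry.R labels.R
NULL

#' NoduleCohort: a cohort of nodule feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding one
#' column per nodule. The `"features"` assay is a features-by-nodules matrix
#' whose rows follow the registry order; `colData` carries `size_mm`
#' (longest diameter, millimetres) and the optional semantic labels
#' `location`, `texture`, `margin` as factors over the canonical
#' vocabularies. Column names are the record ids.
#'
#' @slot registry The [FeatureRegistry-class] the columns conform to.
#' @aliases NoduleCohort
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
setClass("NoduleCohort",
  contains = "SummarizedExperiment",
  representation(registry = "FeatureRegistry")
)

setValidity("NoduleCohort", function(object) {
  if (!"features" %in% assayNames(object))
    return("assay 'features' is missing")
  m <- assay(object, "features")
  if (!identical(rownames(m), featureNames(object@registry)))
    return("assay rownames must equal the registry feature names, in order")
  ids <- colnames(object)
  if (ncol(object) > 0L && (is.null(ids) || anyDuplicated(ids)))
    return("record ids (column names) must be present and unique")
  cd <- colData(object)
  if (!"size_mm" %in% names(cd)) return("colData column 'size_mm' is missing")
  for (task in c("location", "texture", "margin")) {
    if (!task %in% names(cd)) return(sprintf("colData column '%s' is missing", task))
    lv <- switch(task, location = locationLevels(),
                 texture = textureLevels(), margin = marginLevels())
    if (!identical(levels(cd[[task]]), lv))
      return(sprintf("'%s' must be a factor over the canonical levels", task))
  }
  TRUE
})

#' Construct a NoduleCohort
#'
#' @param features Numeric matrix, features x nodules; rownames must cover
#'   the registry names (rows are reordered to registry order).
#' @param size_mm Numeric vector of nodule diameters in mm, one per column.
#' @param registry A [FeatureRegistry-class]; default [buildDefaultRegistry()].
#' @param location,texture,margin Optional label vectors (parsed
#'   case-insensitively) or NULL for an unlabeled cohort.
#' @param record_id Record identifiers; default the column names of
#'   `features`.
#' @param provenance Named list stored in `metadata()` (seed, source, ...).
#' @return A [NoduleCohort-class].
#' @examples
#' reg <- buildDefaultRegistry()
#' m <- matrix(0, nrow = 113, ncol = 2, dimnames = list(featureNames(reg), NULL))
#' co <- NoduleCohort(m, size_mm = c(8, 12), record_id = c("a", "b"))
#' ncol(co)
#' @export
NoduleCohort <- function(features, size_mm, registry = buildDefaultRegistry(),
                         location = NULL, texture = NULL, margin = NULL,
                         record_id = colnames(features),
                         provenance = list()) {
  features <- as.matrix(features)
  n <- ncol(features)
  if (is.null(record_id) && n > 0L)
    record_id <- sprintf("nodule_%03d", seq_len(n))
  fn <- featureNames(registry)
  missing <- setdiff(fn, rownames(features))
  if (length(missing))
    stop(sprintf("feature matrix is missing registry feature '%s'",
                 missing[1L]), call. = FALSE)
  features <- features[fn, , drop = FALSE]
  colnames(features) <- record_id
  blank <- function(lv) factor(rep(NA_character_, n), levels = lv)
  cd <- DataFrame(
    size_mm = as.numeric(size_mm),
    location = if (is.null(location)) blank(locationLevels()) else
      .parseLabelVector(location, locationLevels(), "location", record_id),
    texture = if (is.null(texture)) blank(textureLevels()) else
      .parseLabelVector(texture, textureLevels(), "texture", record_id),
    margin = if (is.null(margin)) blank(marginLevels()) else
      .parseLabelVector(margin, marginLevels(), "margin", record_id),
    row.names = record_id
  )
  se <- SummarizedExperiment(assays = list(features = features), colData = cd)
  metadata(se) <- provenance
  new("NoduleCohort", se, registry = registry)
}

#' @describeIn NoduleCohort-class nodule sizes in mm.
#' @param x A NoduleCohort.
#' @export
setMethod("sizeMM", "NoduleCohort", function(x) {
  stats::setNames(colData(x)$size_mm, colnames(x))
})

#' @describeIn NoduleCohort-class the label triples as a data.frame
#'   (`location`, `texture`, `margin`), NA where unlabeled.
#' @export
setMethod("semanticLabels", "NoduleCohort", function(x) {
  cd <- colData(x)
  data.frame(record_id = colnames(x), location = cd$location,
             texture = cd$texture, margin = cd$margin,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @describeIn NoduleCohort-class the cohort's feature registry.
#' @export
setMethod("cohortRegistry", "NoduleCohort", function(x) x@registry)

setMethod("show", "NoduleCohort", function(object) {
  lab <- sum(stats::complete.cases(as.data.frame(
    colData(object)[, c("location", "texture", "margin")])))
  cat(sprintf("NoduleCohort: %d nodules x %d features (%d fully labeled)\n",
              ncol(object), nrow(object), lab))
  if (ncol(object) > 0L)
    cat(sprintf("  size_mm: %.1f-%.1f mm\n",
                min(colData(object)$size_mm), max(colData(object)$size_mm)))
})

.isLabeled <- function(cohort) {
  cd <- colData(cohort)
  !is.na(cd$location) & !is.na(cd$texture) & !is.na(cd$margin)
}

#' Validate cohort records against the schema invariants
#'
#' Checks each record for missing/non-finite feature values, SISN values
#' outside [0, 1], non-positive sizes, partial label triples, and sizes at
#' or above the 30 mm study inclusion bound (the latter reported with
#' severity `"warning"`, everything else `"error"`).
#'
#' @param cohort A [NoduleCohort-class].
#' @return A data.frame with columns `record_id`, `field`, `severity`,
#'   `message`; zero rows when the cohort is fully conforming.
#' @examples
#' co <- simulateCohort(generatorConfig(n = 4, seed = 1))
#' nrow(validateCohort(co))  # 0
#' @export
validateCohort <- function(cohort) {
  stopifnot(is(cohort, "NoduleCohort"))
  m <- assay(cohort, "features")
  cd <- colData(cohort)
  sisn <- sisnNames(cohortRegistry(cohort))
  out <- list()
  add <- function(id, field, severity, msg) {
    out[[length(out) + 1L]] <<- data.frame(
      record_id = id, field = field, severity = severity, message = msg,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(ncol(cohort))) {
    id <- colnames(cohort)[j]
    v <- m[, j]
    bad <- !is.finite(v)
    if (any(bad))
      add(id, names(v)[which(bad)[1L]], "error",
          "missing or non-finite feature value")
    if (length(sisn)) {
      sv <- v[sisn]
      oob <- is.finite(sv) & (sv < 0 | sv > 1)
      if (any(oob))
        add(id, sisn[which(oob)[1L]], "error",
            sprintf("SISN value %.4g outside [0, 1]", sv[which(oob)[1L]]))
    }
    sz <- cd$size_mm[j]
    if (!is.finite(sz) || sz <= 0) {
      add(id, "size_mm", "error", "size_mm must be a positive number")
    } else if (sz >= 30) {
      add(id, "size_mm", "warning",
          sprintf("size_mm = %.1f exceeds the 30 mm inclusion bound", sz))
    }
    lab <- c(location = is.na(cd$location[j]), texture = is.na(cd$texture[j]),
             margin = is.na(cd$margin[j]))
    if (any(lab) && !all(lab))
      add(id, names(lab)[which(lab)[1L]], "error",
          "partial label triple: all three labels or none")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(record_id = character(0), field = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' Read a cohort from CSV/TSV
#'
#' Expects a header with `record_id`, `size_mm`, all registry feature
#' columns, and optional `location`/`texture`/`margin` columns. Column order
#' is irrelevant (lookup is by name); labels are parsed case-insensitively.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension;
#'   `.tsv`/`.txt` means tab).
#' @param registry Schema to validate against; default the shipped registry.
#' @return A [NoduleCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, registry = buildDefaultRegistry()) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(record_id = "character"))
  if (!"record_id" %in% names(df))
    stop("schema error: missing column 'record_id'", call. = FALSE)
  if (!"size_mm" %in% names(df))
    stop("schema error: missing column 'size_mm'", call. = FALSE)
  fn <- featureNames(registry)
  missing <- setdiff(fn, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing feature column '%s'", missing[1L]),
         call. = FALSE)
  if (anyDuplicated(df$record_id))
    stop(sprintf("integrity error: duplicate record_id '%s'",
                 df$record_id[duplicated(df$record_id)][1L]), call. = FALSE)
  feat <- t(as.matrix(df[, fn, drop = FALSE]))
  storage.mode(feat) <- "double"
  colnames(feat) <- df$record_id
  pick <- function(col) if (col %in% names(df)) df[[col]] else NULL
  NoduleCohort(feat, size_mm = df$size_mm, registry = registry,
               location = pick("location"), texture = pick("texture"),
               margin = pick("margin"), record_id = df$record_id,
               provenance = list(source = path))
}

#' Write a cohort to CSV
#'
#' Writes one row per nodule with `record_id`, `size_mm`, label columns
#' (canonical spellings; empty when unlabeled) and the feature columns in
#' registry order, at full decimal precision so that
#' `readCohort(writeCohort(x))` reproduces `x` exactly.
#'
#' @param cohort A [NoduleCohort-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "NoduleCohort"))
  cd <- colData(cohort)
  df <- data.frame(record_id = if (ncol(cohort)) colnames(cohort) else character(0),
                   size_mm = cd$size_mm,
                   location = as.character(cd$location),
                   texture = as.character(cd$texture),
                   margin = as.character(cd$margin),
                   stringsAsFactors = FALSE, check.names = FALSE)
  feat <- t(assay(cohort, "features"))
  df <- cbind(df, as.data.frame(feat, check.names = FALSE))
  # format full precision; write.csv would lose digits via as.character
  num <- vapply(df, is.numeric, logical(1L))
  for (k in which(num)) df[[k]] <- sprintf("%.17g", df[[k]])
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
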