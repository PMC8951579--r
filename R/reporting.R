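#' @include labels.R lungrads.R
NULL

#' TemplateSet: named report templates with slot placeholders
#'
#' Templates are plain strings with `{slot}` placeholders; every
#' placeholder must be a ReportContext field (`record_id`, `location`,
#' `texture`, `margin`, `size_mm`, `category`), which is checked at load
#' time. A lexicon maps canonical label tokens to the English surface forms
#' substituted into the text.
#'
#' @slot templates Named character vector of template strings.
#' @slot default Name of the default template.
#' @slot lexicon Nested list: task -> canonical token -> surface form.
#' @aliases TemplateSet
#' @export
setClass("TemplateSet", representation(
  templates = "character", default = "character", lexicon = "list"
))

.CONTEXT_FIELDS <- c("record_id", "location", "texture", "margin",
                     "size_mm", "category")

.placeholders <- function(s) {
  m <- gregexpr("\\{([A-Za-z_][A-Za-z0-9_]*)\\}", s)
  gsub("[{}]", "", unlist(regmatches(s, m)))
}

setValidity("TemplateSet", function(object) {
  if (!length(object@templates)) return("value error: no templates")
  if (is.null(names(object@templates)) || anyDuplicated(names(object@templates)))
    return("templates must have unique names")
  if (!object@default %in% names(object@templates))
    return(sprintf("default template '%s' not found", object@default))
  for (nm in names(object@templates)) {
    unknown <- setdiff(.placeholders(object@templates[[nm]]), .CONTEXT_FIELDS)
    if (length(unknown))
      return(sprintf("template error: unknown placeholder '{%s}' in '%s'",
                     unknown[1L], nm))
  }
  TRUE
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d template(s) [%s], default '%s'\n",
              length(object@templates),
              paste(names(object@templates), collapse = ", "),
              object@default))
})

#' Path of the shipped default templates / lexicon
#' @return File path within the installed package.
#' @export
defaultTemplatePath <- function() {
  system.file("extdata", "report_templates.yaml", package = "lungReporter",
              mustWork = TRUE)
}

#' @rdname defaultTemplatePath
#' @export
defaultLexiconPath <- function() {
  system.file("extdata", "label_lexicon.yaml", package = "lungReporter",
              mustWork = TRUE)
}

#' Load report templates
#'
#' Reads a YAML file with a `templates` map (name to template string) and a
#' `default` key; unknown placeholders are rejected at load time.
#'
#' @param path Template YAML file; default the shipped set.
#' @param lexicon_path Surface-form lexicon YAML; default the shipped one.
#' @return A validated [TemplateSet-class].
#' @export
loadTemplates <- function(path = defaultTemplatePath(),
                          lexicon_path = defaultLexiconPath()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$templates) || !length(raw$templates))
    stop("value error: template file has no templates", call. = FALSE)
  tpl <- vapply(raw$templates, as.character, character(1L))
  new("TemplateSet", templates = tpl,
      default = as.character(raw$default %||% names(tpl)[1L]),
      lexicon = yaml::read_yaml(lexicon_path))
}

#' Build a report context
#'
#' The five clinical slots (location, texture, margin, size, Lung-RADS
#' category) plus the record id, validated against the vocabularies.
#'
#' @param location,texture,margin Label tokens (case-insensitive).
#' @param size_mm Positive size in mm (rendered to one decimal).
#' @param category Lung-RADS category, one of `"2"`, `"3"`, `"4A"`, `"4B"`.
#' @param record_id Identifier string.
#' @param metadata Optional named list of extra information (not rendered).
#' @return A list of class `"ReportContext"`.
#' @export
reportContext <- function(location, texture, margin, size_mm, category,
                          record_id = "nodule", metadata = list()) {
  if (!is.finite(size_mm) || size_mm <= 0)
    stop("value error: size_mm must be positive", call. = FALSE)
  category <- toupper(as.character(category))
  if (!category %in% lungRADSLevels())
    stop(sprintf("value error: unknown Lung-RADS category '%s'", category),
         call. = FALSE)
  ctx <- list(
    record_id = as.character(record_id),
    location = as.character(.parseLabelVector(location, locationLevels(),
                                              "location")),
    texture = as.character(.parseLabelVector(texture, textureLevels(),
                                             "texture")),
    margin = as.character(.parseLabelVector(margin, marginLevels(),
                                            "margin")),
    size_mm = as.numeric(size_mm), category = category,
    metadata = metadata)
  if (anyNA(ctx[c("location", "texture", "margin")]))
    stop("value error: all three semantic labels are required", call. = FALSE)
  class(ctx) <- "ReportContext"
  ctx
}

.slotSurface <- function(ctx, field, lexicon) {
  switch(field,
    size_mm = sprintf("%.1f mm", ctx$size_mm),
    category = ctx$category,
    record_id = ctx$record_id,
    lexicon[[field]][[ctx[[field]]]] %||% ctx[[field]])
}

#' Render a report by slot filling
#'
#' Deterministically replaces every `{slot}` placeholder with the slot's
#' human-readable surface form ("right upper lobe (RUL)", "pure
#' ground-glass", "12.0 mm", "4A").
#'
#' @param context A [reportContext()].
#' @param templates A [TemplateSet-class].
#' @param template_name Template to use; default the set's default.
#' @return The rendered report text (single string).
#' @examples
#' ctx <- reportContext("RUL", "Solid", "Spiculated", 16, "4B", "case-1")
#' cat(renderReport(ctx, loadTemplates(),
#'                  template_name = "findings"))
#' @export
renderReport <- function(context, templates = loadTemplates(),
                         template_name = NULL) {
  stopifnot(inherits(context, "ReportContext"), is(templates, "TemplateSet"))
  nm <- template_name %||% templates@default
  if (!nm %in% names(templates@templates))
    stop(sprintf("key error: unknown template '%s'", nm), call. = FALSE)
  text <- templates@templates[[nm]]
  for (field in .CONTEXT_FIELDS) {
    text <- gsub(paste0("{", field, "}"),
                 .slotSurface(context, field, templates@lexicon),
                 text, fixed = TRUE)
  }
  text
}
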