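#' @include labels.R
NULL

#' RuleTable: ordered Lung-RADS assignment rules
#'
#' A versioned, ordered list of rules mapping (texture, margin, size) to a
#' Lung-RADS category. Each rule carries a nonempty texture set, a margin
#' set or wildcard, a half-open size interval `[lo, hi)` in mm (`hi` may be
#' infinite) and a category in `{2, 3, 4A, 4B}`. Load-time validation
#' guarantees totality (every combination with positive size matches a
#' rule) and determinism (overlapping rules agree in category), so the
#' first matching rule always yields the unique answer.
#'
#' @slot version Version tag string.
#' @slot rules List of rule records (`texture`, `margin`, `lo`, `hi`,
#'   `category`).
#' @aliases RuleTable
#' @export
setClass("RuleTable", representation(version = "character", rules = "list"))

.ruleMatches <- function(rule, texture, margin, size_mm) {
  texture %in% rule$texture &&
    (identical(rule$margin, "*") || margin %in% rule$margin) &&
    size_mm >= rule$lo && size_mm < rule$hi
}

setValidity("RuleTable", function(object) {
  for (r in object@rules) {
    if (!length(r$texture) || !all(r$texture %in% textureLevels()))
      return("each rule needs a nonempty texture subset of the vocabulary")
    if (!identical(r$margin, "*") &&
        (!length(r$margin) || !all(r$margin %in% marginLevels())))
      return("rule margin must be '*' or a nonempty subset of the vocabulary")
    if (!is.numeric(r$lo) || !is.numeric(r$hi) || r$lo >= r$hi)
      return("rule size interval must satisfy lo < hi")
    if (!r$category %in% lungRADSLevels())
      return(sprintf("unknown category '%s'", r$category))
  }
  for (tex in textureLevels()) {
    for (mar in marginLevels()) {
      hit <- Filter(function(r) tex %in% r$texture &&
                      (identical(r$margin, "*") || mar %in% r$margin),
                    object@rules)
      if (!length(hit))
        return(sprintf("totality error: no rule covers (%s, %s)", tex, mar))
      ## determinism: overlapping intervals must agree in category
      if (length(hit) > 1L) {
        for (i in seq_len(length(hit) - 1L)) for (j in (i + 1L):length(hit)) {
          a <- hit[[i]]; b <- hit[[j]]
          if (a$lo < b$hi && b$lo < a$hi && a$category != b$category)
            return(sprintf(
              "determinism error: (%s, %s, [%g, %g)) maps to both %s and %s",
              tex, mar, max(a$lo, b$lo), min(a$hi, b$hi),
              a$category, b$category))
        }
      }
      ## totality over (0, Inf): sweep the sorted intervals
      iv <- hit[order(vapply(hit, `[[`, 0, "lo"))]
      cover <- 0
      for (r in iv) {
        if (r$lo > cover)
          return(sprintf(
            "totality error: (%s, %s, size in [%g, %g)) is uncovered",
            tex, mar, cover, r$lo))
        cover <- max(cover, r$hi)
      }
      if (is.finite(cover))
        return(sprintf(
          "totality error: (%s, %s, size >= %g) is uncovered", tex, mar,
          cover))
    }
  }
  TRUE
})

setMethod("show", "RuleTable", function(object) {
  cat(sprintf("RuleTable '%s' with %d rules\n", object@version,
              length(object@rules)))
})

#' Path of the shipped default rule table
#'
#' The default table transcribes the ACR Lung-RADS v1.1 baseline size
#' cut-offs into a texture/margin branch structure: Solid nodules by size
#' alone (<6 mm: 2, 6-8: 3, 8-15: 4A, >=15: 4B); pure ground-glass by size
#' (<30: 2, >=30: 3); part-solid (Subsolid) nodules branch on margin —
#' benign-leaning margins (sharp circumscribed, lobulated) map to 2/3 at
#' the 6 mm cut-off, suspicious margins (spiculated, indistinct) to 4A/4B
#' at 8 mm.
#'
#' @return File path of the YAML rule table.
#' @export
defaultRuleTablePath <- function() {
  system.file("extdata", "lungrads_rules_v11.yaml", package = "lungReporter",
              mustWork = TRUE)
}

.asRule <- function(x) {
  hi <- x$size[[2L]]
  if (is.character(hi)) hi <- Inf  # tolerate "inf"/".inf" spellings
  list(texture = unlist(x$texture), margin = if (identical(x$margin, "*"))
    "*" else unlist(x$margin),
    lo = as.numeric(x$size[[1L]]), hi = as.numeric(hi),
    category = as.character(x$category))
}

#' Load and validate a rule table
#'
#' Reads a YAML (or JSON) rule file and validates totality and determinism;
#' an invalid table fails here, never at assignment time.
#'
#' @param path Rule file; default the shipped v1.1 table.
#' @return A validated [RuleTable-class].
#' @examples
#' tab <- loadRuleTable()
#' assignCategory("Solid", "Lobulated", 5, tab)  # "2"
#' @export
loadRuleTable <- function(path = defaultRuleTablePath()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  if (is.null(raw$rules) || !length(raw$rules))
    stop("rule file has no rules", call. = FALSE)
  new("RuleTable",
      version = as.character(raw$version %||% "unversioned"),
      rules = lapply(raw$rules, .asRule))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a Lung-RADS category
#'
#' Returns the category of the first rule matching the (texture, margin,
#' size) triple; table validation guarantees the match exists and that any
#' overlapping rules agree.
#'
#' @param texture,margin Label tokens (case-insensitive).
#' @param size_mm Positive nodule size in mm.
#' @param table A [RuleTable-class] (default: shipped v1.1 table).
#' @return One of `"2"`, `"3"`, `"4A"`, `"4B"`.
#' @export
assignCategory <- function(texture, margin, size_mm,
                           table = loadRuleTable()) {
  stopifnot(is(table, "RuleTable"))
  if (!is.finite(size_mm) || size_mm <= 0)
    stop("value error: size_mm must be positive", call. = FALSE)
  tex <- as.character(.parseLabelVector(texture, textureLevels(), "texture"))
  mar <- as.character(.parseLabelVector(margin, marginLevels(), "margin"))
  for (r in table@rules)
    if (.ruleMatches(r, tex, mar, size_mm)) return(r$category)
  stop("internal error: validated table failed to match", call. = FALSE)
}

#' Enumerate the rule table as a truth table
#'
#' The exhaustive cartesian product of textures, margins and a size grid,
#' with the assigned category for each row; used as a brute-force oracle
#' in validation and documentation.
#'
#' @param table A [RuleTable-class].
#' @param size_grid Positive sizes in mm.
#' @return data.frame with columns `texture`, `margin`, `size_mm`,
#'   `category` (3 x 4 x length(size_grid) rows).
#' @export
enumerateTruthTable <- function(table = loadRuleTable(),
                                size_grid = c(1, 5, 7, 10, 20, 40)) {
  stopifnot(is(table, "RuleTable"))
  if (!length(size_grid)) stop("value error: empty size grid", call. = FALSE)
  grid <- expand.grid(texture = textureLevels(), margin = marginLevels(),
                      size_mm = size_grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$category <- vapply(seq_len(nrow(grid)), function(i)
    assignCategory(grid$texture[i], grid$margin[i], grid$size_mm[i], table),
    character(1L))
  grid
}
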