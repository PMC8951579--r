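#' Semantic label vocabularies
#'
#' The three semantic label sets used throughout the package, in their
#' canonical order: six lung lobes for Location, three attenuation classes
#' for Texture and four boundary appearances for Margin. The order is the
#' class order of every probability matrix and the tie-break order of
#' `predict()`.
#'
#' @return A character vector of canonical label names.
#' @examples
#' locationLevels()
#' textureLevels()
#' marginLevels()
#' @export
locationLevels <- function() {
  c("RUL", "RML", "RLL", "LUL", "LLL", "LingularLobe")
}

#' @rdname locationLevels
#' @export
textureLevels <- function() {
  c("Solid", "Subsolid", "PureGGO")
}

#' @rdname locationLevels
#' @export
marginLevels <- function() {
  c("SharpCircumscribed", "Lobulated", "Indistinct", "Spiculated")
}

#' @rdname locationLevels
#' @export
lungRADSLevels <- function() {
  c("2", "3", "4A", "4B")
}

## normalized token -> canonical form, tolerant of case, spaces, hyphens
## and underscores ("pure ggo", "Sharp-Circumscribed", "lingular lobe").
.normalizeToken <- function(x) {
  tolower(gsub("[^A-Za-z0-9]", "", x))
}

.parseLabelVector <- function(x, levels, task, ids = NULL) {
  if (is.null(x)) return(NULL)
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  lut <- stats::setNames(levels, .normalizeToken(levels))
  norm <- .normalizeToken(x)
  known <- norm %in% names(lut)
  out[known] <- lut[norm[known]]
  bad <- !known & !is.na(x) & !(trimws(x) == "")
  if (any(bad)) {
    i <- which(bad)[1L]
    where <- if (!is.null(ids)) sprintf(" (record '%s')", ids[i]) else ""
    stop(sprintf("unparseable %s label token '%s'%s; expected one of: %s",
                 task, x[i], where, paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  factor(out, levels = levels)
}

#' Parse semantic label tokens
#'
#' Case-insensitive parsing of Location/Texture/Margin tokens against the
#' canonical vocabularies; spaces, hyphens and underscores are ignored, so
#' `"rul"`, `"Pure GGO"` and `"sharp-circumscribed"` all parse. Unknown
#' tokens raise an error naming the token.
#'
#' @param x Character vector of tokens (NA and empty strings stay NA).
#' @param task One of `"location"`, `"texture"`, `"margin"`.
#' @return A factor over the canonical levels for that task.
#' @examples
#' parseLabels(c("rul", "LLL"), "location")
#' @export
parseLabels <- function(x, task = c("location", "texture", "margin")) {
  task <- match.arg(task)
  levels <- switch(task,
    location = locationLevels(),
    texture = textureLevels(),
    margin = marginLevels()
  )
  .parseLabelVector(x, levels, task)
}
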