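#' @include AllGenerics.R
NULL

#' FeatureRegistry: the named feature schema
#'
#' An ordered set of feature groups, each an ordered character vector of
#' feature names. The default registry ([buildDefaultRegistry()]) carries the
#' 107 radiomics names of the standard extractor's default feature set
#' (first-order intensity, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM) plus the
#' six SISN slice-information names, 113 names in total.
#'
#' @slot groups Named list of character vectors, one per feature group, in
#'   canonical order.
#' @aliases FeatureRegistry
#' @export
setClass("FeatureRegistry", representation(groups = "list"))

setValidity("FeatureRegistry", function(object) {
  g <- object@groups
  if (length(g) == 0L) return("registry has no groups")
  if (is.null(names(g)) || anyDuplicated(names(g)))
    return("group names must be present and unique")
  if (!all(vapply(g, is.character, logical(1L))))
    return("each group must be a character vector of feature names")
  nm <- unlist(g, use.names = FALSE)
  if (anyDuplicated(nm))
    return(sprintf("duplicate feature name: %s", nm[duplicated(nm)][1L]))
  TRUE
})

.RADIOMICS_GROUPS <- c("Intensity", "Shape", "GLCM", "GLRLM", "GLSZM",
                       "NGTDM", "GLDM")

#' Build the default 113-feature registry
#'
#' Returns the shipped feature schema: 107 radiomics names with the
#' per-group cardinalities Intensity 18, Shape 14, GLCM 24, GLRLM 16,
#' GLSZM 16, NGTDM 5, GLDM 14, plus 6 SISN names. Radiomics names use the
#' conventional `original_<matrix>_<Feature>` spelling of the standard
#' extractor's default set, so CSV exports from that tool load without
#' renaming.
#'
#' @return A [FeatureRegistry-class] object.
#' @examples
#' reg <- buildDefaultRegistry()
#' lengths(registryGroups(reg))
#' length(featureNames(reg))  # 113
#' @export
buildDefaultRegistry <- function() {
  firstorder <- c(
    "10Percentile", "90Percentile", "Energy", "Entropy",
    "InterquartileRange", "Kurtosis", "Maximum", "MeanAbsoluteDeviation",
    "Mean", "Median", "Minimum", "Range", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "TotalEnergy", "Uniformity", "Variance"
  )
  shape <- c(
    "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
    "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
    "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
    "VoxelVolume"
  )
  glcm <- c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
    "SumEntropy", "SumSquares"
  )
  glrlm <- c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"
  )
  glszm <- c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"
  )
  ngtdm <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  gldm <- c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"
  )
  sisn <- c("SISN_ratio", "SISN_first", "SISN_last", "SISN_centroid",
            "SISN_span", "SISN_peak")
  groups <- list(
    Intensity = paste0("original_firstorder_", firstorder),
    Shape = paste0("original_shape_", shape),
    GLCM = paste0("original_glcm_", glcm),
    GLRLM = paste0("original_glrlm_", glrlm),
    GLSZM = paste0("original_glszm_", glszm),
    NGTDM = paste0("original_ngtdm_", ngtdm),
    GLDM = paste0("original_gldm_", gldm),
    SISN = sisn
  )
  new("FeatureRegistry", groups = groups)
}

#' @describeIn FeatureRegistry-class the named list of feature-name groups.
#' @param x A FeatureRegistry.
#' @export
setMethod("registryGroups", "FeatureRegistry", function(x) x@groups)

#' @describeIn FeatureRegistry-class all feature names, in registry order.
#' @export
setMethod("featureNames", "FeatureRegistry", function(x) {
  unlist(x@groups, use.names = FALSE)
})

#' @describeIn FeatureRegistry-class the radiomics names (all non-SISN groups).
#' @export
setMethod("radiomicsNames", "FeatureRegistry", function(x) {
  unlist(x@groups[setdiff(names(x@groups), "SISN")], use.names = FALSE)
})

#' @describeIn FeatureRegistry-class the SISN names (empty if no SISN group).
#' @export
setMethod("sisnNames", "FeatureRegistry", function(x) {
  if ("SISN" %in% names(x@groups)) x@groups[["SISN"]] else character(0)
})

setMethod("show", "FeatureRegistry", function(object) {
  n <- lengths(object@groups)
  cat(sprintf("FeatureRegistry with %d features in %d groups\n",
              sum(n), length(n)))
  cat(paste(sprintf("  %-10s %3d", names(n), n), collapse = "\n"), "\n")
})

#' Dump a registry as JSON
#'
#' Writes the group structure as a JSON object (group name to array of
#' feature names), for documentation and interoperability.
#'
#' @param registry A [FeatureRegistry-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeRegistryJSON <- function(registry, path) {
  stopifnot(is(registry, "FeatureRegistry"))
  jsonlite::write_json(registryGroups(registry), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
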