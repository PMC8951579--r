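#' @include AllGenerics.R
NULL

#' PhantomStack: a synthetic binary segmentation stack
#'
#' A 3D binary mask (slices x rows x cols) with its axial slice thickness
#' and in-plane pixel pitch, emulating an exported nodule segmentation.
#'
#' @slot mask 3D array of 0/1 voxel labels, dimension slices x rows x cols.
#' @slot slice_thickness_mm Axial spacing in mm (default 5 mm).
#' @slot pixel_pitch_mm In-plane pixel spacing in mm (default 0.618 mm).
#' @aliases PhantomStack
#' @export
setClass("PhantomStack", representation(
  mask = "array",
  slice_thickness_mm = "numeric",
  pixel_pitch_mm = "numeric"
))

setValidity("PhantomStack", function(object) {
  if (length(dim(object@mask)) != 3L)
    return("mask must be a 3D array (slices x rows x cols)")
  if (!all(object@mask %in% c(0, 1)))
    return("mask must be binary")
  if (object@slice_thickness_mm <= 0 || object@pixel_pitch_mm <= 0)
    return("spacings must be positive")
  TRUE
})

setMethod("show", "PhantomStack", function(object) {
  d <- dim(object@mask)
  cat(sprintf(
    "PhantomStack: %d slices x %d x %d px (%.1f mm slices, %.3f mm pitch), %d labeled slices\n",
    d[1L], d[2L], d[3L], object@slice_thickness_mm, object@pixel_pitch_mm,
    sum(apply(object@mask, 1L, sum) > 0)))
})

## Core SISN computation from per-slice labeled areas. Indices are 0-based
## and every statistic is divided by the total slice count so all six values
## live in [0, 1].
.sisnFromAreas <- function(areas) {
  n <- length(areas)
  if (n < 1L) stop("value error: zero slices", call. = FALSE)
  labeled <- which(areas > 0)
  if (!length(labeled)) stop("value error: no labeled voxels", call. = FALSE)
  idx0 <- labeled - 1L                      # 0-based slice indices
  first <- idx0[1L]
  last <- idx0[length(idx0)]
  w <- areas[labeled]
  c(SISN_ratio = length(labeled) / n,
    SISN_first = first / n,
    SISN_last = last / n,
    SISN_centroid = sum(idx0 * w) / sum(w) / n,
    SISN_span = (last - first + 1) / n,
    SISN_peak = idx0[which.max(w)] / n)    # which.max: tie -> lowest index
}

#' Compute the six SISN slice-information features
#'
#' SISN (slice information of segmentation of nodules) summarises which
#' axial slices of a segmentation stack contain the nodule: the ratio of
#' labeled slices to total slices, the normalised first and last labeled
#' slice indices, the area-weighted centroid slice, the envelope span
#' `(last - first + 1) / total`, and the max-area (peak) slice. Indices are
#' 0-based and every value is divided by the total slice count, so all six
#' lie in [0, 1]. Ties in the peak area resolve to the lowest slice index.
#'
#' @param x A [PhantomStack-class] or a 3D binary array
#'   (slices x rows x cols).
#' @param ... Unused.
#' @return Named numeric vector of the six SISN features.
#' @examples
#' m <- array(0L, c(10, 4, 4)); m[3:5, 2, 2] <- 1L
#' computeSISN(m)  # ratio 0.3, first 0.2, last 0.4, span 0.3
#' @export
setMethod("computeSISN", "PhantomStack", function(x, ...) {
  .sisnFromAreas(apply(x@mask, 1L, sum))
})

#' @rdname computeSISN-PhantomStack-method
#' @export
setMethod("computeSISN", "array", function(x, ...) {
  if (length(dim(x)) != 3L)
    stop("value error: expected a 3D array (slices x rows x cols)",
         call. = FALSE)
  .sisnFromAreas(apply(x, 1L, sum))
})
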