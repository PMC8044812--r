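#' Normalize an rCBV map to normal-appearing white matter
#'
#' Divides every voxel by the mean of the map over the NAWM mask (computed
#' over usable, non-missing voxels only), making the map dimensionless with
#' NAWM mean exactly 1. Each map variant uses its own divisor.
#' Normalization is idempotent.
#'
#' @param map Numeric 3D array (may contain \code{NaN} for excluded voxels).
#' @param nawm_mask Binary/logical 3D array.
#' @return Normalized map with attribute \code{nawm_mean_raw} (the divisor).
#' @export
normalize_to_nawm <- function(map, nawm_mask) {
  stopifnot(all(dim(map) == dim(nawm_mask)))
  vals <- map[nawm_mask > 0]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no usable NAWM voxels in map")
  m <- mean(vals)
  if (!(m > 0)) stop("NAWM mean of raw map is ", signif(m, 4),
                     "; cannot normalize")
  out <- map / m
  attr(out, "nawm_mean_raw") <- m
  out
}

#' Median of a map over a volume of interest
#'
#' Sample median (midpoint convention for even counts) over the non-missing
#' voxels of the mask. An empty intersection yields \code{NA} with a
#' warning.
#'
#' @param map Numeric 3D array.
#' @param mask Binary/logical 3D array.
#' @return Scalar median or \code{NA}.
#' @export
voi_median <- function(map, mask) {
  vals <- map[mask > 0]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    warning("no usable voxels in VOI; median is NA")
    return(NA_real_)
  }
  stats::median(vals)
}

#' Mean of a map over a volume of interest
#'
#' Used for VOI summaries of fit quality (mean voxel adjusted R-squared).
#'
#' @inheritParams voi_median
#' @return Scalar mean or \code{NA}.
#' @export
voi_mean <- function(map, mask) {
  vals <- map[mask > 0]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
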