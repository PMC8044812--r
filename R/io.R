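#' DSC-MRI signal time series
#'
#' Container for a 4D dynamic susceptibility contrast acquisition: the raw
#' signal array (x, y, z, t) plus repetition and echo time. Values must be
#' finite; the time dimension must keep at least 20 dynamics after any
#' leading-volume discard.
#'
#' @param signal Numeric 4D array.
#' @param tr_seconds,te_seconds Positive reals (seconds).
#' @param discarded_leading_volumes Leading volumes already removed.
#' @param affine Optional 4x4 NIfTI affine carried through to outputs.
#' @return Object of class \code{dsc_series}.
#' @export
dsc_series <- function(signal, tr_seconds, te_seconds,
                       discarded_leading_volumes = 0L, affine = NULL) {
  if (length(dim(signal)) != 4)
    stop("DSC signal must be a 4D (x, y, z, t) array; got ",
         length(dim(signal)), " dimensions")
  stopifnot(is.numeric(signal), all(is.finite(signal)),
            tr_seconds > 0, te_seconds > 0)
  if (dim(signal)[4] < 20)
    stop("DSC series must have at least 20 timepoints; got ",
         dim(signal)[4])
  structure(list(signal = signal, tr_seconds = tr_seconds,
                 te_seconds = te_seconds,
                 discarded_leading_volumes =
                   as.integer(discarded_leading_volumes),
                 affine = affine),
            class = "dsc_series")
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("DSC series:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "dynamics (", x$discarded_leading_volumes, "discarded ), TR =",
      x$tr_seconds, "s, TE =", x$te_seconds * 1000, "ms\n")
  invisible(x)
}

#' Volume-of-interest mask set
#'
#' Binary whole-brain, tumor (CET for enhancing / NCET for nonenhancing
#' disease) and normal-appearing white matter masks on the DSC grid. NAWM
#' must lie inside the brain, be disjoint from tumor, and contain at least
#' \code{min_nawm} voxels so the normalization divisor is stable.
#'
#' @param brain,tumor,nawm Binary (0/1) 3D arrays on a common grid.
#' @param min_nawm Minimum NAWM voxel count.
#' @return Object of class \code{voi_set}.
#' @export
voi_set <- function(brain, tumor, nawm, min_nawm = 10L) {
  for (nm in c("brain", "tumor", "nawm")) {
    m <- get(nm)
    if (length(dim(m)) != 3) stop(nm, " mask must be a 3D array")
    if (!all(m %in% c(0, 1)))
      stop(nm, " mask must be binary {0,1}; found other values")
  }
  stopifnot(all(dim(brain) == dim(tumor)), all(dim(brain) == dim(nawm)))
  if (any(nawm == 1 & tumor == 1)) stop("NAWM and tumor masks overlap")
  if (any(nawm == 1 & brain == 0)) stop("NAWM mask must lie inside the brain")
  if (sum(nawm) < min_nawm)
    stop("NAWM mask has ", sum(nawm), " voxels; at least ", min_nawm,
         " required for stable normalization")
  structure(list(brain = brain, tumor = tumor, nawm = nawm),
            class = "voi_set")
}

#' @export
print.voi_set <- function(x, ...) {
  cat("VOI set:", sum(x$brain), "brain /", sum(x$tumor), "tumor /",
      sum(x$nawm), "NAWM voxels on a",
      paste(dim(x$brain), collapse = " x "), "grid\n")
  invisible(x)
}

#' Load one DSC case from NIfTI files
#'
#' Reads the 4D DSC series and the three co-registered binary masks,
#' validating dimensionality, grid agreement, affine agreement (within
#' \code{affine_tol}) and mask binarity. No leading-volume discard is
#' applied here (that is an analysis step). No resampling is performed:
#' masks are consumed as delivered, and affines are carried through
#' untouched.
#'
#' @param dsc_path Path to the 4D DSC NIfTI.
#' @param brain_path,tumor_path,nawm_path Paths to binary 3D mask NIfTIs.
#' @param tr_seconds,te_seconds Acquisition timing in seconds.
#' @param affine_tol Maximum absolute elementwise affine mismatch.
#' @return List with \code{series} (\code{\link{dsc_series}}) and
#'   \code{vois} (\code{\link{voi_set}}).
#' @export
load_case <- function(dsc_path, brain_path, tumor_path, nawm_path,
                      tr_seconds, te_seconds, affine_tol = 1e-3) {
  for (p in c(dsc_path, brain_path, tumor_path, nawm_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  img <- RNifti::readNifti(dsc_path)
  sig <- as.array(img)
  if (length(dim(sig)) != 4)
    stop("DSC input must be a 4D time series; ", dsc_path, " has ",
         length(dim(sig)), " dimensions")
  aff <- RNifti::xform(img)
  read_mask <- function(p) {
    m <- RNifti::readNifti(p)
    a <- RNifti::xform(m)
    if (max(abs(a - aff)) > affine_tol)
      stop("mask affine mismatch beyond tolerance: ", p)
    arr <- as.array(m)
    if (length(dim(arr)) != 3) stop("mask must be 3D: ", p)
    if (!all(dim(arr) == dim(sig)[1:3]))
      stop("mask grid does not match DSC grid: ", p)
    arr
  }
  vois <- voi_set(read_mask(brain_path), read_mask(tumor_path),
                  read_mask(nawm_path))
  series <- dsc_series(sig, tr_seconds, te_seconds, affine = aff)
  list(series = series, vois = vois)
}

#' Write the computed parameter maps as NIfTI volumes
#'
#' Writes one 3D NIfTI per available map (normalized rCBV without and with
#' each correction, K2 and Kep maps, adjusted R-squared per model), carrying
#' the input affine when one is available, and returns a manifest of the
#' written files. Maps are written as double precision so a read-back
#' reproduces the values bit-exactly.
#'
#' @param maps Named list of 3D numeric arrays (entries may be missing).
#' @param out_dir Output directory (created if needed).
#' @param affine Optional 4x4 affine for the outputs.
#' @return Data frame manifest with columns \code{name} and \code{path}.
#' @export
write_maps <- function(maps, out_dir, affine = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  maps <- maps[!vapply(maps, is.null, logical(1))]
  if (!length(maps)) stop("no maps to write")
  paths <- character(0)
  for (nm in names(maps)) {
    img <- RNifti::asNifti(maps[[nm]], datatype = "double")
    if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine,
                                                                  code = 2L))
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths[nm] <- p
  }
  data.frame(name = names(paths), path = unname(paths),
             stringsAsFactors = FALSE)
}
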