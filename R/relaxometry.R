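#' Discard leading volumes of a DSC series
#'
#' The first dynamics of a gradient-echo EPI acquisition are acquired before
#' the signal reaches steady state and are removed before any analysis
#' (two by default).
#'
#' @param series A \code{\link{dsc_series}} object.
#' @param n Number of leading volumes to drop.
#' @return The series with the first \code{n} volumes removed and
#'   \code{discarded_leading_volumes} updated.
#' @export
discard_leading_volumes <- function(series, n = 2L) {
  stopifnot(inherits(series, "dsc_series"), n >= 0)
  nt <- dim(series$signal)[4]
  if (nt - n < 20)
    stop("discarding ", n, " volumes would leave ", nt - n,
         " timepoints; at least 20 are required")
  if (n == 0L) return(series)
  series$signal <- series$signal[, , , -seq_len(n), drop = FALSE]
  series$discarded_leading_volumes <- series$discarded_leading_volumes +
    as.integer(n)
  series
}

#' Baseline signal level and noise of one voxel
#'
#' The baseline signal S0 is the mean of the voxel signal over the pre-bolus
#' baseline indices; its sample standard deviation estimates the noise level
#' used by every QC rule. A degenerate all-equal baseline yields sd = 0,
#' which downstream rules handle via an absolute epsilon.
#'
#' @param trace Numeric vector, voxel signal over time.
#' @param window Acquisition window (uses \code{window$baseline_idx}).
#' @return List with \code{s0} and \code{baseline_sd}.
#' @export
estimate_baseline <- function(trace, window) {
  idx <- window$baseline_idx
  if (length(idx) < 5)
    stop("baseline window has ", length(idx), " points; at least 5 required")
  list(s0 = mean(trace[idx]), baseline_sd = stats::sd(trace[idx]))
}

#' Convert a signal trace to a relaxivity-time curve
#'
#' \eqn{\Delta R_2^*(t) = -(1/T_E)\,\ln(S(t)/S_0)}. A signal increase above
#' baseline gives a negative relaxivity (T1-dominant leakage overshoot) and
#' is preserved, not clipped. Non-positive samples, which the log cannot
#' take, are clamped to \code{clamp_epsilon * s0} and flagged in the
#' \code{clamped} attribute.
#'
#' @param trace Numeric signal vector.
#' @param s0 Baseline signal (> 0; a voxel with s0 <= 0 is unusable).
#' @param te Echo time in seconds.
#' @param clamp_epsilon Clamp level as a fraction of \code{s0}.
#' @return Numeric relaxivity vector (s^-1) with a logical attribute
#'   \code{clamped} marking replaced samples.
#' @export
signal_to_relaxivity <- function(trace, s0, te, clamp_epsilon = 1e-6) {
  stopifnot(is.numeric(trace), te > 0)
  if (!is.finite(s0) || s0 <= 0)
    stop("non-positive baseline signal; voxel is unusable")
  clamped <- trace <= 0
  trace[clamped] <- clamp_epsilon * s0
  out <- -(1 / te) * log(trace / s0)
  attr(out, "clamped") <- clamped
  out
}

#' Sufficient-bolus-drop quality control for one voxel
#'
#' A voxel carries usable first-pass information only if its signal drops by
#' at least \code{n_sd} baseline standard deviations somewhere in the bolus
#' window. With a zero baseline SD (noiseless data) the rule degenerates to
#' "any drop at all", implemented with an absolute epsilon.
#'
#' @param trace Numeric signal vector.
#' @param s0,baseline_sd Baseline statistics from
#'   \code{\link{estimate_baseline}}.
#' @param window Acquisition window; the minimum is taken over
#'   \code{t0:t1}.
#' @param n_sd Drop threshold in baseline SDs.
#' @param sd_zero_epsilon Absolute epsilon used when \code{baseline_sd} is 0.
#' @return \code{TRUE} if the voxel passes.
#' @export
qc_sufficient_drop <- function(trace, s0, baseline_sd, window, n_sd = 5,
                               sd_zero_epsilon = 1e-9) {
  m <- min(trace[window$t0:window$t1])
  if (baseline_sd > 0) m <= s0 - n_sd * baseline_sd
  else                 m < s0 - sd_zero_epsilon
}

#' Select nonenhancing voxels for the whole-brain reference curve
#'
#' A brain voxel is nonenhancing when the absolute difference between its
#' tail mean (final timepoints) and its baseline S0 is below
#' \code{tail_sd_threshold} baseline SDs: contrast has washed out and the
#' signal has returned to baseline, so no leakage is retained. The selection
#' is additionally intersected with the sufficient-drop QC mask, since
#' voxels without a bolus drop carry no perfusion information.
#'
#' @param signal 4D signal array (x, y, z, t).
#' @param brain_mask Logical/binary 3D array.
#' @param window Acquisition window (uses \code{baseline_idx},
#'   \code{tail_idx}, \code{t0}, \code{t1}).
#' @param config A \code{\link{dsc_config}}.
#' @return Logical 3D array marking selected voxels.
#' @export
select_nonenhancing_voxels <- function(signal, brain_mask, window,
                                       config = dsc_config()) {
  dims <- dim(signal)
  stopifnot(length(dims) == 4, all(dim(brain_mask) == dims[1:3]))
  sel <- array(FALSE, dims[1:3])
  idx <- which(brain_mask > 0)
  nt <- dims[4]
  sig2d <- matrix(aperm(signal, c(4, 1, 2, 3)), nrow = nt)[, idx,
                                                           drop = FALSE]
  s0 <- colMeans(sig2d[window$baseline_idx, , drop = FALSE])
  bsd <- apply(sig2d[window$baseline_idx, , drop = FALSE], 2, stats::sd)
  tail_mean <- colMeans(sig2d[window$tail_idx, , drop = FALSE])
  tol <- ifelse(bsd > 0, config$tail_sd_threshold * bsd,
                config$sd_zero_epsilon)
  flat <- abs(tail_mean - s0) < tol
  drop_ok <- vapply(seq_along(idx), function(j)
    qc_sufficient_drop(sig2d[, j], s0[j], bsd[j], window,
                       config$drop_sd_threshold, config$sd_zero_epsilon),
    logical(1))
  keep <- flat & drop_ok
  if (!any(keep))
    stop("no nonenhancing voxels selected; review the tail/drop thresholds ",
         "(a reference curve cannot be built)")
  sel[idx[keep]] <- TRUE
  sel
}

#' Average selected voxel relaxivity curves into the reference curve
#'
#' The whole-brain reference relaxivity curve is the pointwise mean of the
#' relaxivity-time curves of the selected nonenhancing voxels; it drives
#' both leakage models.
#'
#' @param relax_mat Matrix of relaxivity curves, timepoints x voxels.
#' @param time_step Sampling interval in seconds (TR).
#' @param min_voxels Floor on the number of averaged voxels.
#' @return An object of class \code{reference_curve} with fields
#'   \code{values}, \code{time_step}, \code{n_voxels_averaged}.
#' @export
build_reference_curve <- function(relax_mat, time_step, min_voxels = 1L) {
  stopifnot(is.matrix(relax_mat), ncol(relax_mat) >= 1)
  if (ncol(relax_mat) < min_voxels)
    stop("only ", ncol(relax_mat), " voxels available for the reference ",
         "curve; floor is ", min_voxels)
  vals <- rowMeans(relax_mat)
  if (!all(is.finite(vals))) stop("non-finite values in reference curve")
  structure(list(values = vals, time_step = time_step,
                 n_voxels_averaged = ncol(relax_mat)),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("Whole-brain reference relaxivity curve:", length(x$values),
      "timepoints, dt =", x$time_step, "s, averaged over",
      x$n_voxels_averaged, "voxels\n")
  cat("  peak", signif(max(x$values), 4), "s^-1 at index",
      which.max(x$values), "\n")
  invisible(x)
}

#' Locate the baseline and first-pass bolus window on a reference curve
#'
#' Works on the whole-brain mean relaxivity curve. The baseline is grown
#' iteratively from the first \code{baseline_init_points} samples, extending
#' while samples stay within \code{baseline_detect_sd} SDs of the running
#' mean; the first sample exceeding mean + detect_sd * SD marks the bolus
#' upslope. The entry index t0 is the last sub-threshold sample (also
#' excluded from the baseline as a 1-point guard). The exit index t1 is the
#' earlier of (a) the first post-peak sample falling below
#' \code{bolus_exit_fraction} of (peak - baseline) above baseline and (b)
#' the pre-recirculation local minimum. One global window from the reference
#' curve is applied to all voxels; no per-voxel arrival model is used.
#'
#' @param ref A \code{reference_curve}, or a numeric vector of relaxivity
#'   values.
#' @param config A \code{\link{dsc_config}}.
#' @return List of class \code{acq_window}: \code{baseline_idx} (integer
#'   vector), \code{t0}, \code{t1}, \code{peak}, \code{tail_idx},
#'   \code{baseline_mean}, \code{baseline_sd} (of the reference curve).
#' @export
locate_bolus_window <- function(ref, config = dsc_config()) {
  v <- if (inherits(ref, "reference_curve")) ref$values else ref
  n <- length(v)
  stopifnot(n >= 20)
  k0 <- config$baseline_init_points
  eps <- config$sd_zero_epsilon
  b <- NA_integer_
  i <- k0 + 1L
  repeat {
    m <- mean(v[1:(i - 1L)])
    s <- stats::sd(v[1:(i - 1L)])
    thr <- m + config$baseline_detect_sd * max(s, eps)
    if (v[i] > thr) { b <- i; break }
    i <- i + 1L
    if (i > n) break
  }
  if (is.na(b)) stop("no detectable bolus peak (curve never leaves baseline)")
  baseline_idx <- seq_len(max(b - 2L, k0))    # 1-point guard before t0
  m <- mean(v[baseline_idx])
  s <- stats::sd(v[baseline_idx])
  t0 <- b - 1L
  peak <- which.max(v[t0:n]) + t0 - 1L
  if (!(v[peak] - m >= config$drop_sd_threshold * max(s, eps)))
    stop("reference peak below ", config$drop_sd_threshold,
         " baseline SDs; no detectable bolus")
  exit_level <- m + config$bolus_exit_fraction * (v[peak] - m)
  t1_thr <- NA_integer_
  t1_min <- NA_integer_
  if (peak < n) {
    below <- which(v[(peak + 1L):n] < exit_level)
    if (length(below)) t1_thr <- peak + below[1L]
    if (peak + 2L <= n) {
      for (j in (peak + 1L):(n - 1L)) {
        if (v[j] < v[j - 1L] && v[j] < v[j + 1L]) { t1_min <- j; break }
      }
    }
  }
  t1 <- suppressWarnings(min(t1_thr, t1_min, na.rm = TRUE))
  if (!is.finite(t1)) t1 <- n
  if (t1 <= peak) t1 <- min(peak + 1L, n)
  tail_idx <- if (n - t1 >= config$tail_length) (n - config$tail_length + 1L):n
  else {
    warning("fewer than ", config$tail_length, " points after bolus exit; ",
            "using all ", n - t1, " post-bolus points as tail")
    if (t1 < n) (t1 + 1L):n else n
  }
  structure(list(baseline_idx = baseline_idx, t0 = t0, t1 = t1, peak = peak,
                 tail_idx = tail_idx, baseline_mean = m, baseline_sd = s),
            class = "acq_window")
}

#' @export
print.acq_window <- function(x, ...) {
  cat("Acquisition window: baseline 1..", max(x$baseline_idx),
      ", bolus entry t0 = ", x$t0, ", peak = ", x$peak,
      ", exit t1 = ", x$t1, ", tail ", min(x$tail_idx), "..",
      max(x$tail_idx), "\n", sep = "")
  invisible(x)
}
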