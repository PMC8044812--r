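#' Running trapezoidal integral of a relaxivity curve
#'
#' Computes the causal cumulative integral \eqn{\int_0^{t_i} f(t')\,dt'} of a
#' uniformly sampled curve by the trapezoidal rule. Element 1 is 0 and element
#' \eqn{i} uses only samples up to \eqn{t_i}. This is the integral term of the
#' unidirectional leakage model, and the identical discretization is used by
#' the forward simulator so that noiseless parameter recovery is exact.
#'
#' @param values Numeric vector, curve samples (s^-1).
#' @param dt Positive scalar, sampling interval in seconds (the repetition
#'   time TR).
#' @return Numeric vector of the same length; dimensionless (s^-1 times s).
#' @export
cumulative_integral <- function(values, dt) {
  stopifnot(is.numeric(values), length(values) >= 1, is.numeric(dt), dt > 0)
  if (length(values) == 1L) return(0)
  as.numeric(pracma::cumtrapz(seq(0, by = dt, length.out = length(values)),
                              values))
}

#' Exponentially weighted running integral
#'
#' Computes \eqn{\int_0^{t_i} f(t')\, e^{-k_{ep}(t_i - t')}\,dt'} for every
#' sample index \eqn{i}, by the trapezoidal rule on a uniform grid. This is
#' the leakage term of the bidirectional model: contrast that extravasated at
#' time \eqn{t'} washes back with rate \eqn{k_{ep}}, so its contribution
#' decays as \eqn{e^{-k_{ep}(t-t')}}. At \code{kep = 0} the result equals
#' \code{\link{cumulative_integral}} exactly.
#'
#' The trapezoid-with-kernel sum obeys the one-step recursion
#' \deqn{I_i = d\, I_{i-1} + \tfrac{dt}{2}(f_i + d\, f_{i-1}), \quad
#'       d = e^{-k_{ep} dt},}
#' evaluated with a linear recursive filter. The per-step exponent is clipped
#' at +/-50 (with a warning) so that an unconstrained, strongly negative
#' \code{kep} cannot overflow.
#'
#' @param values Numeric vector, curve samples (s^-1).
#' @param dt Positive scalar, sampling interval in seconds.
#' @param kep Scalar back-transfer rate in s^-1; sign unconstrained.
#' @param exp_clip Magnitude at which the per-step exponent is clipped.
#' @return Numeric vector of the same length as \code{values}.
#' @export
exp_weighted_integral <- function(values, dt, kep, exp_clip = 50) {
  stopifnot(is.numeric(values), is.numeric(dt), dt > 0,
            is.numeric(kep), length(kep) == 1L, is.finite(kep))
  n <- length(values)
  if (n == 1L) return(0)
  if (kep == 0) return(cumulative_integral(values, dt))
  expo <- -kep * dt
  if (abs(expo) > exp_clip) {
    warning("exponent ", signif(expo, 3), " clipped to +/-", exp_clip,
            " in exponential kernel")
    expo <- sign(expo) * exp_clip
  }
  d <- exp(expo)
  w <- dt / 2 * (values[-1L] + d * values[-n])
  out <- c(0, as.numeric(stats::filter(w, d, method = "recursive")))
  if (!all(is.finite(out)))
    warning("non-finite values in exponential kernel integral (kep = ",
            signif(kep, 4), ")")
  out
}

#' Trapezoidal integral of a curve over the bolus window
#'
#' The relative cerebral blood volume of a voxel is the trapezoidal integral
#' of its relaxivity curve between the bolus entry and exit indices. Negative
#' results (pathological voxels) are preserved, not clipped.
#'
#' @param values Numeric vector, relaxivity curve (s^-1).
#' @param window An acquisition window, see \code{\link{locate_bolus_window}},
#'   or a list with integer elements \code{t0 < t1}.
#' @param dt Sampling interval in seconds.
#' @return Scalar integral (dimensionless, s^-1 times s).
#' @export
integrate_rcbv <- function(values, window, dt) {
  t0 <- window$t0; t1 <- window$t1
  stopifnot(t0 >= 1, t0 < t1, t1 <= length(values))
  idx <- t0:t1
  pracma::trapz((idx - 1) * dt, values[idx])
}
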