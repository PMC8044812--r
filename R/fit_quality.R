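#' Coefficient of determination between an observed and a fitted trace
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with
#' \eqn{SS_{res} = \sum_t (\hat y_t - y_t)^2} and
#' \eqn{SS_{tot} = \sum_t (y_t - \bar y)^2}. A constant observed trace has
#' \eqn{SS_{tot} = 0} and an undefined \eqn{R^2}; \code{NA} is returned in
#' that case.
#'
#' @param observed,fitted Numeric vectors of equal length (at least 3).
#' @return A list with elements \code{r2}, \code{ss_res}, \code{ss_tot}.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 3,
            all(is.finite(observed)), all(is.finite(fitted)))
  ss_res <- sum((fitted - observed)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(r2 = r2, ss_res = ss_res, ss_tot = ss_tot)
}

#' Adjusted coefficient of determination
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - k - 1)}, where \eqn{n} is the
#' number of timepoints entering the fit and \eqn{k} the number of model
#' parameters (2 for the unidirectional, 3 for the bidirectional leakage
#' model). May be negative for poor fits.
#'
#' @param r2 Unadjusted R-squared (may be \code{NA}, which propagates).
#' @param n Number of observations.
#' @param k Number of model parameters.
#' @return Scalar adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, k) {
  stopifnot(is.numeric(n), is.numeric(k), length(r2) == 1L)
  if (n <= k + 1) stop("adjusted R-squared requires n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}
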