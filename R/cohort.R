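#' Percentage difference between uncorrected and corrected rCBV
#'
#' \code{100 * (uncorrected - corrected) / uncorrected}: positive when the
#' correction lowers rCBV (the typical T2*-dominant case), negative when it
#' raises it. Computed per patient; group values are the mean across
#' patients. A zero uncorrected value is undefined and yields \code{NA}
#' with a warning.
#'
#' @param uncorrected,corrected Numeric vectors (recycled as usual).
#' @return Numeric vector of percentage differences.
#' @export
percent_difference <- function(uncorrected, corrected) {
  out <- 100 * (uncorrected - corrected) / uncorrected
  bad <- uncorrected == 0
  if (any(bad, na.rm = TRUE)) {
    warning("zero uncorrected value(s); percentage difference set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' Wilcoxon signed-rank test for one paired comparison
#'
#' Zero differences are dropped; with no remaining differences the p-value
#' is 1 by convention. The exact null distribution is used for up to
#' \code{exact_max} nonzero pairs when there are no ties in the absolute
#' differences; otherwise the normal approximation with continuity
#' correction and mid-ranks is used.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with \code{p_value}, \code{statistic} (V), \code{n_nonzero},
#'   \code{exact}.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (!length(nz))
    return(list(p_value = 1, statistic = NA_real_, n_nonzero = 0L,
                exact = TRUE))
  ties <- any(duplicated(abs(nz)))
  use_exact <- length(nz) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = use_exact,
                                            correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_nonzero = length(nz), exact = use_exact)
}

#' Paired comparisons of the rCBV variants within a patient group
#'
#' Runs the three paired comparisons (uncorrected vs unidirectional,
#' uncorrected vs bidirectional, unidirectional vs bidirectional) on the
#' per-patient VOI medians of one group with the Wilcoxon signed-rank test,
#' then applies the Holm step-down correction within this three-comparison
#' family. Shapiro-Wilk normality p-values of the paired differences are
#' reported for audit, but the analysis always proceeds nonparametrically.
#'
#' @param records Data frame with columns \code{median_rcbv},
#'   \code{median_rcbv_unidir}, \code{median_rcbv_bidir} (one row per
#'   patient).
#' @param alpha Significance level after correction.
#' @return Data frame with one row per comparison: \code{comparison},
#'   \code{n}, \code{shapiro_p}, \code{p_raw}, \code{p_holm},
#'   \code{significant}.
#' @export
paired_group_tests <- function(records, alpha = 0.05) {
  need <- c("median_rcbv", "median_rcbv_unidir", "median_rcbv_bidir")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) < 6)
    stop("at least 6 paired observations required; got ", nrow(records))
  cmp <- list(uncorrected_vs_unidir = c("median_rcbv",
                                        "median_rcbv_unidir"),
              uncorrected_vs_bidir = c("median_rcbv", "median_rcbv_bidir"),
              unidir_vs_bidir = c("median_rcbv_unidir",
                                  "median_rcbv_bidir"))
  rows <- lapply(names(cmp), function(nm) {
    a <- records[[cmp[[nm]][1]]]
    b <- records[[cmp[[nm]][2]]]
    d <- a - b
    sw <- if (length(unique(d)) > 2 && length(d) >= 3 && length(d) <= 5000)
      tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
    else NA_real_
    w <- wilcoxon_signed_rank(a, b)
    data.frame(comparison = nm, n = length(d), shapiro_p = sw,
               p_raw = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_holm < alpha
  out
}

#' Spearman correlation of rCBV with WHO tumor grade
#'
#' Rank correlation (mid-ranks for ties) between per-patient VOI median
#' rCBV and WHO grade, for each available map variant.
#'
#' @param records Data frame with a \code{grade} column and the rCBV median
#'   columns.
#' @param maps Character vector of record columns to correlate.
#' @return Data frame with \code{map}, \code{n}, \code{rs}, \code{p_value}.
#' @export
grade_correlation <- function(records,
                              maps = c("median_rcbv",
                                       "median_rcbv_unidir",
                                       "median_rcbv_bidir")) {
  keep <- records[is.finite(records$grade), , drop = FALSE]
  if (nrow(keep) < 5)
    stop("at least 5 graded records required; got ", nrow(keep))
  if (length(unique(keep$grade)) < 2)
    stop("tumor grade is constant; correlation undefined")
  rows <- lapply(maps, function(m) {
    ct <- suppressWarnings(stats::cor.test(keep[[m]], keep$grade,
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(map = m, n = nrow(keep), rs = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level summary table of a cohort
#'
#' Per patient group: mean and SD of each rCBV variant over patients, mean
#' per-patient percentage differences of each correction relative to the
#' uncorrected value, Holm-adjusted p-values of the paired comparisons, and
#' mean adjusted R-squared of each model. Percentage differences are
#' averaged across patients, not recomputed from group means.
#'
#' @param records Data frame of per-patient records with a \code{group}
#'   column.
#' @param alpha Significance level.
#' @return Data frame with one row per group.
#' @export
cohort_table <- function(records, alpha = 0.05) {
  stopifnot(nrow(records) >= 1, "group" %in% names(records))
  groups <- unique(records$group)
  rows <- lapply(groups, function(gr) {
    rec <- records[records$group == gr, , drop = FALSE]
    if (nrow(rec) == 1)
      warning("group '", gr, "' has a single patient; SD reported as 0")
    msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                         sd = if (length(x) > 1) stats::sd(x, na.rm = TRUE)
                         else 0)
    u <- msd(rec$median_rcbv)
    un <- msd(rec$median_rcbv_unidir)
    bi <- msd(rec$median_rcbv_bidir)
    pd_uni <- mean(percent_difference(rec$median_rcbv,
                                      rec$median_rcbv_unidir), na.rm = TRUE)
    pd_bi <- mean(percent_difference(rec$median_rcbv,
                                     rec$median_rcbv_bidir), na.rm = TRUE)
    tests <- if (nrow(rec) >= 6) paired_group_tests(rec, alpha) else NULL
    getp <- function(nm) if (is.null(tests)) NA_real_
    else tests$p_holm[tests$comparison == nm]
    data.frame(group = gr, n = nrow(rec),
               rcbv_mean = u["mean"], rcbv_sd = u["sd"],
               rcbv_unidir_mean = un["mean"], rcbv_unidir_sd = un["sd"],
               pct_diff_unidir = pd_uni,
               p_unidir = getp("uncorrected_vs_unidir"),
               rcbv_bidir_mean = bi["mean"], rcbv_bidir_sd = bi["sd"],
               pct_diff_bidir = pd_bi,
               p_bidir = getp("uncorrected_vs_bidir"),
               p_unidir_vs_bidir = getp("unidir_vs_bidir"),
               mean_adj_r2_unidir = mean(rec$mean_adj_r2_unidir,
                                         na.rm = TRUE),
               mean_adj_r2_bidir = mean(rec$mean_adj_r2_bidir,
                                        na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
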