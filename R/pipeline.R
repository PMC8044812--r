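#' Run the full leakage-correction pipeline on one case
#'
#' Executes the per-patient workflow: discard leading volumes; locate the
#' baseline and first-pass bolus window on the whole-brain mean relaxivity
#' curve; apply the voxel QC (5-SD bolus-drop rule); select nonenhancing
#' voxels (tail within 1 baseline SD of baseline) and average their
#' relaxivity curves into the whole-brain reference curve; re-locate the
#' window on the reference curve; fit the requested leakage models per
#' voxel; integrate the uncorrected and corrected curves over the bolus
#' window; and normalize every rCBV map to its own NAWM mean. Voxels
#' failing QC or fit convergence are \code{NaN} in all maps and excluded
#' from VOI medians and NAWM divisors.
#'
#' @param series A \code{\link{dsc_series}}.
#' @param vois A \code{\link{voi_set}} on the same grid.
#' @param model Which corrections to fit: \code{"all"}, \code{"none"}
#'   (uncorrected only), \code{"unidir"}, or \code{"bidir"}.
#' @param config A \code{\link{dsc_config}}.
#' @param verbose Log voxel counts surviving each QC stage.
#' @return Object of class \code{dsc_case}: \code{maps} (named list of
#'   normalized 3D maps: \code{rcbv}, \code{rcbv_unidir},
#'   \code{rcbv_bidir}, \code{k2_unidir}, \code{k2_bidir},
#'   \code{kep_bidir}, \code{adj_r2_unidir}, \code{adj_r2_bidir}),
#'   \code{nawm_mean_raw} (per-map divisors), \code{window},
#'   \code{reference}, \code{qc} (voxel counts per stage), \code{config},
#'   \code{model}, \code{vois}.
#' @export
run_case <- function(series, vois, model = c("all", "none", "unidir",
                                             "bidir"),
                     config = dsc_config(), verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dsc_series"), inherits(vois, "voi_set"))
  if (!all(dim(series$signal)[1:3] == dim(vois$brain)))
    stop("VOI grid does not match DSC grid")
  s <- discard_leading_volumes(series, config$discard_volumes)
  sig <- s$signal
  dims <- dim(sig)
  nt <- dims[4]
  dt <- s$tr_seconds
  te <- s$te_seconds
  say <- function(...) if (verbose) message(...)

  brain_idx <- which(vois$brain > 0)
  sig2d <- matrix(aperm(sig, c(4, 1, 2, 3)), nrow = nt)
  say("brain voxels: ", length(brain_idx))

  # provisional window from the whole-brain mean relaxivity curve
  wb <- rowMeans(sig2d[, brain_idx, drop = FALSE])
  s0p <- mean(wb[seq_len(config$baseline_init_points)])
  wb_relax <- signal_to_relaxivity(wb, s0p, te, config$clamp_epsilon)
  window0 <- locate_bolus_window(as.numeric(wb_relax), config)

  # nonenhancing voxels -> reference curve
  nonenh <- select_nonenhancing_voxels(sig, vois$brain, window0, config)
  nonenh_idx <- which(nonenh)
  say("nonenhancing voxels selected for reference: ", length(nonenh_idx))
  relax_ref <- vapply(nonenh_idx, function(v) {
    b <- estimate_baseline(sig2d[, v], window0)
    as.numeric(signal_to_relaxivity(sig2d[, v], b$s0, te,
                                    config$clamp_epsilon))
  }, numeric(nt))
  reference <- build_reference_curve(matrix(relax_ref, nrow = nt), dt,
                                     config$min_reference_voxels)
  window <- locate_bolus_window(reference, config)
  say("bolus window on reference curve: t0 = ", window$t0, ", t1 = ",
      window$t1)

  fit_uni <- model %in% c("all", "unidir")
  fit_bi <- model %in% c("all", "bidir")
  kernels <- if (fit_bi) precompute_kep_kernels(reference$values, dt,
                                                config) else NULL

  shape3 <- dims[1:3]
  nan_map <- array(NaN, shape3)
  maps <- list(rcbv = nan_map)
  if (fit_uni) maps[c("rcbv_unidir", "k2_unidir",
                      "adj_r2_unidir")] <- list(nan_map)
  if (fit_bi) maps[c("rcbv_bidir", "k2_bidir", "kep_bidir",
                     "adj_r2_bidir")] <- list(nan_map)

  n_drop_fail <- 0L; n_clamp_excl <- 0L; n_fit_fail <- 0L
  win_idx <- window$t0:window$t1
  for (v in brain_idx) {
    trace <- sig2d[, v]
    b <- estimate_baseline(trace, window)
    if (!is.finite(b$s0) || b$s0 <= 0) { n_drop_fail <- n_drop_fail + 1L
      next }
    if (!qc_sufficient_drop(trace, b$s0, b$baseline_sd, window,
                            config$drop_sd_threshold,
                            config$sd_zero_epsilon)) {
      n_drop_fail <- n_drop_fail + 1L
      next
    }
    relax <- signal_to_relaxivity(trace, b$s0, te, config$clamp_epsilon)
    clamped <- attr(relax, "clamped")
    if (mean(clamped[win_idx]) > config$clamp_max_fraction) {
      n_clamp_excl <- n_clamp_excl + 1L
      next
    }
    relax <- as.numeric(relax)
    fit_idx <- which(!clamped)
    maps$rcbv[v] <- integrate_rcbv(relax, window, dt)
    if (fit_uni) {
      f <- leakage_fit(relax, reference, "unidirectional",
                       fit_idx = fit_idx, config = config)
      if (f$converged) {
        maps$k2_unidir[v] <- coef(f)[["k2"]]
        maps$adj_r2_unidir[v] <- f$adj_r_squared
        maps$rcbv_unidir[v] <- integrate_rcbv(correct_curve(f), window, dt)
      } else n_fit_fail <- n_fit_fail + 1L
    }
    if (fit_bi) {
      f <- leakage_fit(relax, reference, "bidirectional",
                       fit_idx = fit_idx, config = config,
                       ref_kernels = kernels)
      if (f$converged) {
        maps$k2_bidir[v] <- coef(f)[["k2"]]
        maps$kep_bidir[v] <- coef(f)[["kep"]]
        maps$adj_r2_bidir[v] <- f$adj_r_squared
        maps$rcbv_bidir[v] <- integrate_rcbv(correct_curve(f), window, dt)
      } else n_fit_fail <- n_fit_fail + 1L
    }
  }
  say("voxels excluded: ", n_drop_fail, " (drop QC), ", n_clamp_excl,
      " (clamping), fit failures: ", n_fit_fail)

  nawm_mean_raw <- list()
  for (nm in intersect(c("rcbv", "rcbv_unidir", "rcbv_bidir"),
                       names(maps))) {
    maps[[nm]] <- normalize_to_nawm(maps[[nm]], vois$nawm)
    nawm_mean_raw[[nm]] <- attr(maps[[nm]], "nawm_mean_raw")
  }

  structure(list(maps = maps, nawm_mean_raw = nawm_mean_raw,
                 window = window, reference = reference,
                 qc = list(n_brain = length(brain_idx),
                           n_nonenhancing = length(nonenh_idx),
                           n_drop_fail = n_drop_fail,
                           n_clamp_excluded = n_clamp_excl,
                           n_fit_fail = n_fit_fail),
                 config = config, model = model, vois = vois,
                 affine = series$affine),
            class = "dsc_case")
}

#' @export
print.dsc_case <- function(x, ...) {
  cat("DSC leakage-correction case (model: ", x$model, ")\n", sep = "")
  print(x$reference)
  print(x$window)
  cat("  QC: ", x$qc$n_brain, " brain voxels, ",
      x$qc$n_nonenhancing, " in reference, ",
      x$qc$n_drop_fail, " failed drop QC, ",
      x$qc$n_clamp_excluded, " clamp-excluded\n", sep = "")
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Per-patient VOI summary of a processed case
#'
#' Median of each normalized rCBV map and each permeability map over the
#' tumor VOI, plus the VOI mean adjusted R-squared of each model; the
#' summary row that cohort statistics consume.
#'
#' @param case A \code{dsc_case} from \code{\link{run_case}}.
#' @param patient_id,group,grade Metadata carried into the record.
#' @return One-row data frame.
#' @export
case_summary <- function(case, patient_id = "case", group = NA_character_,
                         grade = NA_integer_) {
  stopifnot(inherits(case, "dsc_case"))
  m <- case$maps
  tum <- case$vois$tumor
  g <- function(nm, f = voi_median)
    if (!is.null(m[[nm]])) f(m[[nm]], tum) else NA_real_
  data.frame(patient_id = patient_id, group = group, grade = grade,
             median_rcbv = g("rcbv"),
             median_rcbv_unidir = g("rcbv_unidir"),
             median_rcbv_bidir = g("rcbv_bidir"),
             median_k2_unidir = g("k2_unidir"),
             median_k2_bidir = g("k2_bidir"),
             median_kep_bidir = g("kep_bidir"),
             mean_adj_r2_unidir = g("adj_r2_unidir", voi_mean),
             mean_adj_r2_bidir = g("adj_r2_bidir", voi_mean),
             stringsAsFactors = FALSE)
}

#' Write the maps of a processed case
#'
#' Thin wrapper over \code{\link{write_maps}} using the case's own maps and
#' affine; also writes the reference curve and window as TSV/YAML sidecars
#' and the resolved configuration, so a run directory is fully auditable.
#'
#' @param case A \code{dsc_case}.
#' @param out_dir Output directory.
#' @return File manifest data frame (maps plus sidecar files).
#' @export
write_case <- function(case, out_dir) {
  stopifnot(inherits(case, "dsc_case"))
  manifest <- write_maps(case$maps, out_dir, affine = case$affine)
  ref_path <- file.path(out_dir, "reference_curve.tsv")
  utils::write.table(
    data.frame(time_s = (seq_along(case$reference$values) - 1) *
                 case$reference$time_step,
               delta_r2s = case$reference$values),
    ref_path, sep = "\t", quote = FALSE, row.names = FALSE)
  win_path <- file.path(out_dir, "window.yaml")
  w <- case$window
  yaml::write_yaml(list(baseline_first = min(w$baseline_idx),
                        baseline_last = max(w$baseline_idx),
                        t0 = w$t0, t1 = w$t1, peak = w$peak,
                        tail_first = min(w$tail_idx),
                        tail_last = max(w$tail_idx)), win_path)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(case$config, cfg_path)
  rbind(manifest,
        data.frame(name = c("reference_curve", "window", "config"),
                   path = c(ref_path, win_path, cfg_path),
                   stringsAsFactors = FALSE))
}

#' Run a cohort of synthetic phantoms end to end
#'
#' Simulates each phantom, runs the per-case pipeline, and collects the
#' per-patient summary records. Failures in individual cases are caught and
#' reported, not fatal.
#'
#' @param specs List of \code{\link{phantom_spec}} objects, e.g. from
#'   \code{\link{cohort_phantom_specs}}.
#' @param model Passed to \code{\link{run_case}}.
#' @param config A \code{\link{dsc_config}}.
#' @return Data frame of per-patient records (one row per successful case)
#'   with attribute \code{failures} (named character vector of error
#'   messages, empty when all cases ran).
#' @export
run_phantom_cohort <- function(specs, model = "all",
                               config = dsc_config()) {
  stopifnot(length(specs) >= 1)
  failures <- character(0)
  rows <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    pid <- attr(sp, "patient_id") %||% sprintf("case_%03d", i)
    res <- tryCatch({
      sim <- simulate_cohort(sp)
      case <- run_case(sim$series, sim$vois, model = model, config = config)
      case_summary(case, patient_id = pid,
                   group = attr(sp, "group") %||% NA_character_,
                   grade = attr(sp, "grade") %||% NA_integer_)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[pid] <- conditionMessage(res)
    else rows[[pid]] <- res
  }
  if (!length(rows)) stop("all cohort cases failed; first error: ",
                          failures[1])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Run a file-based cohort from a manifest
#'
#' The manifest has one row per patient with columns \code{patient_id},
#' \code{dsc}, \code{brain}, \code{tumor}, \code{nawm} (NIfTI paths),
#' \code{tr_seconds}, \code{te_seconds}, \code{group} and optionally
#' \code{grade}. Each case is loaded, processed, and summarized; per-case
#' failures are reported in the \code{failures} attribute.
#'
#' @param manifest Data frame or path to a TSV manifest.
#' @param model,config Passed to \code{\link{run_case}}.
#' @param out_dir Optional directory; when given, each case's maps are
#'   written under \code{out_dir/<patient_id>}.
#' @return Data frame of per-patient records, as
#'   \code{\link{run_phantom_cohort}}.
#' @export
run_cohort <- function(manifest, model = "all", config = dsc_config(),
                       out_dir = NULL) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(nrow(manifest) >= 1,
            all(c("patient_id", "dsc", "brain", "tumor", "nawm",
                  "tr_seconds", "te_seconds", "group") %in%
                  names(manifest)))
  failures <- character(0)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    res <- tryCatch({
      cs <- load_case(r$dsc, r$brain, r$tumor, r$nawm,
                      r$tr_seconds, r$te_seconds)
      case <- run_case(cs$series, cs$vois, model = model, config = config)
      if (!is.null(out_dir))
        write_case(case, file.path(out_dir, r$patient_id))
      case_summary(case, patient_id = r$patient_id, group = r$group,
                   grade = if ("grade" %in% names(r) &&
                               is.finite(suppressWarnings(
                                 as.integer(r$grade))))
                     as.integer(r$grade) else NA_integer_)
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[r$patient_id] <- conditionMessage(res)
    else rows[[r$patient_id]] <- res
  }
  if (!length(rows)) stop("all cohort cases failed; first error: ",
                          failures[1])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Cohort statistics on per-patient records
#'
#' Convenience wrapper producing the group summary table, the paired
#' Wilcoxon/Holm comparisons per group, and (when grades are present) the
#' Spearman grade correlation.
#'
#' @param records Per-patient records from \code{\link{run_phantom_cohort}}
#'   or \code{\link{run_cohort}}.
#' @param alpha Significance level.
#' @return List with \code{table}, \code{tests} (named by group), and
#'   \code{grade_correlation} (or \code{NULL}).
#' @export
cohort_stats <- function(records, alpha = 0.05) {
  tests <- lapply(split(records, records$group), function(rec)
    if (nrow(rec) >= 6) paired_group_tests(rec, alpha) else NULL)
  gc <- if (sum(is.finite(records$grade)) >= 5 &&
            length(unique(records$grade[is.finite(records$grade)])) >= 2)
    grade_correlation(records) else NULL
  list(table = cohort_table(records, alpha), tests = tests,
       grade_correlation = gc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
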