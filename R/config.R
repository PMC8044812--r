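#' Pipeline configuration with study-faithful defaults
#'
#' Collects every tunable threshold of the pipeline in one auditable object.
#' Defaults follow the standard published procedure: discard the first two
#' dynamics, exclude voxels whose bolus signal drop is below 5 baseline
#' standard deviations, select nonenhancing voxels whose tail (final 10
#' timepoints) returns to within 1 baseline SD of the pre-bolus level,
#' and test at alpha = 0.05.
#'
#' @param discard_volumes Leading dynamics dropped before analysis (signal
#'   not yet at steady state).
#' @param drop_sd_threshold Minimum bolus signal drop, in baseline SDs, for a
#'   voxel to be analysed.
#' @param tail_length Number of final timepoints forming the tail.
#' @param tail_sd_threshold Tail-vs-baseline tolerance in baseline SDs for
#'   nonenhancing-voxel selection.
#' @param baseline_init_points Points seeding the iterative baseline search
#'   on the whole-brain curve.
#' @param baseline_detect_sd Bolus-arrival detection threshold in baseline
#'   SDs on the whole-brain curve.
#' @param bolus_exit_fraction Fraction of (peak - baseline) below which the
#'   first pass is considered finished.
#' @param kep_lower,kep_upper,kep_points Search grid for the back-transfer
#'   rate Kep (s^-1); the grid always includes 0.
#' @param clamp_epsilon Non-positive signal samples are clamped to this
#'   fraction of the voxel baseline before the log transform.
#' @param clamp_max_fraction Voxels with more than this fraction of clamped
#'   in-window samples are excluded.
#' @param sd_zero_epsilon Absolute epsilon replacing a zero baseline SD so
#'   the QC rules stay meaningful on noiseless data.
#' @param exp_clip Exponent clip for the exponential kernel.
#' @param min_nawm_voxels Minimum NAWM mask size.
#' @param min_reference_voxels Floor on the number of voxels averaged into
#'   the whole-brain reference curve.
#' @param alpha Significance level for cohort tests.
#' @param seed Seed for any stochastic step (\code{NULL} = leave RNG alone).
#' @return A list of class \code{dsc_config}.
#' @export
dsc_config <- function(discard_volumes = 2L,
                       drop_sd_threshold = 5,
                       tail_length = 10L,
                       tail_sd_threshold = 1,
                       baseline_init_points = 8L,
                       baseline_detect_sd = 2,
                       bolus_exit_fraction = 0.2,
                       kep_lower = -0.2,
                       kep_upper = 1.0,
                       kep_points = 41L,
                       clamp_epsilon = 1e-6,
                       clamp_max_fraction = 0.10,
                       sd_zero_epsilon = 1e-9,
                       exp_clip = 50,
                       min_nawm_voxels = 10L,
                       min_reference_voxels = 100L,
                       alpha = 0.05,
                       seed = NULL) {
  cfg <- list(discard_volumes = as.integer(discard_volumes),
              drop_sd_threshold = drop_sd_threshold,
              tail_length = as.integer(tail_length),
              tail_sd_threshold = tail_sd_threshold,
              baseline_init_points = as.integer(baseline_init_points),
              baseline_detect_sd = baseline_detect_sd,
              bolus_exit_fraction = bolus_exit_fraction,
              kep_lower = kep_lower,
              kep_upper = kep_upper,
              kep_points = as.integer(kep_points),
              clamp_epsilon = clamp_epsilon,
              clamp_max_fraction = clamp_max_fraction,
              sd_zero_epsilon = sd_zero_epsilon,
              exp_clip = exp_clip,
              min_nawm_voxels = as.integer(min_nawm_voxels),
              min_reference_voxels = as.integer(min_reference_voxels),
              alpha = alpha,
              seed = seed)
  stopifnot(cfg$discard_volumes >= 0, cfg$drop_sd_threshold > 0,
            cfg$tail_length >= 1, cfg$tail_sd_threshold > 0,
            cfg$baseline_init_points >= 4, cfg$baseline_detect_sd > 0,
            cfg$bolus_exit_fraction > 0, cfg$bolus_exit_fraction < 1,
            cfg$kep_lower < 0, cfg$kep_upper > 0, cfg$kep_points >= 3,
            cfg$clamp_epsilon > 0, cfg$clamp_max_fraction > 0,
            cfg$sd_zero_epsilon > 0, cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "dsc_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization round-trips: \code{read_config(write_config(cfg, f))} equals
#' \code{cfg}.
#'
#' @param config A \code{\link{dsc_config}} object.
#' @param path File path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns a \code{dsc_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dsc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(dsc_config, vals[!vapply(vals, is.null, logical(1))])
}
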