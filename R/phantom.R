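#' Specification of a synthetic DSC phantom
#'
#' Defines the ground truth of a seedable digital phantom: grid and timing,
#' a gamma-variate whole-brain reference bolus, per-voxel leakage parameters
#' (K1, K2, Kep), a label geometry (background / normal brain / NAWM /
#' tumor), and an additive Gaussian noise level in signal space. Voxel
#' signals are generated by pushing the reference curve through the forward
#' leakage model and inverting the log relaxivity transform, so the phantom
#' has exactly the statistical structure the analysis assumes.
#'
#' By default the tumor block carries K1 = 2.5, K2 = -0.03 s^-1 (T2*-dominant
#' leakage, elevated curve tail) and Kep = 0.02 s^-1; normal brain and NAWM
#' carry K1 = 1 and no leakage. The default grid is 16 x 16 x 4 voxels with
#' 100 dynamics at TR = 1.1 s and TE = 30 ms, and the noise SD equals
#' s0_mean / 50 (baseline SNR 50).
#'
#' @param grid_shape Integer vector of 3 positive extents (voxels).
#' @param n_timepoints Number of dynamics (>= 20).
#' @param tr_seconds,te_seconds Repetition and echo time in seconds.
#' @param s0_mean Baseline signal level (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param gamma_params List with \code{arrival_index} (pre-arrival samples,
#'   >= 5), \code{shape}, \code{scale_seconds}, \code{peak_amplitude}
#'   (s^-1), \code{recirculation_fraction} (in [0, 1]),
#'   \code{steady_state_level} (s^-1).
#' @param tumor_k1,tumor_k2,tumor_kep Scalars filled into the tumor block of
#'   the truth maps when explicit maps are not given.
#' @param truth_k1,truth_k2,truth_kep Optional explicit per-voxel truth
#'   arrays (grid-shaped).
#' @param mask_layout Optional integer label array (0 background, 1 normal
#'   brain, 2 NAWM, 3 tumor); a default block layout is built otherwise.
#' @param seed Integer seed making the phantom fully reproducible.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 4L),
                         n_timepoints = 100L,
                         tr_seconds = 1.1,
                         te_seconds = 0.030,
                         s0_mean = 600,
                         noise_sd = s0_mean / 50,
                         gamma_params = list(),
                         tumor_k1 = 2.5,
                         tumor_k2 = -0.03,
                         tumor_kep = 0.02,
                         truth_k1 = NULL, truth_k2 = NULL, truth_kep = NULL,
                         mask_layout = NULL,
                         seed = 42L) {
  gp <- utils::modifyList(list(arrival_index = 15L, shape = 3,
                               scale_seconds = 1.5, peak_amplitude = 8,
                               recirculation_fraction = 0.25,
                               steady_state_level = 0.2),
                          gamma_params)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            n_timepoints >= 20, tr_seconds > 0, te_seconds > 0,
            s0_mean > 0, noise_sd >= 0,
            gp$arrival_index >= 5,
            gp$recirculation_fraction >= 0, gp$recirculation_fraction <= 1,
            gp$steady_state_level >= 0, gp$peak_amplitude >= 0)
  if (gp$shape <= 0 || gp$scale_seconds <= 0)
    stop("gamma-variate shape and scale must be positive")
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask_layout)) mask_layout <- .default_layout(grid_shape)
  stopifnot(all(dim(mask_layout) == grid_shape),
            all(mask_layout %in% 0:3))
  if (sum(mask_layout == 2L) < 1L || sum(mask_layout == 3L) < 1L)
    stop("mask layout must contain NAWM (2) and tumor (3) voxels")
  fill <- function(map, tumor_value, brain_value) {
    if (!is.null(map)) { stopifnot(all(dim(map) == grid_shape)); return(map) }
    m <- array(0, grid_shape)
    m[mask_layout %in% c(1L, 2L)] <- brain_value
    m[mask_layout == 3L] <- tumor_value
    m
  }
  k1 <- fill(truth_k1, tumor_k1, brain_value = 1)
  k2 <- fill(truth_k2, tumor_k2, brain_value = 0)
  kep <- fill(truth_kep, tumor_kep, brain_value = 0)
  normalish <- mask_layout %in% c(1L, 2L)
  if (any(k2[normalish] != 0) || any(kep[normalish] != 0))
    stop("truth K2 and Kep must be 0 for normal brain and NAWM voxels")
  structure(list(grid_shape = grid_shape,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, te_seconds = te_seconds,
                 s0_mean = s0_mean, noise_sd = noise_sd,
                 gamma_params = gp,
                 truth_k1 = k1, truth_k2 = k2, truth_kep = kep,
                 mask_layout = mask_layout, seed = as.integer(seed)),
            class = "phantom_spec")
}

# block layout: 1-voxel background shell in x/y, tumor and NAWM blocks in
# opposite quadrants, every slice
.default_layout <- function(g) {
  if (any(g[1:2] < 8))
    stop("the default mask layout needs at least 8 voxels in x and y; ",
         "supply mask_layout explicitly for smaller grids")
  lay <- array(0L, g)
  lay[2:(g[1] - 1L), 2:(g[2] - 1L), ] <- 1L
  tx <- max(2L, floor(g[1] * 0.2)):floor(g[1] * 0.45)
  ty <- max(2L, floor(g[2] * 0.2)):floor(g[2] * 0.45)
  nx <- ceiling(g[1] * 0.6):min(g[1] - 1L, ceiling(g[1] * 0.85))
  ny <- ceiling(g[2] * 0.6):min(g[2] - 1L, ceiling(g[2] * 0.85))
  lay[tx, ty, ] <- 3L
  lay[nx, ny, ] <- 2L
  lay
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("DSC phantom:", paste(x$grid_shape, collapse = " x "), "voxels,",
      x$n_timepoints, "dynamics, TR =", x$tr_seconds, "s, TE =",
      x$te_seconds * 1000, "ms\n")
  cat("  labels: background", sum(x$mask_layout == 0L),
      "| brain", sum(x$mask_layout == 1L),
      "| NAWM", sum(x$mask_layout == 2L),
      "| tumor", sum(x$mask_layout == 3L), "\n")
  cat("  s0 =", x$s0_mean, ", noise SD =", x$noise_sd,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Noiseless gamma-variate reference relaxivity curve of a phantom
#'
#' Builds the whole-brain reference curve the phantom is driven by: a
#' peak-normalized gamma-variate first pass
#' \eqn{A\,((t-t_0)/(s\sigma))^s \exp(s - (t-t_0)/\sigma)} (zero before
#' arrival, analytic peak A at \eqn{t_0 + s\sigma}), plus a dispersed,
#' delayed, scaled recirculation bump of the same family, plus a smooth
#' post-bolus steady-state term emulating the elevated intravascular
#' contrast concentration after first passage. A zero peak amplitude means
#' no bolus was given, so the whole curve is zero.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A \code{reference_curve} (values in s^-1, time step TR).
#' @export
make_reference_curve <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gp <- spec$gamma_params
  t_s <- (seq_len(spec$n_timepoints) - 1) * spec$tr_seconds
  t_arr <- gp$arrival_index * spec$tr_seconds
  vals <- if (gp$peak_amplitude == 0) rep(0, spec$n_timepoints) else {
    tp <- gp$shape * gp$scale_seconds      # time to peak after arrival
    first <- .gamma_variate(t_s, t_arr, gp$shape, gp$scale_seconds,
                            gp$peak_amplitude)
    recirc <- .gamma_variate(t_s, t_arr + 1.5 * tp, gp$shape,
                             2 * gp$scale_seconds,
                             gp$recirculation_fraction * gp$peak_amplitude)
    steady <- ifelse(t_s > t_arr,
                     gp$steady_state_level * (1 - exp(-(t_s - t_arr) / tp)),
                     0)
    first + recirc + steady
  }
  structure(list(values = vals, time_step = spec$tr_seconds,
                 n_voxels_averaged = NA_integer_),
            class = "reference_curve")
}

.gamma_variate <- function(t_s, t0, shape, scale, amp) {
  out <- numeric(length(t_s))
  up <- t_s > t0
  x <- (t_s[up] - t0) / (shape * scale)
  out[up] <- amp * x^shape * exp(shape - (t_s[up] - t0) / scale)
  out
}

#' Forward-simulate one voxel's DSC signal
#'
#' Pushes the reference curve through the leakage forward model
#' \eqn{\Delta R_2^*(t) = k_1\,\overline{\Delta R_2^*}(t) - k_2 \int_0^t
#' \overline{\Delta R_2^*}(t')\,e^{-k_{ep}(t-t')}\,dt'} (with \eqn{k_{ep}=0}
#' giving the unidirectional model), inverts the relaxivity transform,
#' \eqn{S(t) = s_0\,e^{-T_E\,\Delta R_2^*(t)}}, and adds Gaussian noise in
#' signal space. The integral term uses the identical causal trapezoidal
#' discretization as the fitting routines, so noiseless recovery is exact.
#' Uses R's global random number generator; seed with \code{set.seed}.
#'
#' @param ref A \code{reference_curve}.
#' @param k1,k2,kep Leakage parameters of the voxel (k2, kep in s^-1).
#' @param s0 Baseline signal (> 0).
#' @param noise_sd Gaussian noise SD in signal units (0 = noiseless).
#' @param te Echo time in seconds.
#' @return Numeric signal trace with attribute \code{relaxivity} holding the
#'   noiseless model relaxivity curve.
#' @export
simulate_voxel_signal <- function(ref, k1, k2, kep, s0, noise_sd, te) {
  stopifnot(inherits(ref, "reference_curve"), te > 0, s0 > 0, noise_sd >= 0)
  kern <- exp_weighted_integral(ref$values, ref$time_step, kep)
  dr2 <- k1 * ref$values - k2 * kern
  sig <- s0 * exp(-te * dr2)
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  attr(sig, "relaxivity") <- dr2
  sig
}

#' Generate a complete synthetic DSC case
#'
#' Simulates every voxel of the phantom from its ground-truth maps, assembles
#' the 4D signal, the binary brain / tumor / NAWM masks, a per-voxel truth
#' table and per-region truth rCBV (the bolus-window integral of the
#' noiseless K1-scaled reference curve, normalized to NAWM). Fully
#' reproducible from \code{spec$seed}. Background voxels hold a low
#' contrast-free signal. When \code{out_dir} is given, the signal and masks
#' are written as NIfTI, the truth tables as TSV, and the spec as YAML.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param out_dir Optional output directory.
#' @return List with \code{series} (\code{\link{dsc_series}}), \code{vois}
#'   (\code{\link{voi_set}}), \code{reference} (noiseless
#'   \code{reference_curve}), \code{truth_voxels} (data frame),
#'   \code{truth_regions} (data frame with truth normalized rCBV),
#'   \code{spec}, and \code{files} (written paths, if any).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  ref <- make_reference_curve(spec)
  g <- spec$grid_shape
  nt <- spec$n_timepoints
  nvox <- prod(g)
  lay <- spec$mask_layout

  sig <- matrix(0, nrow = nt, ncol = nvox)
  in_brain <- which(lay > 0L)
  bg <- which(lay == 0L)
  # distinct kernels only where (k2, kep) differ; cache by kep value
  kern_cache <- new.env(parent = emptyenv())
  get_kern <- function(kep) {
    key <- format(kep, digits = 17)
    if (is.null(kern_cache[[key]]))
      kern_cache[[key]] <- exp_weighted_integral(ref$values, ref$time_step,
                                                 kep)
    kern_cache[[key]]
  }
  for (v in in_brain) {
    dr2 <- spec$truth_k1[v] * ref$values -
      spec$truth_k2[v] * get_kern(spec$truth_kep[v])
    sig[, v] <- spec$s0_mean * exp(-spec$te_seconds * dr2)
  }
  sig[, bg] <- spec$s0_mean * 0.05
  if (spec$noise_sd > 0)
    sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sd)

  signal <- aperm(array(sig, dim = c(nt, g)), c(2, 3, 4, 1))
  series <- dsc_series(signal, tr_seconds = spec$tr_seconds,
                       te_seconds = spec$te_seconds)
  vois <- voi_set(brain = array(as.numeric(lay > 0L), g),
                  tumor = array(as.numeric(lay == 3L), g),
                  nawm = array(as.numeric(lay == 2L), g))

  truth_voxels <- data.frame(voxel = seq_len(nvox),
                             label = as.integer(lay),
                             k1 = as.numeric(spec$truth_k1),
                             k2 = as.numeric(spec$truth_k2),
                             kep = as.numeric(spec$truth_kep))

  win <- locate_bolus_window(ref)
  base_int <- integrate_rcbv(ref$values, win, ref$time_step)
  region_names <- c(normal_brain = 1L, nawm = 2L, tumor = 3L)
  raw <- vapply(region_names, function(lab)
    mean(spec$truth_k1[lay == lab]) * base_int, numeric(1))
  truth_regions <- data.frame(region = names(region_names),
                              mean_k1 = vapply(region_names, function(lab)
                                mean(spec$truth_k1[lay == lab]), numeric(1)),
                              rcbv_truth = raw / raw[["nawm"]])

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    RNifti::writeNifti(RNifti::asNifti(signal), p("dsc.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vois$brain), p("brain_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vois$tumor), p("tumor_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vois$nawm), p("nawm_mask.nii.gz"))
    utils::write.table(truth_voxels, p("truth_voxels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_regions, p("truth_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sp <- spec
    sp$truth_k1 <- as.numeric(sp$truth_k1)
    sp$truth_k2 <- as.numeric(sp$truth_k2)
    sp$truth_kep <- as.numeric(sp$truth_kep)
    sp$mask_layout <- as.integer(sp$mask_layout)
    yaml::write_yaml(unclass(sp), p("phantom_spec.yaml"))
    files <- c(dsc = p("dsc.nii.gz"), brain = p("brain_mask.nii.gz"),
               tumor = p("tumor_mask.nii.gz"), nawm = p("nawm_mask.nii.gz"),
               truth_voxels = p("truth_voxels.tsv"),
               truth_regions = p("truth_regions.tsv"),
               spec = p("phantom_spec.yaml"))
  }
  list(series = series, vois = vois, reference = ref,
       truth_voxels = truth_voxels, truth_regions = truth_regions,
       spec = spec, files = files)
}

#' Phantom specifications for a synthetic patient cohort
#'
#' Draws one phantom per patient with tumor leakage parameters sampled
#' around values typical of the two clinical groups: enhancing tumors carry
#' substantial T2*-dominant leakage (K1 ~ lognormal around 2.9,
#' K2 ~ Normal(-0.03, 0.015) s^-1, Kep ~ |Normal(0.02, 0.01)| s^-1), while
#' nonenhancing tumors have near-unity K1 and close-to-zero leakage.
#' Tumor WHO grades are attached so grade-correlation statistics can be
#' exercised: enhancing patients are mostly grade IV, nonenhancing mostly
#' grade II.
#'
#' @param n_patients Number of phantoms.
#' @param group \code{"enhancing"} or \code{"nonenhancing"}.
#' @param seed Integer seed; patient i uses \code{seed + i} as phantom seed.
#' @param base A template \code{\link{phantom_spec}} supplying grid, timing
#'   and noise.
#' @return List of \code{phantom_spec} objects, each with attributes
#'   \code{patient_id}, \code{group} and \code{grade}.
#' @export
cohort_phantom_specs <- function(n_patients,
                                 group = c("enhancing", "nonenhancing"),
                                 seed = 1L,
                                 base = phantom_spec()) {
  group <- match.arg(group)
  set.seed(seed)
  lapply(seq_len(n_patients), function(i) {
    if (group == "enhancing") {
      grade <- sample(c(4L, 4L, 4L, 3L, 2L), 1)
      k2 <- stats::rnorm(1, -0.03, 0.015)
      kep <- abs(stats::rnorm(1, 0.02, 0.01))
    } else {
      grade <- sample(c(2L, 2L, 2L, 3L), 1)
      k2 <- stats::rnorm(1, -0.006, 0.004)
      kep <- abs(stats::rnorm(1, 0.005, 0.005))
    }
    # tumor blood volume rises with grade, as in clinical cohorts
    k1 <- stats::rlnorm(1, log(c(NA, 1.4, 2.3, 3.0)[grade]), 0.30)
    sp <- phantom_spec(grid_shape = base$grid_shape,
                       n_timepoints = base$n_timepoints,
                       tr_seconds = base$tr_seconds,
                       te_seconds = base$te_seconds,
                       s0_mean = base$s0_mean, noise_sd = base$noise_sd,
                       gamma_params = base$gamma_params,
                       tumor_k1 = k1, tumor_k2 = k2, tumor_kep = kep,
                       seed = seed + i)
    attr(sp, "patient_id") <- sprintf("%s_%03d", substr(group, 1, 3), i)
    attr(sp, "group") <- group
    attr(sp, "grade") <- grade
    sp
  })
}
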