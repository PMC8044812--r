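make_series <- function(nt = 120, dims = c(4, 4, 2), value = 100) {
  dsc_series(array(value, c(dims, nt)), tr_seconds = 1.1,
             te_seconds = 0.030)
}

test_that("leading-volume discard drops the right number of dynamics", {
  s <- make_series(120)
  expect_equal(dim(discard_leading_volumes(s, 2)$signal)[4], 118)
  s50 <- make_series(50)
  expect_equal(dim(discard_leading_volumes(s50, 2)$signal)[4], 48)
  expect_identical(discard_leading_volumes(s, 0), s)
  expect_error(discard_leading_volumes(make_series(25), 10), "at least 20")
  s2 <- discard_leading_volumes(discard_leading_volumes(s, 2), 3)
  expect_equal(s2$discarded_leading_volumes, 5L)
})

test_that("baseline estimation is the mean and SD over the baseline range", {
  w <- list(baseline_idx = 1:5)
  b <- estimate_baseline(c(100, 102, 98, 100, 100, 55, 20), w)
  expect_equal(b$s0, 100)
  expect_equal(b$baseline_sd, sd(c(100, 102, 98, 100, 100)))
  bc <- estimate_baseline(rep(7, 10), list(baseline_idx = 1:6))
  expect_equal(bc$s0, 7)
  expect_equal(bc$baseline_sd, 0)
  expect_error(estimate_baseline(1:10, list(baseline_idx = 1:4)),
               "at least 5")
})

test_that("relaxivity transform matches the closed form and sign convention", {
  s0 <- 200; te <- 0.030
  expect_equal(as.numeric(signal_to_relaxivity(rep(s0, 5), s0, te)),
               rep(0, 5))
  out <- signal_to_relaxivity(s0 * exp(-1), s0, te)
  expect_equal(as.numeric(out), 1 / te)
  expect_equal(as.numeric(out), 33.3333, tolerance = 1e-4)
  # signal above baseline: negative relaxivity preserved, not clipped
  over <- signal_to_relaxivity(2 * s0, s0, te)
  expect_equal(as.numeric(over), -log(2) / te)
  expect_error(signal_to_relaxivity(1:5, s0 = 0, te), "unusable")
})

test_that("non-positive samples are clamped and flagged", {
  out <- signal_to_relaxivity(c(100, -5, 0, 100), 100, 0.03,
                              clamp_epsilon = 1e-6)
  expect_equal(attr(out, "clamped"), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(is.finite(out)))
})

test_that("relaxivity is invariant under global signal rescaling", {
  set.seed(5)
  sig <- 100 * exp(-0.03 * abs(rnorm(30)))
  a <- as.numeric(signal_to_relaxivity(sig, 100, 0.03))
  b <- as.numeric(signal_to_relaxivity(7 * sig, 700, 0.03))
  expect_equal(a, b)
})

test_that("relaxivity transform inverts the forward signal model exactly", {
  ref <- test_reference()
  sig <- simulate_voxel_signal(ref, k1 = 1.4, k2 = -0.04, kep = 0.05,
                               s0 = 500, noise_sd = 0, te = 0.030)
  back <- as.numeric(signal_to_relaxivity(as.numeric(sig), 500, 0.030))
  expect_lt(max(abs(back - attr(sig, "relaxivity"))), 1e-9)
})

test_that("5-SD drop rule accepts and rejects on the stated inequality", {
  w <- list(t0 = 3L, t1 = 6L)
  tr1 <- c(100, 100, 95, 89, 95, 100)
  expect_true(qc_sufficient_drop(tr1, s0 = 100, baseline_sd = 2, w))
  tr2 <- c(100, 100, 95, 91, 95, 100)
  expect_false(qc_sufficient_drop(tr2, s0 = 100, baseline_sd = 2, w))
  # zero-SD degenerate case: any drop at all
  expect_true(qc_sufficient_drop(c(100, 100, 99.9, 100, 100, 100),
                                 100, 0, w))
  expect_false(qc_sufficient_drop(rep(100, 6), 100, 0, w))
})

test_that("reference averaging follows the mean and its linearity", {
  dt <- 1.1
  set.seed(6)
  c1 <- rnorm(25)
  one <- build_reference_curve(matrix(c1, ncol = 1), dt)
  expect_equal(one$values, c1)
  expect_equal(one$n_voxels_averaged, 1L)
  two <- build_reference_curve(cbind(c1, -c1), dt)
  expect_equal(two$values, rep(0, 25))
  # weighted-mean property: pooled mean equals voxel-count weighted mean
  m1 <- matrix(rnorm(25 * 3), 25)
  m2 <- matrix(rnorm(25 * 5), 25)
  pooled <- build_reference_curve(cbind(m1, m2), dt)$values
  w <- (3 * build_reference_curve(m1, dt)$values +
          5 * build_reference_curve(m2, dt)$values) / 8
  expect_equal(pooled, w)
  expect_error(build_reference_curve(matrix(c1, ncol = 1), dt,
                                     min_voxels = 2), "floor")
})

test_that("bolus window is found on a noiseless gamma-variate curve", {
  spec <- phantom_spec(gamma_params = list(arrival_index = 20L,
                                           recirculation_fraction = 0,
                                           steady_state_level = 0),
                       noise_sd = 0)
  ref <- make_reference_curve(spec)
  w <- locate_bolus_window(ref)
  # first supra-baseline sample is index arrival+2 (1-based); t0 just before
  expect_gte(w$t0, 20)
  expect_lte(w$t0, 22)
  expect_gt(w$peak, w$t0)
  expect_gt(w$t1, w$peak)
  expect_lt(w$peak, spec$n_timepoints - 10)
  expect_true(all(w$baseline_idx < w$t0))
})

test_that("window around a symmetric pulse is symmetric about the peak", {
  v <- c(rep(0, 30), seq(0.1, 1, by = 0.1), seq(0.9, 0, by = -0.1),
         rep(0, 30))
  w <- locate_bolus_window(v, dsc_config(tail_length = 5))
  peak <- which.max(v)
  expect_equal(w$peak, peak)
  expect_equal(peak - w$t0, w$t1 - peak, tolerance = 1)
})

test_that("a flat curve has no detectable bolus", {
  expect_error(locate_bolus_window(rep(1, 50)), "no detectable")
})

test_that("nonenhancing selection keeps NAWM and rejects leaky tumor", {
  spec <- phantom_spec(noise_sd = 0.5,
                       gamma_params = list(recirculation_fraction = 0,
                                           steady_state_level = 0),
                       tumor_k1 = 2.5, tumor_k2 = -0.05, tumor_kep = 0,
                       seed = 21L)
  sim <- simulate_cohort(spec)
  sig <- sim$series$signal
  w <- locate_bolus_window(sim$reference)
  sel <- select_nonenhancing_voxels(sig, sim$vois$brain, w)
  nawm <- sim$vois$nawm > 0
  tumor <- sim$vois$tumor > 0
  expect_gt(mean(sel[nawm]), 0.9)        # tails return to baseline
  expect_equal(sum(sel & tumor), 0)      # elevated tails rejected
  expect_true(all(sim$vois$brain[sel] > 0))
})

test_that("an all-constant voxel is rejected by the drop criterion", {
  sig <- array(100, c(2, 2, 1, 40))
  # compact-support bolus: the tail returns exactly to baseline
  bump <- c(rep(0, 15), 1, 3, 5, 3, 1.5, 0.5, rep(0, 19))
  sig[1, 1, 1, ] <- 100 * exp(-0.03 * bump)
  brain <- array(1, c(2, 2, 1))
  w <- locate_bolus_window(as.numeric(
    signal_to_relaxivity(apply(sig, 4, mean), 100, 0.03)),
    dsc_config(baseline_init_points = 8, tail_length = 5))
  sel <- select_nonenhancing_voxels(sig, brain, w)
  expect_false(any(sel[2:4]))
})
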