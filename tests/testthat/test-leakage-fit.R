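test_that("self-fit and zero-voxel fits return the trivial coefficients", {
  ref <- test_reference()
  f <- leakage_fit(ref$values, ref, "unidirectional")
  expect_equal(unname(coef(f)), c(1, 0), tolerance = 1e-10)
  f0 <- leakage_fit(rep(0, length(ref$values)), ref, "unidirectional")
  expect_equal(unname(coef(f0)), c(0, 0), tolerance = 1e-12)
  fb <- leakage_fit(ref$values, ref, "bidirectional")
  expect_equal(unname(coef(fb)), c(1, 0, 0), tolerance = 1e-8)
})

test_that("noiseless unidirectional parameters are recovered exactly", {
  ref <- test_reference()
  y <- 1.2 * ref$values - 0.03 * cumulative_integral(ref$values,
                                                     ref$time_step)
  f <- leakage_fit(y, ref, "unidirectional")
  expect_equal(unname(coef(f)), c(1.2, 0.03), tolerance = 1e-8)
  expect_true(f$converged)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-9)
})

test_that("a zero reference yields a flagged, non-converged fit", {
  f <- leakage_fit(rnorm(40), rep(0, 40), "unidirectional", dt = 1)
  expect_false(f$converged)
  expect_true(all(is.na(coef(f))))
})

test_that("least squares matches the normal-equations oracle", {
  ref <- test_reference(n_timepoints = 40)
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    y <- rnorm(1, 1, 0.5) * ref$values +
      rnorm(1, 0, 0.05) * cumulative_integral(ref$values, ref$time_step) +
      rnorm(40, 0, 0.3)
    f <- leakage_fit(y, ref, "unidirectional")
    X <- cbind(ref$values, -cumulative_integral(ref$values, ref$time_step))
    beta <- ols_oracle(y, X)
    rel <- max(abs(unname(coef(f)) - as.numeric(beta))) /
      max(abs(beta), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("noiseless bidirectional parameters are recovered to 1e-4", {
  ref <- test_reference()
  truth <- c(1.0, -0.05, 0.02)
  kern <- exp_weighted_integral(ref$values, ref$time_step, truth[3])
  y <- truth[1] * ref$values - truth[2] * kern
  f <- leakage_fit(y, ref, "bidirectional")
  expect_lt(max(abs(unname(coef(f)) - truth) / abs(truth)), 1e-4)
  # corrected curve cancels the leakage term: equals k1 * reference
  expect_lt(max(abs(correct_curve(f) - truth[1] * ref$values)), 1e-6)
})

test_that("data generated with kep = 0 returns the unidirectional fit", {
  ref <- test_reference()
  y <- 0.9 * ref$values -
    (-0.04) * cumulative_integral(ref$values, ref$time_step)
  fu <- leakage_fit(y, ref, "unidirectional")
  fb <- leakage_fit(y, ref, "bidirectional")
  expect_equal(coef(fb)[["kep"]], 0)
  expect_equal(coef(fb)[["k1"]], coef(fu)[["k1"]], tolerance = 1e-8)
  expect_equal(coef(fb)[["k2"]], coef(fu)[["k2"]], tolerance = 1e-8)
})

test_that("nesting: bidirectional SSres never exceeds unidirectional", {
  ref <- test_reference()
  set.seed(99)
  for (i in 1:50) {
    k <- c(runif(1, 0.5, 3), runif(1, -0.08, 0.04), runif(1, 0, 0.1))
    kern <- exp_weighted_integral(ref$values, ref$time_step, k[3])
    y <- k[1] * ref$values - k[2] * kern + rnorm(80, 0, 0.3)
    fu <- leakage_fit(y, ref, "unidirectional")
    fb <- leakage_fit(y, ref, "bidirectional")
    expect_lte(fb$ss_res, fu$ss_res + 1e-10)
    expect_gte(fb$r_squared, fu$r_squared - 1e-12)
  }
})

test_that("scaling the voxel curve scales k1 and k2, leaving kep fixed", {
  ref <- test_reference()
  kern <- exp_weighted_integral(ref$values, ref$time_step, 0.03)
  set.seed(14)
  y <- 1.1 * ref$values + 0.04 * kern + rnorm(80, 0, 0.2)
  f1 <- leakage_fit(y, ref, "bidirectional")
  f3 <- leakage_fit(3 * y, ref, "bidirectional")
  expect_equal(coef(f3)[["k1"]], 3 * coef(f1)[["k1"]], tolerance = 1e-4)
  expect_equal(coef(f3)[["k2"]], 3 * coef(f1)[["k2"]], tolerance = 1e-4)
  expect_equal(coef(f3)[["kep"]], coef(f1)[["kep"]], tolerance = 1e-6)
})

test_that("bidirectional grid search matches a dense grid-refinement oracle", {
  ref <- test_reference(n_timepoints = 60)
  truth <- c(1.3, -0.04, 0.06)
  kern <- exp_weighted_integral(ref$values, ref$time_step, truth[3])
  set.seed(8)
  y <- truth[1] * ref$values - truth[2] * kern + rnorm(60, 0, 0.05)
  f <- leakage_fit(y, ref, "bidirectional")
  # oracle: dense 1-D grid over kep with exact OLS subproblem at each point
  oracle <- function(kep) {
    X <- cbind(ref$values,
               -exp_weighted_integral(ref$values, ref$time_step, kep))
    b <- ols_oracle(y, X)
    sum((y - X %*% b)^2)
  }
  grid <- seq(-0.2, 1, by = 5e-4)
  ss <- vapply(grid, oracle, numeric(1))
  expect_lt(abs(coef(f)[["kep"]] - grid[which.min(ss)]), 1e-3)
  expect_lte(f$ss_res, min(ss) + 1e-8)
})

test_that("correction sign convention: T2*-dominant leakage lowers rCBV", {
  ref <- test_reference()
  # negative k2 elevates the tail (T2* dominant)
  kern <- exp_weighted_integral(ref$values, ref$time_step, 0.02)
  y <- 1.5 * ref$values - (-0.05) * kern
  f <- leakage_fit(y, ref, "bidirectional")
  expect_lt(coef(f)[["k2"]], 0)
  corr <- correct_curve(f)
  w <- locate_bolus_window(ref)
  expect_lt(integrate_rcbv(corr, w, ref$time_step),
            integrate_rcbv(y, w, ref$time_step))
  # corrected tail matches the reference-shaped component
  expect_lt(max(abs(corr - 1.5 * ref$values)), 1e-6)
  # k2 = 0 leaves the curve untouched
  f0 <- leakage_fit(1.5 * ref$values, ref, "unidirectional")
  expect_equal(correct_curve(f0), 1.5 * ref$values, tolerance = 1e-9)
})

test_that("fit object methods are coherent", {
  ref <- test_reference()
  set.seed(33)
  y <- 1.2 * ref$values + rnorm(80, 0, 0.3)
  f <- leakage_fit(y, ref, "bidirectional")
  expect_s3_class(f, "dsc_leakfit")
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newref = ref$values), fitted(f), tolerance = 1e-10)
  expect_equal(f$k, 3L)
  expect_output(print(f), "bidirectional")
  s <- summary(f)
  expect_equal(s$adj_r_squared, f$adj_r_squared)
  expect_lte(s$adj_r_squared, s$r_squared)
})
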