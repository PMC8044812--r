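# Shared fixtures: phantoms are always built in code, never stored.

# Noiseless phantom whose tails return exactly to baseline (no recirculation,
# no steady-state term), so the tail-vs-baseline selection criterion holds
# exactly under the zero-SD epsilon rule.
noiseless_spec <- function(tumor_k1 = 2, tumor_k2 = 0, tumor_kep = 0,
                           seed = 7L, ...) {
  phantom_spec(noise_sd = 0,
               gamma_params = list(recirculation_fraction = 0,
                                   steady_state_level = 0),
               tumor_k1 = tumor_k1, tumor_k2 = tumor_k2,
               tumor_kep = tumor_kep, seed = seed, ...)
}

# Small default reference curve for fitting tests.
test_reference <- function(n_timepoints = 80, dt = 1.1) {
  spec <- phantom_spec(n_timepoints = n_timepoints, tr_seconds = dt,
                       gamma_params = list(recirculation_fraction = 0,
                                           steady_state_level = 0))
  make_reference_curve(spec)
}

# Independent brute-force least squares via explicit normal equations,
# kept deliberately separate from the package's QR-based solver.
ols_oracle <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences.
wilcoxon_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}
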