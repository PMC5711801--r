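# Shared fixtures, memoised so expensive fits run once per test session.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) assign(key, fn(), envir = .fixtures)
  .fixtures[[key]]
}

zero_betas <- function() stats::setNames(rep(0, 16), bp_effects())

# Outcome-level data simulated under the default (reference) effect sizes.
ref_outcomes <- function() {
  memo_fixture("ref_outcomes",
               function() simulate_cycle_outcomes(sim_config(seed = 404)))
}

ref_fit <- function() {
  memo_fixture("ref_fit",
               function() fit_model(ref_outcomes(), "scaled", seed = 11))
}

null_fit <- function() {
  memo_fixture("null_fit", function() {
    cfg <- sim_config(true_betas = zero_betas(), seed = 505)
    fit_model(simulate_cycle_outcomes(cfg), "scaled", seed = 12)
  })
}

# Light MCMC settings for auxiliary fits inside tests.
light_mcmc <- list(chains = 4L, burn_in = 400L, thin = 1L, keep = 1000L)

# n synthetic cycle windows (one full oscillation period each) with known
# relative phase, for phase-estimator validation.
make_cycle_pairs <- function(n, noise_sd = 0.5, fs = 100, amp = 10) {
  lapply(seq_len(n), function(i) {
    f <- stats::runif(1, 1.4, 3.4)
    delta <- stats::runif(1, -90, 270)
    t <- seq(0, 1 / f, by = 1 / fs)
    right <- amp * sin(2 * pi * f * t) + stats::rnorm(length(t), 0, noise_sd)
    left <- amp * sin(2 * pi * f * t + delta * pi / 180) +
      stats::rnorm(length(t), 0, noise_sd)
    list(t = t, left = left, right = right, f = f, delta = delta)
  })
}

# Sine-fit relative phase of one cycle pair (full-period window).
fit_pair_phase <- function(p) {
  f0 <- 1 / (max(p$t) - min(p$t))
  fl <- fit_sine(p$t, p$left, f0 = f0)
  fr <- fit_sine(p$t, p$right, f0 = f0)
  relative_phase(fl, fr)
}
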