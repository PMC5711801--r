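test_that("preprocessing demeans, rejects and excludes as specified", {
  const <- rep(5, 200)
  pp <- preprocess(const, fs = 100)
  expect_true(all(abs(pp$x) < 1e-9))
  expect_false(pp$excluded)
  expect_error(preprocess(rep(NA_real_, 50)), "all samples missing")
  x <- sin(2 * pi * 2 * (0:499) / 100)
  x[1:150] <- NA  # 30% missing
  expect_true(preprocess(x, fs = 100)$excluded)
})

test_that("zero-phase Butterworth attenuation matches the analytic response", {
  fs <- 100; f <- 2; fc <- 7.5
  t <- (0:5999) / fs
  x <- sin(2 * pi * f * t)
  pp <- preprocess(x, fs = fs, cutoff_hz = fc)
  interior <- 500:5500
  gain <- max(abs(pp$x[interior]))
  # first-order Butterworth applied forward and backward: |H|^2 = 1/(1+(f/fc)^2)
  expect_equal(gain, 1 / (1 + (f / fc)^2), tolerance = 1e-3)
})

test_that("gap interpolation stays close to the gapless signal", {
  fs <- 100
  t <- (0:999) / fs
  x <- 10 * sin(2 * pi * 2 * t)
  gapless <- preprocess(x, fs = fs)$x
  xg <- x
  xg[500:504] <- NA  # 50 ms gap
  gapped <- preprocess(xg, fs = fs)$x
  expect_lt(max(abs(gapped - gapless)), 0.05 * 10)
})

test_that("cycle segmentation emits one max-to-min interval per period", {
  fs <- 100; f <- 2; T <- 10
  x <- 10 * sin(2 * pi * f * (0:(fs * T - 1)) / fs)
  cyc <- segment_cycles(x, fs)
  expect_true(abs(nrow(cyc) - f * T) <= 1)
  expect_true(all(cyc$end > cyc$start))
  expect_true(all(diff(cyc$start) > 0))
  expect_true(all(cyc$start[-1] >= cyc$end[-nrow(cyc)]))
  expect_equal(nrow(segment_cycles(rep(0, 1000), fs)), 0)
})

test_that("cycles are assigned the generating metronome plateau", {
  cfg <- sim_config(noise_mm = 0, dropout_rate = 0, pause_rate = 0, seed = 5)
  cond <- list(instruction = "parallel", mirror = "mirrored",
               posture_raw = "both-up")
  tr <- simulate_trial(cfg, cond, 0, seed = 11)
  pp <- preprocess(tr$right$x, tr$right$missing)
  cyc <- segment_cycles(pp$x, 100, tr$schedule)
  lead_s <- cfg$lead_ms / 1000
  truth_level <- tr$truth$speed_level[
    findInterval(cyc$t_mid + lead_s, tr$schedule$t_start)]
  expect_identical(cyc$speed_level, truth_level)
})

test_that("sine fitting recovers exact and noisy windows", {
  fs <- 100
  t <- seq(0, 0.25, by = 1 / fs)  # half period of 2 Hz
  truth_phase_mid <- function(f, phi0, t) {
    # model phase is referenced to the window midpoint
    ph <- (360 * f * mean(range(t)) + phi0)
    ((ph + 180) %% 360) - 180
  }
  x <- 10 * sin(2 * pi * 2 * t + 30 * pi / 180)
  f1 <- fit_sine(t, x)
  expect_equal(f1$amplitude, 10, tolerance = 1e-6)
  expect_equal(f1$frequency, 2, tolerance = 1e-6)
  expect_equal(f1$phase, truth_phase_mid(2, 30, t), tolerance = 1e-6)
  expect_lt(f1$residual_rms, 1e-5)
  expect_error(fit_sine(t[1:3], x[1:3]), "at least 4 samples")

  # Monte-Carlo phase-noise envelope at 0.5 mm noise: a half-period window
  # carries about 2 degrees of median phase noise (the offset term is nearly
  # collinear with the sine over half a period); a full-period window
  # resolves the phase within 2 degrees almost surely.
  set.seed(42)
  errs <- replicate(200, {
    xn <- x + stats::rnorm(length(t), 0, 0.5)
    fn <- fit_sine(t, xn)
    d <- abs(fn$phase - truth_phase_mid(2, 30, t))
    min(d, 360 - d)
  })
  expect_lt(stats::median(errs), 3)
  expect_gte(mean(errs <= 7), 0.95)

  tfull <- seq(0, 0.5, by = 1 / 100)
  xfull <- 10 * sin(2 * pi * 2 * tfull + 30 * pi / 180)
  errs_full <- replicate(200, {
    xn <- xfull + stats::rnorm(length(tfull), 0, 0.5)
    fn <- fit_sine(tfull, xn, f0 = 2)
    d <- abs(fn$phase - truth_phase_mid(2, 30, tfull))
    min(d, 360 - d)
  })
  expect_gte(mean(errs_full <= 2), 0.95)
})

test_that("half-period and full-period fits agree on phase", {
  fs <- 100
  tf <- seq(0, 0.5, by = 1 / fs)       # full period of 2 Hz
  x <- 10 * sin(2 * pi * 2 * tf + 1.1)
  full <- fit_sine(tf, x, f0 = 2)
  half_idx <- which(tf <= 0.25)
  half <- fit_sine(tf[half_idx], x[half_idx])
  # compare instantaneous phase at the half window's midpoint
  tmid_h <- mean(range(tf[half_idx]))
  full_at_h <- full$phase + 360 * full$frequency * (tmid_h - mean(range(tf)))
  d <- abs(((full_at_h - half$phase + 180) %% 360) - 180)
  expect_lt(d, 1)
})

test_that("relative phase wraps into [-90, 270) as specified", {
  f <- list(phase = 30, converged = TRUE)
  expect_equal(relative_phase(f, f), 0)
  g <- list(phase = -150, converged = TRUE)  # half a period apart
  expect_equal(relative_phase(f, g), 180)
  expect_equal(relative_phase(170, -175), -15)  # wrap(345) = -15
  bad <- list(phase = 0, converged = FALSE)
  expect_true(is.na(relative_phase(f, bad)))
  # antisymmetry modulo 360
  set.seed(9)
  a <- stats::runif(200, -180, 180); b <- stats::runif(200, -180, 180)
  s <- (relative_phase(a, b) + relative_phase(b, a)) %% 360
  expect_true(all(pmin(s, 360 - s) < 1e-9))
})

test_that("relative phase is invariant to offset and amplitude rescaling", {
  cfg <- sim_config(dropout_rate = 0, seed = 5)
  cond <- list(instruction = "symmetrical", mirror = "non-mirrored",
               posture_raw = "both-down")
  tr <- simulate_trial(cfg, cond, 0, seed = 13)
  base <- analyze_trial(tr$left, tr$right, tr$schedule)
  shifted <- tr
  shifted$left$x <- 3 * tr$left$x + 40
  shifted$right$x <- 3 * tr$right$x + 40
  mod <- analyze_trial(shifted$left, shifted$right, tr$schedule)
  expect_equal(mod$rel_phase, base$rel_phase, tolerance = 1e-6)
})

test_that("noise-free generator phases are recovered within a degree", {
  cfg <- sim_config(noise_mm = 0, dropout_rate = 0, pause_rate = 0, seed = 5)
  cond <- list(instruction = "symmetrical", mirror = "non-mirrored",
               posture_raw = "both-down")
  tr <- simulate_trial(cfg, cond, 0, seed = 11)
  an <- analyze_trial(tr$left, tr$right, tr$schedule)
  bi <- findInterval(an$t_mid + cfg$lead_ms / 1000, tr$schedule$t_start)
  d <- abs(an$rel_phase - tr$truth$rel_phase[bi])
  expect_true(all(pmin(d, 360 - d) < 1))
})

test_that("continuous phase difference agrees with the sine-fit estimate", {
  fs <- 100
  t <- (0:999) / fs
  l <- sin(2 * pi * 2 * t + pi)
  r <- sin(2 * pi * 2 * t)
  expect_equal(stats::median(continuous_phase_diff(l, r)), 180, tolerance = 1)
  expect_equal(stats::median(abs(continuous_phase_diff(r, r))), 0,
               tolerance = 1)
  b <- zero_betas(); b["intercept"] <- 20  # clean trial: all cycles correct
  cfg <- sim_config(noise_mm = 0.2, dropout_rate = 0, pause_rate = 0,
                    kappa_correct = 50, true_betas = b, seed = 5)
  cond <- list(instruction = "parallel", mirror = "non-mirrored",
               posture_raw = "both-down")
  tr <- simulate_trial(cfg, cond, 0, seed = 17)
  pl <- preprocess(tr$left$x, tr$left$missing)
  pr <- preprocess(tr$right$x, tr$right$missing)
  cyc <- segment_cycles(pr$x, 100, tr$schedule)
  an <- analyze_trial(tr$left, tr$right, tr$schedule)
  cont <- continuous_phase_diff(pl$x, pr$x, cyc)
  d <- abs(cont - an$rel_phase)
  expect_gte(mean(pmin(d, 360 - d) < 5), 0.9)
})

test_that("velocity QC singles out the task-relevant dimension", {
  cfg <- sim_config(seed = 5)
  cond <- list(instruction = "symmetrical", mirror = "non-mirrored",
               posture_raw = "both-down")
  tr <- simulate_trial(cfg, cond, 0, seed = 19)
  traj <- rbind(cbind(hand = "left", tr$left), cbind(hand = "right", tr$right))
  qc <- qc_dimension_stats(traj, fs = 100, schedule = tr$schedule)
  for (h in c("left", "right")) {
    vx <- qc$dimensions$velocity_sd[qc$dimensions$hand == h &
                                      qc$dimensions$dimension == "x"]
    vy <- qc$dimensions$velocity_sd[qc$dimensions$hand == h &
                                      qc$dimensions$dimension == "y"]
    expect_gt(vx, vy)
  }
  # a dead secondary channel has zero velocity spread
  traj0 <- traj; traj0$y <- 0
  qc0 <- qc_dimension_stats(traj0, fs = 100)
  expect_true(all(qc0$dimensions$velocity_sd[qc0$dimensions$dimension == "y"] == 0))
  # cycle yield is roughly even across the ten speed plateaus
  counts <- as.integer(qc$cycles_per_speed$n_cycles)
  expect_true(all(counts >= 3 & counts <= 7))
})
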