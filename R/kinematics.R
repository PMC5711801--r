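#' Preprocess one hand's lateral-position trajectory
#'
#' Linearly interpolates missing samples (edges held constant), applies a
#' zero-phase (forward-backward) first-order Butterworth low-pass filter,
#' and removes the mean. Zero-phase filtering is used because a causal
#' one-pass filter would delay the signal by a frequency-dependent phase
#' shift, biasing phase estimates differentially across movement speeds.
#'
#' @param x numeric position vector in mm; `NA` values count as missing.
#' @param missing optional logical vector flagging missing samples (combined
#'   with `is.na(x)`).
#' @param fs sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff in Hz (default 7.5).
#' @param max_missing maximum tolerated missing fraction; above it the trial
#'   is marked excluded (and returned unfiltered).
#' @return List with the preprocessed signal `x`, the `excluded` flag and
#'   `missing_frac`.
#' @export
preprocess <- function(x, missing = NULL, fs = 100, cutoff_hz = 7.5,
                       max_missing = 0.2) {
  miss <- is.na(x)
  if (!is.null(missing)) miss <- miss | as.logical(missing)
  if (all(miss)) stop("all samples missing")
  if (sum(!miss) < 2) stop("fewer than 2 non-missing samples")
  frac <- mean(miss)
  if (frac > max_missing) {
    return(list(x = x, excluded = TRUE, missing_frac = frac))
  }
  idx <- seq_along(x)
  xi <- x
  if (any(miss)) {
    xi[miss] <- stats::approx(idx[!miss], x[!miss], xout = idx[miss],
                              rule = 2)$y
  }
  # centre and odd-reflect pad before the forward-backward pass so the
  # filter's zero initial state causes no edge transients
  mu <- mean(xi)
  xc <- xi - mu
  n <- length(xc)
  np <- min(n - 1L, max(50L, ceiling(3 * fs / cutoff_hz)))
  pre <- 2 * xc[1] - xc[(np + 1):2]
  post <- 2 * xc[n] - xc[(n - 1):(n - np)]
  bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
  xf <- signal::filtfilt(bf, c(pre, xc, post))[(np + 1):(np + n)]
  list(x = xf - mean(xf), excluded = FALSE, missing_frac = frac)
}

# Alternating extrema via zero-crossing bracketing: a maximum between each
# up- and down-crossing of the demeaned signal, a minimum between each down-
# and up-crossing. Alternation holds by construction; low-amplitude wiggle
# pairs are pruned against a prominence threshold.
find_extrema <- function(x, prominence_frac = 0.1) {
  pos <- x >= 0
  n <- length(x)
  bounds <- c(0L, which(pos[-1] != pos[-n]), n)
  ns <- length(bounds) - 1L
  if (ns < 2) return(data.frame(index = integer(), value = numeric(),
                                kind = character()))
  idx <- integer(ns)
  val <- numeric(ns)
  kind <- character(ns)
  for (k in seq_len(ns)) {
    seg <- (bounds[k] + 1L):bounds[k + 1L]
    if (pos[seg[1]]) {
      i <- seg[which.max(x[seg])]; kind[k] <- "max"
    } else {
      i <- seg[which.min(x[seg])]; kind[k] <- "min"
    }
    idx[k] <- i; val[k] <- x[i]
  }
  thr <- prominence_frac * stats::sd(x)
  # prune least-prominent adjacent pairs, preserving alternation
  repeat {
    if (length(idx) < 2) break
    d <- abs(diff(val))
    j <- which.min(d)
    if (d[j] >= thr) break
    keep <- setdiff(seq_along(idx), c(j, j + 1L))
    idx <- idx[keep]; val <- val[keep]; kind <- kind[keep]
  }
  data.frame(index = idx, value = val, kind = kind)
}

#' Segment movement cycles from the right finger's trajectory
#'
#' A movement cycle is the interval between a consecutive maximum and
#' minimum of the (preprocessed) right finger trajectory. Each cycle is
#' assigned the metronome plateau containing its temporal midpoint, and
#' cycles whose peak-to-peak excursion falls below a fraction of the trial's
#' median excursion are dropped as unidentifiably small movements.
#'
#' @param x preprocessed right-hand position vector.
#' @param fs sampling rate in Hz.
#' @param schedule a [metronome_schedule()]; if `NULL`, `speed_level` is `NA`.
#' @param min_excursion_frac smallness threshold as a fraction of the trial
#'   median peak-to-peak excursion (default 0.2).
#' @param prominence_frac extremum prominence threshold as a fraction of the
#'   trial's position s.d. (default 0.1).
#' @return data frame with one row per cycle: `cycle_index`, `start`, `end`
#'   (sample indices), `t_mid` (s), `speed_level`, `ptp` (mm). Empty when
#'   fewer than two extrema exist.
#' @export
segment_cycles <- function(x, fs = 100, schedule = NULL,
                           min_excursion_frac = 0.2, prominence_frac = 0.1) {
  empty <- data.frame(cycle_index = integer(), start = integer(),
                      end = integer(), t_mid = numeric(),
                      speed_level = integer(), ptp = numeric())
  if (length(x) < 4 || stats::sd(x) == 0) return(empty)
  ext <- find_extrema(x, prominence_frac)
  if (nrow(ext) < 2) return(empty)
  starts <- which(ext$kind == "max")
  starts <- starts[starts < nrow(ext)]
  if (!length(starts)) return(empty)
  cyc <- data.frame(start = ext$index[starts], end = ext$index[starts + 1L],
                    ptp = ext$value[starts] - ext$value[starts + 1L])
  cyc$t_mid <- (cyc$start + cyc$end - 2) / (2 * fs)
  cyc <- cyc[cyc$ptp >= min_excursion_frac * stats::median(cyc$ptp), ,
             drop = FALSE]
  if (!nrow(cyc)) return(empty)
  cyc$speed_level <- if (is.null(schedule)) NA_integer_ else
    speed_level_at(cyc$t_mid, schedule)
  cyc$cycle_index <- seq_len(nrow(cyc))
  cyc[, c("cycle_index", "start", "end", "t_mid", "speed_level", "ptp")]
}

#' Fit a sine wave to a trajectory window
#'
#' Least-squares fit of `offset + amplitude * sin(2*pi*frequency*(t - t_mid)
#' + phase)`, where `t_mid` is the window's temporal midpoint. For a fixed
#' frequency the model is linear in offset and the sine/cosine pair, so the
#' fit profiles the frequency: it is initialized from the window's implied
#' half-period and refined by one-dimensional minimization of the residual
#' sum of squares. The result is canonicalized to `amplitude >= 0` and
#' `phase` in (-180, 180] degrees.
#'
#' @param t sample times in seconds (length >= 4).
#' @param x positions in mm.
#' @param f0 optional initial frequency in Hz; default assumes the window
#'   spans half an oscillation period.
#' @return List with `amplitude` (mm), `frequency` (Hz), `phase` (degrees,
#'   at the window midpoint), `offset` (mm), `residual_rms` (mm),
#'   `converged`.
#' @export
fit_sine <- function(t, x, f0 = NULL) {
  if (length(t) < 4) stop("window must contain at least 4 samples")
  tc <- t - (min(t) + max(t)) / 2
  span <- max(t) - min(t)
  if (is.null(f0)) f0 <- 1 / (2 * span)
  coefs_at <- function(f) {
    X <- cbind(1, sin(2 * pi * f * tc), cos(2 * pi * f * tc))
    fit <- stats::.lm.fit(X, x)
    fit
  }
  rss <- function(f) {
    f <- max(f, 1e-6)
    sum(coefs_at(f)$residuals^2)
  }
  # the window length already pins the half-period, so the frequency is
  # refined only within a +/- 20-25% band around its implied value
  opt <- stats::optimize(rss, interval = c(0.8 * f0, 1.25 * f0),
                         tol = f0 * 1e-6)
  f <- opt$minimum
  fit <- coefs_at(f)
  cf <- fit$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- atan2(cf[3], cf[2]) * 180 / pi
  conv <- is.finite(amp) && amp > 1e-9 && all(is.finite(cf))
  list(amplitude = unname(amp), frequency = f,
       phase = unname(wrap180(phase)), offset = unname(cf[1]),
       residual_rms = sqrt(mean(fit$residuals^2)),
       converged = conv)
}

#' Relative phase of the two fingers
#'
#' The phase difference of the two fitted sine curves (left minus right),
#' wrapped into [-90, 270) so that both coordination attractors lie in the
#' interior: 180 degrees is perfect external-space symmetry, 0 perfect
#' parallel movement.
#'
#' @param fit_left,fit_right [fit_sine()] results (or bare phases in
#'   degrees).
#' @return Relative phase in degrees, in [-90, 270); `NA` if either fit did
#'   not converge.
#' @export
relative_phase <- function(fit_left, fit_right) {
  ph <- function(f) {
    if (is.list(f)) {
      if (!isTRUE(f$converged)) return(NA_real_)
      f$phase
    } else as.numeric(f)
  }
  wrap_phase(ph(fit_left) - ph(fit_right))
}

# FFT-based analytic signal (quadrature component via one-sided spectrum).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Continuous (unfitted) per-cycle phase difference
#'
#' Cross-check of the sine-fit relative phase: instantaneous phase
#' difference of the two analytic (quadrature) signals, circularly averaged
#' within each cycle and wrapped as in [relative_phase()].
#'
#' @param left,right preprocessed position vectors.
#' @param cycles cycle table from [segment_cycles()]; if `NULL`, the full
#'   per-sample phase-difference series is returned instead.
#' @return Numeric vector of per-cycle (or per-sample) phase differences in
#'   degrees, in [-90, 270).
#' @export
continuous_phase_diff <- function(left, right, cycles = NULL) {
  dphi <- Arg(analytic_signal(left) * Conj(analytic_signal(right))) * 180 / pi
  if (is.null(cycles)) return(wrap_phase(dphi))
  vapply(seq_len(nrow(cycles)), function(i) {
    w <- cycles$start[i]:cycles$end[i]
    r <- dphi[w] * pi / 180
    wrap_phase(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
  }, numeric(1))
}

#' Carrier cross-correlation phase estimate
#'
#' Independent relative-phase estimator used for validation: each
#' (demeaned, Hann-windowed) signal is cross-correlated with a complex
#' carrier at the known oscillation frequency, and the two carrier phases
#' are differenced. Equivalent to converting the continuous
#' cross-correlation lag at the movement frequency into a phase, but free of
#' the sine fit's offset and frequency-refinement machinery.
#'
#' @param left,right position vectors covering at least one oscillation
#'   period.
#' @param freq oscillation frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return Phase difference (left minus right) in degrees, in [-90, 270).
#' @export
phase_lag_xcorr <- function(left, right, freq, fs = 100) {
  n <- min(length(left), length(right))
  t <- (0:(n - 1)) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  carrier <- exp(-1i * 2 * pi * freq * t)
  zl <- sum(w * (left[1:n] - mean(left[1:n])) * carrier)
  zr <- sum(w * (right[1:n] - mean(right[1:n])) * carrier)
  wrap_phase(Arg(zl * Conj(zr)) * 180 / pi)
}

#' Movement-dimension quality control
#'
#' Finite-difference velocity summaries per movement dimension, checking
#' that the highest velocities (and velocity variability) occur in the
#' task-relevant lateral dimension rather than an irrelevant one, plus the
#' number of cycles found per speed level.
#'
#' @param traj one trial's trajectory table (columns `hand`, `x` and at
#'   least one extra dimension such as `y`).
#' @param fs sampling rate in Hz.
#' @param schedule optional [metronome_schedule()] for per-speed cycle
#'   counts (from the right hand's lateral signal).
#' @return List with `dimensions` (per hand x dimension: `peak_velocity`,
#'   `velocity_sd`, mm/s) and `cycles_per_speed`.
#' @export
qc_dimension_stats <- function(traj, fs = 100, schedule = NULL) {
  dims <- setdiff(names(traj), c("participant", "trial", "t", "hand",
                                 "missing"))
  if (length(dims) < 2) stop("at least one extra dimension is required")
  rows <- list()
  for (h in unique(traj$hand)) {
    sub <- traj[traj$hand == h, ]
    for (d in dims) {
      v <- diff(stats::approx(seq_along(sub[[d]]),
                              sub[[d]], seq_along(sub[[d]]), rule = 2)$y) * fs
      rows[[paste(h, d)]] <- data.frame(hand = h, dimension = d,
                                        peak_velocity = max(abs(v), na.rm = TRUE),
                                        velocity_sd = stats::sd(v, na.rm = TRUE))
    }
  }
  cps <- NULL
  if (!is.null(schedule) && "right" %in% traj$hand) {
    r <- traj[traj$hand == "right", ]
    pp <- preprocess(r$x, r$missing %||% NULL, fs)
    if (!pp$excluded) {
      cyc <- segment_cycles(pp$x, fs, schedule)
      cps <- as.data.frame(table(factor(cyc$speed_level,
                                        levels = unique(schedule$plateau))),
                           stringsAsFactors = FALSE)
      names(cps) <- c("speed_level", "n_cycles")
    }
  }
  list(dimensions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       cycles_per_speed = cps)
}

#' Analyze one trial: trajectories to per-cycle relative phases
#'
#' Preprocesses both hands, segments cycles on the right finger, fits a
#' sine to each finger within every cycle window and computes the relative
#' phase.
#'
#' @param left,right data frames with columns `x` and `missing` (or `NA`s).
#' @param schedule a [metronome_schedule()].
#' @param fs sampling rate in Hz.
#' @return data frame with one row per cycle: segmentation columns plus the
#'   two sine fits (`amp_*`, `freq_*`, `phase_*`, `rms_*`), `rel_phase` and
#'   `valid`; attribute `excluded` flags trials lost to excessive missing
#'   data.
#' @export
analyze_trial <- function(left, right, schedule, fs = 100) {
  pl <- preprocess(left$x, left$missing %||% NULL, fs)
  pr <- preprocess(right$x, right$missing %||% NULL, fs)
  empty <- data.frame()
  if (pl$excluded || pr$excluded) {
    attr(empty, "excluded") <- TRUE
    return(empty)
  }
  cyc <- segment_cycles(pr$x, fs, schedule)
  if (!nrow(cyc)) {
    attr(empty, "excluded") <- FALSE
    return(empty)
  }
  tgrid <- (seq_along(pr$x) - 1) / fs
  fits <- lapply(seq_len(nrow(cyc)), function(i) {
    w <- cyc$start[i]:cyc$end[i]
    fl <- fit_sine(tgrid[w], pl$x[w])
    fr <- fit_sine(tgrid[w], pr$x[w])
    data.frame(amp_left = fl$amplitude, freq_left = fl$frequency,
               phase_left = fl$phase, rms_left = fl$residual_rms,
               amp_right = fr$amplitude, freq_right = fr$frequency,
               phase_right = fr$phase, rms_right = fr$residual_rms,
               rel_phase = relative_phase(fl, fr),
               valid = fl$converged && fr$converged)
  })
  out <- cbind(cyc, data.table::rbindlist(fits))
  attr(out, "excluded") <- FALSE
  out
}

#' Analyze a full experiment's trajectories
#'
#' Runs [analyze_trial()] on every non-excluded trial of a long-format
#' trajectory table.
#'
#' @param trajectories long table (`participant`, `trial`, `t`, `hand`, `x`,
#'   `missing`), e.g. from [simulate_experiment()] or [read_trajectories()].
#' @param metadata trial metadata with `trial` and `excluded` columns.
#' @param schedule a [metronome_schedule()].
#' @param fs sampling rate in Hz.
#' @return Cycle table: one row per cycle with `participant`, `trial` and
#'   the [analyze_trial()] columns.
#' @export
analyze_experiment <- function(trajectories, metadata, schedule, fs = 100) {
  rows <- split(seq_len(nrow(trajectories)),
                list(hand = trajectories$hand, trial = trajectories$trial))
  meta <- metadata[!as.logical(metadata$excluded), , drop = FALSE]
  res <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    tr <- meta$trial[i]
    left <- trajectories[rows[[paste0("left.", tr)]], , drop = FALSE]
    right <- trajectories[rows[[paste0("right.", tr)]], , drop = FALSE]
    cyc <- analyze_trial(left, right, schedule, fs)
    if (nrow(cyc)) {
      res[[i]] <- cbind(participant = meta$participant[i], trial = tr, cyc)
    }
  }
  as.data.frame(data.table::rbindlist(res[!vapply(res, is.null, logical(1))]))
}
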