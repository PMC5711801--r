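#' Default group-level effect sizes for the synthetic generator
#'
#' Logit-scale weights (intercept + 15 sum-to-zero effects, named as in
#' [bp_effects()]) encoding the canonical accuracy pattern of the
#' mirror-feedback finger-oscillation paradigm: high baseline accuracy, a
#' strong symmetry advantage (`instruction` 0.82), a marked cost of speed
#' (`speed` -0.62), a muscle-homology advantage carried by
#' `instruction_posture` (0.48) and its speed modulation, a direction-feedback
#' mirror effect carried by `instruction_mirror` (-0.09) and
#' `instruction_mirror_speed` (-0.04), and null mirror-posture couplings.
#'
#' @return Named numeric vector of length 16.
#' @export
default_true_betas <- function() {
  c(intercept = 2.06,
    instruction = 0.82, mirror = 0.02, posture = 0.12, speed = -0.62,
    instruction_mirror = -0.09, instruction_posture = 0.48,
    instruction_speed = 0.25, mirror_posture = 0.00, mirror_speed = 0.00,
    posture_speed = 0.02,
    instruction_mirror_posture = -0.03, instruction_mirror_speed = -0.04,
    instruction_posture_speed = 0.05, mirror_posture_speed = 0.02,
    instruction_mirror_posture_speed = -0.01)
}

#' Configuration of a synthetic finger-oscillation experiment
#'
#' Defines the study conditions emulated by the generator: 20 participants,
#' 2 sessions, 4 repetitions of each of the 16 block conditions (2 movement
#' instructions x 2 mirror views x 4 raw hand postures), trials of 50
#' metronome beats ramping over 10 speeds from 1.4 to 3.4 Hz (5 beats per
#' speed, about 22 s per trial), lateral positions sampled at 100 Hz.
#'
#' @param n_participants number of participants.
#' @param sessions number of sessions the repetitions are spread over.
#' @param reps_per_condition repetitions of each block condition (total,
#'   across sessions).
#' @param sampling_rate marker sampling rate in Hz.
#' @param speeds strictly increasing metronome plateau frequencies in Hz.
#' @param beats_per_speed beats spent on each plateau.
#' @param amplitude_mm nominal single-finger oscillation amplitude in mm.
#' @param true_betas named logit-scale generating weights, see
#'   [default_true_betas()].
#' @param participant_sd standard deviation (logit scale) of participant
#'   intercept deviations, drawn Normal(0, `participant_sd`).
#' @param kappa_correct von Mises concentration of the relative-phase error
#'   of correct cycles (truncated to the correctness window).
#' @param dropout_rate per-sample probability of a missing marker value.
#' @param lead_ms dominant-hand temporal lead in ms, realised as the right
#'   finger anticipating the metronome schedule.
#' @param noise_mm s.d. of additive Gaussian positional noise in mm.
#' @param pause_rate per-beat probability of an unidentifiably small
#'   movement (participant pause), lost to cycle analysis.
#' @param tolerance_deg half-width in degrees of the correctness window that
#'   correct-cycle phase errors are confined to.
#' @param seed master RNG seed; per-trial sub-streams are derived from it by
#'   counter so that trials are reproducible independently.
#' @return An object of class `bp_config` (a validated list).
#' @export
sim_config <- function(n_participants = 20L, sessions = 2L,
                       reps_per_condition = 4L, sampling_rate = 100,
                       speeds = seq(1.4, 3.4, length.out = 10),
                       beats_per_speed = 5L, amplitude_mm = 25,
                       true_betas = default_true_betas(),
                       participant_sd = 0.5, kappa_correct = 8,
                       dropout_rate = 0.02, lead_ms = 25, noise_mm = 0.5,
                       pause_rate = 0.03, tolerance_deg = 50, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              sessions = as.integer(sessions),
              reps_per_condition = as.integer(reps_per_condition),
              sampling_rate = sampling_rate, speeds = as.numeric(speeds),
              beats_per_speed = as.integer(beats_per_speed),
              amplitude_mm = amplitude_mm, true_betas = true_betas,
              participant_sd = participant_sd, kappa_correct = kappa_correct,
              dropout_rate = dropout_rate, lead_ms = lead_ms,
              noise_mm = noise_mm, pause_rate = pause_rate,
              tolerance_deg = tolerance_deg, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "bp_config")
}

validate_config <- function(cfg) {
  if (any(diff(cfg$speeds) <= 0) || any(cfg$speeds <= 0))
    stop("speeds must be strictly increasing and positive")
  if (cfg$kappa_correct <= 0) stop("kappa_correct must be > 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (cfg$amplitude_mm <= 0) stop("amplitude_mm must be > 0")
  if (cfg$pause_rate < 0 || cfg$pause_rate >= 1)
    stop("pause_rate must be in [0, 1)")
  if (cfg$tolerance_deg <= 0 || cfg$tolerance_deg >= 90)
    stop("tolerance_deg must be in (0, 90)")
  if (length(cfg$true_betas) != 16L ||
      !setequal(names(cfg$true_betas), bp_effects()))
    stop("true_betas must have exactly the 16 entries named as in bp_effects()")
  invisible(cfg)
}

raw_postures <- function() {
  c("both-down", "both-up", "left-up-right-down", "left-down-right-up")
}

#' Metronome schedule of one trial
#'
#' One row per beat, with the plateau (speed level) it belongs to, its
#' frequency and its start/end times. Plateaus are phase-continuous: each
#' beat lasts one oscillation period of its plateau frequency.
#'
#' @param speeds plateau frequencies in Hz.
#' @param beats_per_speed beats per plateau.
#' @return data frame with columns `beat`, `plateau`, `freq_hz`, `t_start`,
#'   `t_end`.
#' @export
metronome_schedule <- function(speeds = seq(1.4, 3.4, length.out = 10),
                               beats_per_speed = 5L) {
  dur <- rep(1 / speeds, each = beats_per_speed)
  t_end <- cumsum(dur)
  data.frame(beat = seq_along(dur),
             plateau = rep(seq_along(speeds), each = beats_per_speed),
             freq_hz = rep(speeds, each = beats_per_speed),
             t_start = c(0, t_end[-length(t_end)]),
             t_end = t_end)
}

#' Speed level (metronome plateau) containing given times
#'
#' @param times numeric vector of times in seconds.
#' @param schedule a [metronome_schedule()].
#' @return Integer plateau indices (clamped to the schedule's range).
#' @export
speed_level_at <- function(times, schedule) {
  starts <- schedule$t_start[!duplicated(schedule$plateau)]
  i <- findInterval(times, starts)
  pmin(pmax(i, 1L), max(schedule$plateau))
}

# Metronome oscillator phase (radians) at given times; phase-continuous
# across plateau boundaries, one full turn per beat.
metronome_phase <- function(times, schedule) {
  i <- pmin(pmax(findInterval(times, schedule$t_start), 1L), nrow(schedule))
  2 * pi * ((i - 1) + (times - schedule$t_start[i]) * schedule$freq_hz[i])
}

#' Relative-phase offset between muscle space and external space
#'
#' Flipping one palm reverses that hand's abduction direction in external
#' (left-right) coordinates, shifting its oscillation phase by 180 degrees.
#' For the hand pair, the relative phase measured in muscle space therefore
#' differs from the external-space relative phase by 180 degrees exactly
#' when the palms are oriented differently, and not at all when they share
#' an orientation (flipping both palms cancels).
#'
#' @param posture_raw one of `"both-down"`, `"both-up"`,
#'   `"left-up-right-down"`, `"left-down-right-up"`.
#' @return 0 or 180 (degrees).
#' @export
muscle_phase_offset <- function(posture_raw) {
  posture_raw <- match.arg(posture_raw, raw_postures(), several.ok = FALSE)
  if (pool_posture(posture_raw) == "different") 180 else 0
}

check_condition <- function(condition) {
  for (f in c("instruction", "mirror", "posture_raw")) {
    if (is.null(condition[[f]])) stop("condition lacks factor: ", f)
  }
  code_level(condition$instruction, "symmetrical", "parallel", "instruction")
  code_level(condition$mirror, "non-mirrored", "mirrored", "mirror")
  if (!all(condition$posture_raw %in% raw_postures()))
    stop("unknown posture_raw level: '", condition$posture_raw[1], "'")
  invisible(condition)
}

#' Generating probability of a correct cycle
#'
#' Inverse-logit of the generating linear predictor: intercept plus the
#' signed sum of the 15 effect weights under the coding contract of
#' [design_codes()], plus a participant offset.
#'
#' @param config a [sim_config()].
#' @param condition list or one-row data frame with `instruction`, `mirror`
#'   and `posture_raw` (or pooled `posture_pooled`).
#' @param speed_level `"slow"` or `"fast"` (pooled speed).
#' @param participant_effect logit-scale participant offset.
#' @return Probability in (0, 1).
#' @export
true_probability <- function(config, condition, speed_level = c("slow", "fast"),
                             participant_effect = 0) {
  speed_level <- match.arg(speed_level)
  posture <- condition$posture_pooled %||% pool_posture(condition$posture_raw)
  x <- design_codes(condition$instruction, condition$mirror, posture,
                    ifelse(speed_level == "fast", "fast", "slow"))
  betas <- config$true_betas[bp_effects()]
  invlogit(drop(x %*% betas) + participant_effect)
}

# Draw per-beat relative-phase errors (degrees): truncated von Mises inside
# the correctness window when correct, uniform on its complement otherwise.
draw_phase_errors <- function(correct, kappa, tol) {
  eps <- numeric(length(correct))
  nc <- sum(correct == 1L)
  if (nc) eps[correct == 1L] <- rvonmises_trunc(nc, kappa, tol)
  nw <- sum(correct == 0L)
  if (nw) {
    mag <- stats::runif(nw, tol, 180)
    eps[correct == 0L] <- mag * sign(stats::runif(nw) - 0.5)
  }
  eps
}

#' Simulate one finger-oscillation trial
#'
#' Both hands' lateral positions are piecewise sinusoids tracking the
#' metronome ramp. Per beat, correctness is drawn first
#' (Bernoulli([true_probability()])) and the cycle's relative-phase error
#' second, so that downstream scoring recovers the generating probabilities
#' exactly. The right (dominant) hand anticipates the metronome by
#' `lead_ms`; the left hand is offset from the right by the instructed
#' external-space target phase (180 degrees symmetrical, 0 parallel) plus
#' the drawn error. Additive Gaussian noise and Bernoulli dropout (missing
#' flags) are applied per sample; pause beats collapse the amplitude to an
#' unidentifiably small movement.
#'
#' @param config a [sim_config()].
#' @param condition list with `instruction`, `mirror`, `posture_raw`.
#' @param participant_effect logit-scale participant offset.
#' @param seed optional integer seed for this trial's sub-stream.
#' @return List with data frames `left` and `right` (columns `t`, `x`, `y`,
#'   `missing`), the per-beat ground truth `truth` (beat, plateau,
#'   `speed_level`, `speed_pooled`, `correct`, `phase_err`, `rel_phase`,
#'   `pause`), and the `schedule`.
#' @export
simulate_trial <- function(config, condition, participant_effect = 0,
                           seed = NULL) {
  check_condition(condition)
  if (!is.null(seed)) set.seed(seed)
  schedule <- metronome_schedule(config$speeds, config$beats_per_speed)
  B <- nrow(schedule)
  fs <- config$sampling_rate
  lead <- config$lead_ms / 1000
  n <- floor(max(schedule$t_end) * fs)
  t <- (0:(n - 1)) / fs

  th <- metronome_phase(t + lead, schedule)
  bi <- pmin(pmax(floor(th / (2 * pi)) + 1L, 1L), B)

  n_slow <- ceiling(max(schedule$plateau) / 2)
  pooled <- ifelse(schedule$plateau <= n_slow, "slow", "fast")
  p_beat <- ifelse(pooled == "fast",
                   true_probability(config, condition, "fast", participant_effect),
                   true_probability(config, condition, "slow", participant_effect))
  correct <- stats::rbinom(B, 1L, p_beat)
  eps <- draw_phase_errors(correct, config$kappa_correct, config$tolerance_deg)
  target <- if (condition$instruction == "symmetrical") 180 else 0
  delta <- target + eps

  pause <- stats::rbinom(B, 1L, config$pause_rate) == 1L
  amp_r <- config$amplitude_mm * exp(stats::rnorm(B, 0, 0.05)) *
    ifelse(pause, 0.05, 1)
  amp_l <- config$amplitude_mm * exp(stats::rnorm(B, 0, 0.05)) *
    ifelse(pause, 0.05, 1)

  x_r <- amp_r[bi] * sin(th) + stats::rnorm(n, 0, config$noise_mm)
  x_l <- amp_l[bi] * sin(th + delta[bi] * pi / 180) +
    stats::rnorm(n, 0, config$noise_mm)
  y_r <- stats::rnorm(n, 0, config$noise_mm)
  y_l <- stats::rnorm(n, 0, config$noise_mm)
  miss_r <- stats::rbinom(n, 1L, config$dropout_rate) == 1L
  miss_l <- stats::rbinom(n, 1L, config$dropout_rate) == 1L
  x_r[miss_r] <- NA_real_
  x_l[miss_l] <- NA_real_

  truth <- data.frame(beat = schedule$beat, speed_level = schedule$plateau,
                      speed_pooled = pooled, correct = correct,
                      phase_err = eps, rel_phase = wrap_phase(delta),
                      pause = pause)
  list(left = data.frame(t = t, x = x_l, y = y_l, missing = miss_l),
       right = data.frame(t = t, x = x_r, y = y_r, missing = miss_r),
       truth = truth, schedule = schedule)
}

condition_grid <- function(config) {
  g <- expand.grid(rep = seq_len(config$reps_per_condition),
                   posture_raw = raw_postures(),
                   mirror = c("non-mirrored", "mirrored"),
                   instruction = c("symmetrical", "parallel"),
                   participant = sprintf("P%02d", seq_len(config$n_participants)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$session <- ifelse(g$rep <= ceiling(config$reps_per_condition / config$sessions),
                      1L, 2L)
  g$trial <- seq_len(nrow(g))
  g$excluded <- FALSE
  g[, c("trial", "participant", "session", "rep", "instruction", "mirror",
        "posture_raw", "excluded")]
}

#' Simulate a full synthetic experiment
#'
#' Full factorial condition grid (instruction x mirror x 4 raw postures) x
#' repetitions x participants, with participant intercept deviations drawn
#' Normal(0, `participant_sd`). Deterministic under a fixed config seed;
#' each trial uses a counter-derived sub-stream.
#'
#' @param config a [sim_config()].
#' @return List with `trajectories` (long data frame: `participant`, `trial`,
#'   `t`, `hand`, `x`, `y`, `missing`), `metadata` (one row per trial:
#'   condition factors, session, exclusion flag) and `truth` (participant
#'   effects and the per-beat generating record of every trial).
#' @export
simulate_experiment <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  pe <- stats::rnorm(config$n_participants, 0, config$participant_sd)
  names(pe) <- sprintf("P%02d", seq_len(config$n_participants))
  meta <- condition_grid(config)

  traj <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cond <- meta[i, ]
    sim <- simulate_trial(config, cond, pe[[cond$participant]],
                          seed = derive_seed(config$seed, i))
    nr <- nrow(sim$left)
    traj[[i]] <- data.frame(
      participant = rep(cond$participant, 2L * nr),
      trial = rep(cond$trial, 2L * nr),
      t = c(sim$left$t, sim$right$t),
      hand = rep(c("left", "right"), each = nr),
      x = c(sim$left$x, sim$right$x),
      y = c(sim$left$y, sim$right$y),
      missing = as.integer(c(sim$left$missing, sim$right$missing)))
    truth[[i]] <- cbind(trial = cond$trial, sim$truth)
  }
  list(trajectories = as.data.frame(data.table::rbindlist(traj)),
       metadata = meta,
       truth = list(participant_effects = pe,
                    cycles = as.data.frame(data.table::rbindlist(truth))))
}

#' Simulate cycle-level outcomes directly
#'
#' The outcome-level shortcut of the generative model: skips trajectory
#' synthesis and kinematic re-estimation, and emits one row per analyzable
#' movement cycle with its generating relative phase and correctness. Cycle
#' counts per condition and speed level follow the metronome schedule
#' (repetitions x beats per plateau) thinned by the pause rate.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data frame with columns `participant`, `instruction`, `mirror`,
#'   `posture_raw`, `posture_pooled`, `speed_level`, `speed_pooled`,
#'   `rel_phase`, `correct`.
#' @export
simulate_cycle_outcomes <- function(config, seed = NULL) {
  validate_config(config)
  set.seed(seed %||% config$seed)
  pe <- stats::rnorm(config$n_participants, 0, config$participant_sd)
  names(pe) <- sprintf("P%02d", seq_len(config$n_participants))
  n_speeds <- length(config$speeds)
  n_slow <- ceiling(n_speeds / 2)
  g <- expand.grid(speed_level = seq_len(n_speeds),
                   posture_raw = raw_postures(),
                   mirror = c("non-mirrored", "mirrored"),
                   instruction = c("symmetrical", "parallel"),
                   participant = sprintf("P%02d", seq_len(config$n_participants)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  beats <- config$reps_per_condition * config$beats_per_speed
  g$n_cycles <- stats::rbinom(nrow(g), beats, 1 - config$pause_rate)
  g$speed_pooled <- ifelse(g$speed_level <= n_slow, "slow", "fast")
  g$posture_pooled <- pool_posture(g$posture_raw)

  out <- g[rep(seq_len(nrow(g)), g$n_cycles),
           c("participant", "instruction", "mirror", "posture_raw",
             "posture_pooled", "speed_level", "speed_pooled")]
  rownames(out) <- NULL
  X <- design_codes(out$instruction, out$mirror, out$posture_pooled,
                    out$speed_pooled)
  p <- invlogit(drop(X %*% config$true_betas[bp_effects()]) +
                  pe[out$participant])
  out$correct <- stats::rbinom(nrow(out), 1L, p)
  target <- ifelse(out$instruction == "symmetrical", 180, 0)
  eps <- draw_phase_errors(out$correct, config$kappa_correct,
                           config$tolerance_deg)
  out$rel_phase <- wrap_phase(target + eps)
  out
}
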