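#' Pool raw hand postures into a two-level factor
#'
#' Both-hands-down and both-hands-up pool to `"same"` hand orientation;
#' the two mixed orientations pool to `"different"`.
#'
#' @param posture_raw character vector of raw posture labels.
#' @return Character vector of `"same"` / `"different"`.
#' @export
pool_posture <- function(posture_raw) {
  posture_raw <- as.character(posture_raw)
  bad <- !(posture_raw %in% raw_postures())
  if (any(bad)) stop("unknown posture_raw level: '",
                     posture_raw[which(bad)[1]], "'")
  ifelse(posture_raw %in% c("both-down", "both-up"), "same", "different")
}

#' Pool metronome speed levels into slow and fast
#'
#' Collapses the five slowest plateaus (levels 1-5) to `"slow"` and the five
#' fastest (levels 6-10) to `"fast"`.
#'
#' @param speed_level integer plateau index, 1-10.
#' @param n_levels total number of plateaus (default 10).
#' @return Character vector of `"slow"` / `"fast"`.
#' @export
pool_speed <- function(speed_level, n_levels = 10L) {
  speed_level <- as.integer(speed_level)
  if (any(speed_level < 1L | speed_level > n_levels, na.rm = TRUE))
    stop("speed_level out of range 1..", n_levels)
  ifelse(speed_level <= ceiling(n_levels / 2), "slow", "fast")
}

#' Target relative phase of an instruction, in external space
#'
#' @param instruction `"symmetrical"` (target 180) or `"parallel"` (target 0).
#' @return Numeric target phase in degrees.
#' @export
target_phase <- function(instruction) {
  ifelse(code_level(instruction, "symmetrical", "parallel",
                    "instruction") > 0, 180, 0)
}

#' Dichotomize a cycle's relative phase into correct/incorrect
#'
#' A cycle is correct when the circular distance between its relative phase
#' and the instructed target (180 degrees for symmetrical, 0 for parallel)
#' is at most `tolerance`; a distance exactly equal to the tolerance counts
#' as correct.
#'
#' @param relative_phase degrees (any wrapping).
#' @param instruction `"symmetrical"` or `"parallel"` (vectorized).
#' @param tolerance half-width of the correctness window in degrees, in
#'   (0, 90); 50 is the standard criterion, 20 the stricter alternative.
#' @return Integer vector of 0/1.
#' @export
classify_cycle <- function(relative_phase, instruction, tolerance = 50) {
  if (any(tolerance <= 0 | tolerance >= 90)) stop("tolerance must be in (0, 90)")
  as.integer(circ_dist(relative_phase, target_phase(instruction)) <= tolerance)
}

#' Per-participant relative-phase histogram
#'
#' Bins wrapped phases into 18 half-open 20-degree bins spanning [-90, 270)
#' and normalizes counts by the total cycle count, times 100.
#'
#' @param phases numeric vector of relative phases in degrees (wrapped to
#'   [-90, 270); other values are re-wrapped).
#' @return data frame with `bin_lower`, `bin_upper`, `percent`; attribute
#'   `empty` is `TRUE` for empty input (all-zero histogram).
#' @export
phase_histogram <- function(phases) {
  edges <- seq(-90, 270, by = 20)
  if (length(phases) == 0) {
    h <- data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
                    percent = 0)
    attr(h, "empty") <- TRUE
    return(h)
  }
  w <- wrap_phase(phases)
  idx <- findInterval(w, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  h <- data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
                  percent = 100 * counts / length(w))
  attr(h, "empty") <- FALSE
  h
}

#' Pool condition factors for modelling
#'
#' Adds the pooled two-level posture and speed factors to a table carrying
#' `posture_raw` and `speed_level`.
#'
#' @param data data frame with columns `posture_raw` and `speed_level`.
#' @param n_speed_levels total number of speed plateaus (default 10).
#' @return The input with `posture_pooled` and `speed_pooled` columns added.
#' @export
pool_factors <- function(data, n_speed_levels = 10L) {
  data$posture_pooled <- pool_posture(data$posture_raw)
  data$speed_pooled <- pool_speed(data$speed_level, n_speed_levels)
  data
}

#' Congruence structure of the eight pooled conditions
#'
#' Mirrored viewing replaces the right hand's image with the left hand's
#' reflection, so vision always reports a symmetrical movement of two
#' same-oriented hands using homologous muscles. Congruence of that visual
#' impression with the true movement decomposes into three aspects:
#' direction (incongruent when moving in parallel under the mirror), posture
#' (incongruent when the hands are truly oriented differently under the
#' mirror) and muscles (incongruent when the true movement does not use
#' homologous muscles under the mirror). Non-mirrored conditions are
#' congruent on all three aspects. Conditions are numbered 1-8 with odd
#' numbers non-mirrored and even numbers their mirrored counterparts.
#'
#' @param instruction,mirror,posture_pooled vectors of factor levels.
#' @return data frame with `condition_number` (1-8), `direction_congruent`,
#'   `posture_congruent`, `muscle_congruent`, `homologous_required`.
#' @export
congruence_labels <- function(instruction, mirror, posture_pooled) {
  ci <- code_level(instruction, "symmetrical", "parallel", "instruction")
  cm <- code_level(mirror, "non-mirrored", "mirrored", "mirror")
  cp <- code_level(posture_pooled, "same", "different", "posture")
  mirrored <- cm < 0
  parallel <- ci < 0
  different <- cp < 0
  homologous <- !xor(!parallel, !different)  # symmetrical XNOR same
  data.frame(
    condition_number = as.integer(1 + 4 * parallel + 2 * different + mirrored),
    direction_congruent = !(mirrored & parallel),
    posture_congruent = !(mirrored & different),
    muscle_congruent = !(mirrored & !homologous),
    homologous_required = homologous)
}

#' Drop trials flagged for exclusion
#'
#' @param metadata trial metadata with a logical `excluded` column.
#' @param quiet suppress the retention message.
#' @return Filtered metadata; attribute `n_excluded` records the count.
#' @export
exclude_trials <- function(metadata, quiet = FALSE) {
  if (is.null(metadata$excluded)) stop("metadata lacks 'excluded' column")
  keep <- !as.logical(metadata$excluded)
  out <- metadata[keep, , drop = FALSE]
  if (!quiet) message(sum(!keep), " trial(s) excluded, ", sum(keep), " retained")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Score a cycle table against trial metadata
#'
#' Joins per-cycle relative phases with their trial's condition factors,
#' pools posture and speed, dichotomizes accuracy and attaches congruence
#' labels. Invalid cycles and cycles from excluded trials are dropped.
#'
#' @param cycles cycle table from [analyze_experiment()] (columns `trial`,
#'   `speed_level`, `rel_phase`, `valid`), or any table with those columns.
#' @param metadata trial metadata (columns `trial`, `participant`,
#'   `instruction`, `mirror`, `posture_raw`, `excluded`).
#' @param tolerance correctness half-width in degrees (50 or 20).
#' @param n_speed_levels total number of speed plateaus.
#' @return Outcome table with one row per analyzable cycle: condition
#'   factors (raw and pooled), `condition_number`, `rel_phase`, `correct`,
#'   `tolerance`.
#' @export
score_cycles <- function(cycles, metadata, tolerance = 50,
                         n_speed_levels = 10L) {
  metadata <- exclude_trials(metadata, quiet = TRUE)
  if (!is.null(cycles$valid)) cycles <- cycles[as.logical(cycles$valid), ]
  keep <- c("trial", "participant", "instruction", "mirror", "posture_raw")
  cycles <- cycles[, setdiff(names(cycles), keep[-1]), drop = FALSE]
  out <- merge(cycles, metadata[, keep], by = "trial")
  out <- pool_factors(out, n_speed_levels)
  out$correct <- classify_cycle(out$rel_phase, out$instruction, tolerance)
  out$tolerance <- tolerance
  cg <- congruence_labels(out$instruction, out$mirror, out$posture_pooled)
  out$condition_number <- cg$condition_number
  out$homologous_required <- cg$homologous_required
  out
}
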