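#' Posterior prediction for a design cell (or set of cells)
#'
#' Per-draw group-level linear predictor at a cell's sum-to-zero codes, with
#' the participant intercept at its population centre (zero). Factors left
#' `NULL` are collapsed: their code terms cancel, and with
#' `aggregate = "sum"` (the contrast-vector convention used for reported
#' credible differences) the remaining terms are summed over the collapsed
#' factor's levels, contributing a factor of two per collapsed factor;
#' `aggregate = "mean"` averages instead. On the probability scale the
#' mean convention is always used.
#'
#' @param fit a [fit_model()] result.
#' @param instruction,mirror,posture,speed factor levels, or `NULL` to
#'   collapse.
#' @param scale `"logit"` or `"probability"`.
#' @param aggregate `"sum"` or `"mean"` over collapsed factors (logit scale
#'   only).
#' @return Numeric vector with one value per recorded posterior draw.
#' @export
cell_prediction <- function(fit, instruction = NULL, mirror = NULL,
                            posture = NULL, speed = NULL,
                            scale = c("logit", "probability"),
                            aggregate = c("sum", "mean")) {
  scale <- match.arg(scale)
  aggregate <- match.arg(aggregate)
  one <- function(lvl, pos, neg, what) {
    if (is.null(lvl)) 0 else code_level(lvl, pos, neg, what)
  }
  ci <- one(instruction, "symmetrical", "parallel", "instruction")
  cm <- one(mirror, "non-mirrored", "mirrored", "mirror")
  cp <- one(posture, "same", "different", "posture")
  cs <- one(speed, "fast", "slow", "speed")
  codes <- c(1, ci, cm, cp, cs,
             ci * cm, ci * cp, ci * cs, cm * cp, cm * cs, cp * cs,
             ci * cm * cp, ci * cm * cs, ci * cp * cs, cm * cp * cs,
             ci * cm * cp * cs)
  eta <- drop(fit$beta %*% codes)
  n_collapsed <- sum(c(is.null(instruction), is.null(mirror),
                       is.null(posture), is.null(speed)))
  if (scale == "probability") return(invlogit(eta))
  if (aggregate == "sum") eta * 2^n_collapsed else eta
}

#' Credible difference between two cells' posterior predictions
#'
#' Element-wise difference of two equal-length draw vectors paired by MCMC
#' iteration, summarized by its mean, 95% HDI and the fractions of samples
#' falling below and above zero.
#'
#' @param draws_a,draws_b paired posterior prediction draws.
#' @param name contrast label (`difference_a_b` style).
#' @param scale label of the scale the draws live on.
#' @param mass HDI mass.
#' @return One-row data frame: `name`, `scale`, `mean`, `hdi_lower`,
#'   `hdi_upper`, `frac_below_zero`, `frac_above_zero`, `excludes_zero`;
#'   the difference draws are attached as attribute `draws`.
#' @export
credible_difference <- function(draws_a, draws_b, name = "difference",
                                scale = "logit", mass = 0.95) {
  if (length(draws_a) != length(draws_b))
    stop("draw vectors must be paired by iteration (equal lengths)")
  d <- draws_a - draws_b
  h <- hdi(d, mass)
  out <- data.frame(name = name, scale = scale, mean = mean(d),
                    hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
                    frac_below_zero = mean(d < 0),
                    frac_above_zero = mean(d > 0),
                    excludes_zero = h[["lower"]] > 0 | h[["upper"]] < 0)
  attr(out, "draws") <- d
  out
}

#' The full named contrast suite
#'
#' Twelve posterior-predictive credible differences on the logit scale:
#' four muscle-homology contrasts (same minus different posture under the
#' symmetrical instruction, different minus same under parallel, at slow and
#' fast speeds, mirror view collapsed); four mirror contrasts (mirrored
#' minus non-mirrored per instruction and speed, posture collapsed); two
#' muscle-congruence contrasts within mirrored viewing (congruent minus
#' incongruent posture per instruction, speed collapsed); and two
#' congruent-mirrored versus congruent-non-mirrored contrasts (speed
#' collapsed).
#'
#' @param fit a [fit_model()] result.
#' @param mass HDI mass.
#' @return data frame with one row per contrast (see
#'   [credible_difference()]).
#' @export
named_contrast_suite <- function(fit, mass = 0.95) {
  cp <- function(...) cell_prediction(fit, ...)
  cd <- function(a, b, name) credible_difference(a, b, name, "logit", mass)
  rows <- list(
    cd(cp(instruction = "symmetrical", posture = "same", speed = "slow"),
       cp(instruction = "symmetrical", posture = "different", speed = "slow"),
       "same-different_symmetrical_slow"),
    cd(cp(instruction = "symmetrical", posture = "same", speed = "fast"),
       cp(instruction = "symmetrical", posture = "different", speed = "fast"),
       "same-different_symmetrical_fast"),
    cd(cp(instruction = "parallel", posture = "different", speed = "slow"),
       cp(instruction = "parallel", posture = "same", speed = "slow"),
       "different-same_parallel_slow"),
    cd(cp(instruction = "parallel", posture = "different", speed = "fast"),
       cp(instruction = "parallel", posture = "same", speed = "fast"),
       "different-same_parallel_fast"),
    cd(cp(instruction = "symmetrical", mirror = "mirrored", speed = "slow"),
       cp(instruction = "symmetrical", mirror = "non-mirrored", speed = "slow"),
       "mirrored-non-mirrored_symmetrical_slow"),
    cd(cp(instruction = "symmetrical", mirror = "mirrored", speed = "fast"),
       cp(instruction = "symmetrical", mirror = "non-mirrored", speed = "fast"),
       "mirrored-non-mirrored_symmetrical_fast"),
    cd(cp(instruction = "parallel", mirror = "mirrored", speed = "slow"),
       cp(instruction = "parallel", mirror = "non-mirrored", speed = "slow"),
       "mirrored-non-mirrored_parallel_slow"),
    cd(cp(instruction = "parallel", mirror = "mirrored", speed = "fast"),
       cp(instruction = "parallel", mirror = "non-mirrored", speed = "fast"),
       "mirrored-non-mirrored_parallel_fast"),
    cd(cp(instruction = "symmetrical", mirror = "mirrored", posture = "same"),
       cp(instruction = "symmetrical", mirror = "mirrored", posture = "different"),
       "same-different_symmetrical_mirrored"),
    cd(cp(instruction = "parallel", mirror = "mirrored", posture = "different"),
       cp(instruction = "parallel", mirror = "mirrored", posture = "same"),
       "different-same_parallel_mirrored"),
    cd(cp(instruction = "symmetrical", mirror = "mirrored", posture = "same"),
       cp(instruction = "symmetrical", mirror = "non-mirrored", posture = "same"),
       "mirrored-non-mirrored_symmetrical_same"),
    cd(cp(instruction = "parallel", mirror = "mirrored", posture = "different"),
       cp(instruction = "parallel", mirror = "non-mirrored", posture = "different"),
       "mirrored-non-mirrored_parallel_different"))
  do.call(rbind, rows)
}

#' Logit to percent-correct conversion
#'
#' @param x logit value(s).
#' @return `100 * invlogit(x)`.
#' @export
logit_to_percent <- function(x) 100 * invlogit(x)

#' Percentage-point change of a logit-scale effect at a baseline
#'
#' How many percentage points of accuracy a logit-scale improvement `delta`
#' is worth at a given baseline logit: near-ceiling baselines compress even
#' substantial logit effects into small percent changes.
#'
#' @param base baseline logit.
#' @param delta logit-scale change.
#' @return `100 * (invlogit(base + delta) - invlogit(base))`.
#' @export
percent_point_change <- function(base, delta) {
  100 * (invlogit(base + delta) - invlogit(base))
}
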