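#' Effect names of the factorial accuracy model
#'
#' The hierarchical logistic model describes per-cycle accuracy through an
#' intercept plus 15 sum-to-zero coded effects: the four main effects of
#' movement instruction, mirror view, hand posture and movement speed, and
#' all of their 2-, 3- and 4-way interactions. The order returned here is the
#' canonical reporting order used by every function in the package (summary
#' tables, `true_betas` in [sim_config()], posterior draw matrices).
#'
#' @return Character vector of length 16, starting with `"intercept"`.
#' @export
bp_effects <- function() {
  c("intercept",
    "instruction", "mirror", "posture", "speed",
    "instruction_mirror", "instruction_posture", "instruction_speed",
    "mirror_posture", "mirror_speed", "posture_speed",
    "instruction_mirror_posture", "instruction_mirror_speed",
    "instruction_posture_speed", "mirror_posture_speed",
    "instruction_mirror_posture_speed")
}

code_level <- function(x, pos, neg, what) {
  x <- as.character(x)
  bad <- !(x %in% c(pos, neg))
  if (any(bad)) {
    stop(sprintf("unknown %s level: '%s' (expected '%s' or '%s')",
                 what, x[which(bad)[1]], pos, neg))
  }
  ifelse(x == pos, 1, -1)
}

#' Sum-to-zero design codes for the four experimental factors
#'
#' Codes the first factor level as +1 and the second as -1
#' (instruction: symmetrical = 1, parallel = -1; mirror: non-mirrored = 1,
#' mirrored = -1; posture: same = 1, different = -1; speed: fast = 1,
#' slow = -1); every interaction code is the product of its constituent
#' main-effect codes.
#'
#' @param instruction character, `"symmetrical"` or `"parallel"`.
#' @param mirror character, `"non-mirrored"` or `"mirrored"`.
#' @param posture character, `"same"` or `"different"` (pooled posture).
#' @param speed character, `"fast"` or `"slow"` (pooled speed).
#' @return Numeric matrix with one row per input element and 16 columns named
#'   as in [bp_effects()]; the first column is the constant 1 intercept code.
#' @export
design_codes <- function(instruction, mirror, posture, speed) {
  ci <- code_level(instruction, "symmetrical", "parallel", "instruction")
  cm <- code_level(mirror, "non-mirrored", "mirrored", "mirror")
  cp <- code_level(posture, "same", "different", "posture")
  cs <- code_level(speed, "fast", "slow", "speed")
  X <- cbind(1, ci, cm, cp, cs,
             ci * cm, ci * cp, ci * cs, cm * cp, cm * cs, cp * cs,
             ci * cm * cp, ci * cm * cs, ci * cp * cs, cm * cp * cs,
             ci * cm * cp * cs)
  colnames(X) <- bp_effects()
  X
}

#' Build the model design from a scored cycle table
#'
#' @param outcomes data frame with one row per movement cycle, containing
#'   columns `participant`, `instruction`, `mirror`, `posture_pooled`,
#'   `speed_pooled` and the 0/1 outcome `correct`.
#' @return List with the cycle-level design matrix `X` (16 columns), outcome
#'   vector `y`, and the participant factor `participant`.
#' @export
build_design <- function(outcomes) {
  need <- c("participant", "instruction", "mirror", "posture_pooled",
            "speed_pooled", "correct")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcomes table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(outcomes$participant)) < 2)
    stop("at least 2 participants are required")
  y <- as.integer(outcomes$correct)
  if (!all(y %in% c(0L, 1L))) stop("correct must be 0/1")
  X <- design_codes(outcomes$instruction, outcomes$mirror,
                    outcomes$posture_pooled, outcomes$speed_pooled)
  list(X = X, y = y, participant = factor(outcomes$participant))
}

#' MCMC schedule profiles
#'
#' `"paper"` is the full reporting schedule (4 chains, 1,500 burn-in
#' iterations, every 20th post-burn-in sample saved, 3,000 recorded samples
#' per chain = 12,000 total). `"scaled"` is a lighter schedule for testing
#' and iteration (4 chains, 500 burn-in, every 3rd sample saved, 2,000
#' recorded per chain).
#'
#' @param profile `"paper"` or `"scaled"`.
#' @return List with elements `chains`, `burn_in`, `thin`, `keep` (per chain).
#' @export
mcmc_profile <- function(profile = c("scaled", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
         paper  = list(chains = 4L, burn_in = 1500L, thin = 20L, keep = 3000L),
         scaled = list(chains = 4L, burn_in = 500L,  thin = 3L,  keep = 2000L))
}

# Aggregate cycle-level data to binomial cell counts; the linear predictor is
# constant within participant x design cell, so this is lossless.
aggregate_cells <- function(X, y, participant) {
  key <- paste(as.integer(participant),
               apply(X[, -1, drop = FALSE], 1, paste, collapse = ""),
               sep = "|")
  ukey <- unique(key)
  first <- match(ukey, key)
  ys <- rowsum(as.numeric(y), key)
  ns <- rowsum(rep(1, length(y)), key)
  list(X = X[first, , drop = FALSE],
       y = as.numeric(ys[ukey, ]),
       n = as.numeric(ns[ukey, ]),
       pid = as.integer(participant)[first])
}

# One adaptive Metropolis-within-Gibbs chain on binomial cell counts.
run_chain <- function(cells, J, settings, hyper, hyper_shape, hyper_scale,
                      init_beta, chain_seed) {
  set.seed(chain_seed)
  X <- cells$X; y <- cells$y; n <- cells$n; pid <- cells$pid
  m <- nrow(X); P <- ncol(X)
  rows_by_pid <- split(seq_len(m), pid)
  Xcols <- lapply(seq_len(P), function(k) X[, k])

  beta <- init_beta + stats::rnorm(P, 0, 0.05)
  u <- stats::rnorm(J, 0, 0.1)
  phi <- pmax(beta^2, 0.5)     # per-weight prior variances
  phi_u <- 0.5                 # participant-intercept variance
  eta <- as.vector(X %*% beta) + u[pid]
  ll_cur <- sum(y * eta - n * log1pexp(eta))

  ls_beta <- rep(-2, P); ls_u <- rep(-1.5, J); ls_t <- -2
  total <- settings$burn_in + settings$keep * settings$thin
  keep_beta <- matrix(NA_real_, settings$keep, P)
  keep_u <- matrix(NA_real_, settings$keep, J)
  keep_sig <- numeric(settings$keep)
  kept <- 0L

  literal <- hyper == "precision-ig"
  a_h <- hyper_shape; s_h <- hyper_scale

  draw_phi_weight <- function(b, phi_cur) {
    if (literal && a_h == 1) {
      # precision ~ IG(1, s) <=> variance ~ Exp(s); the conditional of the
      # precision given beta is inverse-Gaussian (GIG with lambda = -1/2)
      tau <- rinvgauss1(sqrt(2 * s_h) / max(abs(b), 1e-8), 2 * s_h)
      min(1 / max(tau, 1e-12), 1e8)
    } else if (literal) {
      # variance | beta is GIG(a - 1/2, b^2, 2s); slice sample on log scale
      lphi <- slice_sample1(log(max(phi_cur, 1e-6)), function(l) {
        (a_h - 0.5) * l - s_h * exp(l) - b^2 / (2 * exp(l))
      })
      min(exp(lphi), 1e8)
    } else {
      1 / stats::rgamma(1, a_h + 0.5, rate = s_h + b^2 / 2)
    }
  }

  for (it in seq_len(total)) {
    adapting <- it <= settings$burn_in
    gam <- if (adapting) min(0.25, 5 / sqrt(it)) else 0

    for (k in seq_len(P)) {
      prop <- beta[k] + exp(ls_beta[k]) * stats::rnorm(1)
      eta_p <- eta + (prop - beta[k]) * Xcols[[k]]
      ll_p <- sum(y * eta_p - n * log1pexp(eta_p))
      lr <- ll_p - ll_cur + (beta[k]^2 - prop^2) / (2 * phi[k])
      acc <- log(stats::runif(1)) < lr
      if (acc) { beta[k] <- prop; eta <- eta_p; ll_cur <- ll_p }
      if (adapting) ls_beta[k] <- ls_beta[k] + gam * ((if (acc) 1 else 0) - 0.44)
    }

    # joint translation of intercept vs participant deviations; the
    # likelihood is invariant, only the priors move
    dlt <- exp(ls_t) * stats::rnorm(1)
    lr <- (beta[1]^2 - (beta[1] + dlt)^2) / (2 * phi[1]) +
      sum(u^2 - (u - dlt)^2) / (2 * phi_u)
    acc <- log(stats::runif(1)) < lr
    if (acc) { beta[1] <- beta[1] + dlt; u <- u - dlt; eta <- as.vector(X %*% beta) + u[pid] }
    if (adapting) ls_t <- ls_t + gam * ((if (acc) 1 else 0) - 0.44)

    for (j in seq_len(J)) {
      r <- rows_by_pid[[j]]
      d <- exp(ls_u[j]) * stats::rnorm(1)
      ep <- eta[r] + d
      dll <- sum(y[r] * d - n[r] * (log1pexp(ep) - log1pexp(eta[r])))
      lr <- dll + (u[j]^2 - (u[j] + d)^2) / (2 * phi_u)
      acc <- log(stats::runif(1)) < lr
      if (acc) { u[j] <- u[j] + d; eta[r] <- ep; ll_cur <- ll_cur + dll }
      if (adapting) ls_u[j] <- ls_u[j] + gam * ((if (acc) 1 else 0) - 0.44)
    }

    for (k in seq_len(P)) phi[k] <- draw_phi_weight(beta[k], phi[k])
    su2 <- sum(u^2)
    if (literal) {
      lphi <- slice_sample1(log(phi_u), function(l) {
        (a_h - J / 2) * l - s_h * exp(l) - su2 / (2 * exp(l))
      })
      phi_u <- min(exp(lphi), 1e8)
    } else {
      phi_u <- 1 / stats::rgamma(1, a_h + J / 2, rate = s_h + su2 / 2)
    }

    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0L) {
      kept <- kept + 1L
      keep_beta[kept, ] <- beta
      keep_u[kept, ] <- u
      keep_sig[kept] <- sqrt(phi_u)
    }
  }
  list(beta = keep_beta, u = keep_u, sigma_u = keep_sig)
}

#' Fit the hierarchical Bayesian logistic accuracy model
#'
#' Per-cycle accuracy (0/1) is modelled as Bernoulli with
#' `P(correct) = invlogit(beta_intercept + sum(beta_k * code_k) + u_participant)`,
#' where the 15 effect codes are the sum-to-zero factorial codes of
#' [design_codes()] and `u_participant` are zero-centred participant
#' intercept deviations. All 16 group-level weights have normal priors
#' centred on zero whose precision is drawn from an inverse gamma
#' distribution (default shape 1, scale 0.01); participant deviations share
#' a common normal prior with the same hyperprior family. Sampling uses an
#' in-package adaptive Metropolis-within-Gibbs kernel on binomial cell
#' counts (the linear predictor is constant within participant-by-cell), with
#' proposal scales tuned only during burn-in.
#'
#' @param outcomes scored cycle table, see [build_design()].
#' @param profile `"scaled"` (default) or `"paper"`, see [mcmc_profile()];
#'   ignored for any schedule component supplied via `settings`.
#' @param settings optional list overriding `chains`, `burn_in`, `thin`,
#'   `keep` (recorded draws per chain).
#' @param seed integer; every chain derives its own RNG stream from it.
#' @param hyper `"precision-ig"` reads the hyperprior literally (the
#'   precision of each weight prior is inverse-gamma distributed);
#'   `"variance-ig"` is the conventional conjugate alternative (the variance
#'   is inverse-gamma, i.e. the precision is gamma distributed). Relevance
#'   decisions should agree under both on well-powered data.
#' @param hyper_shape,hyper_scale hyperprior shape and scale (defaults 1 and
#'   0.01; 0.01/0.01 is the robustness-check alternative).
#' @return An object of class `bp_fit`: list with `beta` (recorded draws x 16
#'   matrix, columns [bp_effects()]), `u` (draws x participants), `sigma_u`,
#'   `chain` (chain index per draw), `participants`, `diagnostics` (per-beta
#'   ESS and split-Rhat), `settings`, `convergence_ok`.
#' @export
fit_model <- function(outcomes, profile = c("scaled", "paper"),
                      settings = NULL, seed = 1L,
                      hyper = c("precision-ig", "variance-ig"),
                      hyper_shape = 1, hyper_scale = 0.01) {
  hyper <- match.arg(hyper)
  prof <- mcmc_profile(match.arg(profile))
  prof[names(settings)] <- settings
  stopifnot(prof$chains >= 1, prof$burn_in >= 0, prof$thin >= 1, prof$keep > 0)

  d <- build_design(outcomes)
  if (length(unique(d$y)) < 2L)
    warning("all outcomes identical; posterior is prior-dominated")
  cells <- aggregate_cells(d$X, d$y, d$participant)
  J <- length(levels(d$participant))

  # crude penalised-likelihood start shared by all chains (jittered per chain)
  init_beta <- tryCatch({
    eps <- 0.5
    fit <- suppressWarnings(stats::glm.fit(
      cells$X, cbind(cells$y + eps, cells$n - cells$y + eps),
      family = stats::binomial()))
    b <- fit$coefficients
    b[!is.finite(b)] <- 0
    pmax(pmin(b, 5), -5)
  }, error = function(e) rep(0, ncol(cells$X)))

  chains <- lapply(seq_len(prof$chains), function(c) {
    run_chain(cells, J, prof, hyper, hyper_shape, hyper_scale,
              init_beta, derive_seed(seed, 1000 + c))
  })
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- bp_effects()
  u <- do.call(rbind, lapply(chains, `[[`, "u"))
  colnames(u) <- levels(d$participant)
  chain_id <- rep(seq_len(prof$chains), each = prof$keep)

  diag <- mcmc_diagnostics(beta, chain_id)
  conv <- all(is.na(diag$rhat) | diag$rhat < 1.1)
  if (!conv) warning("possible non-convergence: max split-Rhat = ",
                     round(max(diag$rhat, na.rm = TRUE), 3))

  structure(list(beta = beta, u = u,
                 sigma_u = unlist(lapply(chains, `[[`, "sigma_u")),
                 chain = chain_id, participants = levels(d$participant),
                 diagnostics = diag, settings = prof, hyper = hyper,
                 seed = seed, convergence_ok = conv),
            class = "bp_fit")
}

#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws numeric vector of posterior draws (>= 100 recommended).
#' @param mass interval probability mass, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1, length(draws) >= 2)
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = s[1], upper = s[n]))
  starts <- seq_len(n - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k - 1L])
}

#' HDI relevance decision for an effect
#'
#' An effect is judged to contribute to the prediction of movement accuracy
#' exactly when its 95% HDI excludes zero; an HDI with a boundary at zero
#' spans zero and therefore does not contribute.
#'
#' @param draws posterior draws of one beta weight.
#' @param mass HDI mass (default 0.95).
#' @return `"contributes"` or `"does-not-contribute"`.
#' @export
decide_relevance <- function(draws, mass = 0.95) {
  h <- hdi(draws, mass)
  if (h[["lower"]] > 0 || h[["upper"]] < 0) "contributes" else "does-not-contribute"
}

# Geyer initial-monotone-sequence ESS for one parameter, chains pooled
# Stan-style (autocovariances averaged across chains against the pooled
# variance estimate).
ess_param <- function(x, chain_id) {
  chains <- split(x, chain_id)
  m <- length(chains)
  n <- min(lengths(chains))
  if (n < 4) return(NA_real_)
  chains <- lapply(chains, function(c) c[seq_len(n)])
  acov <- sapply(chains, function(c) {
    stats::acf(c, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- matrix(acov, nrow = n)
  mean_acov <- rowMeans(acov)
  w <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- w * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(sapply(chains, mean))
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive and non-increasing
  maxp <- floor((n - 1) / 2)
  psum <- numeric(maxp)
  for (t in seq_len(maxp)) psum[t] <- rho[2 * t] + rho[2 * t + 1]
  cut <- which(psum <= 0)
  np <- if (length(cut)) cut[1] - 1L else maxp
  if (np > 1) for (t in 2:np) psum[t] <- min(psum[t], psum[t - 1])
  tau <- 1 + 2 * sum(pmax(psum[seq_len(np)], 0))
  max(m * n / max(tau, 1e-12), 1)
}

# Split-Rhat (potential scale reduction) for one parameter.
rhat_param <- function(x, chain_id) {
  chains <- split(x, chain_id)
  if (length(chains) < 2 && min(lengths(chains)) < 4) return(NA_real_)
  n <- min(lengths(chains))
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- unlist(lapply(chains, function(c) {
    list(c[seq_len(half)], c[(half + 1):(2 * half)])
  }), recursive = FALSE)
  means <- sapply(splits, mean)
  vars <- sapply(splits, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w <= 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' MCMC diagnostics: effective sample size and shrink factor
#'
#' Autocorrelation-based effective sample size (Geyer initial monotone
#' estimator, chains combined) and the split-chain potential scale reduction
#' statistic (shrink factor) per parameter. With a single chain the shrink
#' factor is undefined and reported as `NA`.
#'
#' @param draws matrix of draws (rows) by parameters (columns).
#' @param chain_id integer vector assigning each row to a chain.
#' @return data frame with columns `parameter`, `ess`, `rhat`.
#' @export
mcmc_diagnostics <- function(draws, chain_id) {
  draws <- as.matrix(draws)
  single <- length(unique(chain_id)) < 2
  data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    ess = apply(draws, 2, ess_param, chain_id = chain_id),
    rhat = if (single) NA_real_ else apply(draws, 2, rhat_param, chain_id = chain_id),
    row.names = NULL)
}

#' Posterior summary table of a fitted accuracy model
#'
#' @param object a [fit_model()] result.
#' @param mass HDI mass (default 0.95).
#' @param ... unused.
#' @return data frame with one row per beta weight: posterior `mean`,
#'   `hdi_lower`, `hdi_upper`, `ess`, `rhat` and the HDI `relevance`
#'   decision, in the canonical effect order.
#' @export
summary.bp_fit <- function(object, mass = 0.95, ...) {
  hs <- apply(object$beta, 2, hdi, mass = mass)
  data.frame(parameter = colnames(object$beta),
             mean = colMeans(object$beta),
             hdi_lower = hs["lower", ],
             hdi_upper = hs["upper", ],
             ess = object$diagnostics$ess,
             rhat = object$diagnostics$rhat,
             relevance = apply(object$beta, 2, decide_relevance, mass = mass),
             row.names = NULL)
}

#' @export
print.bp_fit <- function(x, ...) {
  cat("Hierarchical Bayesian logistic accuracy model (bimphase)\n")
  cat(sprintf("  %d recorded draws (%d chains), %d participants, hyper = %s\n",
              nrow(x$beta), length(unique(x$chain)),
              length(x$participants), x$hyper))
  s <- summary(x)
  s$mean <- round(s$mean, 3); s$hdi_lower <- round(s$hdi_lower, 3)
  s$hdi_upper <- round(s$hdi_upper, 3); s$ess <- round(s$ess)
  s$rhat <- round(s$rhat, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
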