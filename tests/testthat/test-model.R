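test_that("design codes follow the sign-product contract", {
  x1 <- design_codes("symmetrical", "non-mirrored", "same", "fast")
  expect_true(all(x1 == 1))
  x2 <- drop(design_codes("parallel", "mirrored", "different", "slow"))
  # independent sign-product oracle: mains all -1
  mains <- c(instruction = -1, mirror = -1, posture = -1, speed = -1)
  expect_equal(unname(x2[c("instruction", "mirror", "posture", "speed")]),
               unname(mains))
  expect_true(all(x2[c("instruction_mirror", "instruction_posture",
                       "instruction_speed", "mirror_posture", "mirror_speed",
                       "posture_speed")] == 1))
  expect_true(all(x2[c("instruction_mirror_posture",
                       "instruction_mirror_speed",
                       "instruction_posture_speed",
                       "mirror_posture_speed")] == -1))
  expect_equal(unname(x2["instruction_mirror_posture_speed"]), 1)

  # every interaction code is the product of its constituent main codes
  set.seed(1)
  g <- data.frame(
    instruction = sample(c("symmetrical", "parallel"), 50, TRUE),
    mirror = sample(c("non-mirrored", "mirrored"), 50, TRUE),
    posture = sample(c("same", "different"), 50, TRUE),
    speed = sample(c("fast", "slow"), 50, TRUE))
  X <- design_codes(g$instruction, g$mirror, g$posture, g$speed)
  expect_equal(X[, "instruction_mirror_posture_speed"],
               X[, "instruction"] * X[, "mirror"] * X[, "posture"] *
                 X[, "speed"])
  expect_equal(X[, "mirror_posture"], X[, "mirror"] * X[, "posture"])

  # balanced full factorial: all 15 effect columns pairwise orthogonal
  full <- expand.grid(instruction = c("symmetrical", "parallel"),
                      mirror = c("non-mirrored", "mirrored"),
                      posture = c("same", "different"),
                      speed = c("fast", "slow"), stringsAsFactors = FALSE)
  Xf <- design_codes(full$instruction, full$mirror, full$posture, full$speed)
  G <- crossprod(Xf[, -1])
  expect_true(all(G[upper.tri(G)] == 0))

  expect_error(design_codes("sideways", "mirrored", "same", "fast"),
               "unknown instruction")
})

test_that("the HDI is the shortest window over sorted draws", {
  expect_equal(hdi(rep(3.3, 500)), c(lower = 3.3, upper = 3.3))
  set.seed(2)
  z <- stats::rnorm(1e6)
  h <- hdi(z)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.02)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.02)

  e <- stats::rexp(1e5)
  he <- hdi(e)
  expect_lt(he[["lower"]], 0.01)
  eq_tail <- stats::quantile(e, c(0.025, 0.975))
  expect_lt(he[["upper"]] - he[["lower"]], eq_tail[[2]] - eq_tail[[1]])

  # brute-force shortest-window scan on 10k draws
  set.seed(3)
  d <- stats::rgamma(1e4, 2, 1)
  s <- sort(d)
  k <- ceiling(0.95 * length(s))
  best <- c(Inf, NA, NA)
  for (i in seq_len(length(s) - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + k - 1])
  }
  hb <- hdi(d)
  expect_equal(unname(hb), best[2:3])
})

test_that("relevance decisions hinge on strict zero exclusion", {
  expect_identical(decide_relevance(seq(0.79, 0.85, length.out = 500)),
                   "contributes")
  expect_identical(decide_relevance(seq(-0.01, 0.05, length.out = 500)),
                   "does-not-contribute")
  # 95% HDI lands exactly on (-0.06, 0): a zero boundary still spans zero
  d0 <- c(seq(-0.06, 0, length.out = 950), seq(0.5, 5, length.out = 50))
  expect_equal(unname(hdi(d0)), c(-0.06, 0))
  expect_identical(decide_relevance(d0), "does-not-contribute")
  expect_identical(decide_relevance(seq(-0.85, -0.79, length.out = 500)),
                   "contributes")
})

test_that("diagnostics recover white-noise and AR(1) effective sizes", {
  set.seed(6)
  n <- 4000
  iid <- matrix(stats::rnorm(4 * n), ncol = 1)
  chain <- rep(1:4, each = n)
  dg <- mcmc_diagnostics(iid, chain)
  expect_gt(dg$ess, 0.9 * 4 * n)
  expect_lte(dg$ess, 1.15 * 4 * n)
  expect_lt(dg$rhat, 1.05)

  phi <- 0.95
  ar <- replicate(4, as.numeric(stats::arima.sim(list(ar = phi), n)))
  dga <- mcmc_diagnostics(matrix(as.numeric(ar), ncol = 1), chain)
  # closed-form AR(1) ESS is n * (1 - phi) / (1 + phi) ~ n / 39
  expect_lt(dga$ess, 4 * n / 10)

  # coda cross-check on the white-noise case
  ce <- as.numeric(coda::effectiveSize(coda::mcmc(iid[chain == 1, ,
                                                      drop = FALSE])))
  e1 <- bimphase::mcmc_diagnostics(iid[chain == 1, , drop = FALSE],
                                   rep(1, n))$ess
  expect_true(is.na(bimphase::mcmc_diagnostics(iid[chain == 1, , drop = FALSE],
                                               rep(1, n))$rhat))
  expect_gt(e1 / ce, 0.7); expect_lt(e1 / ce, 1.4)
})

test_that("posterior matches an independent sampler on a small instance", {
  betas <- stats::setNames(c(0.8, 0.5, 0, 0.2, -0.4, rep(0, 11)),
                           bp_effects())
  cfg <- sim_config(n_participants = 6, reps_per_condition = 2,
                    beats_per_speed = 3, participant_sd = 0.3,
                    true_betas = betas, seed = 101)
  out <- simulate_cycle_outcomes(cfg)
  fit <- fit_model(out, settings = list(chains = 4, burn_in = 800,
                                        thin = 2, keep = 2000), seed = 5)
  expect_true(fit$convergence_ok)

  d <- build_design(out)
  cells <- bimphase:::aggregate_cells(d$X, d$y, d$participant)
  jm <- "model {
    for (i in 1:m) { y[i] ~ dbin(ilogit(inprod(X[i,], beta[]) + u[pid[i]]), n[i]) }
    for (k in 1:P) { phiv[k] ~ dexp(s); beta[k] ~ dnorm(0, 1/phiv[k]) }
    for (j in 1:J) { u[j] ~ dnorm(0, 1/phi_u) }
    phi_u ~ dexp(s)
  }"
  jg <- rjags::jags.model(textConnection(jm),
                          data = list(y = cells$y, n = cells$n, X = cells$X,
                                      pid = cells$pid, m = nrow(cells$X),
                                      P = 16, J = 6, s = 0.01),
                          n.chains = 3, quiet = TRUE)
  stats::update(jg, 2000)
  sm <- rjags::coda.samples(jg, "beta", n.iter = 9000, thin = 3)
  jmn <- colMeans(as.matrix(sm))
  mmn <- colMeans(fit$beta)
  psd <- apply(fit$beta, 2, stats::sd)
  expect_true(all(abs(mmn - jmn) < pmax(0.05, 0.3 * psd)))
})

test_that("a lone moderate instruction effect is recovered", {
  b <- zero_betas(); b["intercept"] <- 1; b["instruction"] <- 0.82
  cfg <- sim_config(n_participants = 6, reps_per_condition = 2,
                    participant_sd = 0.3, true_betas = b, seed = 202)
  out <- simulate_cycle_outcomes(cfg)
  fit <- fit_model(out, settings = light_mcmc, seed = 7)
  m <- mean(fit$beta[, "instruction"])
  s <- stats::sd(fit$beta[, "instruction"])
  expect_lt(abs(m - 0.82), 3 * s)
  expect_identical(decide_relevance(fit$beta[, "instruction"]), "contributes")
})

test_that("null data leave effect HDIs spanning zero", {
  fit <- null_fit()
  decisions <- apply(fit$beta[, -1], 2, decide_relevance)
  expect_gte(sum(decisions == "does-not-contribute"), 13)
})

test_that("relabeling a factor flips its posterior signs", {
  out <- ref_outcomes()
  flipped <- out
  flipped$instruction <- ifelse(out$instruction == "symmetrical",
                                "parallel", "symmetrical")
  f1 <- fit_model(out, settings = light_mcmc, seed = 23)
  f2 <- fit_model(flipped, settings = light_mcmc, seed = 23)
  involves <- grepl("instruction", colnames(f1$beta))
  m1 <- colMeans(f1$beta); m2 <- colMeans(f2$beta)
  expect_true(all(abs(m1[involves] + m2[involves]) < 0.05))
  expect_true(all(abs(m1[!involves] - m2[!involves]) < 0.05))
})

test_that("posterior uncertainty shrinks as cycles accumulate", {
  cfg_small <- sim_config(n_participants = 4, reps_per_condition = 1,
                          beats_per_speed = 2, seed = 303)  # ~1.3k cycles
  cfg_big <- sim_config(n_participants = 4, reps_per_condition = 4,
                        beats_per_speed = 10, seed = 303)   # ~12.8k cycles
  f_small <- fit_model(simulate_cycle_outcomes(cfg_small),
                       settings = light_mcmc, seed = 31)
  f_big <- fit_model(simulate_cycle_outcomes(cfg_big),
                     settings = light_mcmc, seed = 31)
  mains <- c("instruction", "mirror", "posture", "speed")
  sd_small <- apply(f_small$beta[, mains], 2, stats::sd)
  sd_big <- apply(f_big$beta[, mains], 2, stats::sd)
  expect_true(all(sd_big < sd_small))
})

test_that("relevance decisions are robust to the hyperprior reading", {
  out <- ref_outcomes()
  f_lit <- fit_model(out, settings = light_mcmc, seed = 41,
                     hyper = "precision-ig")
  f_alt <- fit_model(out, settings = light_mcmc, seed = 41,
                     hyper = "variance-ig", hyper_shape = 0.01,
                     hyper_scale = 0.01)
  truth <- sim_config()$true_betas
  strong <- names(truth)[abs(truth) >= 0.1]
  d_lit <- apply(f_lit$beta[, strong], 2, decide_relevance)
  d_alt <- apply(f_alt$beta[, strong], 2, decide_relevance)
  expect_identical(d_lit, d_alt)
  expect_true(all(d_lit == "contributes"))
})

test_that("degenerate all-identical outcomes warn", {
  out <- ref_outcomes()
  out <- rbind(out[out$participant == "P01", ][1:200, ],
               out[out$participant == "P02", ][1:200, ])
  out$correct <- 1L
  w <- capture_warnings(
    fit_model(out, settings = list(chains = 2, burn_in = 100, thin = 1,
                                   keep = 100), seed = 3))
  expect_true(any(grepl("identical", w)))
})
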