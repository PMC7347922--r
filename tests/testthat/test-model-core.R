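test_that("opportunity cost is rate times handling time with domain checks", {
  expect_equal(opportunityCost(10, 2), 20)
  expect_equal(opportunityCost(0, 8), 0)
  expect_equal(opportunityCost(320 / 22, 8), 320 / 22 * 8)
  expect_error(opportunityCost(-1, 2), "non-negative")
  expect_error(opportunityCost(10, 0), "positive")
})

test_that("the delta rule gates the learning rate on reward delivery", {
  sym <- subjectParams("symmetric", alpha = 0.1)
  u <- rateUpdate(10, 0, sym)
  expect_equal(u$rho_after, 9)
  expect_equal(u$delta, -10)
  expect_equal(u$gate, "-")

  asym <- ref_asym_params()
  expect_equal(rateUpdate(10, 0, asym)$rho_after, 10 * (1 - 0.0016))
  expect_equal(rateUpdate(10, 80, asym)$gate, "+")
  # zero prediction error leaves the estimate unchanged
  expect_equal(rateUpdate(7, 7, sym)$rho_after, 7)
})

test_that("the reward second is two updates whose order matters in general", {
  p <- subjectParams("asymmetric", alpha_pos = 0.5, alpha_neg = 0.1)
  us <- rewardSecondUpdate(10, 80, p)
  expect_equal(us[[1]]$rho_after, 9)
  expect_equal(us[[2]]$rho_after, 9 + 0.5 * (80 - 9))

  sw <- rewardSecondUpdate(10, 80, p, order = "reward_first")
  expect_equal(sw[[1]]$rho_after, 10 + 0.5 * 70)
  expect_false(isTRUE(all.equal(sw[[2]]$rho_after, us[[2]]$rho_after)))

  # vanishing learning rates leave the estimate essentially unchanged
  p0 <- subjectParams("asymmetric", alpha_pos = 1e-12, alpha_neg = 1e-12)
  expect_equal(rewardSecondUpdate(10, 80, p0)[[2]]$rho_after, 10,
    tolerance = 1e-9
  )
})

test_that("the softmax acceptance rule is symmetric, bias-signed and stable", {
  expect_equal(acceptProbability(30, 30, 0, 0.075), 0.5)
  expect_equal(acceptProbability(80, 10, 0, 0), 0.5)
  # positive beta0 biases towards rejection
  expect_lt(acceptProbability(30, 30, 5, 0.075), 0.5)
  expect_equal(acceptProbability(30, 30, 1e4, 0.075), 0)
  # numerically stable log form at extreme arguments
  expect_true(is.finite(acceptProbability(80, 1e6, 0, 1, log.p = TRUE)))
  expect_equal(acceptProbability(80, 0, -50, 1, log.p = TRUE), 0)
})

test_that("the initial rate is the session-average accept-all rate", {
  # single worst-option-only block: 20 points per (2 + 8) s
  env <- structure(
    list(name = "hdlr_only", cycle = c(HDLR = 1L), duration_seconds = 600),
    class = "prey_env"
  )
  d <- sessionDesign("exp2", "RichPoor")
  expect_equal(preyselect:::cycle_rate_accept_all(env, d), 2)
  # best-option-only composition: 80 points per (2 + 2) s
  env$cycle <- c(LDHR = 1L)
  expect_equal(preyselect:::cycle_rate_accept_all(env, d), 20)

  # full sessions: arithmetic mean of the block cycle rates
  rich_rate <- (4 * 80 + 20 + 80 + 20) / (4 * 4 + 4 + 10 + 10)
  poor_rate <- (80 + 20 + 80 + 4 * 20) / (4 + 4 + 10 + 4 * 10)
  expect_equal(rich_rate, 11)
  expect_equal(
    initialRate(sessionDesign("exp1", "RichPoor")),
    mean(c(rich_rate, poor_rate))
  )
  # block order does not change the arithmetic mean
  expect_equal(
    initialRate(sessionDesign("exp1", "PoorRich")),
    initialRate(sessionDesign("exp1", "RichPoor"))
  )
})

test_that("simulation obeys forced directions, is seed-stable and engine-invariant", {
  design <- sessionDesign("exp2", "PoorRich")
  session <- buildSession(design, seed = 11)
  p <- ref_asym_params()

  sim1 <- simulateSubject(session, p, seed = 5)
  sim2 <- simulateSubject(session, p, seed = 5)
  expect_identical(sim1$log, sim2$log)

  forced <- sim1$log$forced
  expect_equal(sim1$log$choice[forced], sim1$log$forced_dir[forced])
  expect_equal(mean(forced), 0.25, tolerance = 0.02)

  simr <- simulateSubject(session, p, seed = 5, trace = TRUE)
  expect_equal(sim1$log, simr$log, ignore_attr = TRUE)
  expect_equal(sim1$rho_final, simr$rho_final)
})

test_that("a near-deterministic chooser reproduces the MVT threshold rule", {
  design <- sessionDesign("exp2", "RichPoor")
  session <- buildSession(design, seed = 2)
  p <- subjectParams("asymmetric",
    alpha_pos = 0.005, alpha_neg = 0.0016,
    beta0 = 0, beta1 = 50
  )
  sim <- simulateSubject(session, p, seed = 9, trace = TRUE)
  # rate estimate at each decision = trace value at the 2nd encounter second
  tr <- sim$trace
  log <- sim$log
  rho_dec <- tr$rho_after[match(log$t_start + 2, tr$second)]
  opts <- optionSet()
  t_of <- setNames(opts$handling_seconds, opts$label)
  r_of <- setNames(opts$reward_points, opts$label)
  free <- !log$forced
  mvt_choice <- ifelse(
    r_of[log$option] >= rho_dec * t_of[log$option], "accept", "reject"
  )
  expect_gte(mean((log$choice == mvt_choice)[free]), 0.99)
})

test_that("the rate estimate stays within [0, max(rho0, 80)] across parameter draws", {
  design <- sessionDesign("exp2", "RichPoor")
  session <- buildSession(design, seed = 4)
  set.seed(42)
  for (i in 1:6) {
    p <- subjectParams("asymmetric",
      alpha_pos = runif(1, 0.001, 0.9), alpha_neg = runif(1, 0.001, 0.9),
      beta0 = rnorm(1, 0, 2), beta1 = runif(1, 0, 0.2)
    )
    rho0 <- runif(1, 0, 100)
    sim <- simulateSubject(session, p, seed = i, rho0 = rho0, trace = TRUE)
    expect_true(all(sim$trace$rho_after >= 0))
    expect_true(all(sim$trace$rho_after <= max(rho0, 80) + 1e-9))
  }
})

test_that("symmetric learning tracks the stationary average reward", {
  # worst-option-only environment, always-accept subject: each 10-s trial
  # delivers 20 points over 11 update ticks (the reward second is two
  # updates), so the delta rule's stationary mean is the per-update average
  # reward 20/11 ~ 1.82 points; the per-second rate (2.0) is overshot
  # downward by exactly that cycle-length ratio
  design <- sessionDesign("exp3", "RichPoor", forced_fraction = 0)
  design$env_names <- "hdlr_only"
  p <- subjectParams("symmetric", alpha = 0.02, beta0 = -30, beta1 = 0.075)
  means <- vapply(1:10, function(s) {
    session <- buildSession(design, seed = s)
    sim <- simulateSubject(session, p, seed = 100 + s, rho0 = 2, trace = TRUE)
    mean(sim$trace$rho_after[sim$trace$second > 100])
  }, numeric(1))
  expect_equal(mean(means), 20 / 11, tolerance = 0.05)

  # optimism bias: with alpha+ > alpha- the asymptote exceeds the symmetric
  # asymptote at alpha = alpha-
  p_asym <- subjectParams("asymmetric",
    alpha_pos = 0.1, alpha_neg = 0.02,
    beta0 = -30, beta1 = 0.075
  )
  means_asym <- vapply(1:10, function(s) {
    session <- buildSession(design, seed = s)
    sim <- simulateSubject(session, p_asym,
      seed = 100 + s, rho0 = 2, trace = TRUE
    )
    mean(sim$trace$rho_after[sim$trace$second > 100])
  }, numeric(1))
  expect_gt(mean(means_asym), mean(means))
})

test_that("likelihood replay reproduces simulation exactly and is pure", {
  design <- sessionDesign("exp2", "PoorRich")
  session <- buildSession(design, seed = 7)
  p <- ref_asym_params()
  sim <- simulateSubject(session, p, seed = 3, trace = TRUE)

  rep_r <- replayLoglik(sim$log, p, engine = "r", trace = TRUE)
  expect_equal(rep_r$trace$rho_after, sim$trace$rho_after)
  expect_equal(rep_r$rho_final, sim$rho_final)

  rep_c1 <- replayLoglik(sim$log, p)
  rep_c2 <- replayLoglik(sim$log, p)
  expect_identical(rep_c1, rep_c2)
  expect_equal(rep_c1$loglik, rep_r$loglik)
  expect_equal(rep_c1$rho_final, rep_r$rho_final)

  # forced-trial likelihood terms can be excluded
  rep_nf <- replayLoglik(sim$log, p, include_forced = FALSE)
  expect_true(all(is.na(rep_nf$trial_loglik[sim$log$forced])))
  expect_gt(rep_nf$loglik, rep_c1$loglik)

  # malformed logs are rejected
  broken <- sim$log
  broken$t_start[10] <- broken$t_start[10] + 1
  expect_error(replayLoglik(broken, p), "malformed")
})

test_that("the asymmetric model nests the symmetric model exactly", {
  design <- sessionDesign("exp2", "RichPoor")
  session <- buildSession(design, seed = 13)
  sym <- subjectParams("symmetric", alpha = 0.02, beta0 = 0.5, beta1 = 0.08)
  asym <- subjectParams("asymmetric",
    alpha_pos = 0.02, alpha_neg = 0.02,
    beta0 = 0.5, beta1 = 0.08
  )
  sim_s <- simulateSubject(session, sym, seed = 21)
  sim_a <- simulateSubject(session, asym, seed = 21)
  expect_identical(sim_s$log$choice, sim_a$log$choice)
  ll_s <- replayLoglik(sim_s$log, sym)
  ll_a <- replayLoglik(sim_s$log, asym)
  expect_identical(ll_s$loglik, ll_a$loglik)
  expect_identical(ll_s$rho_final, ll_a$rho_final)
})

test_that("replay matches a hand-stepped oracle on a toy log", {
  toy <- make_toy_log(c("LDHR", "HDLR"), c("accept", "reject"))
  p <- subjectParams("asymmetric",
    alpha_pos = 0.5, alpha_neg = 0.1,
    beta0 = 0.5, beta1 = 0.1
  )
  want <- oracle_replay(toy, 0.5, 0.1, 0.5, 0.1, rho0 = 10)
  for (eng in c("cpp", "r")) {
    got <- replayLoglik(toy, p, rho0 = 10, engine = eng)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-12)
    expect_equal(got$rho_final, want$rho_final, tolerance = 1e-12)
  }
  # a missed trial contributes timeout seconds but no likelihood
  toy2 <- make_toy_log(c("LDHR", "HDLR"), c("missed", "reject"))
  want2 <- oracle_replay(toy2, 0.5, 0.1, 0.5, 0.1, rho0 = 10)
  got2 <- replayLoglik(toy2, p, rho0 = 10)
  expect_equal(got2$loglik, want2$loglik, tolerance = 1e-12)
  expect_true(is.na(got2$trial_loglik[1]))
})
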