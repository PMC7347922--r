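# Independent oracles and fixture builders used across the test files.

# Brute-force long-run-rate enumeration over acceptance sets, written
# independently of the package implementation.
oracle_best_policy <- function(cycle_counts, rewards, handlings, enc = 2) {
  k <- length(cycle_counts)
  best <- list(rate = -Inf, accept = NULL)
  for (m in 0:(2^k - 1)) {
    acc <- as.logical(intToBits(m)[1:k])
    gain <- sum(cycle_counts[acc] * rewards[acc])
    time <- sum(cycle_counts) * enc + sum(cycle_counts[acc] * handlings[acc])
    rate <- gain / time
    if (rate > best$rate + 1e-12 ||
      (abs(rate - best$rate) <= 1e-12 && sum(acc) > length(best$accept))) {
      best <- list(rate = rate, accept = names(cycle_counts)[acc])
    }
  }
  best
}

# Build a minimal but structurally valid trial log by hand.
# choices: vector of "accept"/"reject"/"missed"; options: labels.
make_toy_log <- function(options, choices,
                         forced = rep(FALSE, length(options)),
                         forced_dir = rep(NA_character_, length(options)),
                         env = rep("rich", length(options)),
                         block = rep(1L, length(options)),
                         experiment = "exp1", order = "RichPoor",
                         subject = "toy") {
  opts <- optionSet()
  t_of <- setNames(opts$handling_seconds, opts$label)
  r_of <- setNames(opts$reward_points, opts$label)
  n <- length(options)
  dur <- ifelse(choices == "accept", 2 + t_of[options],
    ifelse(choices == "reject", 2, 2 + 8)
  )
  t_end <- cumsum(dur)
  t_start <- t_end - dur
  data.frame(
    subject = subject, experiment = experiment, order = order,
    block = block, env = env, trial = seq_len(n), option = options,
    forced = forced, forced_dir = forced_dir, choice = choices,
    reward = ifelse(choices == "accept", r_of[options], 0),
    t_start = t_start, t_end = t_end,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Hand-stepped replay of the learning rule and softmax for a toy log;
# mirrors the model definition with explicit scalar arithmetic only.
oracle_replay <- function(log, alpha_pos, alpha_neg, beta0, beta1, rho0) {
  opts <- optionSet()
  t_of <- setNames(opts$handling_seconds, opts$label)
  r_of <- setNames(opts$reward_points, opts$label)
  rho <- rho0
  total <- 0
  for (i in seq_len(nrow(log))) {
    r <- r_of[[log$option[i]]]
    tt <- t_of[[log$option[i]]]
    rho <- rho + alpha_neg * (0 - rho) # encounter second 1
    rho <- rho + alpha_neg * (0 - rho) # encounter second 2
    p <- 1 / (1 + exp(beta0 - beta1 * (r - rho * tt)))
    if (log$choice[i] == "accept") {
      total <- total + log(p)
      for (s in seq_len(tt - 1)) rho <- rho + alpha_neg * (0 - rho)
      rho <- rho + alpha_neg * (0 - rho) # delay half of the reward second
      rho <- rho + alpha_pos * (r - rho) # reward half
    } else if (log$choice[i] == "reject") {
      total <- total + log(1 - p)
    } else {
      for (s in seq_len(8)) rho <- rho + alpha_neg * (0 - rho)
    }
  }
  list(loglik = total, rho_final = rho)
}

ref_asym_params <- function() {
  subjectParams("asymmetric",
    alpha_pos = 0.005, alpha_neg = 0.0016,
    beta0 = -1.8179, beta1 = 0.0748
  )
}
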