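#' Subject-level model parameters
#'
#' The Symmetric model has a single learning rate \code{alpha}; the
#' Asymmetric model splits it into \code{alpha_pos} (applied on seconds
#' where reward is delivered) and \code{alpha_neg} (applied on reward-free
#' seconds). \code{beta0} is the softmax intercept (positive values bias
#' towards rejecting) and \code{beta1} the sensitivity to the difference
#' between an option's reward and its opportunity cost (per point).
#'
#' @param model \code{"symmetric"} or \code{"asymmetric"}.
#' @param alpha Learning rate in (0,1) (symmetric model).
#' @param alpha_pos,alpha_neg Learning rates in (0,1) (asymmetric model).
#' @param beta0 Softmax intercept (unitless).
#' @param beta1 Softmax slope (per point).
#' @return A list of class \code{prey_params}.
#' @export
subjectParams <- function(model = c("asymmetric", "symmetric"),
                          alpha = NULL, alpha_pos = NULL, alpha_neg = NULL,
                          beta0 = 0, beta1 = 0.075) {
  model <- match.arg(model)
  if (model == "symmetric") {
    stopifnot(!is.null(alpha))
    alpha_pos <- alpha_neg <- alpha
  } else {
    stopifnot(!is.null(alpha_pos), !is.null(alpha_neg))
  }
  if (any(c(alpha_pos, alpha_neg) <= 0) || any(c(alpha_pos, alpha_neg) >= 1)) {
    stop("learning rates must lie strictly in (0, 1)")
  }
  structure(
    list(
      model = model, alpha_pos = alpha_pos, alpha_neg = alpha_neg,
      beta0 = beta0, beta1 = beta1
    ),
    class = "prey_params"
  )
}

#' @export
print.prey_params <- function(x, ...) {
  if (x$model == "symmetric") {
    cat(sprintf(
      "Symmetric model params: alpha=%.4g, beta0=%.4g, beta1=%.4g\n",
      x$alpha_pos, x$beta0, x$beta1
    ))
  } else {
    cat(sprintf(
      "Asymmetric model params: alpha+=%.4g, alpha-=%.4g, beta0=%.4g, beta1=%.4g\n",
      x$alpha_pos, x$alpha_neg, x$beta0, x$beta1
    ))
  }
  invisible(x)
}

#' Opportunity cost of handling an option
#'
#' The cost of the time an option consumes: the current reward-rate estimate
#' multiplied by the option's handling time, \eqn{c_i = \rho t_i}.
#'
#' @param rho Reward-rate estimate (points/second), non-negative.
#' @param t_i Handling time (seconds), positive.
#' @return Opportunity cost in points.
#' @export
opportunityCost <- function(rho, t_i) {
  if (any(rho < 0)) stop("rho must be non-negative")
  if (any(t_i <= 0)) stop("handling time must be positive")
  rho * t_i
}

#' One delta-rule update of the reward-rate estimate
#'
#' \eqn{\rho' = \rho + \alpha (r_t - \rho)}, where the learning rate is
#' \code{alpha_pos} when reward is delivered this second (\eqn{r_t > 0}) and
#' \code{alpha_neg} otherwise.
#'
#' @param rho Current estimate (points/second).
#' @param r_t Reward delivered this second (points; 0 on reward-free seconds).
#' @param params A \code{prey_params}.
#' @return A list (class \code{prey_update}) with \code{rho_before},
#'   \code{r_t}, \code{gate} (\code{"+"} or \code{"-"}), \code{delta} and
#'   \code{rho_after}.
#' @export
rateUpdate <- function(rho, r_t, params) {
  gate <- if (r_t > 0) "+" else "-"
  a <- if (r_t > 0) params$alpha_pos else params$alpha_neg
  delta <- r_t - rho
  structure(
    list(
      rho_before = rho, r_t = r_t, gate = gate, delta = delta,
      rho_after = rho + a * delta
    ),
    class = "prey_update"
  )
}

#' The final handling second: delay update then reward update
#'
#' Reward delivery shares its second with the last tick of the handling
#' delay, so that second is modelled as two consecutive updates: a
#' reward-free update (\eqn{\delta = 0 - \rho}) followed by a reward update
#' (\eqn{\delta = r_i - \rho'}). The order can be swapped; results are
#' reported as robust to this choice.
#'
#' @param rho Current estimate.
#' @param r_i Option reward (points), positive.
#' @param params A \code{prey_params}.
#' @param order \code{"delay_first"} (default) or \code{"reward_first"}.
#' @return A list of two \code{prey_update} steps, in application order.
#' @export
rewardSecondUpdate <- function(rho, r_i, params,
                               order = c("delay_first", "reward_first")) {
  order <- match.arg(order)
  stopifnot(r_i > 0)
  if (order == "delay_first") {
    u1 <- rateUpdate(rho, 0, params)
    u2 <- rateUpdate(u1$rho_after, r_i, params)
  } else {
    u1 <- rateUpdate(rho, r_i, params)
    u2 <- rateUpdate(u1$rho_after, 0, params)
  }
  list(u1, u2)
}

#' Softmax probability of accepting an option
#'
#' \deqn{P(accept) = 1 / (1 + \exp(\beta_0 - \beta_1 (r_i - c_i)))}
#' evaluated in a numerically stable form.
#'
#' @param r_i Option reward (points).
#' @param c_i Opportunity cost (points).
#' @param beta0 Intercept (positive = bias to reject).
#' @param beta1 Slope (per point).
#' @param log.p Return the log probability.
#' @return Acceptance probability (or its log).
#' @export
acceptProbability <- function(r_i, c_i, beta0, beta1, log.p = FALSE) {
  stats::plogis(beta1 * (r_i - c_i) - beta0, log.p = log.p)
}

# accept-all long-run rate of one environment cycle (points/second)
cycle_rate_accept_all <- function(env, design) {
  opts <- option_lookup(names(env$cycle))
  counts <- as.numeric(env$cycle)
  sum(counts * opts$reward_points) /
    sum(counts * (design$encounter_seconds + opts$handling_seconds))
}

#' Initial reward-rate estimate
#'
#' The rate estimate is initialised to the session's average arithmetic
#' reward rate: by default the accept-all rate of each block's cycle,
#' averaged arithmetically across blocks. This is a simplifying convention
#' (it avoids special-casing initial conditions), not a process claim.
#'
#' @param session A \code{prey_session} (or a \code{prey_design}).
#' @param policy \code{"accept_all"} (default) or \code{"mvt"}: which policy
#'   the notional average assumes.
#' @return Initial rate in points/second.
#' @export
initialRate <- function(session, policy = c("accept_all", "mvt")) {
  policy <- match.arg(policy)
  design <- if (inherits(session, "prey_design")) session else session$design
  envs <- lapply(
    design$env_names, environmentSpec,
    duration_seconds = design$duration_seconds
  )
  rates <- vapply(envs, function(e) {
    if (policy == "accept_all") {
      cycle_rate_accept_all(e, design)
    } else {
      mvtOptimalPolicy(e, design)$long_run_rate
    }
  }, numeric(1))
  mean(rates)
}

# ---- simulation -------------------------------------------------------------

empty_trace <- function() {
  data.frame(
    second = integer(0), r_t = numeric(0), gate = character(0),
    rho_before = numeric(0), delta = numeric(0), rho_after = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Simulate one subject on a session
#'
#' Advances a 1-s session clock through the blocks in order. Every elapsed
#' second emits a reward-free delta-rule update except the final handling
#' second of an accepted option, which is modelled as a delay update followed
#' by a reward update. The accept/reject choice is sampled from the softmax
#' rule at the final (2nd) second of the encounter screen, using the rate
#' estimate after that second's update; forced trials execute their mandated
#' direction (and consume no randomness). The estimate carries across blocks
#' with no reset. A new trial starts only while the block clock is inside the
#' block's duration; the last trial may run past the boundary and the next
#' block then starts at its end.
#'
#' @param session A \code{prey_session}.
#' @param params A \code{prey_params}.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param rho0 Initial rate estimate; default \code{initialRate(session)}.
#' @param trace Record the per-second update trace (slower; default TRUE).
#' @param subject Subject identifier stored in the log.
#' @param engine \code{"cpp"} (compiled, default when \code{trace = FALSE})
#'   or \code{"r"} (reference implementation; used automatically when a trace
#'   is requested). Both engines consume the RNG stream identically, so the
#'   same seed gives the same log either way.
#' @return A list of class \code{prey_sim} with \code{log} (a trial-log data
#'   frame, see \code{\link{writeTrialLogs}} for the column dialect) and
#'   \code{trace} (per-update-step data frame, or NULL if \code{trace =
#'   FALSE}). The generating parameters are attached to the log as attribute
#'   \code{"true_params"}.
#' @export
simulateSubject <- function(session, params, seed = NULL, rho0 = NULL,
                            trace = FALSE, subject = "s01",
                            engine = if (trace) "r" else "cpp") {
  stopifnot(inherits(session, "prey_session"), inherits(params, "prey_params"))
  engine <- match.arg(engine, c("cpp", "r"))
  if (trace && engine == "cpp") stop("trace recording requires engine = 'r'")
  design <- session$design
  if (is.null(rho0)) rho0 <- initialRate(session)
  stopifnot(rho0 >= 0)
  if (engine == "cpp") {
    return(simulate_subject_cpp(session, params, seed, rho0, subject))
  }

  with_local_seed(seed, {
    ap <- params$alpha_pos
    an <- params$alpha_neg
    enc <- design$encounter_seconds
    opts_all <- optionSet()
    r_of <- stats::setNames(opts_all$reward_points, opts_all$label)
    t_of <- stats::setNames(opts_all$handling_seconds, opts_all$label)

    rho <- rho0
    t_clock <- 0
    rows <- vector("list", 0L)
    tr <- if (trace) vector("list", 0L) else NULL
    trial_no <- 0L
    block_end <- 0

    for (b in seq_along(session$blocks)) {
      blk <- session$blocks[[b]]
      plan <- blk$plan
      block_end <- block_end + blk$env$duration_seconds
      i <- 0L
      while (t_clock < block_end) {
        i <- i + 1L
        if (i > nrow(plan)) break # plan exhausted (cannot happen by sizing)
        trial_no <- trial_no + 1L
        lab <- plan$option[i]
        r_i <- r_of[[lab]]
        t_i <- t_of[[lab]]
        t_start <- t_clock

        # encounter seconds: reward-free updates
        rho_seq <- rho * (1 - an)^(seq_len(enc))
        if (trace) {
          before <- c(rho, rho_seq[-enc])
          tr[[length(tr) + 1L]] <- data.frame(
            second = t_start + seq_len(enc), r_t = 0, gate = "-",
            rho_before = before, delta = -before, rho_after = rho_seq,
            stringsAsFactors = FALSE
          )
        }
        rho <- rho_seq[enc]

        p_acc <- acceptProbability(r_i, rho * t_i, params$beta0, params$beta1)
        if (plan$forced[i]) {
          choice <- plan$forced_dir[i]
        } else {
          choice <- if (stats::runif(1) < p_acc) "accept" else "reject"
        }

        if (choice == "accept") {
          # t_i - 1 reward-free handling seconds, then the shared final second
          if (t_i > 1) {
            rho_seq <- rho * (1 - an)^(seq_len(t_i - 1))
            if (trace) {
              before <- c(rho, rho_seq[-(t_i - 1)])
              tr[[length(tr) + 1L]] <- data.frame(
                second = t_start + enc + seq_len(t_i - 1), r_t = 0, gate = "-",
                rho_before = before, delta = -before, rho_after = rho_seq,
                stringsAsFactors = FALSE
              )
            }
            rho <- rho_seq[t_i - 1]
          }
          us <- rewardSecondUpdate(rho, r_i, params)
          if (trace) {
            tr[[length(tr) + 1L]] <- data.frame(
              second = t_start + enc + t_i,
              r_t = c(us[[1]]$r_t, us[[2]]$r_t),
              gate = c(us[[1]]$gate, us[[2]]$gate),
              rho_before = c(us[[1]]$rho_before, us[[2]]$rho_before),
              delta = c(us[[1]]$delta, us[[2]]$delta),
              rho_after = c(us[[1]]$rho_after, us[[2]]$rho_after),
              stringsAsFactors = FALSE
            )
          }
          rho <- us[[2]]$rho_after
          reward <- r_i
          t_end <- t_start + enc + t_i
        } else { # reject (synthetic subjects never miss)
          reward <- 0
          t_end <- t_start + enc
        }

        rows[[trial_no]] <- data.frame(
          subject = subject, experiment = design$experiment,
          order = design$order, block = b, env = blk$env$name,
          trial = trial_no, option = lab, forced = plan$forced[i],
          forced_dir = plan$forced_dir[i], choice = choice, reward = reward,
          t_start = t_start, t_end = t_end, stringsAsFactors = FALSE
        )
        t_clock <- t_end
      }
    }

    log <- do.call(rbind, rows)
    attr(log, "true_params") <- params
    attr(log, "rho0") <- rho0
    structure(
      list(
        log = log,
        trace = if (trace) do.call(rbind, tr) else NULL,
        rho_final = rho
      ),
      class = "prey_sim"
    )
  })
}

# Compiled-path simulator: flattens the session's offer plans into vectors,
# runs the per-trial recursion in C++ (consuming R's RNG), and assembles the
# trial-log data frame vectorised.
simulate_subject_cpp <- function(session, params, seed, rho0, subject) {
  design <- session$design
  opts_all <- optionSet()
  r_of <- stats::setNames(opts_all$reward_points, opts_all$label)
  t_of <- stats::setNames(opts_all$handling_seconds, opts_all$label)

  plans <- lapply(session$blocks, `[[`, "plan")
  n_per <- vapply(plans, nrow, integer(1))
  option <- unlist(lapply(plans, `[[`, "option"), use.names = FALSE)
  forced <- unlist(lapply(plans, `[[`, "forced"), use.names = FALSE)
  forced_dir <- unlist(lapply(plans, `[[`, "forced_dir"), use.names = FALSE)
  block_of <- rep(seq_along(plans), times = n_per)
  durs <- vapply(session$blocks, function(b) b$env$duration_seconds, numeric(1))
  block_end <- cumsum(durs)
  fd_code <- ifelse(is.na(forced_dir), NA_integer_,
    ifelse(forced_dir == "accept", 1L, 0L)
  )

  res <- with_local_seed(seed, simulate_core(
    as.numeric(r_of[option]), as.numeric(t_of[option]),
    forced, fd_code, block_end, block_of,
    params$alpha_pos, params$alpha_neg, params$beta0, params$beta1,
    rho0, design$encounter_seconds
  ))

  keep <- res$used == 1L
  choice <- ifelse(res$accept[keep] == 1L, "accept", "reject")
  log <- data.frame(
    subject = subject, experiment = design$experiment, order = design$order,
    block = block_of[keep],
    env = vapply(
      session$blocks, function(b) b$env$name, character(1)
    )[block_of[keep]],
    trial = seq_len(sum(keep)), option = option[keep], forced = forced[keep],
    forced_dir = forced_dir[keep], choice = choice,
    reward = ifelse(choice == "accept", as.numeric(r_of[option[keep]]), 0),
    t_start = res$t_start[keep], t_end = res$t_end[keep],
    stringsAsFactors = FALSE
  )
  attr(log, "true_params") <- params
  attr(log, "rho0") <- rho0
  structure(
    list(log = log, trace = NULL, rho_final = res$rho_final),
    class = "prey_sim"
  )
}

# ---- likelihood replay ------------------------------------------------------

validate_trial_log <- function(log, design) {
  need <- c(
    "block", "option", "forced", "forced_dir", "choice", "reward",
    "t_start", "t_end"
  )
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("trial log missing columns: ", paste(miss, collapse = ", "))
  opts <- option_lookup(log$option)
  enc <- design$encounter_seconds
  expected <- ifelse(
    log$choice == "accept", enc + opts$handling_seconds,
    ifelse(log$choice == "reject", enc, enc + design$timeout_seconds)
  )
  if (any(log$t_end - log$t_start != expected)) {
    stop("malformed trial log: trial durations inconsistent with choices")
  }
  same_block <- diff(log$block) == 0
  gaps <- diff(log$t_start) != (log$t_end - log$t_start)[-nrow(log)]
  if (any(same_block & gaps)) {
    stop("malformed trial log: time gaps between consecutive trials")
  }
  invisible(TRUE)
}

design_from_log <- function(log) {
  sessionDesign(experiment = log$experiment[1], order = log$order[1])
}

#' Deterministic likelihood replay of a trial log
#'
#' Rebuilds the per-second reward-rate trajectory implied by a subject's
#' recorded experience (including forced trials and the elapsed seconds of
#' missed responses) and accumulates the log-likelihood of the recorded
#' accept/reject choices under the softmax rule. Missed trials contribute
#' their timeout seconds to the rate trajectory but no likelihood term;
#' forced-choice trials contribute a likelihood term by default (they were
#' not excluded from model fitting), controllable via \code{include_forced}.
#'
#' @param log A trial-log data frame (one subject).
#' @param params A \code{prey_params}.
#' @param rho0 Initial rate estimate; default reconstructed from the log's
#'   experiment/order columns via \code{\link{initialRate}}.
#' @param include_forced Include forced trials' choices in the likelihood.
#' @param engine \code{"cpp"} (compiled, fast) or \code{"r"} (reference
#'   implementation; required for \code{trace = TRUE}).
#' @param trace Also return the per-second update trace (\code{engine="r"}).
#' @return A list of class \code{prey_loglik}: \code{loglik} (total),
#'   \code{trial_loglik} (per trial; NA for excluded trials), \code{rho_final}
#'   and optionally \code{trace}.
#' @export
replayLoglik <- function(log, params, rho0 = NULL, include_forced = TRUE,
                         engine = c("cpp", "r"), trace = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "prey_params"))
  design <- design_from_log(log)
  validate_trial_log(log, design)
  if (is.null(rho0)) rho0 <- initialRate(design)
  opts <- option_lookup(log$option)
  choice_code <- match(log$choice, c("reject", "accept", "missed")) - 1L
  if (anyNA(choice_code)) stop("unknown choice value in trial log")
  include <- (!log$forced | include_forced) & log$choice != "missed"

  if (engine == "cpp" && !trace) {
    res <- replay_core(
      opts$reward_points, opts$handling_seconds, choice_code, include,
      params$alpha_pos, params$alpha_neg, params$beta0, params$beta1,
      rho0, design$encounter_seconds, design$timeout_seconds
    )
    out <- list(
      loglik = res$loglik, trial_loglik = res$trial_loglik,
      rho_final = res$rho_final
    )
    class(out) <- "prey_loglik"
    return(out)
  }

  ap <- params$alpha_pos
  an <- params$alpha_neg
  enc <- design$encounter_seconds
  rho <- rho0
  n <- nrow(log)
  ll <- rep(NA_real_, n)
  tr <- if (trace) vector("list", 0L) else NULL

  zero_run <- function(rho, k, t0) {
    rho_seq <- rho * (1 - an)^(seq_len(k))
    if (trace) {
      before <- c(rho, rho_seq[-k])
      tr[[length(tr) + 1L]] <<- data.frame(
        second = t0 + seq_len(k), r_t = 0, gate = "-",
        rho_before = before, delta = -before, rho_after = rho_seq,
        stringsAsFactors = FALSE
      )
    }
    rho_seq[k]
  }

  for (i in seq_len(n)) {
    r_i <- opts$reward_points[i]
    t_i <- opts$handling_seconds[i]
    t0 <- log$t_start[i]
    rho <- zero_run(rho, enc, t0)
    if (include[i]) {
      lp <- acceptProbability(r_i, rho * t_i, params$beta0, params$beta1,
        log.p = TRUE
      )
      lq <- stats::plogis(params$beta0 - params$beta1 * (r_i - rho * t_i),
        log.p = TRUE
      )
      ll[i] <- if (choice_code[i] == 1L) lp else lq
    }
    if (choice_code[i] == 1L) { # accept
      if (t_i > 1) rho <- zero_run(rho, t_i - 1, t0 + enc)
      us <- rewardSecondUpdate(rho, r_i, params)
      if (trace) {
        tr[[length(tr) + 1L]] <- data.frame(
          second = t0 + enc + t_i,
          r_t = c(us[[1]]$r_t, us[[2]]$r_t),
          gate = c(us[[1]]$gate, us[[2]]$gate),
          rho_before = c(us[[1]]$rho_before, us[[2]]$rho_before),
          delta = c(us[[1]]$delta, us[[2]]$delta),
          rho_after = c(us[[1]]$rho_after, us[[2]]$rho_after),
          stringsAsFactors = FALSE
        )
      }
      rho <- us[[2]]$rho_after
    } else if (choice_code[i] == 2L) { # missed: timeout seconds
      rho <- zero_run(rho, design$timeout_seconds, t0 + enc)
    }
  }

  out <- list(
    loglik = sum(ll, na.rm = TRUE), trial_loglik = ll, rho_final = rho,
    trace = if (trace) do.call(rbind, tr) else NULL
  )
  class(out) <- "prey_loglik"
  out
}
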