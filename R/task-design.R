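#' The four prey options
#'
#' Each option delivers one of two reward levels (20 or 80 points) after one
#' of two handling delays (2 or 8 s, inclusive of the 1-s reward display).
#' The labels encode delay then reward: e.g. \code{LDHR} = low delay, high
#' reward (the best option), \code{HDLR} = high delay, low reward (the
#' worst).
#'
#' @return A data frame with columns \code{label}, \code{reward_points},
#'   \code{handling_seconds} and \code{category} (best / intermediate /
#'   worst), one row per option.
#' @export
optionSet <- function() {
  data.frame(
    label = c("LDHR", "LDLR", "HDHR", "HDLR"),
    reward_points = c(80, 20, 80, 20),
    handling_seconds = c(2, 2, 8, 8),
    category = c("best", "intermediate", "intermediate", "worst"),
    stringsAsFactors = FALSE
  )
}

option_lookup <- function(labels) {
  opts <- optionSet()
  idx <- match(labels, opts$label)
  if (anyNA(idx)) {
    stop("unknown option label(s): ", paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  opts[idx, , drop = FALSE]
}

#' Profitability of an option
#'
#' Reward per second of handling: \eqn{r_i / t_i}. The two intermediate
#' options (LDLR: 20 points / 2 s; HDHR: 80 points / 8 s) share an identical
#' profitability of 10 points per second.
#'
#' @param option An option label (e.g. \code{"LDLR"}) or a one-row data frame
#'   with columns \code{reward_points} and \code{handling_seconds}.
#' @return Profitability in points per second.
#' @export
profitability <- function(option) {
  if (is.character(option)) option <- option_lookup(option)
  if (any(option$handling_seconds <= 0)) {
    stop("invalid option spec: handling_seconds must be positive")
  }
  option$reward_points / option$handling_seconds
}

#' Environment specification
#'
#' An environment is defined by the composition of its offer cycle. The rich
#' environment presents the best option (LDHR) four times per seven-trial
#' cycle, the poor environment the worst option (HDLR) four times; the other
#' options appear once each. The degenerate \code{hdlr_only} environment (used
#' as the middle block of Experiment 3) offers only the worst option.
#'
#' @param name One of \code{"rich"}, \code{"poor"}, \code{"hdlr_only"}.
#' @param duration_seconds Block duration in seconds.
#' @return A list of class \code{prey_env} with fields \code{name},
#'   \code{cycle} (named counts per option over one cycle) and
#'   \code{duration_seconds}.
#' @export
environmentSpec <- function(name = c("rich", "poor", "hdlr_only"),
                            duration_seconds = 600) {
  name <- match.arg(name)
  stopifnot(duration_seconds > 0)
  cycle <- switch(name,
    rich = c(LDHR = 4L, LDLR = 1L, HDHR = 1L, HDLR = 1L),
    poor = c(LDHR = 1L, LDLR = 1L, HDHR = 1L, HDLR = 4L),
    hdlr_only = c(HDLR = 1L)
  )
  structure(
    list(name = name, cycle = cycle, duration_seconds = duration_seconds),
    class = "prey_env"
  )
}

#' Session design
#'
#' Fixed timing and structure of one experimental session. Experiments 1 and 2
#' comprise a rich and a poor block (15 and 10 min per block respectively);
#' Experiment 3 inserts a 10-min worst-option-only block between them. A
#' quarter of trials are forced-choice attention checks; participants have 2 s
#' to respond to each offer and face an 8-s timeout after a missed response.
#'
#' @param experiment \code{"exp1"}, \code{"exp2"} or \code{"exp3"}.
#' @param order Block order: \code{"RichPoor"} or \code{"PoorRich"}. In
#'   Experiment 3 the worst-only block always sits between the two.
#' @param encounter_seconds Response window per offer (seconds).
#' @param forced_fraction Fraction of trials that are forced choices.
#' @param forced_accept_prob Probability a forced trial mandates acceptance
#'   (the direction split is not constrained by the task; default 0.5).
#' @param timeout_seconds Timeout after a missed response (seconds).
#' @return A list of class \code{prey_design}.
#' @export
sessionDesign <- function(experiment = c("exp1", "exp2", "exp3"),
                          order = c("RichPoor", "PoorRich"),
                          encounter_seconds = 2,
                          forced_fraction = 0.25,
                          forced_accept_prob = 0.5,
                          timeout_seconds = 8) {
  experiment <- match.arg(experiment)
  order <- match.arg(order)
  stopifnot(
    encounter_seconds > 0,
    forced_fraction >= 0, forced_fraction <= 1,
    forced_accept_prob >= 0, forced_accept_prob <= 1
  )
  dur <- if (experiment == "exp1") 900 else 600
  envs <- switch(order,
    RichPoor = c("rich", "poor"),
    PoorRich = c("poor", "rich")
  )
  if (experiment == "exp3") envs <- c(envs[1], "hdlr_only", envs[2])
  structure(
    list(
      experiment = experiment, order = order, env_names = envs,
      duration_seconds = dur, encounter_seconds = encounter_seconds,
      forced_fraction = forced_fraction,
      forced_accept_prob = forced_accept_prob,
      timeout_seconds = timeout_seconds
    ),
    class = "prey_design"
  )
}

#' @export
print.prey_design <- function(x, ...) {
  cat("Prey-selection session design (", x$experiment, ", ", x$order, ")\n",
    sep = ""
  )
  cat("  blocks: ", paste(x$env_names, collapse = " -> "),
    " (", x$duration_seconds, " s each)\n",
    sep = ""
  )
  cat("  encounter ", x$encounter_seconds, " s, forced fraction ",
    x$forced_fraction, ", timeout ", x$timeout_seconds, " s\n",
    sep = ""
  )
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream untouched).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build an offer plan for one block
#'
#' Generates the ordered offer stream for a block: whole cycles are drawn as
#' independent random shuffles of the environment's cycle composition, and
#' enough cycles are generated to fill the block duration even under an
#' all-reject policy. Forced-choice trials are assigned by deterministic
#' quota: with the default forced fraction of 0.25, exactly one trial in every
#' consecutive four-trial window is forced, its position uniform within the
#' window, so the forced fraction is exact up to the block remainder. Forced
#' directions (accept/reject) are drawn independently.
#'
#' @param env A \code{prey_env}.
#' @param design A \code{prey_design}.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A data frame of class \code{prey_plan} with columns \code{option},
#'   \code{forced} (logical) and \code{forced_dir} (\code{"accept"},
#'   \code{"reject"} or \code{NA}).
#' @export
buildOfferPlan <- function(env, design, seed = NULL) {
  stopifnot(inherits(env, "prey_env"), inherits(design, "prey_design"))
  with_local_seed(seed, {
    # worst case one offer per encounter_seconds, plus one spare cycle
    n_needed <- ceiling(env$duration_seconds / design$encounter_seconds)
    cyc <- rep(names(env$cycle), times = env$cycle)
    n_cycles <- ceiling(n_needed / length(cyc)) + 1L
    offers <- unlist(lapply(seq_len(n_cycles), function(i) sample(cyc)))
    n <- length(offers)

    forced <- logical(n)
    if (design$forced_fraction > 0) {
      win <- round(1 / design$forced_fraction)
      per_win <- 1L
      starts <- seq(1L, n, by = win)
      for (s in starts) {
        w <- s:min(s + win - 1L, n)
        if (length(w) == win) {
          forced[w[sample.int(length(w), per_win)]] <- TRUE
        }
      }
    }
    forced_dir <- rep(NA_character_, n)
    nf <- sum(forced)
    if (nf > 0) {
      forced_dir[forced] <- ifelse(
        stats::runif(nf) < design$forced_accept_prob, "accept", "reject"
      )
    }
    structure(
      data.frame(
        option = offers, forced = forced, forced_dir = forced_dir,
        stringsAsFactors = FALSE
      ),
      class = c("prey_plan", "data.frame")
    )
  })
}

#' Build a full session
#'
#' Assembles the ordered blocks of a session: each block couples an
#' environment with a freshly generated offer plan. The same seed always
#' yields the same session.
#'
#' @param design A \code{prey_design}.
#' @param seed Optional integer seed.
#' @return A list of class \code{prey_session} with fields \code{design} and
#'   \code{blocks}; each block is a list with \code{env} and \code{plan}.
#' @export
buildSession <- function(design, seed = NULL) {
  stopifnot(inherits(design, "prey_design"))
  with_local_seed(seed, {
    blocks <- lapply(design$env_names, function(nm) {
      env <- environmentSpec(nm, duration_seconds = design$duration_seconds)
      list(env = env, plan = buildOfferPlan(env, design))
    })
    structure(list(design = design, blocks = blocks), class = "prey_session")
  })
}

#' Optimal acceptance policy under the Marginal Value Theorem
#'
#' Enumerates every acceptance set over the options present in the
#' environment's cycle and computes each set's long-run reward rate: total
#' accepted reward per cycle divided by total time per cycle (every offer
#' consumes the encounter window; accepted offers additionally consume their
#' handling time). Returns the rate-maximising set and verifies that it is
#' MVT-consistent: an option is in the set if and only if
#' \eqn{r_i \ge \rho^* t_i} (ties accepted).
#'
#' @param env A \code{prey_env}.
#' @param design A \code{prey_design} (supplies the encounter duration).
#' @return A list of class \code{prey_policy} with fields \code{accept}
#'   (labels of accepted options), \code{long_run_rate} (points/second) and
#'   \code{mvt_consistent}.
#' @export
mvtOptimalPolicy <- function(env, design) {
  stopifnot(inherits(env, "prey_env"), inherits(design, "prey_design"))
  labels <- names(env$cycle)
  if (length(labels) == 0) stop("empty environment")
  opts <- option_lookup(labels)
  counts <- as.numeric(env$cycle)
  enc <- design$encounter_seconds

  k <- length(labels)
  best_rate <- -Inf
  best_set <- logical(k)
  for (mask in 0:(2^k - 1)) {
    acc <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    reward <- sum(counts[acc] * opts$reward_points[acc])
    time <- sum(counts) * enc + sum(counts[acc] * opts$handling_seconds[acc])
    rate <- reward / time
    # prefer the larger set on rate ties (tied options are accepted)
    if (rate > best_rate + 1e-12 ||
      (abs(rate - best_rate) <= 1e-12 && sum(acc) > sum(best_set))) {
      best_rate <- rate
      best_set <- acc
    }
  }
  should_accept <- opts$reward_points >= best_rate * opts$handling_seconds - 1e-9
  structure(
    list(
      accept = labels[best_set],
      long_run_rate = best_rate,
      mvt_consistent = identical(best_set, should_accept)
    ),
    class = "prey_policy"
  )
}

#' @export
print.prey_policy <- function(x, ...) {
  cat("MVT-optimal policy: accept {", paste(x$accept, collapse = ", "),
    "} at ", format(x$long_run_rate, digits = 4), " points/s",
    if (!x$mvt_consistent) " [NOT MVT-consistent]", "\n",
    sep = ""
  )
  invisible(x)
}
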