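# Gaussian prior helper: prior is list(mean, cov); precompute what the
# objective and sampling need.
prior_machinery <- function(prior) {
  m <- prior$mean
  cov <- prior$cov
  if (is.null(dim(cov))) cov <- diag(cov, length(m))
  ch <- chol(cov)
  prec <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  d <- length(m)
  list(
    mean = m, cov = cov, chol = ch, prec = prec,
    log_norm = -0.5 * (d * log(2 * pi) + logdet), d = d
  )
}

log_prior_density <- function(theta, pm) {
  dd <- theta - pm$mean
  pm$log_norm - 0.5 * sum(dd * (pm$prec %*% dd))
}

# precompute the per-trial arrays replay_core needs, once per subject
subject_replay_data <- function(log, include_forced = TRUE) {
  design <- design_from_log(log)
  validate_trial_log(log, design)
  opts <- option_lookup(log$option)
  choice_code <- match(log$choice, c("reject", "accept", "missed")) - 1L
  list(
    r_i = opts$reward_points, t_i = opts$handling_seconds,
    choice = choice_code,
    include = (!log$forced | include_forced) & log$choice != "missed",
    rho0 = initialRate(design),
    enc = design$encounter_seconds, timeout = design$timeout_seconds
  )
}

replay_ll_fast <- function(dat, theta, model) {
  if (model == "symmetric") {
    ap <- an <- plogis(theta[1])
    b0 <- theta[2]
    b1 <- theta[3]
  } else {
    ap <- plogis(theta[1])
    an <- plogis(theta[2])
    b0 <- theta[3]
    b1 <- theta[4]
  }
  replay_core(
    dat$r_i, dat$t_i, dat$choice, dat$include, ap, an, b0, b1,
    dat$rho0, dat$enc, dat$timeout
  )$loglik
}

#' MAP fit of one subject under a Gaussian prior
#'
#' Maximizes the replay log-likelihood plus the log Gaussian prior density in
#' transformed parameter space, from several starting points (the prior mean
#' plus random draws from the prior), and returns the best optimum together
#' with a finite-difference Hessian of the negative log posterior at the MAP
#' and the Laplace approximation to the subject's log marginal likelihood.
#'
#' @param log A single-subject trial-log data frame.
#' @param prior List with \code{mean} (named vector, transformed space) and
#'   \code{cov} (covariance matrix, or a vector of variances).
#' @param model \code{"symmetric"} or \code{"asymmetric"}.
#' @param restarts Number of optimizer starts.
#' @param seed Optional seed for the restart draws.
#' @param include_forced Include forced-trial choices in the likelihood.
#' @param start Optional extra warm-start vector (used first).
#' @param hess_step Finite-difference step for the Hessian.
#' @return A list of class \code{prey_fit}: \code{par_t} (transformed MAP),
#'   \code{params} (natural space), \code{loglik}, \code{logpost},
#'   \code{hessian}, \code{hess_inv}, \code{laplace_logml},
#'   \code{convergence} (0 = clean) and \code{ridge} (Hessian
#'   regularization applied, normally 0).
# negative-log-posterior objective with analytic gradient (natural-space
# gradient from the compiled core, chained through the logit transforms);
# value and gradient at the same point share one replay.
make_objective <- function(dat, model, pm) {
  cache <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(invisible())
    }
    if (model == "symmetric") {
      ap <- an <- plogis(theta[1])
      b0 <- theta[2]
      b1 <- theta[3]
    } else {
      ap <- plogis(theta[1])
      an <- plogis(theta[2])
      b0 <- theta[3]
      b1 <- theta[4]
    }
    res <- replay_grad_core(
      dat$r_i, dat$t_i, dat$choice, dat$include, ap, an, b0, b1,
      dat$rho0, dat$enc, dat$timeout
    )
    g <- res$grad
    gt <- if (model == "symmetric") {
      c((g[1] + g[2]) * ap * (1 - ap), g[3], g[4])
    } else {
      c(g[1] * ap * (1 - ap), g[2] * an * (1 - an), g[3], g[4])
    }
    dd <- theta - pm$mean
    pd <- as.numeric(pm$prec %*% dd)
    cache$theta <- theta
    cache$value <- -res$loglik - (pm$log_norm - 0.5 * sum(dd * pd))
    cache$grad <- -gt + pd
    invisible()
  }
  list(
    fn = function(theta) {
      eval_at(theta)
      if (is.finite(cache$value)) cache$value else 1e10
    },
    gr = function(theta) {
      eval_at(theta)
      g <- cache$grad
      g[!is.finite(g)] <- 0
      g
    }
  )
}

#' @export
mapFitSubject <- function(log, prior, model = c("asymmetric", "symmetric"),
                          restarts = 5, seed = NULL, include_forced = TRUE,
                          start = NULL, hess_step = 1e-4) {
  model <- match.arg(model)
  pm <- prior_machinery(prior)
  stopifnot(pm$d == length(param_names(model)))
  dat <- subject_replay_data(log, include_forced)
  obj <- make_objective(dat, model, pm)
  f <- obj$fn

  starts <- list(pm$mean)
  if (!is.null(start)) starts <- c(list(start), starts)
  n_extra <- max(0L, restarts - length(starts))
  if (n_extra > 0) {
    extra <- with_local_seed(seed, lapply(seq_len(n_extra), function(i) {
      pm$mean + drop(crossprod(pm$chol, rnorm(pm$d)))
    }))
    starts <- c(starts, extra)
  }

  best <- NULL
  conv <- 1L
  for (s in starts) {
    opt <- tryCatch(
      optim(s, f, obj$gr, method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence
    }
  }
  if (is.null(best)) stop("all optimizer restarts failed for this subject")
  # logpost at MAP must not fall below any initialization value
  theta <- best$par

  H <- optimHess(theta, f, obj$gr,
    control = list(ndeps = rep(hess_step, pm$d))
  )
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) <= 1e-8) {
    ridge <- abs(min(ev)) + 1e-6
    H <- H + diag(ridge, pm$d)
  }
  Hinv <- chol2inv(chol(H))
  logpost <- -best$value
  ll <- replay_ll_fast(dat, theta, model)
  names(theta) <- param_names(model)
  structure(
    list(
      par_t = theta, params = vectorToParams(theta, model),
      loglik = ll, logpost = logpost,
      hessian = H, hess_inv = Hinv,
      laplace_logml = logpost + 0.5 * pm$d * log(2 * pi) -
        0.5 * as.numeric(determinant(H, logarithm = TRUE)$modulus),
      convergence = conv, ridge = ridge
    ),
    class = "prey_fit"
  )
}

default_em_init <- function(model) {
  if (model == "symmetric") {
    list(
      mean = c(logit_alpha = qlogis(0.05), beta0 = 0, beta1 = 0.05),
      sd = c(logit_alpha = 2, beta0 = 2, beta1 = 0.1)
    )
  } else {
    list(
      mean = c(
        logit_alpha_pos = qlogis(0.05), logit_alpha_neg = qlogis(0.05),
        beta0 = 0, beta1 = 0.05
      ),
      sd = c(
        logit_alpha_pos = 2, logit_alpha_neg = 2, beta0 = 2, beta1 = 0.1
      )
    )
  }
}

cohort_log_list <- function(cohort) {
  if (inherits(cohort, "prey_cohort")) {
    logs <- lapply(cohort$subjects, `[[`, "log")
    names(logs) <- vapply(cohort$subjects, `[[`, character(1), "id")
    logs
  } else if (is.data.frame(cohort)) {
    split_idx <- split(seq_len(nrow(cohort)), cohort$subject)
    lapply(split_idx, function(i) {
      out <- cohort[i, ]
      rownames(out) <- NULL
      out
    })
  } else {
    logs <- cohort
    if (is.null(names(logs))) {
      names(logs) <- vapply(logs, function(l) l$subject[1], character(1))
    }
    logs
  }
}

#' Hierarchical empirical-Bayes fit by Expectation Maximization
#'
#' Alternates subject-level MAP estimation with Laplace approximation
#' (E-step) and a closed-form update of the group-level Gaussian mean and
#' (diagonal) covariance (M-step): the group variance of each parameter is
#' the mean over subjects of squared deviation of the MAP from the group
#' mean plus the subject's Laplace posterior variance. Iterates until the
#' largest group-mean change falls below \code{tol}. The covariance of the
#' group means themselves (used for the learning-bias contrast) is estimated
#' with full off-diagonal structure from the MAPs and Laplace covariances.
#'
#' @param cohort A \code{prey_cohort}, a multi-subject trial-log data frame,
#'   or a named list of single-subject logs.
#' @param model \code{"symmetric"} or \code{"asymmetric"}.
#' @param tol Convergence tolerance on group means.
#' @param max_iter Maximum EM iterations.
#' @param restarts Optimizer starts per subject on the first iteration
#'   (later iterations warm-start from the previous MAP).
#' @param seed Optional seed for restart draws.
#' @param init Optional initial prior, list(mean, sd); defaults to a broad
#'   prior.
#' @param include_forced Include forced-trial choices in likelihoods.
#' @return A list of class \code{prey_group_fit}: \code{mean}, \code{sd}
#'   (group prior), \code{mean_cov} (covariance of the group means),
#'   \code{subject_fits}, \code{objective_trace} (sum of Laplace log
#'   marginal likelihoods per iteration), \code{n_iter}, \code{converged}.
#' @export
emFit <- function(cohort, model = c("asymmetric", "symmetric"),
                  tol = 1e-3, max_iter = 200, restarts = 5, seed = NULL,
                  init = NULL, include_forced = TRUE) {
  model <- match.arg(model)
  logs <- cohort_log_list(cohort)
  n <- length(logs)
  if (n < 2) stop("EM fitting requires at least 2 subjects")
  if (is.null(init)) init <- default_em_init(model)
  nms <- param_names(model)
  mu <- init$mean[nms]
  sig2 <- (init$sd[nms])^2
  d <- length(nms)

  warm <- vector("list", n)
  fits <- vector("list", n)
  obj_trace <- numeric(0)
  converged <- FALSE
  it <- 0L

  with_local_seed(seed, {
    while (it < max_iter) {
      it <- it + 1L
      prior <- list(mean = mu, cov = diag(sig2, d))
      for (k in seq_len(n)) {
        fits[[k]] <- mapFitSubject(
          logs[[k]], prior, model,
          restarts = if (it == 1L) restarts else 1L,
          include_forced = include_forced,
          start = warm[[k]]
        )
        warm[[k]] <- fits[[k]]$par_t
      }
      maps <- t(vapply(fits, `[[`, numeric(d), "par_t"))
      mu_new <- colMeans(maps)
      hinv_diag <- t(vapply(fits, function(f) diag(f$hess_inv), numeric(d)))
      sig2 <- colMeans(sweep(maps, 2, mu_new)^2 + hinv_diag) + 1e-8
      obj_trace <- c(obj_trace, sum(vapply(
        fits, `[[`, numeric(1), "laplace_logml"
      )))
      delta <- max(abs(mu_new - mu))
      mu <- mu_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations; returning best iterate")
  }

  maps <- t(vapply(fits, `[[`, numeric(d), "par_t"))
  mean_cov <- matrix(0, d, d, dimnames = list(nms, nms))
  for (k in seq_len(n)) {
    dd <- maps[k, ] - mu
    mean_cov <- mean_cov + outer(dd, dd) + fits[[k]]$hess_inv
  }
  mean_cov <- mean_cov / n^2

  names(fits) <- names(logs)
  structure(
    list(
      model = model, mean = mu, sd = sqrt(sig2),
      mean_cov = mean_cov, subject_fits = fits,
      objective_trace = obj_trace, n_iter = it, converged = converged
    ),
    class = "prey_group_fit"
  )
}

#' @export
print.prey_group_fit <- function(x, ...) {
  cat("Hierarchical EM fit (", x$model, " model, ",
    length(x$subject_fits), " subjects, ", x$n_iter, " iterations",
    if (!x$converged) ", NOT converged", ")\n",
    sep = ""
  )
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}

#' Leave-one-subject-out cross-validated marginal likelihoods
#'
#' For each subject, refits the group prior by EM on the remaining subjects
#' (warm-started from the all-subject fit), then scores the held-out subject
#' by the negative Laplace-approximate log marginal likelihood of their
#' choices under that prior. Lower scores indicate better out-of-sample fit.
#'
#' @param cohort As in \code{\link{emFit}}; at least 3 subjects.
#' @param model \code{"symmetric"} or \code{"asymmetric"}.
#' @param tol,max_iter,restarts,seed,include_forced Passed to the fold fits.
#' @return A named numeric vector of class \code{prey_loocv}: one negative
#'   log marginal likelihood per subject. The full-cohort fit is attached as
#'   attribute \code{"full_fit"}.
#' @export
loocv <- function(cohort, model = c("asymmetric", "symmetric"),
                  tol = 1e-3, max_iter = 200, restarts = 5, seed = NULL,
                  include_forced = TRUE) {
  model <- match.arg(model)
  logs <- cohort_log_list(cohort)
  n <- length(logs)
  if (n < 3) stop("LOOcv requires at least 3 subjects")
  full <- emFit(
    logs, model,
    tol = tol, max_iter = max_iter, restarts = restarts,
    seed = seed, include_forced = include_forced
  )
  warm_init <- list(mean = full$mean, sd = full$sd)
  scores <- vapply(seq_len(n), function(k) {
    fold <- tryCatch(
      emFit(
        logs[-k], model,
        tol = tol, max_iter = max_iter,
        restarts = 1L, seed = seed, init = warm_init,
        include_forced = include_forced
      ),
      error = function(e) {
        stop("LOOcv fold ", k, " (held-out ", names(logs)[k], ") failed: ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
    prior <- list(mean = fold$mean, cov = diag(fold$sd^2, length(fold$mean)))
    held <- mapFitSubject(
      logs[[k]], prior, model,
      restarts = 2L,
      seed = seed, include_forced = include_forced,
      start = full$subject_fits[[k]]$par_t
    )
    -held$laplace_logml
  }, numeric(1))
  names(scores) <- names(logs)
  if (any(!is.finite(scores))) stop("non-finite LOOcv score")
  structure(scores, class = "prey_loocv", full_fit = full)
}

#' Paired comparison of per-subject cross-validation scores
#'
#' Two-tailed paired t-test on per-subject scores from two models fitted to
#' the same subjects (lower scores = better fit, so a negative mean
#' difference a - b favours model a).
#'
#' @param scores_a,scores_b Numeric vectors of per-subject scores, same
#'   subjects in the same order.
#' @return A list of class \code{prey_stat}: statistic, df, p, CI, mean
#'   difference; \code{degenerate = TRUE} (with p = NA) when the paired
#'   differences have zero variance.
#' @export
compareModels <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must cover the same subjects")
  }
  dd <- as.numeric(scores_a) - as.numeric(scores_b)
  if (var(dd) == 0) {
    # zero-variance differences: identical scores give the t -> 0 limit,
    # a constant non-zero difference has no defined t
    zero <- mean(dd) == 0
    return(structure(
      list(
        statistic = "t", value = if (zero) 0 else NA_real_,
        df = length(dd) - 1,
        p = if (zero) 1 else NA_real_,
        ci = c(NA_real_, NA_real_), mean_diff = mean(dd),
        degenerate = TRUE
      ),
      class = "prey_stat"
    ))
  }
  tt <- t.test(as.numeric(scores_a), as.numeric(scores_b), paired = TRUE)
  structure(
    list(
      statistic = "t", value = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      ci = as.numeric(tt$conf.int), mean_diff = unname(tt$estimate),
      degenerate = FALSE
    ),
    class = "prey_stat"
  )
}

#' @export
print.prey_stat <- function(x, ...) {
  if (length(x$df) == 1 && is.na(x$df)) {
    cat(sprintf("%s = %.3f, p = %.4g\n", x$statistic, x$value, x$p))
  } else {
    cat(sprintf(
      "%s(%s) = %.3f, p = %.4g\n", x$statistic,
      paste(format(x$df, digits = 4), collapse = ", "),
      x$value, x$p
    ))
  }
  invisible(x)
}

#' Group-level learning-bias contrast
#'
#' Tests whether the group mean positive-error learning rate exceeds the
#' negative-error rate, using the contrast (1, -1, 0, 0) on the asymmetric
#' model's group means in transformed (logit) space and the full estimated
#' covariance of those means: z = contrast mean / contrast SE, two-tailed p.
#'
#' @param fit A \code{prey_group_fit} for the asymmetric model.
#' @return A \code{prey_stat} with the z value, p, and the contrast estimate
#'   and SE.
#' @export
learningBiasZtest <- function(fit) {
  stopifnot(inherits(fit, "prey_group_fit"))
  if (fit$model != "asymmetric") {
    stop("the learning-bias contrast applies to the asymmetric model")
  }
  ctr <- c(1, -1, 0, 0)
  est <- sum(ctr * fit$mean)
  v <- drop(t(ctr) %*% fit$mean_cov %*% ctr)
  if (!is.finite(v) || v <= 0) stop("singular covariance of the group means")
  z <- est / sqrt(v)
  structure(
    list(
      statistic = "z", value = z, df = NA_real_,
      p = 2 * stats::pnorm(-abs(z)), ci = est + c(-1.96, 1.96) * sqrt(v),
      mean_diff = est, se = sqrt(v), degenerate = FALSE
    ),
    class = "prey_stat"
  )
}
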