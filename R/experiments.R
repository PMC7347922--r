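# replicate-level seed split, kept inside the 32-bit integer range
derive_replicate_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) + 104729 * r) %% 2147483647)
}

free_trial_earnings <- function(log) {
  sum(log$reward[!log$forced])
}

#' Order-effect simulation experiment
#'
#' Repeatedly simulates cohorts of virtual participants, computes each
#' subject's environment difference score (poor minus rich acceptance,
#' averaged over the four options), averages within order condition, and
#' averages those condition means across replicates. With asymmetric
#' learning the PoorRich condition shows a larger difference score than the
#' RichPoor condition; with symmetric learning the two condition means
#' coincide up to Monte Carlo error.
#'
#' @param model Generating model.
#' @param dist Group distribution for the virtual participants.
#' @param n_sims Number of replicate cohorts (default 1000).
#' @param n_subjects Cohort size (default 40, split evenly between orders).
#' @param experiment Experiment configuration tag.
#' @param seed Master seed; every replicate derives its own.
#' @return A list of class \code{prey_report}: \code{config},
#'   \code{per_replicate} (condition means per replicate) and
#'   \code{summary} (condition means, mean earnings, the between-condition
#'   gap and its Monte Carlo standard error).
#' @export
orderEffectExperiment <- function(model = c("asymmetric", "symmetric"),
                                  dist = preyDefaults(experiment, model),
                                  n_sims = 1000, n_subjects = 40,
                                  experiment = "exp1", seed = 1L) {
  model <- match.arg(model)
  reps <- lapply(seq_len(n_sims), function(r) {
    rseed <- derive_replicate_seed(seed, r)
    cohort <- generateCohort(cohortSpec(
      n_subjects = n_subjects, experiment = experiment, dist = dist,
      seed = rseed
    ))
    logs <- cohortLogs(cohort)
    ds <- differenceScore(acceptanceRates(logs, collapse_intermediates = FALSE))
    earn <- vapply(
      cohort$subjects,
      function(s) free_trial_earnings(s$log), numeric(1)
    )
    cond <- vapply(cohort$subjects, `[[`, character(1), "condition")
    data.frame(
      replicate = r, seed = rseed,
      diff_RichPoor = mean(ds$diff_score[ds$order == "RichPoor"]),
      diff_PoorRich = mean(ds$diff_score[ds$order == "PoorRich"]),
      earn_RichPoor = mean(earn[cond == "RichPoor"]),
      earn_PoorRich = mean(earn[cond == "PoorRich"])
    )
  })
  per_rep <- do.call(rbind, reps)
  gap <- per_rep$diff_PoorRich - per_rep$diff_RichPoor
  structure(
    list(
      kind = "order_effect",
      config = list(
        model = model, n_sims = n_sims, n_subjects = n_subjects,
        experiment = experiment, seed = seed,
        group_mean = dist$mean, group_sd = dist$sd
      ),
      per_replicate = per_rep,
      summary = list(
        mean_diff_RichPoor = mean(per_rep$diff_RichPoor),
        mean_diff_PoorRich = mean(per_rep$diff_PoorRich),
        mean_earn_RichPoor = mean(per_rep$earn_RichPoor),
        mean_earn_PoorRich = mean(per_rep$earn_PoorRich),
        gap = mean(gap),
        gap_mc_se = stats::sd(gap) / sqrt(length(gap))
      )
    ),
    class = "prey_report"
  )
}

#' @export
print.prey_report <- function(x, ...) {
  cat("Simulation report: ", x$kind, "\n", sep = "")
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Cost-of-asymmetry simulation experiment
#'
#' Quantifies what a learning bias costs a forager: replicate cohorts of 40
#' virtual participants (20 per order condition) are simulated under each
#' model with every subject at the reference mean learning rates and slope
#' for Experiment 1 and the softmax intercept fixed to zero, isolating the
#' effect of the bias from any overall accept/reject tendency. Per-subject
#' earnings (points on free trials) are pooled across replicates and
#' compared between models with a two-tailed independent-samples t-test.
#'
#' @param n_sims Number of replicate cohorts per model (default 500).
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @return A \code{prey_report} with per-model mean earnings and the test.
#' @export
asymmetryCostExperiment <- function(n_sims = 500, n_subjects = 40,
                                    seed = 1L) {
  ref <- .prey_reference_params$exp1
  dists <- list(
    symmetric = groupDistribution(
      "symmetric",
      mean = c(
        logit_alpha = qlogis(ref$symmetric$mean[["alpha"]]),
        beta0 = 0, beta1 = ref$symmetric$mean[["beta1"]]
      ),
      sd = c(logit_alpha = 0, beta0 = 0, beta1 = 0)
    ),
    asymmetric = groupDistribution(
      "asymmetric",
      mean = c(
        logit_alpha_pos = qlogis(ref$asymmetric$mean[["alpha_pos"]]),
        logit_alpha_neg = qlogis(ref$asymmetric$mean[["alpha_neg"]]),
        beta0 = 0, beta1 = ref$asymmetric$mean[["beta1"]]
      ),
      sd = c(
        logit_alpha_pos = 0, logit_alpha_neg = 0, beta0 = 0, beta1 = 0
      )
    )
  )
  earnings <- lapply(names(dists), function(mod) {
    unlist(lapply(seq_len(n_sims), function(r) {
      rseed <- derive_replicate_seed(
        seed + if (mod == "asymmetric") 500000L else 0L, r
      )
      cohort <- generateCohort(cohortSpec(
        n_subjects = n_subjects, experiment = "exp1", dist = dists[[mod]],
        seed = rseed
      ))
      vapply(cohort$subjects, function(s) free_trial_earnings(s$log), numeric(1))
    }))
  })
  names(earnings) <- names(dists)
  tt <- t.test(earnings$symmetric, earnings$asymmetric, var.equal = TRUE)
  structure(
    list(
      kind = "asymmetry_cost",
      config = list(n_sims = n_sims, n_subjects = n_subjects, seed = seed),
      earnings = earnings,
      summary = list(
        mean_earn_symmetric = mean(earnings$symmetric),
        mean_earn_asymmetric = mean(earnings$asymmetric),
        earn_diff = mean(earnings$symmetric) - mean(earnings$asymmetric),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
      )
    ),
    class = "prey_report"
  )
}

#' Parameter- and model-recovery experiment
#'
#' Generates cohorts from a known group distribution, refits them by
#' hierarchical EM, and reports how well the generating structure is
#' recovered: group-mean errors in transformed space, the Spearman rank
#' correlation between true and recovered per-subject learning bias
#' (asymmetric generator), whether the sign of the group-level bias is
#' recovered, the learning-bias z-test, and (optionally) LOOcv-based model
#' selection between the symmetric and asymmetric models.
#'
#' @param model Generating model.
#' @param dist Generating group distribution.
#' @param n_subjects Cohort size.
#' @param n_cohorts Number of replicate cohorts.
#' @param experiment Experiment configuration tag.
#' @param seed Master seed.
#' @param do_loocv Run LOOcv model comparison per cohort (slow).
#' @param fit_args Extra arguments passed on to \code{\link{emFit}} /
#'   \code{\link{loocv}} (e.g. \code{tol}, \code{restarts}).
#' @return A \code{prey_report} with a per-cohort data frame and summary
#'   recovery rates.
#' @export
recoveryExperiment <- function(model = c("asymmetric", "symmetric"),
                               dist = preyDefaults(experiment, model),
                               n_subjects = 40, n_cohorts = 20,
                               experiment = "exp1", seed = 1L,
                               do_loocv = FALSE, fit_args = list()) {
  model <- match.arg(model)
  rows <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    rseed <- derive_replicate_seed(seed, r)
    cohort <- generateCohort(cohortSpec(
      n_subjects = n_subjects, experiment = experiment, dist = dist,
      seed = rseed
    ))
    true_mat <- t(vapply(
      cohort$subjects, function(s) paramsToVector(s$params),
      numeric(length(param_names(model)))
    ))
    fit <- do.call(emFit, c(
      list(cohort = cohort, model = "asymmetric", seed = rseed),
      fit_args
    ))
    zt <- learningBiasZtest(fit)
    maps <- t(vapply(
      fit$subject_fits, `[[`, numeric(4), "par_t"
    ))
    rec_bias <- maps[, "logit_alpha_pos"] - maps[, "logit_alpha_neg"]
    true_bias <- if (model == "asymmetric") {
      true_mat[, "logit_alpha_pos"] - true_mat[, "logit_alpha_neg"]
    } else {
      rep(0, n_subjects)
    }
    bias_rank_cor <- if (model == "asymmetric" &&
      stats::sd(true_bias) > 0 && stats::sd(rec_bias) > 0) {
      cor(true_bias, rec_bias, method = "spearman")
    } else {
      NA_real_
    }
    row <- data.frame(
      cohort = r, seed = rseed,
      rec_bias_mean = fit$mean[["logit_alpha_pos"]] -
        fit$mean[["logit_alpha_neg"]],
      true_bias_mean = mean(true_bias),
      bias_sign_recovered = sign(
        fit$mean[["logit_alpha_pos"]] - fit$mean[["logit_alpha_neg"]]
      ) == 1,
      bias_rank_cor = bias_rank_cor,
      z_bias = zt$value, p_bias = zt$p
    )
    if (do_loocv) {
      sc_a <- do.call(loocv, c(
        list(cohort = cohort, model = "asymmetric", seed = rseed), fit_args
      ))
      sc_s <- do.call(loocv, c(
        list(cohort = cohort, model = "symmetric", seed = rseed), fit_args
      ))
      row$loocv_asym <- mean(sc_a)
      row$loocv_sym <- mean(sc_s)
      row$selects_asymmetric <- mean(sc_a) < mean(sc_s)
    }
    rows[[r]] <- row
  }
  per_cohort <- do.call(rbind, rows)
  structure(
    list(
      kind = "recovery",
      config = list(
        model = model, n_subjects = n_subjects, n_cohorts = n_cohorts,
        experiment = experiment, seed = seed, do_loocv = do_loocv,
        group_mean = dist$mean, group_sd = dist$sd
      ),
      per_cohort = per_cohort,
      summary = list(
        bias_sign_recovery_rate = mean(per_cohort$bias_sign_recovered),
        mean_bias_rank_cor = mean(per_cohort$bias_rank_cor),
        z_rejection_rate = mean(abs(per_cohort$z_bias) > 1.96),
        asym_selection_rate = if (do_loocv) {
          mean(per_cohort$selects_asymmetric)
        } else {
          NA_real_
        }
      )
    ),
    class = "prey_report"
  )
}
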