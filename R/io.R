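trial_log_columns <- c(
  "subject", "experiment", "order", "block", "env", "trial", "option",
  "forced", "forced_dir", "choice", "reward", "t_start", "t_end"
)

#' Write trial logs to CSV
#'
#' One row per trial, header required, columns: subject, experiment, order,
#' block, env, trial, option, forced, forced_dir, choice, reward, t_start,
#' t_end; times are integer seconds. Multiple subjects share one file.
#'
#' @param x A \code{prey_cohort}, a single trial-log data frame, or a list of
#'   them.
#' @param path Output CSV path.
#' @export
writeTrialLogs <- function(x, path) {
  df <- if (inherits(x, "prey_cohort")) {
    cohortLogs(x)
  } else if (is.data.frame(x)) x else cohortLogs(x)
  miss <- setdiff(trial_log_columns, names(df))
  if (length(miss)) stop("missing trial-log columns: ", paste(miss, collapse = ", "))
  write.csv(df[, trial_log_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read trial logs from CSV
#'
#' @param path CSV path in the \code{\link{writeTrialLogs}} dialect.
#' @return A list of per-subject trial-log data frames, named by subject id.
#' @export
readTrialLogs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(trial_log_columns, names(df))
  if (length(miss)) stop("missing trial-log columns: ", paste(miss, collapse = ", "))
  df$forced <- as.logical(df$forced)
  split_idx <- split(seq_len(nrow(df)), df$subject)
  lapply(split_idx, function(i) {
    out <- df[i, trial_log_columns]
    rownames(out) <- NULL
    out
  })
}

#' Write a cohort manifest (JSON)
#'
#' Records, per subject: id, order condition, derived seed and ground-truth
#' parameters, plus the cohort-level configuration, so a cohort can be
#' audited or regenerated without rereading its trial logs.
#'
#' @param cohort A \code{prey_cohort}.
#' @param path Output JSON path.
#' @export
writeCohortManifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "prey_cohort"))
  manifest <- list(
    experiment = cohort$spec$experiment,
    model = cohort$spec$dist$model,
    n_subjects = cohort$spec$n_subjects,
    n_rich_first = cohort$spec$n_rich_first,
    master_seed = cohort$spec$seed,
    group_mean = as.list(cohort$spec$dist$mean),
    group_sd = as.list(cohort$spec$dist$sd),
    subjects = lapply(cohort$subjects, function(s) {
      list(
        id = s$id, condition = s$condition, seed = s$seed,
        params = as.list(paramsToVector(s$params))
      )
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize fit results
#'
#' Group-level results (means, spreads, covariance of the group means,
#' iteration trace) go to JSON; per-subject MAP estimates go to tidy CSV.
#'
#' @param fit A \code{prey_group_fit} from \code{\link{emFit}}.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @export
writeFitResults <- function(fit, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(fit, "prey_group_fit"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        model = fit$model, mean = as.list(fit$mean), sd = as.list(fit$sd),
        mean_cov = fit$mean_cov, n_iter = fit$n_iter,
        converged = fit$converged, objective_trace = fit$objective_trace
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    maps <- t(vapply(
      fit$subject_fits, function(s) s$par_t,
      numeric(length(fit$mean))
    ))
    df <- data.frame(
      subject = names(fit$subject_fits), maps,
      logpost = vapply(fit$subject_fits, `[[`, numeric(1), "logpost"),
      check.names = FALSE
    )
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(fit)
}

#' Read a session-design configuration (JSON or YAML)
#'
#' Accepts a config with fields \code{experiment}, \code{order} and
#' optionally \code{encounter_seconds}, \code{forced_fraction},
#' \code{forced_accept_prob}, \code{timeout_seconds} and \code{seed}.
#' Format is chosen by file extension (\code{.json} vs \code{.yml}/
#' \code{.yaml}).
#'
#' @param path Config file path.
#' @return A list with \code{design} (a \code{prey_design}) and \code{seed}
#'   (integer or NULL).
#' @export
readDesignConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  stopifnot(!is.null(cfg$experiment), !is.null(cfg$order))
  args <- cfg[intersect(
    names(cfg),
    c(
      "experiment", "order", "encounter_seconds", "forced_fraction",
      "forced_accept_prob", "timeout_seconds"
    )
  )]
  design <- do.call(sessionDesign, args)
  list(design = design, seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}
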