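option_category <- function(labels) {
  opts <- optionSet()
  stats::setNames(opts$category, opts$label)[labels]
}

free_decided <- function(log) {
  !log$forced & log$choice != "missed"
}

#' Per-subject acceptance rates by option and environment
#'
#' The fraction of accept decisions per option (or pooled option category)
#' per environment, computed from free (non-forced), non-missed trials only.
#' With \code{collapse_intermediates = TRUE} the two equally profitable
#' intermediate options are pooled at the trial level (a single percentage
#' of decisions, not an average of two rates). Cells with no eligible trials
#' are returned as NA.
#'
#' @param log A trial-log data frame (one or many subjects).
#' @param collapse_intermediates Pool LDLR and HDHR into one
#'   \code{intermediate} category.
#' @param envs Environments to tabulate (default rich and poor; the
#'   worst-only block of Experiment 3 is excluded from acceptance tables).
#' @return A data frame of class \code{prey_acceptance}: subject, order,
#'   env, option (or category), n, n_accept, rate.
#' @export
acceptanceRates <- function(log, collapse_intermediates = TRUE,
                            envs = c("rich", "poor")) {
  keep <- free_decided(log) & log$env %in% envs
  df <- log[keep, , drop = FALSE]
  df$cell <- if (collapse_intermediates) {
    unname(option_category(df$option))
  } else {
    df$option
  }
  cells <- if (collapse_intermediates) {
    c("best", "intermediate", "worst")
  } else {
    optionSet()$label
  }
  subjects <- unique(log$subject)
  order_of <- stats::setNames(
    log$order[match(subjects, log$subject)], subjects
  )
  grid <- expand.grid(
    subject = subjects, env = envs, cell = cells,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  key <- function(s, e, c) paste(s, e, c, sep = "\r")
  n <- tapply(
    rep(1L, nrow(df)), key(df$subject, df$env, df$cell), sum,
    default = 0L
  )
  na <- tapply(
    as.integer(df$choice == "accept"), key(df$subject, df$env, df$cell),
    sum,
    default = 0L
  )
  k <- key(grid$subject, grid$env, grid$cell)
  grid$n <- as.integer(ifelse(is.na(n[k]), 0L, n[k]))
  grid$n_accept <- as.integer(ifelse(is.na(na[k]), 0L, na[k]))
  grid$rate <- ifelse(grid$n > 0, grid$n_accept / grid$n, NA_real_)
  grid$order <- unname(order_of[grid$subject])
  names(grid)[names(grid) == "cell"] <-
    if (collapse_intermediates) "category" else "option"
  grid <- grid[order(grid$subject, grid$env), ]
  rownames(grid) <- NULL
  class(grid) <- c("prey_acceptance", "data.frame")
  grid
}

#' Per-subject environment difference score
#'
#' The mean, over the four options, of the acceptance-rate difference
#' poor minus rich. Positive scores mean the subject accepted more in the
#' poor environment.
#'
#' @param table A 4-option acceptance table from
#'   \code{\link{acceptanceRates}(collapse_intermediates = FALSE)}.
#' @return Data frame: subject, order, diff_score.
#' @export
differenceScore <- function(table) {
  need <- c("subject", "env", "option", "rate")
  if (!all(need %in% names(table))) {
    stop("expected a 4-option acceptance table (collapse_intermediates = FALSE)")
  }
  if (!all(c("rich", "poor") %in% table$env)) {
    stop("difference scores need both a rich and a poor environment")
  }
  wide <- merge(
    table[table$env == "poor", c("subject", "order", "option", "rate")],
    table[table$env == "rich", c("subject", "option", "rate")],
    by = c("subject", "option"), suffixes = c("_poor", "_rich")
  )
  wide$d <- wide$rate_poor - wide$rate_rich
  agg <- stats::aggregate(d ~ subject + order, data = wide, FUN = mean)
  names(agg)[names(agg) == "d"] <- "diff_score"
  agg[order(agg$subject), c("subject", "order", "diff_score")]
}

#' Acceptance by previous-offer category
#'
#' Splits current free-trial decisions by the option category the subject
#' encountered on the immediately preceding trial (regardless of the
#' previous decision; forced previous trials count as history since their
#' offers were experienced) and by environment. The first trial of every
#' block has no previous offer and is excluded. Forced current trials are
#' excluded by default.
#'
#' @param log A trial-log data frame.
#' @param include_forced_current Also count forced current trials' mandated
#'   responses.
#' @param envs Environments to tabulate.
#' @return Data frame: subject, env, prev_category, n, n_accept, rate.
#' @export
previousOfferTable <- function(log, include_forced_current = FALSE,
                               envs = c("rich", "poor")) {
  split_idx <- split(seq_len(nrow(log)), log$subject)
  res <- lapply(split_idx, function(idx) {
    sl <- log[idx, , drop = FALSE]
    sl <- sl[order(sl$trial), , drop = FALSE]
    prev_opt <- c(NA_character_, sl$option[-nrow(sl)])
    prev_opt[c(TRUE, diff(sl$block) != 0)] <- NA # first trial of each block
    ok <- !is.na(prev_opt) & sl$env %in% envs & sl$choice != "missed"
    if (!include_forced_current) ok <- ok & !sl$forced
    data.frame(
      subject = sl$subject[ok], env = sl$env[ok],
      prev_category = unname(option_category(prev_opt[ok])),
      accept = as.integer(sl$choice[ok] == "accept"),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  agg_n <- stats::aggregate(
    accept ~ subject + env + prev_category,
    data = df, FUN = length
  )
  agg_a <- stats::aggregate(
    accept ~ subject + env + prev_category,
    data = df, FUN = sum
  )
  out <- agg_n
  names(out)[names(out) == "accept"] <- "n"
  out$n_accept <- agg_a$accept
  out$rate <- out$n_accept / out$n
  out[order(out$subject, out$env, out$prev_category), ]
}

#' Mixed-design repeated-measures ANOVA
#'
#' Standard sums-of-squares ANOVA with within-subject factors (and an
#' optional between-subject factor), via \code{aov} with an error stratum
#' per within-subject factor combination. Requires one observation per
#' subject per within-cell (aggregate first) and a balanced within design.
#' Returns F, degrees of freedom, p and partial eta squared
#' (SS_effect / (SS_effect + SS_error)) for every effect.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional between-subject factor column.
#' @param subject Subject-identifier column.
#' @return Data frame: effect, df1, df2, F, p, peta2.
#' @export
mixedAnova <- function(data, dv, within, between = NULL,
                       subject = "subject") {
  df <- data
  df[[subject]] <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (!is.null(between)) df[[between]] <- factor(df[[between]])

  cell <- interaction(df[, within, drop = FALSE], drop = TRUE)
  counts <- table(df[[subject]], cell)
  if (any(counts != 1)) {
    stop("unbalanced within-subject design: need exactly one value per subject per cell")
  }
  if (anyNA(df[[dv]])) stop("missing response values; aggregate or impute first")

  dv_scale <- stats::var(df[[dv]])

  fixed <- paste(c(within, between), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(dv, "~", fixed, "+", err))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    effects <- trimws(rownames(tab))
    resid_row <- effects == "Residuals"
    if (!any(resid_row)) next
    ss_err <- tab$`Sum Sq`[resid_row]
    df_err <- tab$Df[resid_row]
    for (i in which(!resid_row)) {
      degenerate <- dv_scale == 0 # no variance anywhere: all effects are null
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effects[i], df1 = tab$Df[i], df2 = df_err,
        F = if (degenerate) 0 else tab$`F value`[i],
        p = if (degenerate) 1 else tab$`Pr(>F)`[i],
        peta2 = if (degenerate) {
          0
        } else {
          tab$`Sum Sq`[i] / (tab$`Sum Sq`[i] + ss_err)
        },
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample and between-condition tests on difference scores
#'
#' Per order condition, a two-tailed one-sample t-test of the difference
#' scores against zero; plus a two-tailed independent-samples t-test
#' (pooled variance) comparing the two conditions.
#'
#' @param diff_scores Data frame from \code{\link{differenceScore}} (columns
#'   \code{diff_score} and a condition column).
#' @param condition Name of the condition column.
#' @return A list of class \code{prey_group_tests} with one
#'   \code{prey_stat} per condition (named by condition) and
#'   \code{$between}. Zero-variance cells are flagged degenerate.
#' @export
groupTests <- function(diff_scores, condition = "order") {
  conds <- sort(unique(diff_scores[[condition]]))
  one_sample <- lapply(conds, function(cc) {
    x <- diff_scores$diff_score[diff_scores[[condition]] == cc]
    if (length(x) < 2) stop("need at least 2 subjects per condition")
    if (var(x) == 0) {
      return(structure(
        list(
          statistic = "t", value = if (mean(x) == 0) 0 else NA_real_,
          df = length(x) - 1, p = if (mean(x) == 0) 1 else NA_real_,
          ci = c(mean(x), mean(x)), mean_diff = mean(x), degenerate = TRUE
        ),
        class = "prey_stat"
      ))
    }
    tt <- t.test(x, mu = 0)
    structure(
      list(
        statistic = "t", value = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value,
        ci = as.numeric(tt$conf.int), mean_diff = unname(tt$estimate),
        degenerate = FALSE
      ),
      class = "prey_stat"
    )
  })
  names(one_sample) <- conds

  between <- NULL
  if (length(conds) == 2) {
    x <- diff_scores$diff_score[diff_scores[[condition]] == conds[1]]
    y <- diff_scores$diff_score[diff_scores[[condition]] == conds[2]]
    if (var(c(x, y)) == 0) {
      between <- structure(
        list(
          statistic = "t", value = 0, df = length(x) + length(y) - 2,
          p = 1, ci = c(0, 0), mean_diff = mean(x) - mean(y),
          degenerate = TRUE
        ),
        class = "prey_stat"
      )
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
      between <- structure(
        list(
          statistic = "t", value = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value,
          ci = as.numeric(tt$conf.int),
          mean_diff = unname(diff(rev(tt$estimate))), degenerate = FALSE
        ),
        class = "prey_stat"
      )
    }
  }
  structure(
    c(one_sample, list(between = between)),
    class = "prey_group_tests"
  )
}

#' Data-quality exclusion screen
#'
#' Flags each subject on the pre-registered-style screens: 20 or more missed
#' responses; 10 or more incorrect forced-trial responses; poor
#' discriminability (accepting the worst option a greater percentage of free
#' trials than the best option, or accepting/rejecting every option on every
#' free trial). A subject is dropped if any flag is set. A
#' did-not-finish flag is carried as structurally FALSE: synthetic sessions
#' always complete.
#'
#' @param log A trial-log data frame (one or many subjects).
#' @return Data frame of class \code{prey_exclusions}: one row per subject
#'   with the individual flags and \code{keep}.
#' @export
applyExclusions <- function(log) {
  split_idx <- split(seq_len(nrow(log)), log$subject)
  rows <- lapply(names(split_idx), function(s) {
    sl <- log[split_idx[[s]], , drop = FALSE]
    n_missed <- sum(sl$choice == "missed")
    forced <- sl$forced & sl$choice != "missed"
    n_bad_forced <- sum(sl$choice[forced] != sl$forced_dir[forced])
    free <- free_decided(sl)
    rate_of <- function(lab) {
      sel <- free & sl$option == lab
      if (!any(sel)) NA_real_ else mean(sl$choice[sel] == "accept")
    }
    worst_gt_best <- isTRUE(rate_of("HDLR") > rate_of("LDHR"))
    all_same <- length(unique(sl$choice[free])) <= 1
    flags <- c(
      missed_20 = n_missed >= 20,
      incorrect_forced_10 = n_bad_forced >= 10,
      poor_discriminability = worst_gt_best,
      all_accept_or_reject = all_same,
      did_not_finish = FALSE
    )
    data.frame(
      subject = s, t(flags), keep = !any(flags),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("prey_exclusions", "data.frame")
  out
}
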