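test_that("acceptance tables match hand counts and exclude forced/missed trials", {
  # 12 hand-built trials: rich block then poor block
  log <- make_toy_log(
    options = c(
      "LDHR", "LDLR", "HDHR", "HDLR", "LDHR", "LDLR",
      "LDHR", "LDLR", "HDHR", "HDLR", "HDLR", "HDHR"
    ),
    choices = c(
      "accept", "reject", "accept", "reject", "accept", "missed",
      "accept", "accept", "reject", "accept", "reject", "accept"
    ),
    forced = c(
      FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, TRUE, FALSE, FALSE
    ),
    forced_dir = c(
      NA, NA, "accept", NA, NA, NA,
      NA, NA, NA, "accept", NA, NA
    ),
    env = rep(c("rich", "poor"), each = 6),
    block = rep(1:2, each = 6)
  )
  tab <- acceptanceRates(log, collapse_intermediates = FALSE)
  pick <- function(e, o) tab$rate[tab$env == e & tab$option == o]
  # rich free decided trials: LDHR acc,acc; LDLR rej; HDLR rej
  expect_equal(pick("rich", "LDHR"), 1)
  expect_equal(pick("rich", "LDLR"), 0)
  expect_true(is.na(pick("rich", "HDHR"))) # only a forced trial
  expect_equal(pick("rich", "HDLR"), 0)
  # poor: LDHR acc; LDLR acc; HDHR rej,acc; HDLR rej (forced excluded)
  expect_equal(pick("poor", "HDHR"), 0.5)
  expect_equal(pick("poor", "HDLR"), 0)

  # collapsed intermediates pool trials, not average the two rates
  tab3 <- acceptanceRates(log, collapse_intermediates = TRUE)
  # poor intermediates: LDLR acc + HDHR rej,acc -> 2/3
  expect_equal(
    tab3$rate[tab3$env == "poor" & tab3$category == "intermediate"], 2 / 3
  )

  # all-accept log: every defined entry is 1; forced-only log: all NA
  all_acc <- make_toy_log(
    rep(c("LDHR", "HDLR"), 4), rep("accept", 8),
    env = rep(c("rich", "poor"), each = 4), block = rep(1:2, each = 4)
  )
  t_all <- acceptanceRates(all_acc, collapse_intermediates = FALSE)
  expect_true(all(t_all$rate[t_all$n > 0] == 1))
  forced_only <- make_toy_log(
    rep("LDHR", 4), rep("accept", 4),
    forced = rep(TRUE, 4), forced_dir = rep("accept", 4)
  )
  expect_true(all(is.na(acceptanceRates(forced_only)$rate)))
})

test_that("collapsed intermediate rates equal the count-weighted pooled rates", {
  co <- generateCohort(cohortSpec(n_subjects = 4, experiment = "exp2", seed = 8))
  logs <- cohortLogs(co)
  t4 <- acceptanceRates(logs, collapse_intermediates = FALSE)
  t3 <- acceptanceRates(logs, collapse_intermediates = TRUE)
  for (s in unique(logs$subject)) {
    for (e in c("rich", "poor")) {
      sub4 <- t4[t4$subject == s & t4$env == e & t4$option %in% c("LDLR", "HDHR"), ]
      pooled <- sum(sub4$n_accept) / sum(sub4$n)
      expect_equal(
        t3$rate[t3$subject == s & t3$env == e & t3$category == "intermediate"],
        pooled
      )
    }
  }
  # analyses are pure functions of the log
  expect_identical(t4, acceptanceRates(logs, collapse_intermediates = FALSE))
})

test_that("difference scores average the per-option poor-minus-rich change", {
  tab <- expand.grid(
    subject = "s1", env = c("rich", "poor"),
    option = c("LDHR", "LDLR", "HDHR", "HDLR"),
    stringsAsFactors = FALSE
  )
  tab$order <- "RichPoor"
  rich_rates <- c(LDHR = 0.9, LDLR = 0.2, HDHR = 0.3, HDLR = 0.0)
  poor_rates <- c(LDHR = 1.0, LDLR = 0.6, HDHR = 0.5, HDLR = 0.1)
  tab$rate <- ifelse(
    tab$env == "rich", rich_rates[tab$option], poor_rates[tab$option]
  )
  ds <- differenceScore(tab)
  expect_equal(
    ds$diff_score,
    mean(c(1.0 - 0.9, 0.6 - 0.2, 0.5 - 0.3, 0.1 - 0.0))
  )

  # identical behavior in both environments gives 0; a uniform +0.1 shift
  # gives +0.1
  tab$rate <- rich_rates[tab$option]
  expect_equal(differenceScore(tab)$diff_score, 0)
  tab$rate[tab$env == "poor"] <- tab$rate[tab$env == "poor"] + 0.1
  expect_equal(differenceScore(tab)$diff_score, 0.1)

  tab_rich <- tab[tab$env == "rich", ]
  expect_error(differenceScore(tab_rich), "rich and a poor")
})

test_that("previous-offer partitioning matches a hand partition and model predictions", {
  # 6 hand-built trials, one block: previous offers define the cells
  log <- make_toy_log(
    options = c("LDHR", "HDLR", "LDLR", "LDHR", "HDHR", "HDLR"),
    choices = c("accept", "reject", "accept", "accept", "reject", "reject"),
    forced = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    forced_dir = c(NA, NA, "accept", NA, NA, NA)
  )
  tab <- previousOfferTable(log)
  # trial 1 excluded (no previous); trial 3 forced (excluded as current);
  # remaining: t2 prev best rej, t4 prev intermediate acc,
  # t5 prev best rej, t6 prev intermediate rej
  expect_equal(tab$rate[tab$prev_category == "best"], 0)
  expect_equal(tab$rate[tab$prev_category == "intermediate"], 0.5)
  expect_equal(sum(tab$n), 4)
  with_forced <- previousOfferTable(log, include_forced_current = TRUE)
  expect_equal(sum(with_forced$n), 5)

  # history-blind chooser: rates equal across previous-offer categories up
  # to counting noise
  dist <- preyDefaults("exp2", "asymmetric")
  dist$sd[] <- 0
  dist$mean[["beta0"]] <- 0
  dist$mean[["beta1"]] <- 0
  co <- generateCohort(cohortSpec(
    n_subjects = 6, experiment = "exp2",
    dist = dist, seed = 12
  ))
  t_blind <- previousOfferTable(cohortLogs(co))
  by_prev <- tapply(t_blind$rate, t_blind$prev_category, mean)
  expect_lt(max(by_prev) - min(by_prev), 0.1)

  # asymmetric cohort: acceptance rises as the previous offer worsens
  co2 <- generateCohort(cohortSpec(n_subjects = 20, experiment = "exp2", seed = 4))
  t_asym <- previousOfferTable(cohortLogs(co2))
  by_prev2 <- tapply(t_asym$rate, t_asym$prev_category, mean)
  expect_gt(by_prev2[["worst"]], by_prev2[["best"]])
})

test_that("the mixed ANOVA reproduces an independent sums-of-squares oracle", {
  # balanced 2 (option) x 2 (env) within x 2-group between design, 6 subjects
  set.seed(33)
  df <- expand.grid(
    subject = paste0("s", 1:6), option = c("best", "worst"),
    env = c("rich", "poor"), stringsAsFactors = FALSE
  )
  df$grp <- ifelse(df$subject %in% paste0("s", 1:3), "g1", "g2")
  df$y <- round(
    2 * (df$option == "best") + 0.8 * (df$env == "poor") +
      0.5 * (df$option == "best") * (df$grp == "g2") + rnorm(nrow(df), 0, 0.4),
    2
  )

  got <- mixedAnova(df, "y", within = c("option", "env"), between = "grp")

  # independent oracle: textbook mixed-design SS decomposition from cell means
  y <- df$y
  gm <- mean(y)
  ss <- function(m, n_per) n_per * sum((m - gm)^2)
  m_subj <- tapply(y, df$subject, mean)
  m_grp <- tapply(y, df$grp, mean)
  m_opt <- tapply(y, df$option, mean)
  m_env <- tapply(y, df$env, mean)
  ss_grp <- ss(m_grp, 12)
  ss_subj <- ss(m_subj, 4)
  ss_opt <- ss(m_opt, 12)
  ss_env <- ss(m_env, 12)
  m_oxg <- tapply(y, interaction(df$option, df$grp), mean)
  ss_oxg <- ss(m_oxg, 6) - ss_opt - ss_grp
  m_oxs <- tapply(y, interaction(df$option, df$subject), mean)
  ss_oxs_err <- ss(m_oxs, 2) - ss_opt - ss_subj - ss_oxg
  f_opt <- (ss_opt / 1) / (ss_oxs_err / 4)

  row <- got[got$effect == "option", ]
  expect_equal(row$F, f_opt)
  expect_equal(row$df1, 1)
  expect_equal(row$df2, 4)
  expect_equal(row$peta2, ss_opt / (ss_opt + ss_oxs_err))
  row_g <- got[got$effect == "grp", ]
  expect_equal(row_g$F, (ss_grp / 1) / ((ss_subj - ss_grp) / 4))

  # identical responses: all F are 0 (no variance anywhere)
  df0 <- df
  df0$y <- 1
  got0 <- mixedAnova(df0, "y", within = c("option", "env"), between = "grp")
  expect_true(all(is.na(got0$F) | got0$F == 0))

  # relabelling the between groups leaves within-subject main effects intact
  df_sw <- df
  df_sw$grp <- ifelse(df$grp == "g1", "g2", "g1")
  got_sw <- mixedAnova(df_sw, "y", within = c("option", "env"), between = "grp")
  expect_equal(
    got_sw[got_sw$effect == "option", c("F", "p")],
    got[got$effect == "option", c("F", "p")]
  )

  # unbalanced designs are refused
  expect_error(
    mixedAnova(df[-1, ], "y", within = c("option", "env"), between = "grp"),
    "unbalanced"
  )
})

test_that("group tests match closed-form t statistics and their invariances", {
  ds <- data.frame(
    subject = paste0("s", 1:10),
    order = rep(c("RichPoor", "PoorRich"), each = 5),
    diff_score = c(0.05, 0.02, -0.01, 0.04, 0.00, 0.21, 0.15, 0.18, 0.25, 0.11)
  )
  gt <- groupTests(ds)

  x <- ds$diff_score[6:10]
  t_hand <- mean(x) / (sd(x) / sqrt(5))
  expect_equal(gt$PoorRich$value, t_hand)
  expect_equal(gt$PoorRich$df, 4)

  y <- ds$diff_score[1:5]
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  t_ind <- (mean(y) - mean(x)) / (sp * sqrt(2 / 5))
  expect_equal(abs(gt$between$value), abs(t_ind))
  expect_equal(gt$between$df, 8)

  # all-zero scores: degenerate with t = 0, p = 1
  ds0 <- ds
  ds0$diff_score <- 0
  gt0 <- groupTests(ds0)
  expect_equal(gt0$RichPoor$value, 0)
  expect_equal(gt0$RichPoor$p, 1)
  expect_true(gt0$RichPoor$degenerate)

  # shifting every score changes one-sample t but not the independent t
  ds_shift <- ds
  ds_shift$diff_score <- ds$diff_score + 0.5
  gt_s <- groupTests(ds_shift)
  expect_equal(gt_s$between$value, gt$between$value)
  expect_false(isTRUE(all.equal(gt_s$PoorRich$value, gt$PoorRich$value)))
})

test_that("exclusion screens flag the pre-registered data-quality failures", {
  co <- generateCohort(cohortSpec(n_subjects = 2, experiment = "exp2", seed = 14))
  clean <- cohortLogs(co)
  rep_clean <- applyExclusions(clean)
  expect_true(all(rep_clean$keep))
  expect_true(all(!rep_clean$did_not_finish))

  # 20 missed responses
  missed <- co$subjects[[1]]$log
  idx <- which(!missed$forced)[1:20]
  missed$choice[idx] <- "missed"
  missed$reward[idx] <- 0
  expect_false(applyExclusions(missed)$keep)
  expect_true(applyExclusions(missed)$missed_20)

  # 10 incorrect forced responses
  bad_forced <- co$subjects[[1]]$log
  fidx <- which(bad_forced$forced)[1:10]
  bad_forced$choice[fidx] <- ifelse(
    bad_forced$forced_dir[fidx] == "accept", "reject", "accept"
  )
  expect_true(applyExclusions(bad_forced)$incorrect_forced_10)

  # accepting everything on every free trial
  all_acc <- co$subjects[[2]]$log
  all_acc$choice[!all_acc$forced] <- "accept"
  rep_acc <- applyExclusions(all_acc)
  expect_true(rep_acc$all_accept_or_reject)
  expect_false(rep_acc$keep)

  # worst accepted more often than best
  anti <- co$subjects[[2]]$log
  free <- !anti$forced
  anti$choice[free & anti$option == "HDLR"] <- "accept"
  anti$choice[free & anti$option == "LDHR"] <- "reject"
  expect_true(applyExclusions(anti)$poor_discriminability)
})

test_that("the canonical cohort ANOVA shows the option, environment and order effects", {
  co <- generateCohort(cohortSpec(n_subjects = 20, experiment = "exp2", seed = 42))
  acc <- acceptanceRates(cohortLogs(co))
  res <- mixedAnova(acc, "rate", within = c("category", "env"), between = "order")
  p_of <- function(e) res$p[res$effect == e]
  # acceptance tracks option quality and environment richness, their
  # interaction, and the block-order modulation of the environment effect
  expect_lt(p_of("category"), 0.001)
  expect_lt(p_of("env"), 0.05)
  expect_lt(p_of("category:env"), 0.05)
  expect_lt(p_of("env:order"), 0.05)
  expect_true(all(res$peta2 >= 0 & res$peta2 <= 1))
})
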