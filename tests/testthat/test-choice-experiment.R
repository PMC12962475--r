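# Session simulation, preference ratios, bias screening, the hierarchical
# choice model and LOO model comparison.

test_that("preference ratio matches its definition on counts and proportions", {
  expect_equal(preferenceRatio(0.598, 0.25), 0.598 / 0.848)
  # printed two-decimal form, via the published intermediate 0.705
  expect_equal(round(round(preferenceRatio(0.598, 0.25), 3), 2), 0.70)
  expect_equal(preferenceRatio(60, 40), 0.6)
  expect_equal(preferenceRatio(0, 5), 0)
  expect_error(preferenceRatio(0, 0), "undefined")
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50)
    expect_equal(preferenceRatio(a, b) + preferenceRatio(b, a), 1)
  }
})

test_that("session simulation is deterministic and honors its timing", {
  l1 <- simulateSession("b1", mu = 0.5, seed = 99)
  l2 <- simulateSession("b1", mu = 0.5, seed = 99)
  expect_identical(l1@records, l2@records)

  play <- l1@records[l1@records$phase == "playback", ]
  expect_equal(nrow(play), 120L)
  expect_true(all(diff(play$t_start_s) >= 2 + 0.7 + 5 - 1e-9))
  expect_true(validObject(l1))

  forced <- simulateSession("b2", bird_logit = Inf, n_trials = 50, seed = 1)
  fp <- forced@records[forced@records$phase == "playback", ]
  expect_true(all(fp$stimulus_category == "long"))
  expect_true(all(fp$perch == forced@side_assignment))

  expect_error(simulateSession("b3", n_trials = 500), "impossible timing")
})

test_that("an indifferent bird chooses each side half the time", {
  l <- simulateSession("null", mu = 0, sigma_b = 0, n_trials = 10000,
                       seed = 4, session_s = 1e5)
  play <- l@records[l@records$phase == "playback", ]
  frac <- mean(play$stimulus_category == "long")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))  # 3 binomial SEs
})

test_that("session logs round-trip through the CSV format", {
  logs <- simulateExperiment(n_birds = 3, n_trials = 20, seed = 8,
                             experiments = c("replication", "extension"))
  f <- tempfile(fileext = ".csv")
  writeSessionLogs(logs, f)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", header),
               c("bird_id", "session_order", "experiment", "phase",
                 "t_start_s", "perch", "stimulus_category", "stimulus_id",
                 "interrupted"))
  back <- readSessionLogs(f)
  expect_equal(length(back), length(logs))
  orig <- logs[[1]]
  match_id <- vapply(back, function(l)
    l@bird_id == orig@bird_id && l@experiment == orig@experiment,
    logical(1))
  got <- back[[which(match_id)]]
  expect_equal(got@side_assignment, orig@side_assignment)
  expect_equal(got@records$perch, orig@records$perch)
  expect_equal(got@records$t_start_s, orig@records$t_start_s,
               tolerance = 1e-9)
  unlink(f)
})

test_that("the baseline bias screen walks its state machine exactly", {
  expect_equal(baselineBiasScreen(c(10, 10))$decision, "pass")
  expect_equal(baselineBiasScreen(c(16, 4))$decision, "rerun_baseline")
  expect_equal(baselineBiasScreen(c(15, 5))$decision, "pass")  # 0.75 < 0.80
  expect_equal(baselineBiasScreen(c(17, 3))$decision, "rerun_baseline")
  expect_equal(baselineBiasScreen(c(79, 21))$decision, "pass")
  expect_equal(baselineBiasScreen(c(16, 4), c(17, 3))$decision,
               "retest_later")
  expect_equal(baselineBiasScreen(c(16, 4), c(10, 10))$decision, "pass")
  expect_equal(baselineBiasScreen(c(16, 4), c(4, 16))$decision, "pass")
  expect_equal(baselineBiasScreen(c(16, 4), c(17, 3), c(18, 2))$decision,
               "exclude")
  expect_equal(baselineBiasScreen(c(16, 4), c(17, 3), c(11, 9))$decision,
               "pass")
  expect_error(baselineBiasScreen(c(0, 0)), "insufficient data")

  # invariance to left/right relabeling
  set.seed(31)
  for (i in 1:20) {
    b1 <- sample(0:20, 2); if (sum(b1) == 0) b1 <- c(1, 1)
    b2 <- if (runif(1) < 0.7) sample(0:20, 2) else NULL
    if (!is.null(b2) && sum(b2) == 0) b2 <- c(1, 0)
    b3 <- if (!is.null(b2) && runif(1) < 0.5) sample(1:20, 2) else NULL
    d1 <- baselineBiasScreen(b1, b2, b3)$decision
    d2 <- baselineBiasScreen(rev(b1), if (!is.null(b2)) rev(b2),
                             if (!is.null(b3)) rev(b3))$decision
    expect_identical(d1, d2)
  }
})

test_that("the hierarchical model needs multiple birds and playback data", {
  solo <- list(simulateSession("only", seed = 1))
  expect_error(fitChoiceGlmm(solo), "at least 2 birds")
})

test_that("a null population effect is covered by the credible interval", {
  logs <- simulateExperiment(n_birds = 10, mu = 0, sigma_b = 0,
                             n_trials = 300, seed = 41, session_s = 4000)
  fit <- suppressWarnings(
    fitChoiceGlmm(logs, chains = 2, adapt = 500, burnin = 500,
                  sample_iter = 1000, seed = 41))
  ci <- credibleInterval(fit)
  expect_lt(ci["lower"], 0)
  expect_gt(ci["upper"], 0)
})

test_that("complete separation is handled by the weakly informative priors", {
  logs <- lapply(1:4, function(b)
    simulateSession(paste0("b", b), bird_logit = Inf, n_trials = 50,
                    seed = b))
  fit <- suppressWarnings(
    fitChoiceGlmm(logs, chains = 2, adapt = 500, burnin = 500,
                  sample_iter = 1000, seed = 3))
  mu_draws <- fit@draws[, "mu"]
  expect_gt(median(plogis(mu_draws)), 0.9)
  expect_true(all(is.finite(mu_draws)))
})

test_that("the posterior mean agrees with a likelihood-based fit", {
  skip_if_not_installed("lme4")
  logs <- simulateExperiment(n_birds = 16, mu = qlogis(0.65), sigma_b = 0.4,
                             n_trials = 100, seed = 55)
  fit <- fitChoiceGlmm(logs, seed = 55)
  trials <- songpath:::choicesFromLogs(logs)
  df <- do.call(rbind, lapply(split(trials, trials$bird), function(d)
    data.frame(bird = d$bird[1], y = sum(d$choice), n = nrow(d))))
  gl <- lme4::glmer(cbind(y, n - y) ~ 1 + (1 | bird), data = df,
                    family = binomial)
  expect_equal(fit@posterior_mean_logit, unname(lme4::fixef(gl)[1]),
               tolerance = 0.1)
})

test_that("identical model specs are a statistical tie under LOO", {
  logs <- simulateExperiment(n_birds = 6, mu = 0.3, n_trials = 40, seed = 12)
  cmp <- suppressWarnings(
    compareModels(logs, list(choiceModelSpec(), choiceModelSpec()),
                  chains = 2, adapt = 300, burnin = 300,
                  sample_iter = 600, seed = 7))
  expect_true(all(cmp$tie_with_best))
  expect_lt(abs(cmp$delta_elpd[2]), 1)
})

test_that("a strong phase effect is detected by model comparison", {
  # playback preference at logit 1, silent phases indifferent: phase matters
  logs <- simulateExperiment(n_birds = 10, mu = 1.0, sigma_b = 0.3,
                             n_trials = 80, seed = 19)
  cmp <- suppressWarnings(
    compareModels(logs,
                  list(choiceModelSpec(), choiceModelSpec(fixed = "phase")),
                  chains = 2, adapt = 400, burnin = 400,
                  sample_iter = 800, seed = 19))
  expect_equal(cmp$model[1], "choice ~ phase + (1 | bird)")
  expect_false(cmp$tie_with_best[2])
})

test_that("null data do not favor the larger model", {
  wins <- 0L
  for (r in 1:4) {
    logs <- simulateExperiment(n_birds = 6, mu = 0, sigma_b = 0.2,
                               n_trials = 40, seed = 100 + r,
                               experiments = c("replication", "extension"))
    cmp <- suppressWarnings(
      compareModels(logs,
                    list(choiceModelSpec(),
                         choiceModelSpec(fixed = "experiment")),
                    chains = 2, adapt = 300, burnin = 300,
                    sample_iter = 600, seed = 100 + r))
    base_row <- grep("^choice ~ \\(1", cmp$model)
    if (cmp$tie_with_best[base_row] ||
        abs(cmp$delta_elpd[base_row]) <= cmp$se_delta[base_row])
      wins <- wins + 1L
  }
  expect_gte(wins, 2L)  # >= 50% of replicates
})
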