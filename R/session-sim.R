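## Operant two-choice session simulator and session-log bookkeeping:
## baseline -> playback -> post phases, preference ratios, and the
## baseline side-bias screening state machine.

#' Simulate one operant two-choice session
#'
#' Generates a full session for one bird: a silent baseline (both perches
#' active, no audio), a playback phase in which each 2-s perch dwell
#' triggers a randomly selected stimulus of that perch's category, and a
#' silent post-playback phase. Playback choices are Bernoulli draws on the
#' long-path perch with probability \code{plogis(bird_logit)}, where
#' \code{bird_logit = mu + Normal(0, sigma_b)} unless supplied directly.
#' Consecutive playback trials honor the dwell time, stimulus duration and
#' the inter-trial interval, plus an exponential think-time jitter.
#' Interrupted trials (the bird leaves the perch before the stimulus ends)
#' are flagged with probability \code{p_interrupt}; the audio keeps playing,
#' so the trigger still counts as a response. The simulation is
#' deterministic given \code{seed}.
#'
#' @param bird_id bird label.
#' @param mu population log-odds of choosing the long-path perch.
#' @param sigma_b between-bird SD of the intercept on the log-odds scale
#'   (>= 0).
#' @param bird_logit optional fixed bird-level log-odds (overrides
#'   \code{mu}/\code{sigma_b}); may be infinite to force one side.
#' @param n_trials number of playback trials (>= 1; default 120, the
#'   response count a 30-min session typically yields).
#' @param seed integer seed.
#' @param experiment \code{"replication"} or \code{"extension"}.
#' @param session_order \code{"first"} or \code{"second"}.
#' @param side_assignment perch carrying the long-path stimuli.
#' @param long_stimuli,short_stimuli stimulus id pools per category
#'   (defaults: the single replication pair).
#' @param p_interrupt per-trial interruption probability (default 0.1).
#' @param side_logit baseline/post log-odds of landing on the left perch
#'   (default 0: unbiased).
#' @param dwell_s,stim_s,iti_s trigger dwell, stimulus duration and
#'   inter-trial interval in seconds (defaults 2, 0.7, 5).
#' @param session_s playback-phase duration (default 1800 s = 30 min).
#' @param baseline_s,post_s silent-phase durations (default 600 s each).
#' @param baseline_rate_per_min mean perch landings per minute in the silent
#'   phases (default 4).
#' @return a [SessionLog-class].
#' @export
simulateSession <- function(bird_id, mu = 0, sigma_b = 0.5,
                            bird_logit = NULL, n_trials = 120L, seed = 1L,
                            experiment = "replication",
                            session_order = "first",
                            side_assignment = "left",
                            long_stimuli = "long_1",
                            short_stimuli = "short_1",
                            p_interrupt = 0.1, side_logit = 0,
                            dwell_s = 2, stim_s = 0.7, iti_s = 5,
                            session_s = 1800, baseline_s = 600,
                            post_s = 600, baseline_rate_per_min = 4) {
  stopifnot(n_trials >= 1L, sigma_b >= 0)
  min_spacing <- dwell_s + stim_s + iti_s
  if (n_trials * min_spacing > session_s)
    stop("impossible timing: ", n_trials, " trials at minimum spacing ",
         min_spacing, " s exceed the ", session_s, " s session")
  withLocalSeed(seed, {
    if (is.null(bird_logit)) bird_logit <- mu + rnorm(1L, 0, sigma_b)
    p_long <- plogis(bird_logit)
    other <- if (side_assignment == "left") "right" else "left"

    silentPhase <- function(phase, dur) {
      n <- max(1L, stats::rpois(1L, baseline_rate_per_min * dur / 60))
      t <- sort(runif(n, 0, dur))
      left <- runif(n) < plogis(side_logit)
      data.frame(phase = phase, t_start_s = t,
                 perch = ifelse(left, "left", "right"),
                 stimulus_category = "none", stimulus_id = "none",
                 interrupted = FALSE)
    }
    baseline <- silentPhase("baseline", baseline_s)

    # playback-trial spacing: dwell + stimulus + ITI + exponential think-time
    # jitter; if the jittered schedule overruns the session, only the jitter
    # is compressed, so the minimum spacing always holds
    base <- min_spacing * (seq_len(n_trials) - 1L)
    jit <- cumsum(c(0, rexp(n_trials - 1L, rate = 1)))
    budget <- session_s - min_spacing - base[n_trials]
    if (n_trials > 1L && jit[n_trials] > budget)
      jit <- jit * max(budget, 0) / jit[n_trials]
    t_trial <- base + jit
    choice_long <- runif(n_trials) < p_long
    stim <- ifelse(choice_long,
                   sample(rep(long_stimuli, 2L), n_trials, replace = TRUE),
                   sample(rep(short_stimuli, 2L), n_trials, replace = TRUE))
    playback <- data.frame(
      phase = "playback", t_start_s = t_trial,
      perch = ifelse(choice_long, side_assignment, other),
      stimulus_category = ifelse(choice_long, "long", "short"),
      stimulus_id = stim,
      interrupted = runif(n_trials) < p_interrupt)

    post <- silentPhase("post", post_s)
    new("SessionLog", bird_id = as.character(bird_id),
        session_order = session_order, experiment = experiment,
        side_assignment = side_assignment,
        records = rbind(baseline, playback, post))
  })
}

#' Simulate a full counter-balanced experiment
#'
#' Draws one intercept per bird from \code{Normal(mu, sigma_b)} and
#' simulates one session per requested experiment for every bird, with the
#' long-path side and the experiment order counter-balanced across birds.
#'
#' @inheritParams simulateSession
#' @param n_birds number of birds (default 22).
#' @param experiments experiments each bird completes (default replication
#'   only; use \code{c("replication", "extension")} for the two-session
#'   design).
#' @param n_extension_stimuli stimuli per category in the extension pools
#'   (default 10).
#' @param ... further arguments passed to [simulateSession()].
#' @return list of [SessionLog-class] objects.
#' @export
simulateExperiment <- function(n_birds = 22L, mu = 0, sigma_b = 0.5,
                               n_trials = 120L, seed = 1L,
                               experiments = "replication",
                               n_extension_stimuli = 10L, ...) {
  stopifnot(n_birds >= 1L)
  bird_logits <- withLocalSeed(seed, mu + rnorm(n_birds, 0, sigma_b))
  logs <- list()
  for (b in seq_len(n_birds)) {
    first_exp <- experiments[1L + (b %% length(experiments))]
    order_of <- function(e) if (e == first_exp) "first" else "second"
    for (e in experiments) {
      side <- if ((b + match(e, experiments)) %% 2L == 0L) "left" else "right"
      pools <- if (e == "extension")
        list(long = sprintf("ext_long_%02d", seq_len(n_extension_stimuli)),
             short = sprintf("ext_short_%02d", seq_len(n_extension_stimuli)))
      else list(long = "long_1", short = "short_1")
      logs[[length(logs) + 1L]] <- simulateSession(
        bird_id = sprintf("bird_%02d", b), bird_logit = bird_logits[b],
        n_trials = n_trials, seed = seed + 1000L * b + match(e, experiments),
        experiment = e, session_order = order_of(e), side_assignment = side,
        long_stimuli = pools$long, short_stimuli = pools$short, ...)
    }
  }
  logs
}

#' Preference ratio
#'
#' \code{long / (long + short)}: the proportion of long-path responses among
#' all responses. Inputs need not be integers — the same formula applies to
#' time proportions (e.g. proportions 0.598 and 0.25 give 0.705).
#'
#' @param long_count,short_count nonnegative response counts or proportions,
#'   not both zero.
#' @return ratio in [0, 1].
#' @examples
#' preferenceRatio(0.598, 0.25)  # 0.705...
#' @export
preferenceRatio <- function(long_count, short_count) {
  stopifnot(long_count >= 0, short_count >= 0)
  if (long_count + short_count == 0)
    stop("preference ratio undefined: no responses on either side")
  long_count / (long_count + short_count)
}

#' Baseline side-bias screening
#'
#' State machine applied before playback sessions. The bias ratio of a
#' baseline is \code{max(side counts) / total}. A first baseline with ratio
#' below 0.80 passes. A ratio of at least 0.80 (the boundary triggers)
#' requires a second 10-min baseline; if the second baseline is biased
#' toward the same side, the bird must be retested on a later day; if the
#' retest shows the same persistent bias, the bird is excluded. A follow-up
#' baseline that is unbiased — or biased toward the other side — clears the
#' screen. Decisions are invariant to relabeling left and right.
#'
#' @param baseline1 numeric length-2 perch counts \code{c(left, right)} with
#'   a positive total.
#' @param baseline2,retest optional follow-up counts in the same format.
#' @return list with \code{decision} (\code{"pass"},
#'   \code{"rerun_baseline"}, \code{"retest_later"} or \code{"exclude"}),
#'   per-stage bias ratios, and the biased side (or NA).
#' @examples
#' baselineBiasScreen(c(16, 4))$decision  # "rerun_baseline": ratio is 0.80
#' @export
baselineBiasScreen <- function(baseline1, baseline2 = NULL, retest = NULL) {
  stage <- function(x) {
    stopifnot(length(x) == 2L, all(x >= 0))
    if (sum(x) == 0) stop("insufficient data: baseline has no perch triggers")
    ratio <- max(x) / sum(x)
    side <- if (x[1] == x[2]) NA_character_
            else c("left", "right")[which.max(x)]
    list(ratio = ratio, side = side, biased = ratio >= 0.80)
  }
  s1 <- stage(baseline1)
  out <- list(ratio1 = s1$ratio, side1 = s1$side,
              ratio2 = NA_real_, ratio_retest = NA_real_)
  if (!s1$biased) { out$decision <- "pass"; return(out) }
  if (is.null(baseline2)) { out$decision <- "rerun_baseline"; return(out) }
  s2 <- stage(baseline2)
  out$ratio2 <- s2$ratio
  if (!(s2$biased && identical(s2$side, s1$side))) {
    out$decision <- "pass"
    return(out)
  }
  if (is.null(retest)) { out$decision <- "retest_later"; return(out) }
  s3 <- stage(retest)
  out$ratio_retest <- s3$ratio
  out$decision <- if (s3$biased && identical(s3$side, s1$side)) "exclude"
                  else "pass"
  out
}

#' Write / read session logs as CSV
#'
#' One row per trial with columns \code{bird_id, session_order, experiment,
#' phase, t_start_s, perch, stimulus_category, stimulus_id, interrupted}
#' (the fields the playback controller logs). The long-path side assignment
#' is recovered on read from the playback rows (the perch on which
#' long-category stimuli played), so the round trip is lossless.
#'
#' @param logs a [SessionLog-class] or list of them.
#' @param path CSV file path.
#' @return \code{readSessionLogs()} returns a list of
#'   [SessionLog-class] objects; \code{writeSessionLogs()} returns
#'   \code{path} invisibly.
#' @export
writeSessionLogs <- function(logs, path) {
  if (is(logs, "SessionLog")) logs <- list(logs)
  rows <- lapply(logs, function(l) {
    cbind(data.frame(bird_id = l@bird_id, session_order = l@session_order,
                     experiment = l@experiment), l@records)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSessionLogs
#' @export
readSessionLogs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$bird_id, df$experiment, df$session_order, drop = TRUE)
  lapply(split(df, key), function(d) {
    play <- d[d$phase == "playback" & d$stimulus_category == "long", ]
    side <- if (nrow(play)) play$perch[1L] else "left"
    new("SessionLog", bird_id = as.character(d$bird_id[1L]),
        session_order = d$session_order[1L], experiment = d$experiment[1L],
        side_assignment = side,
        records = d[, c("phase", "t_start_s", "perch", "stimulus_category",
                        "stimulus_id", "interrupted")])
  })
}
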