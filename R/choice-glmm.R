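## Bayesian hierarchical logistic choice model (fit with JAGS) and
## approximate leave-one-out model comparison.
##
## choice ~ (1 | bird) is the base model; optional fixed effects (phase,
## experiment, session order) and an optional stimulus-ID random effect
## extend it. Bernoulli trials are aggregated to binomial cells on the full
## (bird, phase, experiment, session order, stimulus) cross before fitting:
## the likelihood is identical, the MCMC far cheaper, and the cell partition
## is the same for every nested model, which keeps LOO scores comparable.

#' Specify a choice model
#'
#' @param fixed character subset of \code{c("phase", "experiment",
#'   "session_order")} to include as fixed effects (treatment-coded;
#'   reference levels playback / replication / first).
#' @param stimulus_ranef logical; add a random intercept per stimulus ID
#'   (the extension-experiment term).
#' @return a list with class \code{"choiceModelSpec"} carrying the model
#'   label in lme4-style notation.
#' @examples
#' choiceModelSpec()                      # choice ~ (1 | bird)
#' choiceModelSpec(fixed = "phase")
#' @export
choiceModelSpec <- function(fixed = character(), stimulus_ranef = FALSE) {
  if (length(fixed))
    fixed <- match.arg(fixed, c("phase", "experiment", "session_order"),
                       several.ok = TRUE)
  label <- paste0("choice ~ ",
                  if (length(fixed)) paste(c("", fixed), collapse = " + ")
                  else "",
                  if (length(fixed)) " + " else "",
                  "(1 | bird)",
                  if (stimulus_ranef) " + (1 | stimulus)" else "")
  structure(list(fixed = fixed, stimulus_ranef = stimulus_ranef,
                 label = gsub("~  \\+ ", "~ ", label)),
            class = "choiceModelSpec")
}

# Per-trial choice data frame from session logs. Playback trials code
# choice = 1 for the long-path stimulus; silent-phase (baseline/post) perch
# triggers are coded against the session's long-path side.
choicesFromLogs <- function(logs, phases = "playback",
                            include_interrupted = TRUE) {
  stopifnot(length(logs) > 0L)
  if (is(logs, "SessionLog")) logs <- list(logs)
  rows <- lapply(logs, function(l) {
    r <- l@records
    r <- r[r$phase %in% phases, , drop = FALSE]
    if (!include_interrupted) r <- r[!r$interrupted, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(bird = l@bird_id, phase = r$phase,
               experiment = l@experiment, session_order = l@session_order,
               stimulus_id = r$stimulus_id,
               choice = as.integer(r$perch == l@side_assignment))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no choices found in the requested phases")
  out
}

# Aggregate trials to binomial cells on the full covariate cross.
aggregateCells <- function(trials) {
  cells <- aggregate(cbind(y = trials$choice, n = 1) ~
                       bird + phase + experiment + session_order + stimulus_id,
                     data = trials, FUN = sum)
  cells[do.call(order, cells[c("bird", "phase", "experiment",
                               "session_order", "stimulus_id")]), ,
        drop = FALSE]
}

fixedDesign <- function(cells, fixed) {
  refs <- c(phase = "playback", experiment = "replication",
            session_order = "first")
  cols <- list()
  for (f in fixed) {
    v <- factor(cells[[f]])
    if (refs[[f]] %in% levels(v)) v <- stats::relevel(v, refs[[f]])
    for (lev in levels(v)[-1L])
      cols[[paste0(f, "_", lev)]] <- as.numeric(v == lev)
  }
  if (!length(cols)) return(matrix(0, nrow(cells), 0L))
  do.call(cbind, cols)
}

choiceJagsCode <- function(n_beta, stimulus_ranef, prior_sd_fixed,
                           prior_scale_ranef) {
  paste0(
    "model {\n",
    "  for (i in 1:C) {\n",
    "    y[i] ~ dbin(p[i], n[i])\n",
    "    logit(p[i]) <- mu + b[bird[i]]",
    if (n_beta > 0L) " + inprod(X[i,], beta)" else "",
    if (stimulus_ranef) " + s[stim[i]]" else "", "\n",
    "  }\n",
    "  for (j in 1:B) { b[j] ~ dnorm(0, tau_b) }\n",
    "  sigma_b ~ dnorm(0, ", 1 / prior_scale_ranef^2, ") T(0,)\n",
    "  tau_b <- pow(sigma_b, -2)\n",
    if (n_beta > 0L) paste0(
      "  for (m in 1:P) { beta[m] ~ dnorm(0, ", 1 / prior_sd_fixed^2,
      ") }\n") else "",
    if (stimulus_ranef) paste0(
      "  for (q in 1:S) { s[q] ~ dnorm(0, tau_s) }\n",
      "  sigma_s ~ dnorm(0, ", 1 / prior_scale_ranef^2, ") T(0,)\n",
      "  tau_s <- pow(sigma_s, -2)\n") else "",
    "  mu ~ dnorm(0, ", 1 / prior_sd_fixed^2, ")\n",
    "}\n")
}

#' Fit the Bayesian hierarchical choice model
#'
#' Fits a binomial logit model for the probability of choosing the
#' long-path stimulus, with a random intercept per bird and the optional
#' terms of a [choiceModelSpec()]. Priors are weakly informative:
#' Normal(0, 1.5) on the population log-odds and fixed effects (roughly flat
#' on the probability scale) and half-Normal(1) on random-effect SDs, so
#' complete separation (every bird choosing long) still yields a proper
#' posterior. Sampling uses JAGS with a fixed, recorded seed; convergence is
#' checked with split-Rhat on the population-level parameters and failures
#' are flagged on the returned object (never silently dropped).
#'
#' @param logs list of [SessionLog-class] objects from at least 2 birds.
#' @param spec a [choiceModelSpec()] (default: the base random-intercept
#'   model).
#' @param phases phases whose responses enter the model. Default:
#'   \code{"playback"} for models without a phase effect, all three phases
#'   when \code{"phase"} is a fixed effect.
#' @param include_interrupted count interrupted trials as choices (default
#'   TRUE: the perch trigger is the choice and responses are counted
#'   including interrupted trials).
#' @param chains,adapt,burnin,sample_iter MCMC settings (default 4 chains,
#'   1000 adaptation, 1000 burn-in, 2000 retained iterations per chain).
#' @param seed integer sampler seed.
#' @param rhat_threshold split-Rhat convergence threshold (default 1.01).
#' @param prior_sd_fixed,prior_scale_ranef prior scales (defaults 1.5, 1).
#' @param max_loo_draws posterior draws retained for the pointwise
#'   log-likelihood / LOO computation (default 1000).
#' @return a [PreferenceEstimate-class].
#' @export
fitChoiceGlmm <- function(logs, spec = choiceModelSpec(),
                          phases = NULL, include_interrupted = TRUE,
                          chains = 4L, adapt = 1000L, burnin = 1000L,
                          sample_iter = 2000L, seed = 1L,
                          rhat_threshold = 1.01, prior_sd_fixed = 1.5,
                          prior_scale_ranef = 1, max_loo_draws = 1000L) {
  stopifnot(inherits(spec, "choiceModelSpec"))
  if (is.null(phases))
    phases <- if ("phase" %in% spec$fixed)
      c("baseline", "playback", "post") else "playback"
  trials <- choicesFromLogs(logs, phases = phases,
                            include_interrupted = include_interrupted)
  if (!any(trials$phase == "playback"))
    stop("no playback-phase choices present")
  cells <- aggregateCells(trials)
  birds <- sort(unique(cells$bird))
  if (length(birds) < 2L)
    stop("the hierarchical model needs at least 2 birds")
  X <- fixedDesign(cells, spec$fixed)
  stims <- sort(unique(cells$stimulus_id))
  dat <- list(y = cells$y, n = cells$n, C = nrow(cells),
              bird = match(cells$bird, birds), B = length(birds))
  if (ncol(X) > 0L) { dat$X <- X; dat$P <- ncol(X) }
  if (spec$stimulus_ranef) {
    dat$stim <- match(cells$stimulus_id, stims)
    dat$S <- length(stims)
  }
  code <- choiceJagsCode(ncol(X), spec$stimulus_ranef, prior_sd_fixed,
                         prior_scale_ranef)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))
  jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = TRUE)
  update(jm, n.iter = burnin, progress.bar = "none")
  monitors <- c("mu", "sigma_b",
                if (ncol(X) > 0L) "beta",
                if (spec$stimulus_ranef) "sigma_s", "b",
                if (spec$stimulus_ranef) "s")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = sample_iter, progress.bar = "none")

  pop_pars <- c("mu", "sigma_b",
                if (ncol(X) > 0L) grep("^beta", coda::varnames(samp),
                                       value = TRUE))
  rhat <- tryCatch(
    coda::gelman.diag(samp[, pop_pars, drop = FALSE], autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1L],
    error = function(e) setNames(rep(NA_real_, length(pop_pars)), pop_pars))
  converged <- all(is.finite(rhat)) && all(rhat < rhat_threshold)
  if (!converged)
    warning("convergence not reached: max split-Rhat = ",
            signif(max(rhat, na.rm = TRUE), 4),
            " (threshold ", rhat_threshold, ")")

  draws <- as.matrix(samp)
  mu_d <- draws[, "mu"]

  # pointwise binomial log-likelihood on thinned draws
  keep <- unique(round(seq(1L, nrow(draws),
                           length.out = min(max_loo_draws, nrow(draws)))))
  eta <- matrix(mu_d[keep], length(keep), nrow(cells))
  bcols <- paste0("b[", dat$bird, "]")
  eta <- eta + draws[keep, bcols, drop = FALSE]
  if (ncol(X) > 0L) {
    beta_cols <- paste0("beta", if (ncol(X) == 1L) "" else
      paste0("[", seq_len(ncol(X)), "]"))
    if (!all(beta_cols %in% colnames(draws)))
      beta_cols <- grep("^beta", colnames(draws), value = TRUE)
    eta <- eta + draws[keep, beta_cols, drop = FALSE] %*% t(X)
  }
  if (spec$stimulus_ranef)
    eta <- eta + draws[keep, paste0("s[", dat$stim, "]"), drop = FALSE]
  # per-draw Bernoulli log-likelihoods for each cell outcome (stable tails)
  lls <- plogis(eta, log.p = TRUE)                      # success (long)
  llf <- plogis(eta, log.p = TRUE, lower.tail = FALSE)  # failure (short)
  ll <- cbind(lls, llf)
  loo <- bernoulliLoo(ll, cells$y, cells$n)

  fx <- if (ncol(X) > 0L) {
    bc <- grep("^beta", colnames(draws), value = TRUE)
    data.frame(term = colnames(X), mean = colMeans(draws[, bc, drop = FALSE]),
               ci95_low = apply(draws[, bc, drop = FALSE], 2L, quantile, 0.025),
               ci95_high = apply(draws[, bc, drop = FALSE], 2L, quantile, 0.975),
               row.names = NULL)
  } else data.frame(term = character(), mean = numeric(),
                    ci95_low = numeric(), ci95_high = numeric())

  new("PreferenceEstimate",
      posterior_mean_logit = mean(mu_d),
      ci95_low = unname(quantile(mu_d, 0.025)),
      ci95_high = unname(quantile(mu_d, 0.975)),
      pr_mean = plogis(mean(mu_d)),
      model_label = spec$label,
      loo_elpd = loo$elpd, loo_se = loo$se,
      fixed_effects = fx,
      diagnostics = list(rhat = rhat,
                         n_eff = coda::effectiveSize(samp[, pop_pars,
                                                          drop = FALSE]),
                         chains = chains, adapt = adapt, burnin = burnin,
                         sample_iter = sample_iter, seed = seed,
                         phases = phases,
                         include_interrupted = include_interrupted),
      converged = converged,
      draws = draws[, pop_pars, drop = FALSE],
      log_lik = ll, cells = cells)
}

# Leave-one-trial-out elpd for one column of log-likelihood draws, by
# truncated importance sampling: raw weights 1/p(y_i|theta) truncated at
# sqrt(S) times their mean (Ionides 2008), combined on the log scale.
tisElpd <- function(llcol) {
  S <- length(llcol)
  logSumExp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lw <- -llcol
  lw <- lw - max(lw)
  lw <- pmin(lw, log(mean(exp(lw))) + 0.5 * log(S))
  logSumExp(lw + llcol) - logSumExp(lw)
}

# Observation-level (Bernoulli) approximate LOO. Trials within a cell that
# share an outcome have identical leave-one-out predictive densities, so the
# elpd is evaluated once per cell-outcome pair and replicated by its count.
# `ll` holds the success columns (1..C) then the failure columns (C+1..2C).
bernoulliLoo <- function(ll, y, n) {
  C <- length(y)
  es <- vapply(seq_len(C), function(i)
    if (y[i] > 0L) tisElpd(ll[, i]) else NA_real_, numeric(1))
  ef <- vapply(seq_len(C), function(i)
    if (n[i] - y[i] > 0L) tisElpd(ll[, C + i]) else NA_real_, numeric(1))
  pointwise <- unlist(lapply(seq_len(C), function(i)
    c(rep(es[i], y[i]), rep(ef[i], n[i] - y[i]))))
  list(elpd = sum(pointwise), se = sqrt(length(pointwise) * var(pointwise)),
       pointwise = pointwise)
}

#' Compare choice models by approximate LOO
#'
#' Fits each model specification on the same data (same phases, same
#' interrupted-trial handling, hence identical binomial cells) and ranks
#' them by approximate leave-one-out expected log predictive density. The
#' standard error of each pairwise difference against the best model is
#' computed from the paired pointwise differences; models within one SE of
#' the best are flagged as statistically indistinguishable ties.
#'
#' @param logs list of [SessionLog-class] objects.
#' @param specs list of [choiceModelSpec()] objects (>= 2).
#' @param phases phases to include for all models; default: all three
#'   phases if any model has a phase effect, playback only otherwise.
#' @param ... further arguments passed to [fitChoiceGlmm()].
#' @return data.frame ranked by \code{elpd_loo} with columns \code{model},
#'   \code{elpd_loo}, \code{se_elpd}, \code{delta_elpd}, \code{se_delta},
#'   \code{tie_with_best}; the fitted models are attached as attribute
#'   \code{"fits"}.
#' @export
compareModels <- function(logs, specs, phases = NULL, ...) {
  stopifnot(length(specs) >= 2L,
            all(vapply(specs, inherits, logical(1), "choiceModelSpec")))
  if (is.null(phases))
    phases <- if (any(vapply(specs, function(s) "phase" %in% s$fixed,
                             logical(1))))
      c("baseline", "playback", "post") else "playback"
  fits <- lapply(specs, function(s)
    fitChoiceGlmm(logs, spec = s, phases = phases, ...))
  key <- lapply(fits, function(f)
    f@cells[c("bird", "phase", "experiment", "session_order", "stimulus_id",
              "y", "n")])
  if (!all(vapply(key[-1L], identical, logical(1), key[[1L]])))
    stop("models were fit on differing data cells; comparison is invalid")
  pw <- lapply(fits, function(f)
    bernoulliLoo(f@log_lik, f@cells$y, f@cells$n)$pointwise)
  elpd <- vapply(pw, sum, numeric(1))
  se <- vapply(pw, function(p) sqrt(length(p) * var(p)), numeric(1))
  best <- which.max(elpd)
  delta <- elpd - elpd[best]
  se_delta <- vapply(seq_along(pw), function(m) {
    dd <- pw[[m]] - pw[[best]]
    sqrt(length(dd) * var(dd))
  }, numeric(1))
  out <- data.frame(
    model = vapply(fits, function(f) f@model_label, character(1)),
    elpd_loo = elpd, se_elpd = se, delta_elpd = delta, se_delta = se_delta,
    tie_with_best = abs(delta) <= pmax(se_delta, 1e-8))
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
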