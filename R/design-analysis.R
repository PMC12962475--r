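## Design analysis in the Gelman-Carlin sense: given an assumed true effect
## A (log-odds of the hypothesized preference ratio) and the standard error
## s the planned design is expected to achieve, compute the power of the
## two-sided test, the Type S error (probability a significant estimate has
## the wrong sign) and the Type M error (expected exaggeration factor of a
## significant estimate).

#' Convert a preference ratio to log-odds
#'
#' \code{ln(pr / (1 - pr))}: the effect size, on the log-odds scale, that a
#' hypothetical preference ratio corresponds to in the logistic model.
#' Boundary values (0 and 1) are rejected.
#'
#' @param pr preference ratio strictly inside (0, 1).
#' @return log-odds.
#' @examples
#' prToLogodds(0.70)  # 0.8473
#' @export
prToLogodds <- function(pr) {
  if (any(pr <= 0 | pr >= 1))
    stop("preference ratio must lie strictly inside (0, 1)")
  qlogis(pr)
}

#' @rdname prToLogodds
#' @param logodds value on the log-odds scale.
#' @export
logoddsToPr <- function(logodds) plogis(logodds)

#' Power, Type S and Type M for an assumed effect and standard error
#'
#' With lambda = A/s and z* the two-sided critical value at level
#' \code{alpha}:
#' \deqn{power = \Phi(\lambda - z^*) + \Phi(-\lambda - z^*)}
#' \deqn{Type\,S = \Phi(-\lambda - z^*) / power}
#' \deqn{Type\,M = E[|\lambda + Z| \cdot 1\{|\lambda + Z| > z^*\}] /
#'   (power \cdot \lambda)}
#' Type M is evaluated in closed truncated-normal form (or by numerical
#' integration of the t density when \code{df} is finite). An independent
#' seeded Monte-Carlo mode (\code{method = "mc"}) is provided as an oracle.
#' For A = 0 power equals alpha and Type S equals 0.5 by symmetry, while
#' Type M is undefined and reported as \code{NA} with a message.
#'
#' @param pr hypothetical preference ratio (converted to
#'   \code{A = ln(pr/(1-pr))}); alternatively supply \code{A} directly.
#' @param A true effect on the log-odds scale (used when \code{pr} is
#'   missing).
#' @param s standard error of the estimate, > 0 (default 0.22, the expected
#'   maximum SE of the planned 22-bird design; see the vignette).
#' @param alpha two-sided test level (default 0.05).
#' @param df degrees of freedom of the reference distribution
#'   (default \code{Inf}: standard normal).
#' @param method \code{"analytic"} (default) or \code{"mc"}.
#' @param n_sim Monte-Carlo draws for \code{method = "mc"} (default 1e6).
#' @param seed Monte-Carlo seed.
#' @return a [RetrodesignResult-class].
#' @examples
#' retrodesign(pr = 0.60, s = 0.22)   # power ~ 0.45
#' retrodesign(pr = 0.55, s = 0.22)   # Type M ~ 2.7
#' @export
retrodesign <- function(pr = NULL, A = NULL, s = 0.22, alpha = 0.05,
                        df = Inf, method = c("analytic", "mc"),
                        n_sim = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (!is.null(pr)) A <- prToLogodds(pr)
  if (is.null(A)) stop("supply either pr or A")
  stopifnot(s > 0, alpha > 0, alpha < 1)
  sign_flip <- A < 0
  A_abs <- abs(A)
  lam <- A_abs / s
  crit <- if (is.finite(df)) qt(1 - alpha / 2, df) else qnorm(1 - alpha / 2)
  pdist <- function(q) if (is.finite(df)) pt(q, df) else pnorm(q)

  if (method == "mc") {
    res <- withLocalSeed(seed, {
      est <- A_abs + s * (if (is.finite(df)) rt(n_sim, df) else rnorm(n_sim))
      sig <- abs(est / s) > crit
      pow <- mean(sig)
      ts <- if (pow > 0) mean(est < 0 & sig) / pow else NA_real_
      tm <- if (A_abs > 0 && pow > 0) mean(abs(est[sig])) / A_abs
            else NA_real_
      list(pow = pow, ts = ts, tm = tm)
    })
    pow <- res$pow; ts <- res$ts; tm <- res$tm
  } else {
    pow <- pdist(lam - crit) + pdist(-lam - crit)
    ts <- pdist(-lam - crit) / pow
    tm <- if (A_abs == 0) {
      message("Type M is undefined for a zero effect; reporting NA")
      NA_real_
    } else if (is.finite(df)) {
      num <- integrate(function(t) abs(lam + t) *
                         (abs(lam + t) > crit) * stats::dt(t, df),
                       -Inf, Inf, rel.tol = 1e-10)$value
      num / (pow * lam)
    } else {
      # E[(lam+Z) 1{Z > crit-lam}] + E[-(lam+Z) 1{Z < -crit-lam}]
      e_hi <- lam * pnorm(lam - crit) + dnorm(lam - crit)
      e_lo <- -lam * pnorm(-crit - lam) + dnorm(crit + lam)
      (e_hi + e_lo) / (pow * lam)
    }
  }
  if (A_abs == 0 && method == "analytic") ts <- 0.5
  new("RetrodesignResult", power = pow, type_s = ts, type_m = tm,
      effect = if (sign_flip) -A_abs else A_abs, se = s, alpha = alpha,
      method = method)
}

#' Design-analysis table over hypothetical preference ratios
#'
#' Tabulates power, Type S and Type M for a set of hypothetical preference
#' ratios at a common standard error — the planning table for the operant
#' preference design (strong preference 0.70 down to weak preference 0.55).
#'
#' @param prs preference ratios (default \code{c(0.55, 0.60, 0.65, 0.70)}).
#' @inheritParams retrodesign
#' @return data.frame with columns \code{pr}, \code{log_odds}, \code{power},
#'   \code{type_s}, \code{type_m}.
#' @export
retrodesignTable <- function(prs = c(0.55, 0.60, 0.65, 0.70), s = 0.22,
                             alpha = 0.05) {
  rows <- lapply(prs, function(p) {
    r <- retrodesign(pr = p, s = s, alpha = alpha)
    data.frame(pr = p, log_odds = r@effect, power = r@power,
               type_s = r@type_s, type_m = r@type_m)
  })
  do.call(rbind, rows)
}

#' Sampling distribution of the population-effect standard error
#'
#' Simulates the planned hierarchical design repeatedly (birds with
#' Normal-distributed intercept and slope deviations, binomial responses)
#' and, per scenario, estimates the standard error of the population
#' log-odds by a fast approximation: an intercept-only binomial logistic
#' fit on bird-level counts with a cluster-robust (sandwich) variance,
#' clustering on bird. Reports the minimum, mean and maximum SE across
#' scenarios — the quantities that feed [retrodesign()] when planning.
#'
#' @param birds number of birds (default 22).
#' @param trials responses per bird (default 120; must be >= 2).
#' @param sigma_bird SD of bird intercept deviations, log-odds (default
#'   0.5).
#' @param sigma_slope SD of bird slope (condition) deviations, log-odds
#'   (default 0.25); adds bird-level variance to the playback effect.
#' @param mu population log-odds (default 0).
#' @param n_scenarios number of simulated scenarios (>= 1).
#' @param seed integer seed.
#' @return list with \code{summary} (min, mean, max) and the per-scenario
#'   \code{se} vector.
#' @export
seDistribution <- function(birds = 22L, trials = 120L, sigma_bird = 0.5,
                           sigma_slope = 0.25, mu = 0, n_scenarios = 100L,
                           seed = 1L) {
  stopifnot(n_scenarios >= 1L, birds >= 2L)
  if (trials < 2L)
    stop("degenerate design: need at least 2 trials per bird")
  sd_tot <- sqrt(sigma_bird^2 + sigma_slope^2)
  se <- withLocalSeed(seed, vapply(seq_len(n_scenarios), function(sc) {
    eta <- mu + rnorm(birds, 0, sd_tot)
    y <- rbinom(birds, trials, plogis(eta))
    fit <- glm(cbind(y, trials - y) ~ 1, family = binomial())
    vc <- sandwich::vcovCL(fit, cluster = factor(seq_len(birds)))
    sqrt(vc[1L, 1L])
  }, numeric(1)))
  list(summary = c(min = min(se), mean = mean(se), max = max(se)), se = se)
}
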