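#' Stimulus set of the 2AFC temporal-frequency task
#'
#' The nine grating frequencies, split into a low class and a high class
#' around the boundary \code{s0}.  The boundary stimulus belongs to
#' neither class and is randomly rewarded in the task.
#'
#' @param s0 Category boundary in Hz.
#' @param low_tfs,high_tfs Class members in Hz; equal counts \code{K}.
#' @return An object of class \code{"stimulus_set"}.
#' @export
stimulus_set <- function(s0 = 2.12,
                         low_tfs = c(0.25, 0.82, 1.32, 1.75),
                         high_tfs = c(2.48, 2.91, 3.41, 4)) {
  if (length(low_tfs) != length(high_tfs)) {
    stop("low and high classes must have equal counts")
  }
  structure(list(s0 = s0, low_tfs = sort(low_tfs),
                 high_tfs = sort(high_tfs), K = length(low_tfs)),
            class = "stimulus_set")
}

#' Per-animal ideal-observer parameters
#'
#' @param sigma Sensory noise in Hz-equivalent units (> 0).  May have one
#'   entry per intensity level.
#' @param gamma Gain factor(s), one per intensity level (or per condition),
#'   all > 0 for a monotone psychometric function.
#' @param eps_h,eps_l Lapse rates towards "high" / "low"; non-negative,
#'   summing to at most 1.
#' @param lam Offset term in Hz (projection intercept over slope);
#'   0 in the core model.
#' @return An object of class \code{"observer_params"}.
#' @export
observer_params <- function(sigma, gamma, eps_h = 0, eps_l = 0, lam = 0) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (eps_h < 0 || eps_l < 0 || eps_h + eps_l > 1) {
    stop("lapse rates must be non-negative and sum to at most 1")
  }
  structure(list(sigma = sigma, gamma = gamma, eps_h = eps_h,
                 eps_l = eps_l, lam = lam),
            class = "observer_params")
}

#' Psychometric function of the gain-compressed ideal observer
#'
#' Probability of reporting "high" for stimulus \code{s} under sound
#' intensity level \code{level}:
#' \deqn{p(\hat C = H \mid s, n) = \epsilon_H + (1 - \epsilon_H - \epsilon_L)
#'   \Phi\!\left[\frac{\gamma_n s - s_0 + (\gamma_n - 1)\lambda}{\sigma}\right].}
#' With \eqn{\lambda = 0} this is the core model: the sound scales the
#' internal measurement by \eqn{\gamma_n} while the decision boundary
#' stays at its training value, so \eqn{\gamma_n < 1} shifts responses
#' toward "high", most strongly at high frequencies.
#'
#' @param s Stimulus temporal frequency in Hz (vectorised).
#' @param level Intensity-level index into \code{params$gamma} (vectorised).
#' @param params An \code{observer_params} object.
#' @param s0 Category boundary in Hz.
#' @return Probability of reporting "high", in \eqn{[\epsilon_H, 1-\epsilon_L]}.
#' @export
psychometric <- function(s, level, params, s0 = 2.12) {
  if (any(level < 1) || any(level > length(params$gamma))) {
    stop("'level' indexes a gain that does not exist")
  }
  g <- params$gamma[level]
  sg <- if (length(params$sigma) > 1) params$sigma[level] else params$sigma
  params$eps_h + (1 - params$eps_h - params$eps_l) *
    pnorm((g * s - s0 + (g - 1) * params$lam) / sg)
}

#' Draw a single choice from the psychometric model
#'
#' @inheritParams psychometric
#' @return Character vector of choices, \code{"H"} or \code{"L"}.
#' @export
simulate_choice <- function(s, level, params, s0 = 2.12) {
  p <- psychometric(s, level, params, s0)
  ifelse(runif(length(p)) < p, "H", "L")
}

#' Reduced generative-observer configuration
#'
#' Under linear population encoding the measurement is Gaussian with mean
#' \eqn{\nu(s) = a + b s} and sd \eqn{\rho}; \code{a} and \code{b} are the
#' projections of the encoding intercept and slope on the readout axis.
#' This reduction is exact, so the full neural population never needs to
#' be simulated.
#'
#' @param intercept_proj Projection intercept \code{a} (measurement units).
#' @param slope_proj Projection slope \code{b} (measurement units per Hz,
#'   non-zero).
#' @param rho Measurement noise sd (> 0).
#' @param n_mc Monte-Carlo draws for \code{\link{generative_oracle}}.
#' @return An object of class \code{"generative_observer_config"}.
#' @export
generative_observer_config <- function(intercept_proj = 0, slope_proj = 1,
                                       rho = 0.5, n_mc = 1e5) {
  if (slope_proj == 0) stop("'slope_proj' must be non-zero")
  if (rho <= 0) stop("'rho' must be positive")
  structure(list(intercept_proj = intercept_proj, slope_proj = slope_proj,
                 rho = rho, n_mc = n_mc),
            class = "generative_observer_config")
}

#' Bayes-optimal decision boundary of the measurement
#'
#' For the symmetric stimulus set the class posteriors are equal exactly
#' at the image of the boundary stimulus, \eqn{x^* = a + b s_0}.
#' \code{numeric = TRUE} instead root-finds the posterior-equality point of
#' the 9-component mixture, as an independent check of the identity.
#'
#' @param cfg A \code{generative_observer_config}.
#' @param stimset A \code{stimulus_set}.
#' @param numeric Root-find the boundary instead of using the closed form.
#' @return Measurement-unit threshold \eqn{x^*}.
#' @export
decision_boundary <- function(cfg, stimset = stimulus_set(), numeric = FALSE) {
  xstar <- cfg$intercept_proj + cfg$slope_proj * stimset$s0
  if (!numeric) return(xstar)
  nu <- function(s) cfg$intercept_proj + cfg$slope_proj * s
  f <- function(x) class_posterior(x, cfg, stimset) - 0.5
  span <- abs(cfg$slope_proj) * (max(stimset$high_tfs) - min(stimset$low_tfs)) +
    6 * cfg$rho
  uniroot(f, lower = xstar - span, upper = xstar + span, tol = 1e-12)$root
}

#' Posterior probability of the high class given a measurement
#'
#' Evaluates the class-conditional likelihoods as Gaussian mixtures over
#' the stimulus set (each class: its K members with weight 2/(2K+1) each
#' plus the shared boundary stimulus with weight 1/(2K+1)) and returns
#' \eqn{p(H \mid x)} with equal class priors.
#'
#' @param x Measurement value(s).
#' @param cfg A \code{generative_observer_config}.
#' @param stimset A \code{stimulus_set}.
#' @return Posterior probability of class H, vectorised over \code{x}.
#' @export
class_posterior <- function(x, cfg, stimset = stimulus_set()) {
  nu <- function(s) cfg$intercept_proj + cfg$slope_proj * s
  K <- stimset$K
  mix <- function(x, tfs) {
    w <- c(rep(2, K), 1) / (2 * K + 1)
    mu <- nu(c(tfs, stimset$s0))
    vals <- vapply(seq_along(mu),
                   function(j) w[j] * dnorm(x, mu[j], cfg$rho),
                   numeric(length(x)))
    if (length(x) == 1L) sum(vals) else rowSums(vals)
  }
  lh <- mix(x, stimset$high_tfs)
  ll <- mix(x, stimset$low_tfs)
  lh / (lh + ll)
}

#' Monte-Carlo generative observer
#'
#' Brute-force route to the choice probability: draws measurements from
#' the sound-scaled encoding \eqn{x \sim N(\gamma(a + b s), \rho)} (the
#' gain multiplies the full mean response) and thresholds them at the
#' training-condition boundary \eqn{x^* = a + b s_0}.  Its empirical
#' choice rate converges to the closed-form psychometric function with
#' \eqn{\sigma = \rho / b} and \eqn{\lambda = a / b}.
#'
#' @param s Stimulus frequency in Hz (scalar).
#' @param gamma Gain factor.
#' @param cfg A \code{generative_observer_config}.
#' @param stimset A \code{stimulus_set}.
#' @return Empirical probability of reporting "high".
#' @export
generative_oracle <- function(s, gamma, cfg, stimset = stimulus_set()) {
  xstar <- cfg$intercept_proj + cfg$slope_proj * stimset$s0
  mu <- gamma * (cfg$intercept_proj + cfg$slope_proj * s)
  x <- rnorm(cfg$n_mc, mu, cfg$rho)
  if (cfg$slope_proj > 0) mean(x > xstar) else mean(x < xstar)
}
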