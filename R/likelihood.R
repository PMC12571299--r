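#' Per-trial log-likelihood of observer parameters
#'
#' Log probability of each observed choice under the psychometric model:
#' \eqn{\log p(\hat C = H \mid s, n)} for "high" choices and the log of
#' the complement for "low" choices.  Probabilities are clipped to
#' \code{[1e-12, 1 - 1e-12]} before taking logs.
#'
#' @param params An \code{\link{observer_params}} object.
#' @param trials Trial data frame; every row must carry a visual stimulus
#'   and (when the parameter set has several gains) an intensity level.
#' @param s0 Category boundary in Hz.
#' @return Numeric vector of per-trial log probabilities.
#' @export
log_likelihood <- function(params, trials, s0 = 2.12) {
  bad <- which(is.na(trials$visual_tf_hz))
  if (length(bad)) {
    stop("trial(s) without a visual stimulus must be excluded upstream: row ",
         bad[1])
  }
  lev <- if (length(params$gamma) == 1L) rep(1L, nrow(trials))
         else trials$intensity_level
  p <- psychometric(trials$visual_tf_hz, lev, params, s0)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ifelse(trials$choice == "H", log(p), log1p(-p))
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Evaluates the per-trial log-likelihood at every retained posterior
#' draw, the quantity needed for predictive-density model comparison.
#' Computed in draw blocks to bound memory.
#'
#' @param fit An \code{observer_fit}.
#' @param block Draws per block.
#' @return An S x N matrix (posterior draws by trials).
#' @export
pointwise_loglik <- function(fit, block = 200L) {
  y <- fit$trials$choice == "H"
  S <- fit$n_draws * fit$chains
  out <- matrix(NA_real_, S, nrow(fit$trials))
  for (lo in seq(1L, S, by = block)) {
    hi <- min(lo + block - 1L, S)
    p <- choice_prob_matrix(fit, fit$trials, rows = lo:hi)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    out[lo:hi, !y] <- log1p(-p[, !y, drop = FALSE])
    out[lo:hi, y] <- log(p[, y, drop = FALSE])
  }
  out
}

#' Probability of direction of a posterior sample
#'
#' Proportion of the posterior draws sharing the sign of the posterior
#' median; ranges from 0.5 (no directional evidence) to 1.  The companion
#' value \eqn{p \simeq 2(1 - pd)} approximates a two-sided frequentist
#' p-value in simple regression settings.
#'
#' @param x Numeric posterior draws of a scalar parameter (>= 100).
#' @return List with elements \code{pd} and \code{p_two_sided}.
#' @export
probability_of_direction <- function(x) {
  if (length(x) < 100) stop("need at least 100 draws")
  md <- median(x)
  pd <- if (md >= 0) mean(x > 0) else mean(x < 0)
  pd <- max(pd, 0.5)
  list(pd = pd, p_two_sided = 2 * (1 - pd))
}
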