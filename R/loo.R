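# Predictive-density model comparison.
#
# ELPD_LOO = sum_i log( average over the leave-one-out posterior of the
# likelihood of trial i ).  Exact computation refits the model once per
# trial; the importance-sampling approximation reuses the full-data
# posterior with per-trial importance ratios 1/p(d_i | theta), stabilised
# by Pareto-smoothing the right tail of the ratio distribution.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Generalised Pareto fit to tail exceedances (Zhang & Stephens 2009
# posterior-mean estimator, with the mild prior regularisation of the
# shape parameter customary for importance-ratio diagnostics).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * xq)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  k <- (n * k + 5 * 0.5) / (n + 10)   # shrink shape towards 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth a vector of log importance ratios; returns the smoothed
# log weights (unnormalised, capped at the raw maximum) and the shape k.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = 0))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (max(exc) <= 0) return(list(lw = lw, k = 0))
  fit <- gpd_fit(exc[exc > 0])
  if (!is.finite(fit$k)) return(list(lw = lw, k = Inf))
  p <- (rank(lw[tail_idx], ties.method = "first") - 0.5) / M
  sm <- log(qgpd(p, fit$k, fit$sigma) + exp(cutoff))
  lw[tail_idx] <- pmin(sm, 0)
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Computes the leave-one-out ELPD of a fitted observer model by
#' Pareto-smoothed importance sampling over the posterior draws.  Returns
#' the total ELPD, its standard error over trials, the per-trial values
#' and the per-trial Pareto shape diagnostics (values above 0.7 flag
#' unreliable importance ratios).
#'
#' @param fit An \code{observer_fit}, or a precomputed S x N pointwise
#'   log-likelihood matrix.
#' @param digest Optional dataset digest (taken from the fit when given).
#' @return An object of class \code{"elpd_result"}.
#' @export
pointwise_elpd <- function(fit, digest = NULL) {
  if (inherits(fit, "observer_fit")) {
    ll <- pointwise_loglik(fit)
    digest <- fit$data_digest
  } else {
    ll <- fit
    if (is.null(ll) || !is.matrix(ll)) stop("pointwise log-likelihood is missing")
  }
  N <- ncol(ll)
  pw <- numeric(N); kk <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - logsumexp(sm$lw)
    pw[i] <- logsumexp(lw + ll[, i])
    kk[i] <- sm$k
  }
  structure(list(elpd = sum(pw), se = sqrt(N * var(pw)), pointwise = pw,
                 pareto_k = kk, n_trials = N, digest = digest),
            class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(sprintf("ELPD (PSIS-LOO): %.2f (se %.2f) over %d trials\n",
              x$elpd, x$se, x$n_trials))
  nk <- sum(x$pareto_k > 0.7)
  if (nk) cat(sprintf("  %d trial(s) with Pareto k > 0.7\n", nk))
  invisible(x)
}

#' Exact leave-one-out ELPD by refitting
#'
#' Brute-force reference for \code{\link{pointwise_elpd}}: refits the
#' model once per trial, excluding that trial, and averages the excluded
#' trial's likelihood over the refit posterior.  Only feasible for tiny
#' datasets, hence the explicit budget.
#'
#' @param trials Trial table (all rows usable in the likelihood).
#' @param model Model menu name or spec.
#' @param budget Maximum number of trials (refits) allowed.
#' @param chains,adapt,burn,draws,seed Passed to \code{\link{fit_observer}}.
#' @return An \code{"elpd_result"} (with \code{se} computed over trials).
#' @export
exact_loo_oracle <- function(trials, model = "1s5g", budget = 40,
                             chains = 2, adapt = 200, burn = 200,
                             draws = 250, seed = 1L) {
  N <- nrow(trials)
  if (N > budget) {
    stop("exact leave-one-out refuses ", N, " refits (budget ", budget, ")")
  }
  pw <- numeric(N)
  for (i in seq_len(N)) {
    f <- fit_observer(trials[-i, , drop = FALSE], model = model,
                      chains = chains, adapt = adapt, burn = burn,
                      draws = draws, seed = seed + i)
    ll <- loglik_at_trials(f, trials[i, , drop = FALSE])
    pw[i] <- logsumexp(ll[, 1]) - log(length(ll[, 1]))
  }
  structure(list(elpd = sum(pw), se = sqrt(N * var(pw)), pointwise = pw,
                 pareto_k = rep(NA_real_, N), n_trials = N,
                 digest = trial_digest(trials)),
            class = "elpd_result")
}

# per-draw log-likelihood of arbitrary trials under a fit's posterior
# (the trials' animals must be present in the fit)
loglik_at_trials <- function(fit, newtrials) {
  p <- choice_prob_matrix(fit, newtrials)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- newtrials$choice == "H"
  ll <- matrix(NA_real_, nrow(p), nrow(newtrials))
  ll[, y] <- log(p[, y, drop = FALSE])
  ll[, !y] <- log1p(-p[, !y, drop = FALSE])
  ll
}

#' Compare models by ELPD
#'
#' Ranks a set of \code{elpd_result}s fitted to the identical trial set
#' (checked via trial count and dataset digest) and reports each model's
#' ELPD difference from the best model with the paired standard error of
#' that difference, computed from the per-trial ELPD differences.
#'
#' @param results Named list of \code{elpd_result} objects.
#' @return A data frame of class \code{"elpd_comparison"}, sorted by ELPD:
#'   columns \code{model}, \code{elpd}, \code{se}, \code{delta_elpd},
#'   \code{delta_se}.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  n <- vapply(results, `[[`, 0, "n_trials")
  if (length(unique(n)) != 1) stop("comparison error: models fitted to different trial counts")
  dg <- unique(unlist(lapply(results, `[[`, "digest")))
  if (length(dg) > 1) stop("comparison error: models fitted to different datasets")
  elpd <- vapply(results, `[[`, 0, "elpd")
  best <- which.max(elpd)
  tab <- data.frame(model = names(results), elpd = elpd,
                    se = vapply(results, `[[`, 0, "se"),
                    delta_elpd = elpd - elpd[best],
                    delta_se = vapply(seq_along(results), function(j) {
                      if (j == best) return(0)
                      d <- results[[j]]$pointwise - results[[best]]$pointwise
                      sqrt(length(d) * var(d))
                    }, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$elpd), ]
  rownames(tab) <- NULL
  class(tab) <- c("elpd_comparison", "data.frame")
  tab
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat("Model comparison by PSIS-LOO ELPD (best first):\n")
  print.data.frame(cbind(x[1], round(x[-1], 2)), row.names = FALSE)
  invisible(x)
}

#' Summary of the linear gain-vs-intensity model
#'
#' Posterior mean and sd of the slope (per dB) and intercept of the
#' population gain line, plus the implied population gain mean at each
#' intensity level.
#'
#' @param fit An \code{observer_fit} of the \code{"linear"} model.
#' @return A list with \code{slope}, \code{intercept} (each mean/sd),
#'   \code{slope_draws}, and \code{implied_mu_gamma} (per-level mean/sd).
#' @export
fit_linear_gamma_summary <- function(fit) {
  if (fit$spec$gamma_structure != "linear_in_intensity") {
    stop("fit is not of the linear gain-vs-intensity model")
  }
  sl <- as.vector(fit$draws[, , "g_slope"])
  ic <- as.vector(fit$draws[, , "g_intercept"])
  I <- fit$spec$intensity_values
  implied <- sapply(I, function(ii) ic + sl * ii)
  list(slope = c(mean = mean(sl), sd = sd(sl)),
       intercept = c(mean = mean(ic), sd = sd(ic)),
       slope_draws = sl,
       implied_mu_gamma = data.frame(intensity_db = I,
                                     mean = colMeans(implied),
                                     sd = apply(implied, 2, sd)))
}
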