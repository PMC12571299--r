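#' Prior predictive psychometric envelopes
#'
#' Samples population parameter sets from the hyperpriors (gain means
#' Normal(0, 9), scale hyperparameters Exponential with mean 3, lapse
#' simplex Dirichlet(1,1,1)) and evaluates the population-average
#' psychometric curve for each intensity level.  Because the priors are
#' identical across levels, the envelopes must coincide across levels up
#' to sampling noise: the priors encode no sound effect.
#'
#' @param n_sims Number of prior draws.
#' @param n_levels Number of intensity levels.
#' @param s_grid Stimulus grid in Hz.
#' @param s0 Category boundary in Hz.
#' @return A data frame with columns \code{s}, \code{level}, \code{mean},
#'   \code{sd} (per-cell moments of the simulated proportion-high).
#' @export
prior_predictive <- function(n_sims = 1000, n_levels = 5,
                             s_grid = task_frequencies(), s0 = 2.12) {
  curves <- array(NA_real_, c(n_sims, n_levels, length(s_grid)))
  for (j in seq_len(n_sims)) {
    mu_gamma <- rnorm(n_levels, 0, 3)
    k <- rexp(1, 1 / 3); th <- rexp(1, 1 / 3)
    sigma <- max(k * th, 1e-6)            # population-mean sensory noise
    e <- rgamma(3, 1); e <- e / sum(e)
    for (l in seq_len(n_levels)) {
      curves[j, l, ] <- e[2] + (1 - e[1] - e[2]) *
        pnorm((mu_gamma[l] * s_grid - s0) / sigma)
    }
  }
  envelope_table(curves, s_grid)
}

#' Posterior predictive psychometric envelopes
#'
#' Evaluates, for every retained posterior draw, the population-average
#' psychometric curve per intensity level (gains at the draw's population
#' means, sigma at its population mean, lapses averaged across animals)
#' and summarises the curves by their per-cell mean and sd, the quantities
#' plotted as 1-sd and 2-sd envelope bands.
#'
#' @param fit An \code{observer_fit}.
#' @param s_grid Stimulus grid in Hz.
#' @return A data frame with columns \code{s}, \code{level}, \code{mean},
#'   \code{sd}.
#' @export
posterior_predictive <- function(fit, s_grid = task_frequencies()) {
  pd <- population_draws(fit)
  S <- length(pd$sigma)
  NG <- fit$spec$n_gamma
  curves <- array(NA_real_, c(S, NG, length(s_grid)))
  for (l in seq_len(NG)) {
    g <- pd$gamma[, l]
    for (i in seq_along(s_grid)) {
      curves[, l, i] <- pd$eps_h + (1 - pd$eps_h - pd$eps_l) *
        pnorm((g * s_grid[i] - fit$s0 + (g - 1) * pd$lam) / pd$sigma)
    }
  }
  envelope_table(curves, s_grid)
}

envelope_table <- function(curves, s_grid) {
  NG <- dim(curves)[2]
  out <- expand.grid(s = s_grid, level = seq_len(NG))
  out$mean <- NA_real_; out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- curves[, out$level[r], match(out$s[r], s_grid)]
    out$mean[r] <- mean(v); out$sd[r] <- sd(v)
  }
  out
}

#' Cell-level posterior predictive calibration check
#'
#' For each posterior draw, regenerates the choices of the fitted trials
#' from that draw's animal-level parameters and aggregates the proportion
#' of "high" reports per (stimulus, intensity level) cell, pooled across
#' animals.  The observed cell proportions are then compared against the
#' simulated mean +/- 2 sd envelope.  On data the model itself generated,
#' roughly 95\% of cells should fall inside.
#'
#' @param fit An \code{observer_fit}.
#' @param n_sims Number of posterior draws to simulate from.
#' @param seed Seed for the replicate choices.
#' @return Data frame with one row per populated (s, level) cell:
#'   observed proportion, predictive mean and sd, and an \code{inside}
#'   flag.
#' @export
posterior_predictive_cells <- function(fit, n_sims = 300, seed = 1L) {
  tr <- fit$trials
  gidx <- gamma_index_of(tr, fit$spec)
  cell <- interaction(tr$visual_tf_hz, gidx, drop = TRUE, sep = "|")
  obs <- tapply(tr$choice == "H", cell, mean)
  sims <- withr_rng(seed, {
    reps <- simulate(fit, nsim = n_sims)
    vapply(reps, function(ch) tapply(ch == "H", cell, mean), numeric(nlevels(cell)))
  })
  mu <- rowMeans(sims); sdv <- apply(sims, 1, sd)
  parts <- strsplit(levels(cell), "|", fixed = TRUE)
  out <- data.frame(
    s = as.numeric(vapply(parts, `[`, "", 1)),
    level = as.integer(vapply(parts, `[`, "", 2)),
    n = as.integer(table(cell)),
    observed = as.numeric(obs), pred_mean = mu, pred_sd = sdv)
  out$inside <- abs(out$observed - out$pred_mean) <= 2 * pmax(out$pred_sd, 1e-9)
  out
}
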