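#' Specify a hierarchical observer model variant
#'
#' The model menu varies how many sensory-noise and gain parameters each
#' animal has: \code{"1s5g"} (one sigma, one gain per intensity level) is
#' the reference model; \code{"1s1g"} and \code{"5s1g"} are
#' sound-independent controls; \code{"5s5g"} frees both; \code{"1s11g"}
#' gives every sound condition its own gain; \code{"1s5g1l"} adds the
#' hierarchical offset term lambda; \code{"linear"} ties the population
#' gain means to a linear function of the level's mean sound intensity.
#'
#' @param model Menu name (see above), or \code{NULL} to give the pieces
#'   explicitly.
#' @param n_sigma 1 or 5 sensory-noise parameters per animal.
#' @param n_gamma 1, 5 or 11 gains per animal.
#' @param include_lambda Add the offset-term hierarchy.
#' @param gamma_structure \code{"free"} or \code{"linear_in_intensity"}.
#' @param intensity_values Mean dB per intensity level (required for the
#'   linear structure).
#' @return An object of class \code{"observer_model_spec"}.
#' @export
model_spec <- function(model = "1s5g", n_sigma = NULL, n_gamma = NULL,
                       include_lambda = NULL, gamma_structure = NULL,
                       intensity_values = NULL) {
  if (!is.null(model)) {
    menu <- list(
      "1s1g"   = list(1L, 1L,  FALSE, "free"),
      "1s5g"   = list(1L, 5L,  FALSE, "free"),
      "5s1g"   = list(5L, 1L,  FALSE, "free"),
      "5s5g"   = list(5L, 5L,  FALSE, "free"),
      "1s11g"  = list(1L, 11L, FALSE, "free"),
      "1s5g1l" = list(1L, 5L,  TRUE,  "free"),
      "linear" = list(1L, 5L,  FALSE, "linear_in_intensity"))
    if (!model %in% names(menu)) {
      stop("unknown model '", model, "'; choose one of ",
           paste(names(menu), collapse = ", "))
    }
    m <- menu[[model]]
    n_sigma <- m[[1]]; n_gamma <- m[[2]]
    include_lambda <- m[[3]]; gamma_structure <- m[[4]]
  }
  if (!n_sigma %in% c(1L, 5L) || !n_gamma %in% c(1L, 5L, 11L)) {
    stop("(n_sigma, n_gamma) must be in the tested menu")
  }
  if (gamma_structure == "linear_in_intensity") {
    if (n_gamma != 5L) stop("the linear gain structure ties gains to the 5 intensity levels")
    if (is.null(intensity_values)) intensity_values <- level_intensities()
  }
  structure(list(name = if (is.null(model)) "custom" else model,
                 n_sigma = as.integer(n_sigma), n_gamma = as.integer(n_gamma),
                 include_lambda = isTRUE(include_lambda),
                 gamma_structure = gamma_structure,
                 intensity_values = intensity_values),
            class = "observer_model_spec")
}

# JAGS model code for a given spec.  Hyperpriors: mu_gamma ~ N(0, 9),
# scale hyperparameters ~ Exponential(mean 3); per-animal priors:
# Dirichlet(1,1,1) lapse simplex, Gamma(k, theta) sigma, Normal gains
# (untruncated, as specified by the hierarchy).
jags_model_code <- function(spec) {
  gamma_hyper <- if (spec$gamma_structure == "linear_in_intensity") "
  # centred parameterisation of the gain-vs-intensity line (the raw
  # slope/intercept pair is nearly collinear and mixes poorly)
  g_slope ~ dnorm(0, 0.1111111)
  g_centre ~ dnorm(0, 0.1111111)
  g_intercept <- g_centre - g_slope * mean(I)
  sd_gamma0 ~ dexp(0.3333333)
  for (n in 1:NG) {
    mu_gamma[n] <- g_centre + g_slope * (I[n] - mean(I))
    sd_gamma[n] <- sd_gamma0
  }" else "
  for (n in 1:NG) {
    mu_gamma[n] ~ dnorm(0, 0.1111111)
    sd_gamma[n] ~ dexp(0.3333333)
  }"
  lambda_block <- if (spec$include_lambda) "
    lambda[r] ~ dnorm(mu_lambda, 1 / (sd_lambda * sd_lambda))" else "
    lambda[r] <- 0"
  lambda_hyper <- if (spec$include_lambda) "
  mu_lambda ~ dnorm(0, 0.1111111)
  sd_lambda ~ dexp(0.3333333)" else ""
  paste0("model {
  for (i in 1:N) {
    eta[i] <- (gamma[rat[i], gidx[i]] * s[i] - s0 +
               (gamma[rat[i], gidx[i]] - 1) * lambda[rat[i]]) /
              sigma[rat[i], sidx[i]]
    pr[i] <- epsH[rat[i]] + (1 - epsH[rat[i]] - epsL[rat[i]]) * phi(eta[i])
    y[i] ~ dbern(max(min(pr[i], 1 - 1.0E-12), 1.0E-12))
  }
  for (r in 1:R) {
    eps[r, 1:3] ~ ddirch(alpha)
    epsL[r] <- eps[r, 1]
    epsH[r] <- eps[r, 2]
    for (j in 1:NS) {
      sigma[r, j] ~ dgamma(k_sigma, rate_sigma)
    }
    for (n in 1:NG) {
      gamma[r, n] ~ dnorm(mu_gamma[n], 1 / (sd_gamma[n] * sd_gamma[n]))
    }", lambda_block, "
  }", gamma_hyper, "
  k_sigma ~ dexp(0.3333333)
  theta_sigma ~ dexp(0.3333333)
  rate_sigma <- 1 / theta_sigma", lambda_hyper, "
}")
}

# map each trial to its gamma index under the spec
gamma_index_of <- function(trials, spec) {
  if (spec$n_gamma == 1L) {
    rep(1L, nrow(trials))
  } else if (spec$n_gamma == 5L) {
    trials$intensity_level
  } else {
    # per-condition gains: fixed = 1, the 9 AM conditions = 2..10, silence = 11
    tfs <- task_frequencies()
    idx <- integer(nrow(trials))
    idx[trials$sound_kind == "fixed"] <- 1L
    idx[trials$sound_kind == "silence"] <- 11L
    am <- trials$sound_kind == "am"
    idx[am] <- 1L + vapply(trials$sound_tf_hz[am],
                           function(f) which.min(abs(tfs - f)), integer(1))
    idx
  }
}

#' Fit the hierarchical Bayesian observer model to a trial table
#'
#' Builds the hierarchical model (per-animal lapse simplex, Gamma sensory
#' noise and Normal gains; weakly informative hyperpriors) and samples its
#' posterior by MCMC with seeded, reproducible chains.  Auditory-only
#' trials (no visual stimulus) and trials with missing response times are
#' excluded from the likelihood, with a reported count.
#'
#' @param trials Trial data frame as produced by
#'   \code{\link{simulate_cohort}} or \code{\link{read_trials}}.
#' @param model Model menu name or an \code{observer_model_spec}.
#' @param chains Number of chains (replication profile: 4).
#' @param adapt,burn Adaptation and burn-in iterations per chain.
#' @param draws Retained draws per chain (replication profile: 1000).
#' @param thin Thinning interval.
#' @param seed Integer seed; chains get distinct derived seeds.
#' @param s0 Category boundary in Hz.
#' @param include_boundary Keep boundary-stimulus trials in the
#'   likelihood (default TRUE; their choice probability is well defined).
#' @param quiet Suppress sampler progress output.
#' @return An object of class \code{"observer_fit"}.
#' @export
fit_observer <- function(trials, model = "1s5g", chains = 2, adapt = 500,
                         burn = 500, draws = 500, thin = 1, seed = 1L,
                         s0 = 2.12, include_boundary = TRUE, quiet = TRUE) {
  spec <- if (inherits(model, "observer_model_spec")) model else model_spec(model)
  n0 <- nrow(trials)
  keep <- !is.na(trials$visual_tf_hz) & !is.na(trials$response_time_s)
  if (!include_boundary) keep <- keep & abs(trials$visual_tf_hz - s0) > 1e-9
  excluded <- n0 - sum(keep)
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("no usable trials after exclusions")
  if (spec$n_gamma == 5L || spec$n_sigma == 5L) {
    if (any(is.na(trials$intensity_level))) {
      stop("specification error: trials lack intensity_level values required by the model")
    }
  }
  rat_ids <- sort(unique(trials$rat_id))
  rat <- match(trials$rat_id, rat_ids)
  gidx <- gamma_index_of(trials, spec)
  if (any(is.na(gidx))) stop("specification error: could not index gains for all trials")
  sidx <- if (spec$n_sigma == 1L) rep(1L, nrow(trials)) else trials$intensity_level
  y <- as.integer(trials$choice == "H")

  data <- list(N = nrow(trials), R = length(rat_ids), NG = spec$n_gamma,
               NS = spec$n_sigma, s0 = s0, alpha = c(1, 1, 1),
               y = y, rat = rat, s = trials$visual_tf_hz,
               gidx = gidx, sidx = sidx)
  if (spec$gamma_structure == "linear_in_intensity") data$I <- spec$intensity_values

  R <- length(rat_ids)
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (as.integer(seed) * 97L + ch * 1009L) %% 2147483629L + 1L,
                k_sigma = 2, theta_sigma = 0.5,
                sigma = matrix(1, R, spec$n_sigma),
                gamma = matrix(1, R, spec$n_gamma),
                eps = matrix(rep(c(0.05, 0.05, 0.9), each = R), R, 3))
    if (spec$gamma_structure == "linear_in_intensity") {
      ini$g_slope <- 0; ini$g_centre <- 1; ini$sd_gamma0 <- 0.3
    } else {
      ini$mu_gamma <- rep(1, spec$n_gamma)
      ini$sd_gamma <- rep(0.3, spec$n_gamma)
    }
    if (spec$include_lambda) {
      ini$lambda <- rep(0, R); ini$mu_lambda <- 0; ini$sd_lambda <- 0.3
    }
    ini
  })

  monitors <- c("mu_gamma", "sd_gamma", "k_sigma", "theta_sigma",
                "sigma", "gamma", "eps")
  if (spec$include_lambda) monitors <- c(monitors, "lambda", "mu_lambda", "sd_lambda")
  if (spec$gamma_structure == "linear_in_intensity") {
    monitors <- c(monitors, "g_slope", "g_intercept")
  }

  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_code(spec)), data = data,
                            inits = inits, n.chains = chains, n.adapt = adapt,
                            quiet = TRUE)
    if (burn > 0) update(jm, burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = draws * thin, thin = thin,
                        progress.bar = "none")
  }
  sm <- if (quiet) suppressWarnings(suppressMessages(run())) else run()

  pn <- colnames(sm[[1]])
  # the sampler drops indices from 1 x 1 arrays; restore canonical names
  canon <- c(gamma = "gamma[1,1]", sigma = "sigma[1,1]", lambda = "lambda[1]",
             mu_gamma = "mu_gamma[1]", sd_gamma = "sd_gamma[1]")
  hit <- pn %in% names(canon)
  pn[hit] <- canon[pn[hit]]
  arr <- array(NA_real_, dim = c(nrow(sm[[1]]), chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(chains)) arr[, ch, ] <- as.matrix(sm[[ch]])

  structure(list(draws = arr, spec = spec, trials = trials,
                 rat_ids = rat_ids, s0 = s0,
                 n_excluded = excluded,
                 chains = chains, n_draws = dim(arr)[1], seed = seed,
                 sampler = list(adapt = adapt, burn = burn, thin = thin),
                 divergences = NA_integer_,  # slice/Gibbs samplers: no HMC divergence diagnostic
                 data_digest = trial_digest(trials)),
            class = "observer_fit")
}

# md5 digest of a canonicalised trial table, to guard model comparisons
# against silently comparing fits of different datasets
trial_digest <- function(trials) {
  cols <- intersect(.trial_columns, names(trials))
  df <- trials[do.call(order, trials[cols]), cols, drop = FALSE]
  tf <- tempfile()
  on.exit(unlink(tf))
  write.table(format(df, digits = 10), tf, row.names = FALSE, quote = FALSE)
  unname(tools::md5sum(tf))
}

# population-level parameter names of a fit
population_par_names <- function(fit) {
  spec <- fit$spec
  pn <- dimnames(fit$draws)[[3]]
  keep <- grepl("^(mu_gamma|sd_gamma|k_sigma|theta_sigma|mu_lambda|sd_lambda|g_slope|g_intercept)",
                pn)
  pn[keep]
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("Hierarchical Bayesian observer fit (model ", x$spec$name, ")\n", sep = "")
  cat(sprintf("  %d animals, %d trials (%d excluded), %d chains x %d draws\n",
              length(x$rat_ids), nrow(x$trials), x$n_excluded,
              x$chains, x$n_draws))
  s <- summary(x)
  mg <- s[grepl("^mu_gamma", s$parameter), ]
  if (nrow(mg)) {
    cat("  population gain means:\n")
    print(data.frame(parameter = mg$parameter,
                     mean = round(mg$mean, 3), sd = round(mg$sd, 3),
                     r_hat = round(mg$r_hat, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Posterior summary of an observer fit
#'
#' Per-parameter posterior mean, sd, 3\%/97\% HDI, Monte-Carlo standard
#' errors, bulk/tail ESS and split R-hat for the population-level
#' parameters, plus the across-animal average lapse rates (the lapse
#' parameters carry no hierarchy, so their population description is a
#' simple average).
#'
#' @param object An \code{observer_fit}.
#' @param pars Optional character vector of parameter names.
#' @param ... Unused.
#' @return A data frame, one row per parameter.
#' @export
summary.observer_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) pars <- population_par_names(object)
  dl <- lapply(pars, function(p) object$draws[, , p])
  names(dl) <- pars
  tab <- posterior_summary_table(dl)
  # across-animal mean lapse rates per draw
  pn <- dimnames(object$draws)[[3]]
  for (j in 1:2) {
    cols <- pn[grepl(sprintf("^eps\\[\\d+,%d\\]$", j), pn)]
    m <- apply(object$draws[, , cols, drop = FALSE], c(1, 2), mean)
    row <- posterior_summary_table(setNames(list(m), c("mu_epsL", "mu_epsH")[j]))
    tab <- rbind(tab, row)
  }
  rownames(tab) <- NULL
  tab
}

#' @export
coef.observer_fit <- function(object, ...) {
  s <- summary(object)
  setNames(s$mean, s$parameter)
}

# posterior draws of the population-average observer parameters:
# gains = mu_gamma, sigma = k_sigma * theta_sigma (population mean),
# lapses = across-animal means
population_draws <- function(fit) {
  pn <- dimnames(fit$draws)[[3]]
  flat <- function(p) as.vector(fit$draws[, , p])
  NG <- fit$spec$n_gamma
  gam <- sapply(seq_len(NG), function(n) flat(sprintf("mu_gamma[%d]", n)))
  sig <- flat("k_sigma") * flat("theta_sigma")
  epsl <- rowMeans(sapply(pn[grepl("^eps\\[\\d+,1\\]$", pn)], flat))
  epsh <- rowMeans(sapply(pn[grepl("^eps\\[\\d+,2\\]$", pn)], flat))
  lam <- if (fit$spec$include_lambda) flat("mu_lambda") else 0
  list(gamma = gam, sigma = sig, eps_l = epsl, eps_h = epsh, lam = lam)
}

#' Predicted psychometric curves from a fit
#'
#' Posterior-mean probability of reporting "high" at the requested
#' stimuli and levels, for the population-average observer (gains at
#' their population means, sigma at its population mean, lapses averaged
#' across animals) or for a single animal.
#'
#' @param object An \code{observer_fit}.
#' @param newdata Data frame with columns \code{s} (Hz) and \code{level}
#'   (gain index); defaults to the full stimulus-by-level grid.
#' @param rat Optional animal id for animal-level prediction.
#' @param ... Unused.
#' @return \code{newdata} with a \code{prob_high} column appended.
#' @export
predict.observer_fit <- function(object, newdata = NULL, rat = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- expand.grid(s = task_frequencies(),
                           level = seq_len(object$spec$n_gamma))
  }
  pd <- population_draws(object)
  if (!is.null(rat)) {
    r <- match(rat, object$rat_ids)
    if (is.na(r)) stop("unknown rat id")
    flat <- function(p) as.vector(object$draws[, , p])
    pd$gamma <- sapply(seq_len(object$spec$n_gamma),
                       function(n) flat(sprintf("gamma[%d,%d]", r, n)))
    pd$sigma <- flat(sprintf("sigma[%d,1]", r))
    pd$eps_l <- flat(sprintf("eps[%d,1]", r))
    pd$eps_h <- flat(sprintf("eps[%d,2]", r))
    if (object$spec$include_lambda) pd$lam <- flat(sprintf("lambda[%d]", r))
  }
  p <- vapply(seq_len(nrow(newdata)), function(i) {
    g <- pd$gamma[, newdata$level[i]]
    mean(pd$eps_h + (1 - pd$eps_h - pd$eps_l) *
           pnorm((g * newdata$s[i] - object$s0 + (g - 1) * pd$lam) / pd$sigma))
  }, numeric(1))
  newdata$prob_high <- p
  newdata
}

#' Simulate choices from the fitted posterior
#'
#' Posterior-predictive replicate trial tables: for each simulation a
#' posterior draw is selected and choices are regenerated at the fitted
#' trials' stimuli using that draw's animal-level parameters.
#'
#' @param object An \code{observer_fit}.
#' @param nsim Number of replicate tables.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of \code{nsim} character vectors of choices ("H"/"L"),
#'   aligned with \code{object$trials}.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- object$n_draws * object$chains
  idx <- sample.int(S, nsim, replace = nsim > S)
  p <- choice_prob_matrix(object, object$trials, rows = idx)
  lapply(seq_len(nsim), function(j) {
    ifelse(runif(ncol(p)) < p[j, ], "H", "L")
  })
}

# S x N matrix of choice-H probabilities for `trials` under the fit's
# posterior draws (optionally a subset of flattened draw indices)
choice_prob_matrix <- function(fit, trials, rows = NULL) {
  rat <- match(trials$rat_id, fit$rat_ids)
  if (any(is.na(rat))) stop("trial references an animal absent from the fit")
  gidx <- gamma_index_of(trials, fit$spec)
  sidx <- if (fit$spec$n_sigma == 1L) rep(1L, nrow(trials))
          else trials$intensity_level
  S <- fit$n_draws * fit$chains
  if (is.null(rows)) rows <- seq_len(S)
  flatd <- matrix(fit$draws, nrow = S,
                  dimnames = list(NULL, dimnames(fit$draws)[[3]]))
  G <- flatd[rows, sprintf("gamma[%d,%d]", rat, gidx), drop = FALSE]
  SG <- flatd[rows, sprintf("sigma[%d,%d]", rat, sidx), drop = FALSE]
  EH <- flatd[rows, sprintf("eps[%d,2]", rat), drop = FALSE]
  EL <- flatd[rows, sprintf("eps[%d,1]", rat), drop = FALSE]
  LAM <- if (fit$spec$include_lambda)
    flatd[rows, sprintf("lambda[%d]", rat), drop = FALSE] else 0
  eta <- (sweep(G, 2, trials$visual_tf_hz, `*`) - fit$s0 + (G - 1) * LAM) / SG
  EH + (1 - EH - EL) * pnorm(eta)
}

#' @export
plot.observer_fit <- function(x, levels = seq_len(x$spec$n_gamma), ...) {
  grid <- expand.grid(s = seq(0.25, 4, length.out = 60), level = levels)
  pr <- predict(x, grid)
  cols <- hcl.colors(max(levels), "Zissou 1")
  plot(NULL, xlim = c(0.25, 4), ylim = c(0, 1),
       xlab = "visual temporal frequency (Hz)", ylab = "p(report high)", ...)
  for (l in levels) {
    sub <- pr[pr$level == l, ]
    lines(sub$s, sub$prob_high, col = cols[l], lwd = 2)
  }
  legend("bottomright", legend = paste("level", levels), col = cols[levels],
         lwd = 2, bty = "n")
  invisible(x)
}
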