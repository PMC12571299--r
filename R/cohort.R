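#' Population-level (hyper)parameters of the observer hierarchy
#'
#' Per-animal parameters are drawn as
#' \eqn{(\epsilon_L, \epsilon_H, \cdot) \sim Dirichlet(1,1,1)},
#' \eqn{\sigma \sim Gamma(k_\sigma, \theta_\sigma)} (shape/scale) and
#' \eqn{\gamma_n \sim N(\mu_{\gamma n}, \sigma_{\gamma n}^2)} per intensity
#' level.  Default gain means follow the fitted linear dependence of gain
#' on sound level (slope -8.6e-3 per dB, intercept 1.636) evaluated at the
#' five level intensities 32, 48.5, 64.2, 70.7 and 74.8 dB, so the default
#' cohort expresses the sound-intensity-dependent compression.
#'
#' @param mu_gamma Per-level gain means.
#' @param sd_gamma Per-level gain sds (between-animal spread).
#' @param k_sigma,theta_sigma Shape and scale of the sensory-noise Gamma.
#' @param mu_lambda,sd_lambda Optional offset-term hierarchy (NULL = the
#'   core lambda = 0 model).
#' @return An object of class \code{"population_params"}.
#' @export
population_params <- function(mu_gamma = 1.636 - 8.6e-3 * level_intensities(),
                              sd_gamma = rep(0.1, length(mu_gamma)),
                              k_sigma = 4, theta_sigma = 0.25,
                              mu_lambda = NULL, sd_lambda = NULL) {
  if (any(sd_gamma <= 0) || k_sigma <= 0 || theta_sigma <= 0) {
    stop("population scale parameters must be positive")
  }
  structure(list(mu_gamma = mu_gamma, sd_gamma = sd_gamma,
                 k_sigma = k_sigma, theta_sigma = theta_sigma,
                 mu_lambda = mu_lambda, sd_lambda = sd_lambda),
            class = "population_params")
}

#' Mean perceived sound level of the 5 intensity levels
#'
#' Average perceived dB per level: silence/visual-only (ambient), the
#' 0.25 Hz AM cluster, the 0.82 Hz AM cluster, the 1.32-4 Hz AM cluster
#' and the fixed-amplitude sound.
#'
#' @return Numeric vector of length 5 (dB).
#' @export
level_intensities <- function() c(32, 48.5, 64.2, 70.7, 74.8)

#' Specification of a synthetic cohort
#'
#' @param n_rats Number of animals.
#' @param trials_per_rat Trials per animal.
#' @param condition_weights Probabilities of the four trial categories
#'   (V+fixed, V+AM, V-only, A-only); default proportional to the task's
#'   design-cell counts 9:81:9:9.
#' @param population A \code{population_params} object.
#' @param rt_meanlog,rt_sdlog Lognormal response-time model (seconds),
#'   truncated to (0.3, 2]; the task aborts responses under 300 ms and
#'   allows at most 2 s.
#' @param session_size Trials per session (bookkeeping only).
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_rats = 10, trials_per_rat = 2000,
                        condition_weights = c(9, 81, 9, 9) / 108,
                        population = population_params(),
                        rt_meanlog = log(0.7), rt_sdlog = log(1.4),
                        session_size = 250, seed = 1L) {
  if (n_rats < 1 || trials_per_rat < 1) stop("cohort must be non-empty")
  if (length(condition_weights) != 4 || any(condition_weights < 0) ||
      sum(condition_weights) <= 0) {
    stop("'condition_weights' must be 4 non-negative weights")
  }
  structure(list(n_rats = n_rats, trials_per_rat = trials_per_rat,
                 condition_weights = condition_weights / sum(condition_weights),
                 population = population, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, session_size = session_size,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw one animal's parameters from the population
#'
#' Uses the hierarchy's own distributions, except that gains are truncated
#' to be positive: the Normal population distribution admits negative
#' gains, which would invert the psychometric function, so the generator
#' rejects them (the inference model keeps the untruncated prior).
#'
#' @param population A \code{population_params} object.
#' @return An \code{\link{observer_params}} object.
#' @export
sample_rat_params <- function(population = population_params()) {
  e <- rgamma(3, 1)            # Dirichlet(1,1,1) via normalised exponentials
  e <- e / sum(e)
  sigma <- rgamma(1, shape = population$k_sigma, scale = population$theta_sigma)
  gamma <- mapply(function(m, s) {
    g <- rnorm(1, m, s)
    while (g <= 0) g <- rnorm(1, m, s)
    g
  }, population$mu_gamma, population$sd_gamma)
  lam <- if (is.null(population$mu_lambda)) 0 else
    rnorm(1, population$mu_lambda, population$sd_lambda)
  observer_params(sigma = sigma, gamma = unname(gamma),
                  eps_l = e[1], eps_h = e[2], lam = lam)
}

#' Build a task-faithful trial schedule
#'
#' Draws each trial's category from \code{condition_weights} and its
#' stimuli uniformly within category, enforcing the task constraint that
#' at most three consecutive visual trials carry the same stimulus class
#' (the boundary stimulus is randomly assigned a class per trial, as in
#' training).  When a fourth same-class trial would occur, the visual
#' stimulus is rejection-sampled until the constraint is met, keeping the
#' per-stimulus distribution as uniform as the constraint allows.
#'
#' @param n_trials Number of trials.
#' @param condition_weights Category probabilities (V+fixed, V+AM, V-only,
#'   A-only).
#' @param stimset A \code{stimulus_set}.
#' @return A data frame with columns \code{category}, \code{visual_tf},
#'   \code{sound_kind}, \code{sound_tf}, \code{visual_class}.
#' @export
build_schedule <- function(n_trials, condition_weights = c(9, 81, 9, 9) / 108,
                           stimset = stimulus_set()) {
  stopifnot(n_trials >= 1)
  if (length(condition_weights) != 4 || any(condition_weights < 0) ||
      sum(condition_weights) <= 0) {
    stop("schedule constraint error: invalid category weights")
  }
  cats <- c("v_fixed", "v_am", "v_only", "a_only")
  category <- sample(cats, n_trials, replace = TRUE, prob = condition_weights)
  tfs <- task_frequencies()
  visual_tf <- rep(NA_real_, n_trials)
  sound_tf <- rep(NA_real_, n_trials)
  visual_class <- rep(NA_character_, n_trials)
  run_class <- ""; run_len <- 0L
  for (i in seq_len(n_trials)) {
    if (category[i] == "a_only") {
      sound_tf[i] <- sample(tfs, 1)
      next                      # no visual stimulus: does not extend the run
    }
    # rejection-sample the stimulus until it does not extend a 3-run
    # (the boundary stimulus is randomly assigned a class per trial)
    repeat {
      s <- sample(tfs, 1)
      cls <- if (s < stimset$s0) "L" else if (s > stimset$s0) "H" else
        sample(c("L", "H"), 1)
      if (!(cls == run_class && run_len >= 3L)) break
    }
    visual_tf[i] <- s
    visual_class[i] <- cls
    if (cls == run_class) run_len <- run_len + 1L
    else { run_class <- cls; run_len <- 1L }
    if (category[i] == "v_am") sound_tf[i] <- sample(tfs, 1)
  }
  sound_kind <- c(v_fixed = "fixed", v_am = "am", v_only = "silence",
                  a_only = "am")[category]
  data.frame(category = category, visual_tf = visual_tf,
             sound_kind = unname(sound_kind), sound_tf = sound_tf,
             visual_class = visual_class, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' For each animal: draw observer parameters from the population, build a
#' schedule, and generate choices from the psychometric model at the
#' trial's intensity level.  Auditory-only trials draw unbiased coin-flip
#' choices (animals are insensitive to the sound's temporal frequency).
#' Response times are lognormal, truncated to the task's (0.3 s, 2 s]
#' response window.  The result is a deterministic function of
#' \code{spec$seed}.
#'
#' @param spec A \code{cohort_spec}.
#' @param stimset A \code{stimulus_set}.
#' @return A data frame of trials (columns \code{rat_id}, \code{session},
#'   \code{visual_tf_hz}, \code{sound_kind}, \code{sound_tf_hz},
#'   \code{intensity_level}, \code{choice}, \code{response_time_s}) with
#'   the generating per-animal parameters in attribute \code{"true_params"}.
#' @export
simulate_cohort <- function(spec = cohort_spec(), stimset = stimulus_set()) {
  withr_rng(spec$seed, {
    out <- vector("list", spec$n_rats)
    truths <- vector("list", spec$n_rats)
    for (r in seq_len(spec$n_rats)) {
      pars <- sample_rat_params(spec$population)
      truths[[r]] <- pars
      sch <- build_schedule(spec$trials_per_rat, spec$condition_weights, stimset)
      lev <- intensity_level_of(sch$sound_kind, sch$sound_tf)
      lev[sch$category == "a_only"] <- NA_integer_
      choice <- character(nrow(sch))
      vis <- !is.na(sch$visual_tf)
      choice[vis] <- simulate_choice(sch$visual_tf[vis], lev[vis], pars,
                                     s0 = stimset$s0)
      choice[!vis] <- ifelse(runif(sum(!vis)) < 0.5, "H", "L")
      rt <- rlnorm(nrow(sch), spec$rt_meanlog, spec$rt_sdlog)
      bad <- rt <= 0.3 | rt > 2
      while (any(bad)) {
        rt[bad] <- rlnorm(sum(bad), spec$rt_meanlog, spec$rt_sdlog)
        bad <- rt <= 0.3 | rt > 2
      }
      out[[r]] <- data.frame(
        rat_id = sprintf("rat%02d", r),
        session = (seq_len(nrow(sch)) - 1L) %/% spec$session_size + 1L,
        visual_tf_hz = sch$visual_tf,
        sound_kind = sch$sound_kind,
        sound_tf_hz = sch$sound_tf,
        intensity_level = lev,
        choice = choice,
        response_time_s = round(rt, 4),
        stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, out)
    rownames(trials) <- NULL
    names(truths) <- sprintf("rat%02d", seq_len(spec$n_rats))
    attr(trials, "true_params") <- truths
    attr(trials, "population") <- spec$population
    trials
  })
}

.trial_columns <- c("rat_id", "session", "visual_tf_hz", "sound_kind",
                    "sound_tf_hz", "intensity_level", "choice",
                    "response_time_s")

#' Write a trial table to delimited text
#'
#' @param trials Trial data frame.
#' @param path Output file path (tab-separated, with header).
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from delimited text
#'
#' Validates the schema and the task's response window: rows with
#' response times at or below the 300 ms abort threshold (or above the
#' 2 s limit) are rejected as aborted-trial violations.  Unknown columns
#' are preserved.  An empty file yields an empty table, not an error.
#'
#' @param path Path to a tab- or comma-separated trial table with header.
#' @return Trial data frame.
#' @export
read_trials <- function(path) {
  if (file.size(path) == 0) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.trial_columns))),
      .trial_columns))
  }
  sep <- if (grepl(",", readLines(path, n = 1), fixed = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(df))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) && any(df$response_time_s <= 0.3 | df$response_time_s > 2)) {
    bad <- which(df$response_time_s <= 0.3 | df$response_time_s > 2)[1]
    stop("aborted-trial violation: response_time_s outside (0.3, 2] at row ",
         bad)
  }
  df
}
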