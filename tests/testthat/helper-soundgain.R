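# Shared fixtures: all synthetic, built in code at test time.

# small cohort of visual trials only (all rows usable in the likelihood)
make_visual_cohort <- function(n_rats = 3, trials_per_rat = 300, seed = 11,
                               population = population_params()) {
  simulate_cohort(cohort_spec(n_rats = n_rats, trials_per_rat = trials_per_rat,
                              condition_weights = c(9, 81, 9, 0) / 99,
                              population = population, seed = seed))
}

# short-chain fit for unit tests
quick_fit <- function(trials, model = "1s5g", seed = 1, draws = 300, ...) {
  fit_observer(trials, model = model, chains = 2, adapt = 200, burn = 200,
               draws = draws, seed = seed, ...)
}

# cache shared between acceptance blocks (the recovery fit is reused for
# the posterior-predictive calibration check)
acceptance_cache <- new.env(parent = emptyenv())
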