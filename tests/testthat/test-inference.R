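test_that("the likelihood matches the psychometric model exactly", {
  tr <- make_visual_cohort(n_rats = 1, trials_per_rat = 60, seed = 2)
  pars <- observer_params(sigma = 0.6, gamma = c(1.3, 1.2, 1.1, 1.05, 1),
                          eps_h = 0.05, eps_l = 0.08)
  # pure guessing: eps_h + eps_l = 1 makes every trial log(1/2)
  guess <- observer_params(sigma = 0.6, gamma = rep(1, 5),
                           eps_h = 0.5, eps_l = 0.5)
  expect_equal(log_likelihood(guess, tr), rep(log(0.5), nrow(tr)))

  # single trial: log of the psychometric probability, to 1e-12
  one <- tr[5, , drop = FALSE]
  p <- psychometric(one$visual_tf_hz, one$intensity_level, pars)
  expect_equal(log_likelihood(pars, one),
               if (one$choice == "H") log(p) else log(1 - p),
               tolerance = 1e-12)

  # total vs an independent brute-force product over 10 trials
  ten <- tr[1:10, ]
  probs <- vapply(1:10, function(i) {
    pi <- psychometric(ten$visual_tf_hz[i], ten$intensity_level[i], pars)
    if (ten$choice[i] == "H") pi else 1 - pi
  }, numeric(1))
  expect_equal(sum(log_likelihood(pars, ten)), log(prod(probs)),
               tolerance = 1e-9)

  # nesting: one shared gain equals five equal gains
  p1 <- observer_params(sigma = 0.6, gamma = 0.9)
  p5 <- observer_params(sigma = 0.6, gamma = rep(0.9, 5))
  expect_equal(log_likelihood(p1, tr), log_likelihood(p5, tr))

  # auditory-only trials must be excluded upstream
  bad <- tr
  bad$visual_tf_hz[3] <- NA
  expect_error(log_likelihood(pars, bad), "row 3")
})

test_that("posterior sampling is seeded-deterministic and well-shaped", {
  tr <- make_visual_cohort(n_rats = 2, trials_per_rat = 150, seed = 8)
  f1 <- quick_fit(tr, seed = 4, draws = 120)
  f2 <- quick_fit(tr, seed = 4, draws = 120)
  expect_identical(f1$draws, f2$draws)

  ll <- pointwise_loglik(f1)
  expect_equal(dim(ll), c(f1$chains * f1$n_draws, nrow(f1$trials)))
  expect_true(all(is.finite(ll)))

  # likelihood correctness at a parameter point: the pointwise matrix row
  # equals the standalone likelihood evaluated at that draw's parameters
  j <- 17
  flat <- matrix(f1$draws, nrow = f1$chains * f1$n_draws,
                 dimnames = list(NULL, dimnames(f1$draws)[[3]]))
  r <- 1
  pars <- observer_params(
    sigma = flat[j, "sigma[1,1]"],
    gamma = flat[j, sprintf("gamma[1,%d]", 1:5)],
    eps_l = flat[j, "eps[1,1]"], eps_h = flat[j, "eps[1,2]"])
  mine <- tr[tr$rat_id == "rat01" & !is.na(tr$visual_tf_hz), ]
  idx <- which(f1$trials$rat_id == "rat01")
  expect_equal(unname(ll[j, idx]), unname(log_likelihood(pars, mine)),
               tolerance = 1e-9)

  # diagnostics table carries the standard columns, all finite
  s <- summary(f1)
  expect_true(all(c("mean", "sd", "hdi_3", "hdi_97", "mcse_mean", "mcse_sd",
                    "ess_bulk", "ess_tail", "r_hat") %in% names(s)))
  expect_true(all(is.finite(as.matrix(s[, -1]))))
  expect_true(all(s$hdi_3 <= s$mean & s$mean <= s$hdi_97))
})

test_that("the posterior concentrates on the generating parameters", {
  # single animal, strong data: Bernstein-von-Mises style check of both
  # location and spread against the curvature of the log-likelihood
  set.seed(14)
  truth <- observer_params(sigma = 0.55, gamma = rep(0.9, 5),
                           eps_h = 0.02, eps_l = 0.02)
  sch <- build_schedule(4000, condition_weights = c(9, 81, 9, 0) / 99)
  lev <- intensity_level_of(sch$sound_kind, sch$sound_tf)
  tr <- data.frame(rat_id = "rat01", session = 1L,
                   visual_tf_hz = sch$visual_tf, sound_kind = sch$sound_kind,
                   sound_tf_hz = sch$sound_tf, intensity_level = lev,
                   choice = simulate_choice(sch$visual_tf, lev, truth),
                   response_time_s = 0.8)
  fit <- fit_observer(tr, "1s1g", chains = 2, adapt = 300, burn = 300,
                      draws = 400, seed = 6)
  g <- as.vector(fit$draws[, , "gamma[1,1]"])
  # observed-information sd for the shared gain, all else held at truth
  gg <- seq(0.85, 0.95, length.out = 201)
  t1 <- observer_params(sigma = 0.55, gamma = 1, eps_h = 0.02, eps_l = 0.02)
  llg <- vapply(gg, function(x) {
    sum(log_likelihood(observer_params(0.55, x, 0.02, 0.02), tr))
  }, numeric(1))
  curv <- -(diff(diff(llg)) / diff(gg)[1]^2)[which.min(abs(gg[-c(1, 201)] - 0.9))]
  info_sd <- 1 / sqrt(curv)
  expect_lt(abs(mean(g) - 0.9), 4 * sd(g))
  expect_gt(sd(g), 0.5 * info_sd)       # no spurious overconfidence
  expect_lt(sd(g), 4 * info_sd)         # concentrates at the data's rate
})

test_that("hierarchical pooling shrinks an outlier animal toward the group", {
  set.seed(77)
  pop <- population_params(mu_gamma = rep(1.2, 5), sd_gamma = rep(0.05, 5))
  tr <- make_visual_cohort(n_rats = 6, trials_per_rat = 500, seed = 71,
                           population = pop)
  # overwrite one animal with an outlier gain well above the population
  truth_out <- observer_params(sigma = 0.6, gamma = rep(1.8, 5),
                               eps_h = 0.05, eps_l = 0.05)
  idx <- tr$rat_id == "rat01" & !is.na(tr$visual_tf_hz)
  tr$choice[idx] <- simulate_choice(tr$visual_tf_hz[idx],
                                    tr$intensity_level[idx], truth_out)
  joint <- quick_fit(tr, model = "1s1g", seed = 3)
  alone <- quick_fit(tr[tr$rat_id == "rat01", ], model = "1s1g", seed = 3)
  g_joint <- mean(joint$draws[, , "gamma[1,1]"])
  g_alone <- mean(alone$draws[, , "gamma[1,1]"])
  pop_mean <- mean(sapply(2:6, function(r)
    mean(joint$draws[, , sprintf("gamma[%d,1]", r)])))
  # partial pooling: the joint estimate sits between the animal's own
  # estimate and the group, strictly closer to the group
  expect_lt(abs(g_joint - pop_mean), abs(g_alone - pop_mean))
  expect_gt(g_joint, pop_mean)
})

test_that("prior predictive envelopes are level-symmetric", {
  set.seed(10)
  pp <- prior_predictive(n_sims = 1500)
  expect_equal(nrow(pp), 45)
  expect_true(all(pp$mean >= 0 & pp$mean <= 1))
  # the five level envelopes coincide up to simulation noise
  for (sv in unique(pp$s)) {
    sub <- pp[pp$s == sv, ]
    expect_lt(max(sub$mean) - min(sub$mean),
              4 * max(sub$sd) / sqrt(1500) * 3 + 0.05)
  }
})

test_that("probability of direction follows its definition", {
  expect_equal(probability_of_direction(runif(200, 0.1, 2))$pd, 1)
  set.seed(2)
  sym <- rnorm(20000)
  expect_lt(abs(probability_of_direction(sym)$pd - 0.5), 0.02)
  # analytic normal-tail oracle
  x <- rnorm(20000, -0.17, 0.19)
  pd <- probability_of_direction(x)$pd
  expect_lt(abs(pd - pnorm(0.17 / 0.19)), 0.01)
  expect_equal(probability_of_direction(x)$p_two_sided, 2 * (1 - pd))
  expect_error(probability_of_direction(rnorm(50)), "100")
})
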