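test_that("the psychometric function matches its closed form and bounds", {
  p0 <- observer_params(sigma = 0.5, gamma = 1)
  expect_equal(psychometric(2.12, 1, p0), 0.5)

  # symmetry about the boundary when gamma = 1
  for (d in c(0.3, 0.9, 1.5)) {
    expect_equal(psychometric(2.12 + d, 1, p0),
                 1 - psychometric(2.12 - d, 1, p0))
  }

  # independent CDF evaluation (numeric integration of the normal density)
  pc <- psychometric(4, 1, observer_params(sigma = 0.5, gamma = 0.8))
  z <- (0.8 * 4 - 2.12) / 0.5
  expect_equal(pc, integrate(dnorm, -Inf, z, rel.tol = 1e-10)$value,
               tolerance = 1e-8)

  # lapse bounds: output always in [eps_h, 1 - eps_l]
  set.seed(1)
  for (i in 1:20) {
    e <- rgamma(3, 1); e <- e / sum(e)
    pars <- observer_params(sigma = runif(1, 0.2, 2),
                            gamma = runif(5, 0.3, 2),
                            eps_h = e[1], eps_l = e[2])
    s <- runif(9, 0.25, 4)
    p <- psychometric(s, sample(1:5, 9, TRUE), pars)
    expect_true(all(p >= e[1] - 1e-12 & p <= 1 - e[2] + 1e-12))
    expect_true(all(diff(psychometric(sort(s), rep(3, 9), pars)) >= 0))
  }
  # strictly increasing in s (parameters kept clear of probit saturation)
  for (i in 1:10) {
    pars <- observer_params(sigma = runif(1, 0.4, 1.5),
                            gamma = runif(5, 0.5, 1.3))
    pg <- psychometric(task_frequencies(), rep(sample(1:5, 1), 9), pars)
    expect_true(all(diff(pg) > 0))
  }
  expect_error(psychometric(2, 7, p0), "does not exist")
})

test_that("releasing gain compression shifts choices asymmetrically toward high", {
  # the boundary is learned under the loudest (training) sound, gamma = 1;
  # quieter sounds release the suppression, gamma > 1, and the fixed
  # boundary then misclassifies more stimuli as "high" -- an upward shift
  # that is larger at the high end of the frequency grid than at the low end
  s <- task_frequencies()
  p1 <- psychometric(s, 1, observer_params(sigma = 1.2, gamma = 1))
  pg <- psychometric(s, 1, observer_params(sigma = 1.2, gamma = 1.25))
  shift <- pg - p1
  expect_true(all(shift >= 0))
  expect_gt(shift[9], shift[1])
  expect_gt(min(shift[s > 2.12]), max(shift) * 0.1)  # prominent at high TFs
  # mirrored: compressing below the training gain shifts toward low
  pl <- psychometric(s, 1, observer_params(sigma = 1.2, gamma = 0.8))
  expect_true(all(pl - p1 <= 0))
})

test_that("simulated choices follow the psychometric probabilities", {
  expect_true(all(simulate_choice(rep(1, 50), 1,
    observer_params(1, 1, eps_h = 1, eps_l = 0)) == "H"))
  expect_true(all(simulate_choice(rep(4, 50), 1,
    observer_params(1, 1, eps_h = 0, eps_l = 1)) == "L"))
  set.seed(42)
  pars <- observer_params(sigma = 0.7, gamma = 0.9, eps_h = 0.1, eps_l = 0.05)
  n <- 4e4
  emp <- mean(simulate_choice(rep(3, n), 1, pars) == "H")
  p <- psychometric(3, 1, pars)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the decision boundary is the image of the boundary stimulus", {
  cfg <- generative_observer_config(0, 1, 0.5)
  expect_equal(decision_boundary(cfg), 2.12)
  cfg2 <- generative_observer_config(3, 2, 0.5)
  expect_equal(decision_boundary(cfg2), 3 + 2 * 2.12)

  # posterior-equality root for exactly symmetric stimulus sets
  set.seed(7)
  for (i in 1:5) {
    off <- sort(runif(4, 0.1, 2))
    ss <- stimulus_set(s0 = 2.12, low_tfs = 2.12 - off, high_tfs = 2.12 + off)
    cfg3 <- generative_observer_config(rnorm(1), runif(1, 0.5, 3),
                                       runif(1, 0.3, 1.5))
    expect_equal(decision_boundary(cfg3, ss, numeric = TRUE),
                 decision_boundary(cfg3, ss), tolerance = 1e-6)
  }
})

test_that("class posteriors behave at the boundary and in the tails", {
  cfg <- generative_observer_config(1, 1.5, 0.6)
  # exactly symmetric stimulus classes around the boundary
  ss <- stimulus_set(s0 = 2.12, low_tfs = 2.12 - c(0.4, 0.8, 1.3, 1.9),
                     high_tfs = 2.12 + c(0.4, 0.8, 1.3, 1.9))
  expect_equal(class_posterior(1 + 1.5 * 2.12, cfg, ss), 0.5, tolerance = 1e-9)
  expect_equal(class_posterior(1 + 1.5 * 10, cfg, ss), 1, tolerance = 1e-6)
  x <- seq(-2, 10, length.out = 23)
  ph <- class_posterior(x, cfg, ss)
  expect_true(all(ph >= 0 & ph <= 1))
  # with the task's printed grid (symmetric only to rounding) the
  # posterior-equality point sits within ~0.01 of the boundary image
  expect_equal(class_posterior(1 + 1.5 * 2.12, cfg, stimulus_set()), 0.5,
               tolerance = 0.02)
})

test_that("the generative observer converges to the closed form", {
  set.seed(31)
  ss <- stimulus_set()
  # gamma = 1: plain cumulative normal in s with sigma = rho / b
  cfg <- generative_observer_config(0.5, 1.2, 0.9, n_mc = 1e5)
  for (s in c(0.25, 2.12, 4)) {
    emp <- generative_oracle(s, 1, cfg, ss)
    p <- pnorm((s - 2.12) / (0.9 / 1.2))
    tol <- 3 * sqrt(max(p * (1 - p), 1e-4) / cfg$n_mc)
    expect_lt(abs(emp - p), max(tol, 2e-3))
  }
  # gamma != 1 with a != 0: the lambda-form closed expression
  cfg2 <- generative_observer_config(0.8, 1.5, 0.6, n_mc = 1e5)
  lam <- 0.8 / 1.5
  pars <- observer_params(sigma = 0.6 / 1.5, gamma = 0.85, lam = lam)
  for (s in c(1.32, 2.91)) {
    emp <- generative_oracle(s, 0.85, cfg2, ss)
    p <- psychometric(s, 1, pars)
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / cfg2$n_mc) + 2e-3)
  }
})
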