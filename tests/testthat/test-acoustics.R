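calib <- calibration_constants()

test_that("SPL definition, ambient floor and the inverse pair are consistent", {
  # zero stimulus pressure collapses to the ambient level
  expect_equal(level_from_pressure(0, calib), calib$La)
  # ambient pressure from the printed ambient level
  expect_equal(ambient_pressure(calib), 7.962143e-4, tolerance = 1e-6)
  expect_equal(ambient_pressure(calibration_constants(La = 0)), calib$p0)
  # the calibrated fixed-amplitude sound level
  expect_equal(level_from_pressure(calib$f * calib$sigma_eff, calib), 74.8,
               tolerance = 0.1 / 74.8)
  # inverse pair, to 1e-9 relative
  p <- c(1e-4, 5e-3, 0.11, 0.9)
  expect_equal(pressure_from_level(level_from_pressure(p, calib), calib), p,
               tolerance = 1e-9)
  expect_equal(pressure_from_level(74.8, calib), 0.110, tolerance = 1e-2)
  expect_equal(pressure_from_level(calib$La, calib), 0)
  expect_error(pressure_from_level(20, calib), "ambient floor")
  # monotone in level
  L <- seq(32, 90, by = 2)
  expect_true(all(diff(pressure_from_level(L, calib)) > 0))
})

test_that("control signals follow the stimulus definitions", {
  fx <- make_control_signal(sound_condition("fixed"), 10, calib, seed = 4)
  expect_equal(sd(fx), calib$sigma_eff, tolerance = 0.01 / calib$sigma_eff)
  expect_true(all(abs(fx) <= 1))

  am <- make_control_signal(sound_condition("am", 0.25), 2, calib, seed = 4)
  expect_identical(am[1], 0)              # raised-cosine envelope is 0 at onset
  expect_true(max(abs(am)) <= 1)

  sl <- make_control_signal(sound_condition("silence"), 1, calib, seed = 4)
  expect_true(all(sl == 0))

  expect_identical(make_control_signal(sound_condition("am", 4), 1, calib, 7),
                   make_control_signal(sound_condition("am", 4), 1, calib, 7))

  bad <- sound_condition("fixed")
  bad$kind <- "chirp"
  expect_error(make_control_signal(bad, 1, calib), "invalid")
  expect_error(sound_condition("am", modulation_freq = 0.5), "task frequencies")
})

test_that("the full design has 11 distinct conditions", {
  conds <- sound_conditions()
  expect_length(conds, 11)
  expect_length(unique(names(conds)), 11)
  kinds <- vapply(conds, `[[`, "", "kind")
  expect_equal(as.integer(table(kinds)[c("fixed", "am", "silence")]), c(1L, 9L, 1L))
})

test_that("analytic intensity profiles match a sliding-RMS computation", {
  prof <- intensity_profile(sound_condition("am", 2.48), 2, calib, tau = 0.005)
  expect_equal(prof$levels[1], calib$La)  # envelope zero at onset
  expect_true(all(prof$levels >= calib$La))

  # the 5 ms sliding-RMS estimator carries an irreducible ~0.26 dB noise
  # floor (220 carrier samples per window), so agreement is assessed as
  # the typical (mean absolute) deviation over the valid domain
  sig <- make_control_signal(sound_condition("am", 2.48), 2, calib, seed = 5)
  nprof <- numeric_intensity_profile(sig, calib, tau = 0.005)
  num <- approx(nprof$times, nprof$levels, prof$times, rule = 2)$y
  ok <- prof$levels > calib$La + 3
  expect_lt(mean(abs(prof$levels[ok] - num[ok])), 0.5)
  expect_lt(max(abs(prof$levels[ok] - num[ok])), 2)

  fixp <- intensity_profile(sound_condition("fixed"), 1, calib)
  expect_true(all(abs(fixp$levels - 74.8) < 0.1))
  silp <- intensity_profile(sound_condition("silence"), 1, calib)
  expect_true(all(silp$levels == calib$La))

  expect_warning(intensity_profile(sound_condition("am", 4), 1, calib, tau = 0.5),
                 "scale separation")
})

test_that("scaling the control signal scales the derived pressure linearly", {
  sig <- make_control_signal(sound_condition("fixed"), 5, calib, seed = 6)
  p1 <- pressure_from_level(
    mean(numeric_intensity_profile(sig, calib, tau = 1)$levels), calib)
  dim08 <- 0.8 * sig
  attr(dim08, "sample_rate") <- calib$sample_rate
  p2 <- pressure_from_level(
    mean(numeric_intensity_profile(dim08, calib, tau = 1)$levels), calib)
  expect_equal(p2 / p1, 0.8, tolerance = 0.01 / 0.8)
})

test_that("perceived intensity averages the profile over the reaction time", {
  fixp <- intensity_profile(sound_condition("fixed"), 2, calib)
  expect_equal(mean_perceived_intensity(fixp, 1.1)$mean_level,
               level_from_pressure(calib$f * calib$sigma_eff, calib))
  silp <- intensity_profile(sound_condition("silence"), 2, calib)
  expect_equal(mean_perceived_intensity(silp, 0.8)$mean_level, 32)
  expect_equal(mean_perceived_intensity(silp, 0.8)$rct, 0.5)

  # periodicity: one vs two full envelope periods give the same mean
  amp <- intensity_profile(sound_condition("am", 4), 1, calib,
                           grid_step = 1e-4)
  m1 <- mean_perceived_intensity(amp, 0.55)$mean_level  # RcT = 1 period
  m2 <- mean_perceived_intensity(amp, 0.80)$mean_level  # RcT = 2 periods
  expect_equal(m1, m2, tolerance = 1e-3)

  expect_error(mean_perceived_intensity(fixp, 0.25), "invalid trial")
  # pressure-domain averaging convention is selectable and differs for AM
  mdb <- mean_perceived_intensity(amp, 1.3, average = "db")$mean_level
  mpa <- mean_perceived_intensity(amp, 1.3, average = "pressure")$mean_level
  expect_gt(mpa, mdb)
})

test_that("the 11 conditions group into 5 ordered intensity levels", {
  lev <- assign_intensity_levels()
  expect_length(unique(lev), 5)
  expect_equal(unname(lev["silence"]), 1L)
  expect_equal(unname(lev["fixed"]), 5L)
  expect_equal(unname(lev["am_0.25"]), 2L)
  expect_equal(unname(lev["am_0.82"]), 3L)
  expect_true(all(lev[c("am_1.32", "am_1.75", "am_2.12", "am_2.48",
                        "am_2.91", "am_3.41", "am_4.00")] == 4L))

  # recompute per-condition mean perceived dB under a spread of reaction
  # times and verify group means increase with level index
  rts <- seq(0.45, 1.9, by = 0.05)
  means <- vapply(sound_conditions(), function(cn) {
    prof <- suppressWarnings(intensity_profile(cn, 2, calib))
    mean(vapply(rts, function(rt)
      mean_perceived_intensity(prof, rt)$mean_level, numeric(1)))
  }, numeric(1))
  grp <- tapply(means, lev[names(means)], mean)
  expect_false(is.unsorted(grp, strictly = TRUE))
  # condition-based rule is unchanged under degenerate equal means
  expect_length(unique(suppressWarnings(assign_intensity_levels(
    mean_levels = setNames(rep(50, 11), names(lev))))), 5)
})
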