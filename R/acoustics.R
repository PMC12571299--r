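#' Temporal frequencies used in the discrimination task
#'
#' The nine grating temporal frequencies (Hz), log-symmetric around the
#' category boundary at 2.12 Hz.  The amplitude-modulated sounds use the
#' same nine frequencies for their envelopes.
#'
#' @return Numeric vector of length 9.
#' @export
task_frequencies <- function() {
  c(0.25, 0.82, 1.32, 1.75, 2.12, 2.48, 2.91, 3.41, 4)
}

#' Define a sound condition
#'
#' A sound condition is one of: a fixed-amplitude white-noise burst, an
#' amplitude-modulated (AM) white-noise burst with a raised-cosine envelope
#' at one of the nine task frequencies, or silence (ambient noise only).
#'
#' @param kind One of \code{"fixed"}, \code{"am"}, \code{"silence"}.
#' @param modulation_freq Envelope frequency in Hz; required iff
#'   \code{kind = "am"} and must be one of \code{task_frequencies()}.
#' @param label Optional identifier; a default is derived from the kind.
#' @return An object of class \code{"sound_condition"}.
#' @export
sound_condition <- function(kind = c("fixed", "am", "silence"),
                            modulation_freq = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "am") {
    if (is.null(modulation_freq) ||
        !isTRUE(any(abs(modulation_freq - task_frequencies()) < 1e-9))) {
      stop("'modulation_freq' must be one of the 9 task frequencies for AM sounds")
    }
  } else if (!is.null(modulation_freq)) {
    stop("'modulation_freq' is only meaningful for kind = \"am\"")
  }
  if (is.null(label)) {
    label <- switch(kind,
      fixed = "fixed",
      silence = "silence",
      am = sprintf("am_%.2f", modulation_freq))
  }
  structure(list(kind = kind, modulation_freq = modulation_freq, label = label),
            class = "sound_condition")
}

#' The full 11-condition sound design
#'
#' One fixed-amplitude condition, nine AM conditions (one per task
#' frequency) and one silence condition.
#'
#' @return A list of 11 \code{sound_condition} objects, named by label.
#' @export
sound_conditions <- function() {
  conds <- c(list(sound_condition("fixed")),
             lapply(task_frequencies(),
                    function(f) sound_condition("am", modulation_freq = f)),
             list(sound_condition("silence")))
  names(conds) <- vapply(conds, `[[`, "", "label")
  conds
}

#' Calibration constants of the sound delivery chain
#'
#' The control signal \eqn{a(t)} (arbitrary units in [-1, 1]) is converted
#' to a pressure wave \eqn{p(t) = f a(t)} by the amplifier/speaker.  The
#' constants below summarise a phonometer calibration of that chain:
#' \code{f} is the pressure per control-signal unit, \code{La} the ambient
#' sound level inside the operant chamber, \code{sigma_eff} the effective
#' standard deviation of the normalised Gaussian noise used for the
#' fixed-amplitude stimulus, and \code{a_bar_am} the RMS of the uniform
#' carrier of the AM stimuli (\eqn{\sqrt{1/3}}).
#'
#' @param f Pascals per control-signal unit.
#' @param p0 Reference pressure in pascals (20 micropascal).
#' @param La Ambient sound level in dB.
#' @param sigma_eff Effective sd of the normalised Gaussian noise.
#' @param sample_rate White-noise sampling rate in Hz.
#' @param a_bar_am RMS amplitude of the uniform [-1, 1] carrier.
#' @return An object of class \code{"calibration_constants"}.
#' @export
calibration_constants <- function(f = 0.39, p0 = 2e-5, La = 32,
                                  sigma_eff = 0.283, sample_rate = 44100,
                                  a_bar_am = sqrt(1 / 3)) {
  vals <- c(f = f, p0 = p0, sigma_eff = sigma_eff,
            sample_rate = sample_rate, a_bar_am = a_bar_am)
  if (any(!is.finite(vals)) || any(vals <= 0) || !is.finite(La)) {
    stop("calibration constants must be finite and strictly positive")
  }
  structure(list(f = f, p0 = p0, La = La, sigma_eff = sigma_eff,
                 sample_rate = sample_rate, a_bar_am = a_bar_am),
            class = "calibration_constants")
}

#' Ambient pressure from the ambient level
#'
#' Inverts the SPL definition at zero stimulus pressure:
#' \eqn{p_a = p_0 10^{L_a / 20}}.
#'
#' @param calib A \code{calibration_constants} object.
#' @return Ambient RMS pressure in pascals.
#' @export
ambient_pressure <- function(calib = calibration_constants()) {
  calib$p0 * 10^(calib$La / 20)
}

#' Sound level from RMS pressure
#'
#' \eqn{L = 10 \log_{10}((\bar p^2 + p_a^2) / p_0^2)}: the ambient pressure
#' adds in quadrature, so the computed level never falls below the ambient
#' floor \code{La}.
#'
#' @param p_rms RMS stimulus pressure in pascals (vectorised; 0 is valid).
#' @param calib A \code{calibration_constants} object.
#' @return Level(s) in dB.
#' @export
level_from_pressure <- function(p_rms, calib = calibration_constants()) {
  if (any(p_rms < 0)) stop("'p_rms' must be non-negative")
  pa <- ambient_pressure(calib)
  10 * log10((p_rms^2 + pa^2) / calib$p0^2)
}

#' RMS pressure from sound level
#'
#' Inverse of \code{\link{level_from_pressure}}:
#' \eqn{\bar p = p_0 \sqrt{10^{L/10} - (p_a/p_0)^2}}.  Only levels at or
#' above the ambient floor are invertible.
#'
#' @param L Level(s) in dB, each \code{>= calib$La}.
#' @param calib A \code{calibration_constants} object.
#' @return RMS pressure(s) in pascals.
#' @export
pressure_from_level <- function(L, calib = calibration_constants()) {
  pa <- ambient_pressure(calib)
  rad <- 10^(L / 10) - (pa / calib$p0)^2
  if (any(rad < -1e-12)) {
    stop("level below the ambient floor La cannot be inverted to a pressure")
  }
  calib$p0 * sqrt(pmax(rad, 0))
}

#' Synthesize the digital control signal of a sound condition
#'
#' Fixed-amplitude: i.i.d. Gaussian samples with standard deviation
#' \code{sigma_eff}, clamped to [-1, 1] (the clamp stands in for the
#' normalisation applied before WAV conversion; at sd 0.283 it touches
#' ~0.04\% of samples).  AM: i.i.d. uniform [-1, 1] carrier multiplied by
#' the raised-cosine envelope \eqn{m(t) = (1 - \cos 2\pi\nu t)/2}.
#' Silence: zeros.  As in the task, one carrier realisation per condition:
#' the output is deterministic given \code{seed}.
#'
#' @param condition A \code{sound_condition}.
#' @param duration Signal duration in seconds.
#' @param calib A \code{calibration_constants} object.
#' @param seed Integer seed for the carrier noise.
#' @return Numeric vector of samples in [-1, 1], with attribute
#'   \code{"sample_rate"}.
#' @export
make_control_signal <- function(condition, duration,
                                calib = calibration_constants(), seed = 1L) {
  stopifnot(inherits(condition, "sound_condition"), duration > 0)
  n <- round(duration * calib$sample_rate)
  a <- switch(condition$kind,
    fixed = {
      z <- withr_rng(seed, rnorm(n, 0, calib$sigma_eff))
      pmin(pmax(z, -1), 1)
    },
    am = {
      t <- (seq_len(n) - 1) / calib$sample_rate
      m <- (1 - cos(2 * pi * condition$modulation_freq * t)) / 2
      withr_rng(seed, runif(n, -1, 1)) * m
    },
    silence = numeric(n),
    stop("invalid sound condition kind"))
  attr(a, "sample_rate") <- calib$sample_rate
  a
}

# evaluate expr under a local RNG state seeded by `seed`
withr_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Analytic intensity profile of a sound condition
#'
#' For an AM condition the RMS pressure over a window \eqn{\tau} much
#' longer than the carrier sampling period but much shorter than the
#' modulation period factorises into the carrier RMS times the envelope,
#' giving the closed form
#' \deqn{L(t) = 10 \log_{10}\left[\left(\frac{f \bar a (1-\cos\omega t)/2}{p_0}\right)^2
#'   + \left(\frac{p_a}{p_0}\right)^2\right].}
#' Fixed-amplitude and silence conditions have constant profiles.
#'
#' @param condition A \code{sound_condition}.
#' @param duration Profile duration in seconds.
#' @param calib A \code{calibration_constants} object.
#' @param tau RMS window in seconds (default 5 ms).  A warning is issued
#'   when \code{tau} violates the scale separation that justifies the
#'   closed form; the profile is still returned.
#' @param grid_step Time grid step in seconds (rendering choice only).
#' @return An object of class \code{"intensity_profile"}: a list with
#'   \code{times} (s), \code{levels} (dB) and \code{window_tau}.
#' @export
intensity_profile <- function(condition, duration,
                              calib = calibration_constants(),
                              tau = 0.005, grid_step = 0.001) {
  stopifnot(inherits(condition, "sound_condition"), duration > 0, tau > 0)
  times <- seq(0, duration, by = grid_step)
  if (condition$kind == "am") {
    if (tau * calib$sample_rate < 10 || tau * condition$modulation_freq > 0.25) {
      warning("RMS window tau violates the scale separation ",
              "sample period << tau << modulation period; ",
              "the analytic profile may not track the signal")
    }
    pa <- ambient_pressure(calib)
    env <- (1 - cos(2 * pi * condition$modulation_freq * times)) / 2
    pbar <- calib$f * calib$a_bar_am * env
    levels <- 10 * log10((pbar / calib$p0)^2 + (pa / calib$p0)^2)
  } else if (condition$kind == "fixed") {
    lfix <- level_from_pressure(calib$f * calib$sigma_eff, calib)
    levels <- rep(lfix, length(times))
  } else {
    levels <- rep(calib$La, length(times))
  }
  structure(list(times = times, levels = levels, window_tau = tau,
                 condition = condition$label),
            class = "intensity_profile")
}

#' Numeric intensity profile by sliding RMS
#'
#' Independent route to the intensity profile: converts a generated control
#' signal to pressure via the calibration factor, takes a centred sliding
#' RMS (windows truncated at the signal edges) and applies the SPL
#' definition.  Used to validate \code{\link{intensity_profile}}.
#'
#' @param signal Control-signal samples from \code{\link{make_control_signal}}.
#' @param calib A \code{calibration_constants} object.
#' @param tau RMS window in seconds.
#' @param grid_step Output grid step in seconds.
#' @return An \code{"intensity_profile"} object.
#' @export
numeric_intensity_profile <- function(signal, calib = calibration_constants(),
                                      tau = 0.005, grid_step = 0.001) {
  sr <- attr(signal, "sample_rate")
  if (is.null(sr)) sr <- calib$sample_rate
  n <- length(signal)
  p2 <- (calib$f * signal)^2
  cs <- c(0, cumsum(p2))
  half <- max(1L, round(tau * sr / 2))
  idx <- unique(pmin(n, 1L + round(seq(0, (n - 1) / sr, by = grid_step) * sr)))
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  ms <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(list(times = (idx - 1L) / sr,
                 levels = level_from_pressure(sqrt(ms), calib),
                 window_tau = tau, condition = NA_character_),
            class = "intensity_profile")
}

#' Average perceived intensity over a trial's reaction time
#'
#' A rat hears the sound from trial onset until it starts its motor
#' response: the reaction time is the response time minus a fixed motor
#' response time (0.3 s).  The perceived intensity is the time average of
#' the dB profile over that window (averaging in pressure units before
#' converting to dB is available as an alternative convention).
#'
#' @param profile An \code{"intensity_profile"}.
#' @param response_time Trial response time in seconds (> \code{mors_t}).
#' @param mors_t Motor response time in seconds.
#' @param average \code{"db"} (default) averages the dB profile;
#'   \code{"pressure"} averages mean-square pressure, then converts.
#' @return A list with \code{mean_level} (dB) and \code{rct} (s).
#' @export
mean_perceived_intensity <- function(profile, response_time, mors_t = 0.3,
                                     average = c("db", "pressure")) {
  average <- match.arg(average)
  if (response_time <= mors_t) {
    stop("invalid trial: response_time must exceed the motor response time")
  }
  rct <- response_time - mors_t
  keep <- profile$times <= rct + 1e-12
  if (!any(keep)) keep[1] <- TRUE
  lev <- profile$levels[keep]
  mean_level <- if (average == "db") mean(lev) else 10 * log10(mean(10^(lev / 10)))
  list(mean_level = mean_level, rct = rct)
}

#' Group the 11 sound conditions into 5 intensity levels
#'
#' Perceived AM intensities cluster by modulation frequency: the 0.25 Hz
#' and 0.82 Hz envelopes each form their own cluster, while 1.32-4 Hz are
#' virtually identical.  With silence at the bottom and the fixed-amplitude
#' sound at the top this yields 5 ordered intensity levels.  The grouping
#' rule is condition-based; when mean levels are supplied the level
#' ordering is checked to be monotone in mean dB.
#'
#' @param conditions A list of \code{sound_condition} objects (default the
#'   full design).
#' @param mean_levels Optional named numeric vector of per-condition mean
#'   dB (names = condition labels) used to verify monotonicity.
#' @return Named integer vector: level index 1 (quietest) to 5 (loudest)
#'   per condition label.
#' @export
assign_intensity_levels <- function(conditions = sound_conditions(),
                                    mean_levels = NULL) {
  lev <- vapply(conditions, function(cn) {
    switch(cn$kind,
      silence = 1L,
      fixed = 5L,
      am = if (cn$modulation_freq < 0.5) 2L
           else if (cn$modulation_freq < 1.0) 3L
           else 4L)
  }, integer(1))
  names(lev) <- vapply(conditions, `[[`, "", "label")
  if (!is.null(mean_levels)) {
    grp <- tapply(mean_levels[names(lev)], lev, mean)
    if (is.unsorted(grp, strictly = TRUE)) {
      warning("group mean dB is not strictly increasing with level index")
    }
  }
  lev
}

#' Intensity level of a trial's sound
#'
#' Maps a (sound_kind, sound_tf) pair to its intensity level index, with
#' the silence level standing in for visual-only trials.
#'
#' @param sound_kind Character vector: "fixed", "am" or "silence".
#' @param sound_tf Numeric vector of AM modulation frequencies (NA
#'   elsewhere).
#' @return Integer vector of level indices 1..5.
#' @export
intensity_level_of <- function(sound_kind, sound_tf) {
  lev <- integer(length(sound_kind))
  lev[sound_kind == "silence"] <- 1L
  lev[sound_kind == "fixed"] <- 5L
  am <- sound_kind == "am"
  lev[am] <- ifelse(sound_tf[am] < 0.5, 2L, ifelse(sound_tf[am] < 1.0, 3L, 4L))
  lev
}
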