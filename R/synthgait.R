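#' Configuration for a synthetic stepping session
#'
#' Describes a stepping-in-place session: quasi-periodic gait cycles of
#' nominal period `cycle_period_s` (one left plus one right step per cycle),
#' LFP contacts carrying band-limited oscillations whose amplitude is
#' modulated by the gait phase, 1/f background noise, a common-mode
#' component shared across contacts, coupled EEG channels, per-foot force
#' traces and a triaxial trunk accelerometer.
#'
#' @param duration_s session length in seconds (> 2 cycles).
#' @param fs sampling rate in Hz.
#' @param cycle_period_s nominal full gait-cycle duration in seconds
#'   (default 2 s: one right and one left step).
#' @param cycle_jitter_sd_s SD of the per-cycle duration in seconds; each
#'   cycle duration is drawn as `cycle_period_s + N(0, sd^2)` truncated to
#'   `> 0.5 * cycle_period_s`.
#' @param n_lfp_contacts number of monopolar LFP contacts (>= 2).
#' @param modulation_bands list of 4-vectors
#'   `c(f_low, f_high, depth, preferred_phase)`: each plants a band-limited
#'   oscillation whose instantaneous amplitude is
#'   `1 + depth * cos(phase - preferred_phase)`; depth in `[0, 1]`,
#'   preferred phase in `[-pi, pi)`.
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param noise_scale RMS of the per-contact background noise relative to
#'   the unit-RMS band oscillation carriers.
#' @param common_mode_gain RMS of the common-mode component added
#'   identically to every monopolar contact.
#' @param eeg_coupling gain of the lagged LFP oscillation copy mixed into
#'   the EEG channels (creates nonzero imaginary LFP-EEG coherence).
#' @param eeg_lag_s lag of that copy in seconds.
#' @param sensor_noise_sd white-noise SD on force and accelerometer traces.
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @return a validated `session_config` list.
#' @seealso [generate_session()]
#' @export
session_config <- function(duration_s = 60,
                           fs = 2048,
                           cycle_period_s = 2,
                           cycle_jitter_sd_s = 0,
                           n_lfp_contacts = 4,
                           modulation_bands = list(c(8, 12, 0.5, 0),
                                                   c(20, 25, 0.5, 0)),
                           noise_exponent = 1,
                           noise_scale = 1,
                           common_mode_gain = 1,
                           eeg_coupling = 0.3,
                           eeg_lag_s = 0.010,
                           sensor_noise_sd = 0.02,
                           seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs,
              cycle_period_s = cycle_period_s,
              cycle_jitter_sd_s = cycle_jitter_sd_s,
              n_lfp_contacts = as.integer(n_lfp_contacts),
              modulation_bands = modulation_bands,
              noise_exponent = noise_exponent,
              noise_scale = noise_scale,
              common_mode_gain = common_mode_gain,
              eeg_coupling = eeg_coupling,
              eeg_lag_s = eeg_lag_s,
              sensor_noise_sd = sensor_noise_sd,
              seed = as.integer(seed))
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  fail_if(cfg$fs <= 0, "invalid config: fs must be > 0")
  fail_if(cfg$duration_s <= 2 * cfg$cycle_period_s,
          "invalid config: duration_s must exceed 2 * cycle_period_s")
  fail_if(cfg$cycle_jitter_sd_s < 0,
          "invalid config: cycle_jitter_sd_s must be >= 0")
  fail_if(cfg$n_lfp_contacts < 2,
          "invalid config: n_lfp_contacts must be >= 2")
  for (b in cfg$modulation_bands) {
    fail_if(length(b) != 4,
            "invalid config: each modulation_bands entry needs (f_low, f_high, depth, preferred_phase)")
    fail_if(b[1] <= 0 || b[2] <= b[1] || b[2] >= cfg$fs / 2,
            "invalid config: modulation_bands edges must satisfy 0 < f_low < f_high < fs/2")
    fail_if(b[3] < 0 || b[3] > 1,
            "invalid config: modulation_bands depth must lie in [0, 1]")
    fail_if(b[4] < -pi || b[4] >= pi,
            "invalid config: modulation_bands preferred_phase must lie in [-pi, pi)")
  }
  fail_if(cfg$noise_scale < 0, "invalid config: noise_scale must be >= 0")
  fail_if(cfg$common_mode_gain < 0,
          "invalid config: common_mode_gain must be >= 0")
  invisible(cfg)
}

#' Per-sample gait phase series
#'
#' @param phase numeric vector of phases in `[-pi, pi)`.
#' @param valid logical vector: `FALSE` outside detected/generated cycles.
#' @param fs sampling rate in Hz.
#' @param strike_observable whether phase 0 is anchored on a measured event
#'   (force strike); `FALSE` for accelerometer-derived phase.
#' @return an object of class `phase_series`.
#' @export
phase_series <- function(phase, valid = rep(TRUE, length(phase)), fs,
                         strike_observable = TRUE) {
  fail_if(length(phase) != length(valid), "phase and valid length mismatch")
  fail_if(any(phase < -pi | phase >= pi, na.rm = TRUE),
          "phase values must lie in [-pi, pi)")
  structure(list(phase = phase, valid = as.logical(valid), fs = fs,
                 strike_observable = isTRUE(strike_observable)),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz, %.1f%% valid\n",
              length(x$phase), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

# Gait cycle table constructor (one row per full cycle).
gait_cycle_table <- function(lift_sample, strike_sample, next_lift_sample,
                             fs) {
  fail_if(!all(lift_sample < strike_sample & strike_sample < next_lift_sample),
          "cycle anchors must satisfy lift < strike < next_lift")
  d <- data.frame(
    cycle = seq_along(lift_sample),
    lift_sample = as.integer(lift_sample),
    strike_sample = as.integer(strike_sample),
    next_lift_sample = as.integer(next_lift_sample),
    duration_s = (next_lift_sample - lift_sample) / fs,
    lift_duration_s = (strike_sample - lift_sample) / fs
  )
  class(d) <- c("gait_cycle_table", "data.frame")
  attr(d, "fs") <- fs
  d
}

# --- noise synthesis -------------------------------------------------------

# 1/f^a noise by spectral shaping of white noise, unit RMS.
colored_noise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  x <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency magnitude
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  y <- Re(stats::fft(x * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Band-limited Gaussian noise carrier, unit RMS, via hard FFT mask.
bandlimited_noise <- function(n, f_low, f_high, fs) {
  w <- stats::rnorm(n)
  x <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= f_low & f <= f_high)
  y <- Re(stats::fft(x * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

# --- session generation ----------------------------------------------------

#' Generate a synthetic stepping session with known ground truth
#'
#' Draws quasi-periodic gait cycles, builds the piecewise-linear ground-truth
#' phase (lift at -pi/pi, strike at 0, linear in between), and synthesizes
#' all sensor channels from it:
#' * LFP contacts: per-band unit-RMS carriers (independent across contacts)
#'   with instantaneous amplitude `1 + depth * cos(phase - preferred_phase)`,
#'   plus 1/f background and a common-mode component shared by all contacts;
#' * EEG `Fz`/`Cz`: own background plus a lagged, attenuated copy of the
#'   contact-0 oscillation (so LFP-EEG imaginary coherence is nonzero);
#' * force plates: sinusoidal load transfer between the feet
#'   (`amp/2 * (1 + sin(phase))` per foot, right foot half a cycle offset),
#'   so the 0.5-5 Hz band-passed trace crosses zero exactly at lift and
#'   strike; positive while loaded, maximal mid-stance, minimal in swing;
#' * accelerometer: x-axis has one minimum per cycle at phase ±pi with the
#'   y-axis increasing there; z is noise.
#'
#' @param config a [session_config()].
#' @return an object of class `synthetic_session`: a list with elements
#'   `recording` (a [recording()]), `truth_phase` (a [phase_series()]),
#'   `truth_cycles` (a `gait_cycle_table`), and `config`.
#' @examples
#' sess <- generate_session(session_config(duration_s = 20, fs = 256, seed = 1))
#' sess$recording
#' head(sess$truth_cycles)
#' @export
generate_session <- function(config) {
  validate_session_config(config)
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- seq(0, n - 1) / fs

  ## -- cycle anchors -------------------------------------------------------
  # first anchor 1 s into the trace (clear of the filter-settle region);
  # cycles are kept while their closing anchor stays 0.25 s clear of the
  # end, so the first uncounted anchor falls inside the detectors' 0.3 s
  # edge guard and cannot surface as an extra cycle
  margin <- 1.0
  n_draw <- ceiling(cfg$duration_s / cfg$cycle_period_s) + 8
  durations <- cfg$cycle_period_s + stats::rnorm(n_draw) * cfg$cycle_jitter_sd_s
  bad <- durations <= 0.5 * cfg$cycle_period_s
  while (any(bad)) {                # truncated normal by redraw
    durations[bad] <- cfg$cycle_period_s +
      stats::rnorm(sum(bad)) * cfg$cycle_jitter_sd_s
    bad <- durations <= 0.5 * cfg$cycle_period_s
  }
  lifts <- margin + cumsum(c(0, durations))
  keep <- which(lifts <= cfg$duration_s - 0.25)
  lifts <- lifts[keep]
  fail_if(length(lifts) < 3, "duration too short for two full cycles")
  n_cyc <- length(lifts) - 1
  strikes <- lifts[seq_len(n_cyc)] + diff(lifts) / 2

  ## -- ground-truth phase (piecewise linear, continuous everywhere) --------
  # Unwrapped phase through anchors: -pi at lift k, 0 at strike k, pi at
  # lift k+1; extrapolated linearly beyond the outer anchors.
  anchor_t <- as.vector(rbind(lifts[seq_len(n_cyc)], strikes))
  anchor_t <- c(anchor_t, lifts[n_cyc + 1])
  anchor_phi <- seq(-pi, by = pi, length.out = length(anchor_t))
  phi_unwrapped <- stats::approx(anchor_t, anchor_phi, xout = t,
                                 rule = 2)$y
  # linear extrapolation at both ends (approx rule=2 clamps; redo edges)
  sl0 <- pi / (strikes[1] - lifts[1])
  pre <- t < anchor_t[1]
  phi_unwrapped[pre] <- -pi + sl0 * (t[pre] - anchor_t[1])
  slN <- pi / (lifts[n_cyc + 1] - strikes[n_cyc])
  post <- t > anchor_t[length(anchor_t)]
  phi_unwrapped[post] <- anchor_phi[length(anchor_phi)] +
    slN * (t[post] - anchor_t[length(anchor_t)])
  phase <- wrap_angle(phi_unwrapped)
  valid <- t >= lifts[1] & t < lifts[n_cyc + 1]

  to_sample <- function(x) pmin(pmax(round(x * fs) + 1L, 1L), n)
  cycles <- gait_cycle_table(to_sample(lifts[seq_len(n_cyc)]),
                             to_sample(strikes),
                             to_sample(lifts[-1]), fs)

  ## -- LFP contacts --------------------------------------------------------
  n_lfp <- cfg$n_lfp_contacts
  common <- colored_noise(n, cfg$noise_exponent, fs) * cfg$common_mode_gain
  osc_by_contact <- vector("list", n_lfp)
  lfp <- matrix(0, n_lfp, n)
  for (k in seq_len(n_lfp)) {
    osc <- rep(0, n)
    for (b in cfg$modulation_bands) {
      env <- 1 + b[3] * cos(phase - b[4])
      osc <- osc + bandlimited_noise(n, b[1], b[2], fs) * env
    }
    osc_by_contact[[k]] <- osc
    lfp[k, ] <- osc +
      colored_noise(n, cfg$noise_exponent, fs) * cfg$noise_scale +
      common
  }

  ## -- EEG: lagged, attenuated copy of contact-0 oscillation + background --
  lag <- round(cfg$eeg_lag_s * fs)
  lagged <- c(rep(0, lag), osc_by_contact[[1]])[seq_len(n)]
  eeg_fz <- cfg$eeg_coupling * lagged +
    colored_noise(n, cfg$noise_exponent, fs)
  eeg_cz <- 0.5 * cfg$eeg_coupling * lagged +
    colored_noise(n, cfg$noise_exponent, fs)

  ## -- gait sensors --------------------------------------------------------
  # the stepping rhythm is guided throughout the trace, so the sensors stay
  # periodic beyond the outermost counted anchors
  s <- sin(phase)
  force_left <- 0.5 + 0.5 * s + stats::rnorm(n) * cfg$sensor_noise_sd
  force_right <- 0.5 - 0.5 * s + stats::rnorm(n) * cfg$sensor_noise_sd
  accel_x <- cos(phase) + stats::rnorm(n) * cfg$sensor_noise_sd
  accel_y <- -s + stats::rnorm(n) * cfg$sensor_noise_sd
  accel_z <- stats::rnorm(n) * cfg$sensor_noise_sd

  sigs <- rbind(lfp, eeg_fz, eeg_cz, force_left, force_right,
                accel_x, accel_y, accel_z)
  labels <- c(as.character(seq_len(n_lfp) - 1L), "Fz", "Cz",
              "force_left", "force_right", "accel_x", "accel_y", "accel_z")
  kinds <- c(rep("lfp", n_lfp), "eeg", "eeg", "force", "force",
             "accel", "accel", "accel")
  rec <- recording(sigs, fs, labels, kinds)

  structure(
    list(recording = rec,
         truth_phase = phase_series(phase, valid, fs),
         truth_cycles = cycles,
         config = cfg),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %.1f s @ %g Hz, %d gait cycles, seed %d\n",
              x$config$duration_s, x$config$fs, nrow(x$truth_cycles),
              x$config$seed))
  print(x$recording)
  invisible(x)
}
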