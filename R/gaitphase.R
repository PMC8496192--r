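# Gait-phase reconstruction from force-plate or accelerometer traces.
#
# Convention: one full gait cycle spans 2*pi; the foot-lift instant carries
# phase -pi (opening a cycle) / pi (closing it), the heel strike carries
# phase 0, and all other samples are linearly interpolated between the
# surrounding anchors.

# Sub-sample zero-crossing times of a trace, split by direction.
find_zero_crossings <- function(x, fs) {
  n <- length(x)
  i <- seq_len(n - 1)
  up <- which(x[i] < 0 & x[i + 1] >= 0)
  down <- which(x[i] >= 0 & x[i + 1] < 0)
  frac <- function(j) -x[j] / (x[j + 1] - x[j])
  list(up = (up - 1 + frac(up)) / fs,
       down = (down - 1 + frac(down)) / fs)
}

# Merge chronologically sorted anchor events: drop events closer than
# debounce_s to the previously kept one, then enforce type alternation.
debounce_events <- function(times, types, debounce_s) {
  ord <- order(times)
  times <- times[ord]; types <- types[ord]
  keep_t <- numeric(0); keep_k <- character(0)
  for (j in seq_along(times)) {
    if (length(keep_t) == 0) {
      keep_t <- times[j]; keep_k <- types[j]
    } else if (times[j] - keep_t[length(keep_t)] >= debounce_s &&
               types[j] != keep_k[length(keep_k)]) {
      keep_t <- c(keep_t, times[j]); keep_k <- c(keep_k, types[j])
    }
  }
  list(times = keep_t, types = keep_k)
}

# Piecewise-linear phase through anchor times with unwrapped anchor phases,
# linearly extrapolated beyond the outer anchors, then wrapped.
interp_phase <- function(anchor_t, anchor_phi, n, fs) {
  t <- seq(0, n - 1) / fs
  phi <- stats::approx(anchor_t, anchor_phi, xout = t, rule = 2)$y
  k <- length(anchor_t)
  sl0 <- (anchor_phi[2] - anchor_phi[1]) / (anchor_t[2] - anchor_t[1])
  pre <- t < anchor_t[1]
  phi[pre] <- anchor_phi[1] + sl0 * (t[pre] - anchor_t[1])
  slN <- (anchor_phi[k] - anchor_phi[k - 1]) / (anchor_t[k] - anchor_t[k - 1])
  post <- t > anchor_t[k]
  phi[post] <- anchor_phi[k] + slN * (t[post] - anchor_t[k])
  wrap_angle(phi)
}

#' Gait phase from a band-pass-filtered force trace
#'
#' Zero-crossings of the 0.5-5 Hz filtered force define the gait events:
#' decreasing crossings (unloading, foot starts to lift) are assigned phase
#' -pi/pi and increasing crossings (foot touches down and starts to carry
#' weight) phase 0. Phase at all other samples is linear interpolation
#' between the surrounding anchors (sub-sample crossing times are used).
#' Crossings closer than `debounce_s` to the previous kept event, or
#' repeating the same direction, are discarded as sensor chatter.
#'
#' Only full lift-strike-lift cycles enter the cycle table and are marked
#' valid; partial cycles at the block edges keep an interpolated phase value
#' but `valid = FALSE`.
#'
#' @param force numeric force trace, already band-passed 0.5-5 Hz
#'   (see [default_filters()]), loading positive.
#' @param fs sampling rate in Hz.
#' @param debounce_s minimum separation between kept events in seconds.
#' @param guard_s events within this distance of either trace end are
#'   discarded (filter-settle region; default 0.3 s).
#' @return list with `phase` (a [phase_series()]) and `cycles`
#'   (a `gait_cycle_table`: per cycle lift/strike/next-lift samples,
#'   `duration_s`, and `lift_duration_s` = lift-to-strike swing time).
#' @examples
#' fs <- 100; t <- seq(0, 20, by = 1 / fs)
#' res <- phase_from_force(sin(2 * pi * t / 2), fs)
#' head(res$cycles)
#' @export
phase_from_force <- function(force, fs, debounce_s = 0.25, guard_s = 0.3) {
  fail_if(all(force == force[1]), "no gait cycles detected")
  zc <- find_zero_crossings(force, fs)
  t_end <- (length(force) - 1) / fs
  zc <- lapply(zc, function(tt) tt[tt >= guard_s & tt <= t_end - guard_s])
  fail_if(length(zc$up) + length(zc$down) < 3, "no gait cycles detected")
  ev <- debounce_events(c(zc$up, zc$down),
                        rep(c("strike", "lift"),
                            c(length(zc$up), length(zc$down))),
                        debounce_s)
  fail_if(length(ev$times) < 3, "no gait cycles detected")

  # unwrapped anchor phases: first anchor is -pi (lift) or 0 (strike),
  # each subsequent (alternating) anchor adds pi
  phi0 <- if (ev$types[1] == "lift") -pi else 0
  anchor_phi <- phi0 + pi * (seq_along(ev$times) - 1)
  n <- length(force)
  phase <- interp_phase(ev$times, anchor_phi, n, fs)

  lifts <- which(ev$types == "lift")
  lifts <- lifts[lifts + 2 <= length(ev$times)]
  fail_if(length(lifts) < 1, "no gait cycles detected")
  to_sample <- function(tt) pmin(pmax(round(tt * fs) + 1L, 1L), n)
  cycles <- gait_cycle_table(to_sample(ev$times[lifts]),
                             to_sample(ev$times[lifts + 1]),
                             to_sample(ev$times[lifts + 2]), fs)
  valid <- rep(FALSE, n)
  t_first <- ev$times[lifts[1]]
  t_last <- ev$times[lifts[length(lifts)] + 2]
  tt <- seq(0, n - 1) / fs
  valid[tt >= t_first & tt < t_last] <- TRUE
  list(phase = phase_series(phase, valid, fs, strike_observable = TRUE),
       cycles = cycles)
}

#' Gait phase from trunk accelerometer traces
#'
#' Anchors are samples with a local minimum of the (band-passed) x-axis
#' acceleration where the y-axis acceleration is increasing; each anchor is
#' assigned phase -pi/pi and phase runs linearly from -pi to pi between
#' consecutive anchors. The heel strike is not observable from the trunk
#' accelerometer, so no phase-0 anchor exists: the cycle table's strike
#' sample is the cycle midpoint and the returned series carries
#' `strike_observable = FALSE`. Accelerometer-derived phase 0/pi need not
#' coincide with force-derived phase 0/pi.
#'
#' @param acc_x,acc_y accelerometer traces, band-passed 0.5-5 Hz.
#' @param fs sampling rate in Hz.
#' @param debounce_s minimum separation between anchors in seconds.
#' @param guard_s anchors within this distance of either trace end are
#'   discarded (filter-settle region).
#' @return list with `phase` ([phase_series()]) and `cycles`
#'   (`gait_cycle_table`).
#' @export
phase_from_accel <- function(acc_x, acc_y, fs, debounce_s = 0.25,
                             guard_s = 0.3) {
  n <- length(acc_x)
  fail_if(length(acc_y) != n, "acc_x and acc_y length mismatch")
  i <- 2:(n - 1)
  is_min <- acc_x[i] < acc_x[i - 1] & acc_x[i] <= acc_x[i + 1] &
    acc_x[i] < 0 & acc_y[i + 1] > acc_y[i - 1]
  cand <- i[is_min]
  guard <- round(guard_s * fs)
  cand <- cand[cand > guard & cand <= n - guard]
  # debounce: within debounce_s keep the deeper minimum
  if (length(cand) > 1) {
    kept <- cand[1]
    for (j in cand[-1]) {
      last <- kept[length(kept)]
      if ((j - last) / fs < debounce_s) {
        if (acc_x[j] < acc_x[last]) kept[length(kept)] <- j
      } else {
        kept <- c(kept, j)
      }
    }
    cand <- kept
  }
  fail_if(length(cand) < 2, "fewer than two gait-cycle anchors detected")

  anchor_t <- (cand - 1) / fs
  anchor_phi <- -pi + 2 * pi * (seq_along(cand) - 1)
  phase <- interp_phase(anchor_t, anchor_phi, n, fs)

  k <- length(cand)
  strike <- round((cand[-k] + cand[-1]) / 2)
  cycles <- gait_cycle_table(cand[-k], strike, cand[-1], fs)
  valid <- rep(FALSE, n)
  valid[seq(cand[1], cand[k] - 1)] <- TRUE
  list(phase = phase_series(phase, valid, fs, strike_observable = FALSE),
       cycles = cycles)
}

#' Stepping-cycle variability
#'
#' Sample standard deviation (n - 1 denominator) of the per-cycle
#' lift-to-strike (swing) duration, i.e. of the period when the foot was
#' lifted.
#'
#' @param cycles a `gait_cycle_table`.
#' @return SD in seconds.
#' @export
cycle_variability <- function(cycles) {
  fail_if(nrow(cycles) < 2, "need at least 2 cycles")
  stats::sd(cycles$lift_duration_s)
}

#' Split cycles into more-regular and less-regular groups
#'
#' Ranks cycles by the absolute deviation of their duration from the mean
#' duration; the `fraction` with the smallest deviations is labeled
#' `regular`, the `fraction` with the largest `less_regular` (group size
#' `floor(fraction * n)`). Ties are broken deterministically by earlier
#' cycle first in the deviation-then-index ordering, so the labels are
#' invariant to row permutation of the input.
#'
#' @param cycles a `gait_cycle_table` with >= 8 cycles.
#' @param fraction fraction per group, in `(0, 0.5]` (default 0.25).
#' @return data.frame with `cycle`, `deviation_s`, `label` (one of
#'   `regular`, `less_regular`, `unlabeled`); attribute `fraction`.
#' @export
split_regularity <- function(cycles, fraction = 0.25) {
  fail_if(fraction <= 0 || fraction > 0.5, "fraction must lie in (0, 0.5]")
  n <- nrow(cycles)
  fail_if(n < 8, "need at least 8 cycles to split")
  ord_rows <- order(cycles$cycle)
  cyc <- cycles[ord_rows, ]
  dev <- abs(cyc$duration_s - mean(cyc$duration_s))
  n_lab <- floor(fraction * n)
  ord <- order(dev, cyc$cycle)
  label <- rep("unlabeled", n)
  label[ord[seq_len(n_lab)]] <- "regular"
  label[ord[seq(n - n_lab + 1, n)]] <- "less_regular"
  out <- data.frame(cycle = cyc$cycle, deviation_s = dev, label = label)
  attr(out, "fraction") <- fraction
  out
}
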