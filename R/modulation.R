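# Phase-binned power modulograms and the KL-divergence modulation index.

# 18 half-open bins [-pi + k*2pi/18, -pi + (k+1)*2pi/18); the last bin is
# closed at pi (phase is wrapped into [-pi, pi) so pi itself never occurs).
phase_bin_index <- function(phase, n_bins) {
  b <- floor((phase + pi) / (2 * pi / n_bins)) + 1L
  pmin.int(pmax.int(b, 1L), n_bins)
}

# Per-frequency per-bin mean of a power matrix given a bin index per sample.
bin_mean_power <- function(power, bins, n_bins) {
  counts <- tabulate(bins, nbins = n_bins)
  sums <- t(rowsum(t(power), bins, reorder = TRUE))
  out <- matrix(0, nrow(power), n_bins)
  present <- sort(unique(bins))
  out[, present] <- sums
  sweep(out, 2, pmax(counts, 1L), "/")
}

#' Gait-phase power modulogram
#'
#' Averages wavelet power within 18 non-overlapping gait-phase bins with
#' equally spaced centres from -pi to pi, per frequency, and normalizes
#' each frequency row two ways: against the mean of all bins (percent, for
#' display and statistics) and against the sum of all bins (a probability
#' vector, the input to the modulation index).
#'
#' Only samples with a valid gait phase and with edge-clean wavelet
#' coefficients at every frequency of the grid contribute.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param phase a [phase_series()] on the same time base.
#' @param n_bins number of phase bins (default 18).
#' @param channel channel of the tfr.
#' @return object of class `modulogram`: list with `mean_norm`
#'   (frequency x bins, percent of bin-mean), `sum_norm` (frequency x bins,
#'   rows sum to 1), `bin_edges` (length `n_bins + 1`, from -pi to pi),
#'   `bin_centers`, `freqs`, `n_bins`.
#' @examples
#' sess <- generate_session(session_config(duration_s = 30, fs = 256))
#' tfr <- morlet_tfr(sess$recording, freqs = 5:40, channels = "0")
#' m <- modulogram(tfr, sess$truth_phase)
#' @export
modulogram <- function(tfr, phase, n_bins = 18, channel = 1) {
  fail_if(length(phase$phase) != tfr$n_time,
          "tfr (%d samples) and phase (%d samples) time bases differ",
          tfr$n_time, length(phase$phase))
  sel <- phase$valid & tfr_all_valid(tfr)
  fail_if(!any(sel), "no valid samples shared by tfr and phase")
  bins <- phase_bin_index(phase$phase[sel], n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  empty <- which(counts == 0)
  fail_if(length(empty) > 0, "empty phase bin(s): %s",
          paste(empty, collapse = ", "))
  power <- tfr_power(tfr, channel)[, sel, drop = FALSE]
  raw <- bin_mean_power(power, bins, n_bins)
  new_modulogram(raw, tfr$freqs, n_bins)
}

# Build a modulogram object from raw per-bin mean power.
new_modulogram <- function(raw, freqs, n_bins) {
  mean_norm <- 100 * raw / rowMeans(raw)
  sum_norm <- raw / rowSums(raw)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  structure(list(mean_norm = mean_norm, sum_norm = sum_norm,
                 bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 freqs = freqs, n_bins = n_bins),
            class = "modulogram")
}

#' @export
print.modulogram <- function(x, ...) {
  cat(sprintf("<modulogram> %d freqs (%g-%g Hz) x %d phase bins\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_bins))
  invisible(x)
}

#' Modulation index spectrum
#'
#' For each frequency, the Kullback-Leibler divergence between the
#' phase-binned power distribution P (the sum-normalized modulogram row)
#' and the uniform distribution U over the N bins, normalized by `log(N)`:
#' `MI = D_KL(P, U) / log(N)` with `D_KL = sum_j P_j log(P_j / U_j)` and
#' the convention `0 * log 0 = 0`. MI is 0 iff P is uniform (no phase
#' locking) and 1 when all power concentrates in one bin; it is invariant
#' to overall power gain.
#'
#' @param m a [modulogram()].
#' @return object of class `mi_spectrum`: list with `mi` (per-frequency MI
#'   in `[0, 1]`) and `freqs`.
#' @export
modulation_index <- function(m) {
  P <- m$sum_norm
  fail_if(any(P < 0), "negative probabilities in sum-normalized modulogram")
  mi <- apply(P, 1, function(p) kl_uniform(p) / log(length(p)))
  structure(list(mi = as.numeric(mi), freqs = m$freqs),
            class = "mi_spectrum")
}

# D_KL(p, uniform) with 0*log0 = 0.
kl_uniform <- function(p) {
  n <- length(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] * n))
}

#' Maximum modulation index within a frequency band
#'
#' @param spec an [modulation_index()] result.
#' @param band numeric `c(low, high)` in Hz (default the whole 1-95 Hz
#'   wide band).
#' @return list with `freq` (argmax frequency, ties broken toward the
#'   lower frequency) and `value`.
#' @export
max_mi <- function(spec, band = c(1, 95)) {
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  fail_if(length(sel) == 0, "band [%g, %g] outside the frequency grid",
          band[1], band[2])
  i <- sel[which.max(spec$mi[sel])]     # which.max: first (lowest) on ties
  list(freq = spec$freqs[i], value = spec$mi[i])
}

#' Plot a modulogram with its modulation index
#'
#' Heat map of the percent-normalized modulogram with the MI spectrum as a
#' side panel, mirroring the standard per-channel display.
#'
#' @param x a [modulogram()].
#' @param mi optional [modulation_index()] result (computed if missing).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the MI spectrum.
#' @export
plot.modulogram <- function(x, mi = NULL, ...) {
  if (is.null(mi)) mi <- modulation_index(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(mi$mi, mi$freqs, type = "l", xlab = "modulation index",
                 ylab = "frequency (Hz)")
  graphics::image(x$bin_centers, x$freqs, t(x$mean_norm),
                  xlab = "gait phase (rad)", ylab = "frequency (Hz)",
                  main = "power (% of bin mean)", ...)
  invisible(mi)
}
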