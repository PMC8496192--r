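#' Complex Morlet time-frequency decomposition
#'
#' Convolves each channel with complex Morlet wavelets on a linear frequency
#' grid (default 1-95 Hz in 1 Hz steps) with a linearly spaced number of
#' cycles (default 4 at the lowest to 8 at the highest frequency).
#' Implementation is by multiplication in the Fourier domain with an
#' analytic Gaussian kernel of peak gain 1 at the centre frequency, so a
#' unit-amplitude tone yields power 1 at its own frequency regardless of
#' the frequency.
#'
#' Coefficients within half a wavelet support (3 temporal SDs) of either
#' edge are affected by the signal boundary; their positions are recorded
#' per frequency and excluded from all averages downstream.
#'
#' @param rec a [recording()].
#' @param freqs frequency grid in Hz (each must be below `fs/2`).
#' @param n_cycles per-frequency wavelet cycle counts, same length as
#'   `freqs`, non-decreasing.
#' @param channels channel selector (labels, indices, or `NULL` for all).
#' @return an object of class `tfr`: list with `coef` (list of complex
#'   frequency x time matrices, one per channel), `freqs`, `n_cycles`,
#'   `fs`, `labels`, `edge` (per-frequency half-support in samples), and
#'   `n_time`.
#' @examples
#' rec <- generate_session(session_config(duration_s = 20, fs = 256))$recording
#' tfr <- morlet_tfr(rec, freqs = 5:40, channels = "0")
#' @export
morlet_tfr <- function(rec, freqs = 1:95,
                       n_cycles = seq(4, 8, length.out = length(freqs)),
                       channels = NULL) {
  fail_if(length(n_cycles) != length(freqs),
          "n_cycles must have one entry per frequency")
  fail_if(any(diff(n_cycles) < 0), "n_cycles must be non-decreasing")
  fail_if(any(freqs >= rec$fs / 2),
          "all frequencies must be below fs/2 = %g Hz", rec$fs / 2)
  fail_if(any(freqs <= 0), "frequencies must be positive")
  idx <- resolve_channels(rec, channels)
  n <- n_samples(rec)
  fs <- rec$fs

  sd_t <- n_cycles / (2 * pi * freqs)
  edge <- ceiling(3 * sd_t * fs)
  fail_if(n <= 2 * max(edge),
          "signal (%d samples) shorter than the longest wavelet support (%d)",
          n, 2 * max(edge))

  fg <- seq(0, n - 1) * fs / n
  pos <- fg <= fs / 2
  sigma_f <- freqs / n_cycles

  coef <- vector("list", length(idx))
  for (ci in seq_along(idx)) {
    X <- stats::fft(rec$signals[idx[ci], ])
    m <- matrix(0i, length(freqs), n)
    for (fi in seq_along(freqs)) {
      H <- numeric(n)
      H[pos] <- 2 * exp(-0.5 * ((fg[pos] - freqs[fi]) / sigma_f[fi])^2)
      m[fi, ] <- stats::fft(X * H, inverse = TRUE) / n
    }
    coef[[ci]] <- m
  }
  structure(list(coef = coef, freqs = freqs, n_cycles = n_cycles, fs = fs,
                 labels = rec$labels[idx], edge = edge, n_time = n),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d channel(s) x %d freqs (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$coef), length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_time, x$fs))
  invisible(x)
}

#' Wavelet power of one channel
#' @param tfr a [morlet_tfr()] result.
#' @param channel channel label or index within the tfr.
#' @return real matrix frequency x time of `|coef|^2`.
#' @export
tfr_power <- function(tfr, channel = 1) {
  ci <- tfr_channel_index(tfr, channel)
  p <- tfr$coef[[ci]]
  Re(p * Conj(p))
}

tfr_channel_index <- function(tfr, channel) {
  if (is.character(channel)) {
    ci <- match(channel, tfr$labels)
    fail_if(is.na(ci), "channel '%s' not in tfr", channel)
    ci
  } else {
    as.integer(channel)
  }
}

# Logical vector over time, TRUE where coefficients at every frequency are
# unaffected by the signal edges (the per-frequency edge windows are nested,
# so this is governed by the largest edge).
tfr_all_valid <- function(tfr) {
  e <- min(max(tfr$edge), tfr$n_time)
  v <- rep(TRUE, tfr$n_time)
  if (e > 0) {
    v[seq_len(e)] <- FALSE
    v[seq(tfr$n_time - e + 1, tfr$n_time)] <- FALSE
  }
  v
}

# Logical matrix frequency x time, TRUE where coefficients are unaffected
# by the signal edges.
tfr_valid_mask <- function(tfr) {
  m <- matrix(TRUE, length(tfr$freqs), tfr$n_time)
  for (fi in seq_along(tfr$freqs)) {
    e <- tfr$edge[fi]
    if (e > 0) {
      m[fi, seq_len(min(e, tfr$n_time))] <- FALSE
      m[fi, seq(max(1, tfr$n_time - e + 1), tfr$n_time)] <- FALSE
    }
  }
  m
}

#' Percent-normalized power spectral density
#'
#' Averages wavelet power over the selected time samples (excluding
#' edge-contaminated coefficients) and normalizes each channel by the sum
#' over the whole frequency grid, so the values are percentages summing
#' to 100 per channel.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param time_mask logical vector over time samples selecting the period
#'   of interest (`NULL` = all samples).
#' @return object of class `psd_percent`: list with `values`
#'   (channel x frequency matrix, percent) and `freqs`.
#' @export
psd_percent <- function(tfr, time_mask = NULL) {
  if (is.null(time_mask)) time_mask <- rep(TRUE, tfr$n_time)
  fail_if(length(time_mask) != tfr$n_time, "time_mask length mismatch")
  fail_if(!any(time_mask), "time_mask selects no samples")
  vm <- tfr_valid_mask(tfr)
  values <- matrix(0, length(tfr$coef), length(tfr$freqs),
                   dimnames = list(tfr$labels, NULL))
  for (ci in seq_along(tfr$coef)) {
    p <- tfr_power(tfr, ci)
    for (fi in seq_along(tfr$freqs)) {
      sel <- time_mask & vm[fi, ]
      fail_if(!any(sel), "no valid samples at %g Hz after edge exclusion",
              tfr$freqs[fi])
      values[ci, fi] <- mean(p[fi, sel])
    }
    values[ci, ] <- 100 * values[ci, ] / sum(values[ci, ])
  }
  structure(list(values = values, freqs = tfr$freqs), class = "psd_percent")
}

#' Imaginary coherence between two channels
#'
#' Computes the magnitude of the imaginary part of the normalized
#' cross-spectrum, `|Im(G_ab)| / sqrt(G_aa * G_bb)`, with cross- and
#' auto-spectral densities estimated by averaging products of Morlet
#' coefficients over the selected time samples. Insensitive to zero-lag
#' (volume-conducted or artifactual) coupling: a signal paired with any
#' real-scaled copy of itself gives 0 at all frequencies.
#'
#' @param tfr_a,tfr_b [morlet_tfr()] results sharing the frequency grid,
#'   cycle counts, sampling rate and length (may be the same object).
#' @param time_mask logical vector over time samples (`NULL` = all).
#' @param channel_a,channel_b channel within each tfr.
#' @return object of class `coherence_spectrum`: list with `values`
#'   (per-frequency IC in `[0, 1]`), `freqs`, and `pair`.
#' @export
imaginary_coherence <- function(tfr_a, tfr_b, time_mask = NULL,
                                channel_a = 1, channel_b = 1) {
  fail_if(!isTRUE(all.equal(tfr_a$freqs, tfr_b$freqs)) ||
            !isTRUE(all.equal(tfr_a$n_cycles, tfr_b$n_cycles)) ||
            tfr_a$fs != tfr_b$fs || tfr_a$n_time != tfr_b$n_time,
          "tfr grids do not match")
  if (is.null(time_mask)) time_mask <- rep(TRUE, tfr_a$n_time)
  fail_if(length(time_mask) != tfr_a$n_time, "time_mask length mismatch")
  ca <- tfr_a$coef[[tfr_channel_index(tfr_a, channel_a)]]
  cb <- tfr_b$coef[[tfr_channel_index(tfr_b, channel_b)]]
  vm <- tfr_valid_mask(tfr_a) & tfr_valid_mask(tfr_b)
  values <- numeric(length(tfr_a$freqs))
  for (fi in seq_along(tfr_a$freqs)) {
    sel <- time_mask & vm[fi, ]
    fail_if(!any(sel), "no valid samples at %g Hz after edge exclusion",
            tfr_a$freqs[fi])
    gab <- mean(ca[fi, sel] * Conj(cb[fi, sel]))
    gaa <- mean(Mod(ca[fi, sel])^2)
    gbb <- mean(Mod(cb[fi, sel])^2)
    values[fi] <- abs(Im(gab)) / sqrt(gaa * gbb)
  }
  structure(list(values = values, freqs = tfr_a$freqs,
                 pair = c(a = tfr_a$labels[tfr_channel_index(tfr_a, channel_a)],
                          b = tfr_b$labels[tfr_channel_index(tfr_b, channel_b)])),
            class = "coherence_spectrum")
}
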