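#' Bipolar re-referencing of adjacent contacts
#'
#' Builds spatially focal bipolar channels by differencing each pair of
#' spatially adjacent electrode contacts, which suppresses common-mode
#' (volume-conducted or reference) activity.
#'
#' @param rec a [recording()].
#' @param contact_order character vector of >= 2 monopolar contact labels in
#'   spatial order along the electrode.
#' @return a `recording` with `length(contact_order) - 1` channels, where
#'   channel k is contact k minus contact k+1, labeled `"a-b"`.
#' @examples
#' rec <- generate_session(session_config(duration_s = 10, fs = 256))$recording
#' make_bipolar(rec, c("0", "1", "2", "3"))
#' @export
make_bipolar <- function(rec, contact_order) {
  fail_if(length(contact_order) < 2,
          "need at least two contacts for a bipolar montage")
  missing <- setdiff(contact_order, rec$labels)
  fail_if(length(missing) > 0, "contact label(s) not in recording: %s",
          paste(missing, collapse = ", "))
  idx <- match(contact_order, rec$labels)
  k <- length(idx)
  out <- rec$signals[idx[-k], , drop = FALSE] -
    rec$signals[idx[-1], , drop = FALSE]
  labels <- paste(contact_order[-k], contact_order[-1], sep = "-")
  recording(out, rec$fs, labels, rec$kinds[idx[-k]])
}

#' Butterworth filter specification
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param order even integer: the final design order of the band filter
#'   (an order-8 band filter is designed from an order-4 prototype), before
#'   the forward-backward (zero-phase) application which doubles the
#'   effective magnitude order.
#' @param edges numeric `c(low, high)` corner frequencies in Hz.
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), order, edges,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  fail_if(order %% 2 != 0 || order < 2, "filter order must be a positive even integer")
  fail_if(length(edges) != 2 || edges[1] <= 0 || edges[2] <= edges[1],
          "edges must be c(low, high) with 0 < low < high")
  structure(list(kind = kind, order = as.integer(order),
                 edges = as.numeric(edges), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Design the signal::butter filter for a spec at sampling rate fs.
design_butter <- function(spec, fs) {
  fail_if(spec$edges[2] >= fs / 2,
          "filter edges must lie inside (0, fs/2); got high edge %g at fs %g",
          spec$edges[2], fs)
  type <- if (spec$kind == "bandstop") "stop" else "pass"
  signal::butter(spec$order / 2, spec$edges / (fs / 2), type = type)
}

# Zero-phase forward-backward filtering with odd reflect padding, so that
# startup transients of the low corner do not contaminate short gait blocks.
filtfilt_padded <- function(filt, x, fs, low_edge) {
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * fs / low_edge))
  fail_if(pad < 1, "signal too short to filter")
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(filt, xp)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[seq(pad + 1, pad + n)]
}

#' Apply a zero-phase Butterworth filter to selected channels
#'
#' Filters run forward-backward over odd-reflection padding (3 periods of
#' the low corner frequency), so the output has zero phase distortion and
#' negligible edge transients.
#'
#' @param rec a [recording()].
#' @param spec a [filter_spec()].
#' @param channels channel selector (labels, indices, or `NULL` for all).
#' @return a `recording` with the selected channels filtered in place.
#' @examples
#' rec <- generate_session(session_config(duration_s = 10, fs = 256))$recording
#' spec <- filter_spec("bandpass", 6, c(0.5, 5))
#' filtered <- apply_filter(rec, spec, channels = "force_left")
#' @export
apply_filter <- function(rec, spec, channels = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  filt <- design_butter(spec, rec$fs)
  idx <- resolve_channels(rec, channels)
  out <- rec$signals
  for (i in idx) {
    if (spec$zero_phase) {
      out[i, ] <- filtfilt_padded(filt, rec$signals[i, ], rec$fs,
                                  spec$edges[1])
    } else {
      out[i, ] <- as.numeric(signal::filter(filt, rec$signals[i, ]))
    }
  }
  recording(out, rec$fs, rec$labels, rec$kinds)
}

#' Default per-kind filter chain
#'
#' LFP and EEG channels: 48-52 Hz order-8 band-stop (line noise), then
#' 0.5-250 Hz order-8 band-pass. Force and accelerometer channels:
#' 0.5-5 Hz order-6 band-pass. All zero-phase.
#'
#' @param kind channel kind tag.
#' @return list of [filter_spec()]s to apply in order.
#' @export
default_filters <- function(kind) {
  switch(kind,
    lfp = ,
    eeg = list(filter_spec("bandstop", 8, c(48, 52)),
               filter_spec("bandpass", 8, c(0.5, 250))),
    force = ,
    accel = list(filter_spec("bandpass", 6, c(0.5, 5))),
    stop(sprintf("unknown channel kind '%s'", kind))
  )
}

#' Apply the default filter chain to every channel of a recording
#'
#' @param rec a [recording()].
#' @return filtered `recording`. When `fs <= 500` Hz the 0.5-250 Hz
#'   band-pass high edge is reduced to `0.45 * fs` so the design stays valid
#'   on downsampled data.
#' @export
preprocess_recording <- function(rec) {
  out <- rec
  for (kind in unique(rec$kinds)) {
    specs <- default_filters(kind)
    for (spec in specs) {
      if (spec$edges[2] >= rec$fs / 2) {
        spec$edges[2] <- 0.45 * rec$fs
      }
      if (spec$edges[1] >= rec$fs / 2) next
      out <- apply_filter(out, spec, channels = which(rec$kinds == kind))
    }
  }
  out
}

#' Resample a recording to a lower sampling rate
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency, which is simultaneously an ideal anti-alias filter, and
#' inverse-transformed on the new grid. Duration is preserved to within one
#' output sample and in-band tones keep their amplitude.
#'
#' @param rec a [recording()].
#' @param fs_new target sampling rate in Hz, strictly below `rec$fs`.
#' @return a `recording` at `fs_new` with `round(n * fs_new / fs)` samples.
#' @examples
#' rec <- generate_session(session_config(duration_s = 10, fs = 2048))$recording
#' resample_recording(rec, 256)
#' @export
resample_recording <- function(rec, fs_new) {
  fail_if(fs_new >= rec$fs, "fs_new (%g) must be below fs (%g)",
          fs_new, rec$fs)
  n_in <- n_samples(rec)
  n_out <- round(n_in * fs_new / rec$fs)
  out <- matrix(0, nrow(rec$signals), n_out)
  for (i in seq_len(nrow(rec$signals))) {
    out[i, ] <- fft_resample(rec$signals[i, ], n_out)
  }
  recording(out, fs_new, rec$labels, rec$kinds)
}

# Resample a vector to n_out samples by Fourier truncation/zero-padding.
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  X <- stats::fft(x)
  keep <- floor(n_out / 2)
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[n_out - seq_len(keep) + 1] <- X[n_in - seq_len(keep) + 1]
    if (n_out %% 2 == 0) {
      # split the Nyquist bin to keep the output real
      Y[keep + 1] <- Re(X[keep + 1])
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Flag high-amplitude artifact samples
#'
#' Simple automated stand-in for visual artifact screening: samples whose
#' absolute amplitude exceeds `z_thresh` robust SDs (1.4826 * MAD) of their
#' channel are flagged, dilated by `pad_s` on both sides.
#'
#' @param rec a [recording()].
#' @param z_thresh robust z-score threshold (default 5).
#' @param pad_s dilation in seconds around flagged samples.
#' @return logical matrix (channels x samples), `TRUE` where flagged.
#' @export
flag_artifacts <- function(rec, z_thresh = 5, pad_s = 0.1) {
  flags <- matrix(FALSE, nrow(rec$signals), n_samples(rec))
  pad <- round(pad_s * rec$fs)
  for (i in seq_len(nrow(rec$signals))) {
    x <- rec$signals[i, ]
    s <- stats::mad(x)
    if (s == 0) next
    bad <- which(abs(x - stats::median(x)) > z_thresh * s)
    if (length(bad) == 0) next
    hits <- unique(pmin(pmax(rep(bad, each = 2 * pad + 1) +
                               rep(-pad:pad, length(bad)), 1L),
                        n_samples(rec)))
    flags[i, hits] <- TRUE
  }
  flags
}
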