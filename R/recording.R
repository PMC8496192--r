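#' Multichannel recording container
#'
#' A `recording` bundles uniformly sampled multichannel time series with
#' per-channel labels and kind tags, the common container for raw and
#' preprocessed electrophysiology plus the synchronized gait sensors.
#'
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param labels character vector of unique channel names (one per row).
#' @param kinds character vector of channel kinds, each one of
#'   `"lfp"`, `"eeg"`, `"force"`, `"accel"`.
#' @return an object of class `recording` with fields `signals`, `fs`,
#'   `labels`, `kinds`.
#' @export
recording <- function(signals, fs, labels, kinds) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  signals <- as.matrix(signals)
  fail_if(!is.numeric(fs) || length(fs) != 1 || fs <= 0,
          "fs must be a single positive number")
  fail_if(length(labels) != nrow(signals),
          "labels length (%d) != number of channels (%d)",
          length(labels), nrow(signals))
  fail_if(anyDuplicated(labels) > 0, "channel labels must be unique")
  fail_if(length(kinds) != nrow(signals),
          "kinds length (%d) != number of channels (%d)",
          length(kinds), nrow(signals))
  bad <- setdiff(unique(kinds), c("lfp", "eeg", "force", "accel"))
  fail_if(length(bad) > 0, "unknown channel kind(s): %s",
          paste(bad, collapse = ", "))
  fail_if(anyNA(signals), "signals contain NA")
  rownames(signals) <- labels
  structure(
    list(signals = signals, fs = fs,
         labels = as.character(labels), kinds = as.character(kinds)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  tab <- table(x$kinds)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$signals)

#' Select channels of a recording
#'
#' @param rec a [recording()].
#' @param channels character vector of labels, or integer/logical index.
#' @return a `recording` containing the selected channels, in the
#'   requested order.
#' @export
select_channels <- function(rec, channels) {
  idx <- resolve_channels(rec, channels)
  recording(rec$signals[idx, , drop = FALSE], rec$fs,
            rec$labels[idx], rec$kinds[idx])
}

# Map a label/index/logical selector to integer channel indices.
resolve_channels <- function(rec, channels) {
  if (is.null(channels)) return(seq_along(rec$labels))
  if (is.character(channels)) {
    idx <- match(channels, rec$labels)
    fail_if(anyNA(idx), "channel(s) not found: %s",
            paste(channels[is.na(idx)], collapse = ", "))
    return(idx)
  }
  if (is.logical(channels)) return(which(channels))
  as.integer(channels)
}

# Extract one channel as a numeric vector.
channel_signal <- function(rec, channel) {
  idx <- resolve_channels(rec, channel)
  fail_if(length(idx) != 1, "expected a single channel")
  rec$signals[idx, ]
}
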