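# Independent oracles and small fixture builders shared across test files.

# Analytic-signal envelope via the FFT Hilbert transform; independent of the
# package's wavelet pipeline.
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Literal 2^n enumeration of the exact two-sided signed-rank p-value.
wilcoxon_brute_force <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Full n! enumeration of the exact two-sided Spearman p-value.
spearman_brute_force <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- gaitmod:::all_permutations(n)
  rho_all <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# A tfr object with externally supplied coefficients, for tests that need
# exact control over power (no edges, single channel).
fake_tfr <- function(coef, freqs, fs) {
  structure(list(coef = list(coef), freqs = freqs,
                 n_cycles = rep(7, length(freqs)), fs = fs,
                 labels = "x", edge = rep(0L, length(freqs)),
                 n_time = ncol(coef)),
            class = "tfr")
}

# A small stepping session tuned for fast tests.
quick_session <- function(seed = 1, duration_s = 30, fs = 256,
                          depth = 0.8, band = c(20, 25), pref = 0,
                          jitter = 0, ...) {
  generate_session(session_config(
    duration_s = duration_s, fs = fs, cycle_jitter_sd_s = jitter,
    modulation_bands = list(c(band[1], band[2], depth, pref)),
    seed = seed, ...))
}

# Recording wrapper around plain vectors.
vec_recording <- function(..., fs, kind = "lfp") {
  sig <- rbind(...)
  recording(sig, fs, labels = paste0("ch", seq_len(nrow(sig))),
            kinds = rep(kind, nrow(sig)))
}
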