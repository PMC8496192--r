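# Unsupervised LFP state analysis: a hidden Markov model whose per-state
# observation model is a multivariate autoregressive (AR) process, fitted by
# maximum-likelihood EM; gait-phase occupancy histograms per state; and
# K-medoids clustering of the histograms.
#
# This is a deliberately simplified variant of variational HMM-MAR
# toolboxes: plain EM with hard (Viterbi) state assignment and
# occupancy-based pruning of unused states.

# Lagged design matrix: row t holds x_{t-1}, ..., x_{t-p} (channels fastest).
ar_design <- function(X, p) {
  Tn <- nrow(X); d <- ncol(X)
  Z <- matrix(0, Tn - p, d * p)
  for (l in seq_len(p)) {
    Z[, (l - 1) * d + seq_len(d)] <- X[(p + 1 - l):(Tn - l), , drop = FALSE]
  }
  Z
}

# Log emission densities: residual log-likelihood of Y under each state's
# AR coefficients and noise covariance. Returns (T - p) x K matrix.
ar_log_emissions <- function(Y, Z, A, Sigma) {
  K <- length(A)
  d <- ncol(Y)
  out <- matrix(0, nrow(Y), K)
  for (k in seq_len(K)) {
    E <- Y - Z %*% A[[k]]
    R <- chol(Sigma[[k]])
    quad <- rowSums((E %*% backsolve(R, diag(d)))^2)
    out[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
  }
  out
}

# Scaled forward-backward. Returns gamma, xi sums, and the log-likelihood.
forward_backward <- function(logB, trans, pi0) {
  Tn <- nrow(logB); K <- ncol(logB)
  shift <- apply(logB, 1, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K)
  cscale <- numeric(Tn)
  a <- pi0 * B[1, ]
  cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% trans) * B[t, ]
    cscale[t] <- sum(a)
    alpha[t, ] <- a / cscale[t]
  }
  beta[Tn, ] <- 1
  xi_sum <- matrix(0, K, K)
  for (t in (Tn - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    xi <- (alpha[t, ] %o% bb) * trans
    xi_sum <- xi_sum + xi / sum(xi)
    beta[t, ] <- (trans %*% bb) / cscale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cscale)) + sum(shift))
}

# Viterbi decoding in log space.
viterbi_path <- function(logB, trans, pi0) {
  Tn <- nrow(logB); K <- ncol(logB)
  lt <- log(trans)
  delta <- log(pi0) + logB[1, ]
  psi <- matrix(0L, Tn, K)
  for (t in 2:Tn) {
    cand <- delta + lt                   # K x K: from i (row) to j (col)
    psi[t, ] <- max.col(t(cand))
    delta <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# Weighted AR fit for one state: coefficients and noise covariance.
weighted_ar_fit <- function(Y, Z, w, ridge = 1e-8) {
  sw <- sqrt(w)
  Zw <- Z * sw
  Yw <- Y * sw
  G <- crossprod(Zw) + ridge * diag(ncol(Z))
  A <- solve(G, crossprod(Zw, Yw))
  E <- Y - Z %*% A
  Sigma <- crossprod(E * sw) / sum(w)
  Sigma <- Sigma + ridge * diag(ncol(Y))
  list(A = A, Sigma = Sigma)
}

# Window features for k-means initialization: log power and low-lag
# autocorrelations per channel over short windows.
init_window_features <- function(X, fs, win_s = 0.25) {
  w <- max(8L, round(win_s * fs))
  Tn <- nrow(X); d <- ncol(X)
  starts <- seq(1, Tn - w + 1, by = w)
  feats <- matrix(0, length(starts), d * 3)
  for (i in seq_along(starts)) {
    seg <- X[starts[i]:(starts[i] + w - 1), , drop = FALSE]
    for (j in seq_len(d)) {
      s <- seg[, j]
      ac <- stats::acf(s, lag.max = 2, plot = FALSE,
                       demean = TRUE)$acf[2:3]
      feats[i, (j - 1) * 3 + 1:3] <- c(log(stats::var(s) + 1e-12), ac)
    }
  }
  list(feats = feats, starts = starts, win = w)
}

#' Fit an autoregressive hidden Markov model to multichannel LFP
#'
#' Segments a multichannel time series into recurring dynamical states,
#' each modeled as a multivariate AR(`ar_order`) process with its own
#' coefficients and noise covariance, using maximum-likelihood EM.
#' Initialization is by k-means on short-window variance/autocorrelation
#' features (with additional randomized restarts); the best restart by
#' final log-likelihood is kept. The per-sample state sequence is the
#' Viterbi (hard) assignment, and states whose fractional occupancy falls
#' below `prune_tol` are pruned.
#'
#' Channels are standardized to zero mean and unit variance before
#' fitting.
#'
#' @param x a [recording()] (its LFP channels are used) or a numeric
#'   channels x samples matrix; intended for data downsampled to ~256 Hz.
#' @param fs sampling rate in Hz (taken from the recording if given).
#' @param n_states_max number of states to start from (default 30; unused
#'   states are pruned).
#' @param ar_order AR model order (default 3).
#' @param seed integer seed (controls initialization restarts).
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param n_restarts randomized restarts beyond the k-means start.
#' @param prune_tol occupancy below which a state is pruned.
#' @return object of class `state_model`: `state_sequence` (per-sample
#'   most-probable state for samples `ar_order + 1 .. T`), `offset`
#'   (= `ar_order`), `fractional_occupancy`, `transition`, `A` (per-state
#'   AR coefficient matrices), `Sigma`, `loglik_trace`, `converged`,
#'   `n_states`, `fs`.
#' @export
fit_state_model <- function(x, fs = NULL, n_states_max = 30, ar_order = 3,
                            seed = 1L, max_iter = 100, tol = 1e-6,
                            n_restarts = 2, prune_tol = 1e-6) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    X <- t(x$signals[x$kinds == "lfp", , drop = FALSE])
  } else {
    X <- t(as.matrix(x))
    fail_if(is.null(fs), "fs required when x is a matrix")
  }
  Tn <- nrow(X)
  fail_if(Tn / fs < 5, "need at least a few seconds of data")
  X <- scale(X)                       # unit-variance channels
  p <- as.integer(ar_order)
  K <- as.integer(n_states_max)
  Y <- X[(p + 1):Tn, , drop = FALSE]
  Z <- ar_design(X, p)
  Tm <- nrow(Y)

  run_em <- function(gamma0) {
    trans <- matrix(0.1 / max(K - 1, 1), K, K); diag(trans) <- 0.9
    if (K == 1) trans <- matrix(1, 1, 1)
    pi0 <- rep(1 / K, K)
    gamma <- gamma0
    ll_trace <- numeric(0)
    converged <- FALSE
    fit <- NULL
    for (it in seq_len(max_iter)) {
      fit <- lapply(seq_len(K), function(k)
        weighted_ar_fit(Y, Z, gamma[, k] + 1e-10))
      A <- lapply(fit, `[[`, "A")
      Sigma <- lapply(fit, `[[`, "Sigma")
      logB <- ar_log_emissions(Y, Z, A, Sigma)
      fb <- forward_backward(logB, trans, pi0)
      gamma <- fb$gamma
      trans <- fb$xi_sum / pmax(rowSums(fb$xi_sum), 1e-300)
      pi0 <- gamma[1, ]
      pi0 <- pi0 / sum(pi0)
      ll_trace <- c(ll_trace, fb$loglik)
      if (it > 1 &&
          abs(ll_trace[it] - ll_trace[it - 1]) <
            tol * abs(ll_trace[it - 1])) {
        converged <- TRUE
        break
      }
    }
    list(A = lapply(fit, `[[`, "A"), Sigma = lapply(fit, `[[`, "Sigma"),
         trans = trans, pi0 = pi0, loglik = ll_trace[length(ll_trace)],
         loglik_trace = ll_trace, converged = converged)
  }

  best <- with_seed(seed, {
    inits <- list()
    # k-means on window features, expanded to per-sample responsibilities
    wf <- init_window_features(X, fs)
    km_centers <- min(K, nrow(wf$feats))
    km <- tryCatch(stats::kmeans(scale(wf$feats), centers = km_centers,
                                 nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km)) {
      lab <- integer(Tn)
      for (i in seq_along(wf$starts)) {
        lab[wf$starts[i]:(wf$starts[i] + wf$win - 1)] <- km$cluster[i]
      }
      lab[lab == 0] <- km$cluster[length(km$cluster)]
      g <- matrix(0.05 / max(K - 1, 1), Tm, K)
      g[cbind(seq_len(Tm), lab[(p + 1):Tn])] <- 0.95
      inits[[length(inits) + 1]] <- g / rowSums(g)
    }
    for (r in seq_len(n_restarts)) {
      g <- matrix(stats::rexp(Tm * K), Tm, K)
      inits[[length(inits) + 1]] <- g / rowSums(g)
    }
    fits <- lapply(inits, run_em)
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  })
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning the best model")
  }

  logB <- ar_log_emissions(Y, Z, best$A, best$Sigma)
  path <- viterbi_path(logB, best$trans, best$pi0)
  occ <- tabulate(path, nbins = K) / Tm

  keep <- which(occ >= prune_tol)
  relabel <- match(seq_len(K), keep)
  path <- relabel[path]
  structure(list(
    state_sequence = path, offset = p,
    fractional_occupancy = occ[keep] / sum(occ[keep]),
    transition = best$trans[keep, keep, drop = FALSE] /
      rowSums(best$trans[keep, keep, drop = FALSE]),
    A = best$A[keep], Sigma = best$Sigma[keep],
    loglik_trace = best$loglik_trace, converged = best$converged,
    n_states = length(keep), ar_order = p, fs = fs
  ), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %d state(s), AR order %d, %d decoded samples\n",
              x$n_states, x$ar_order, length(x$state_sequence)))
  cat("  occupancy:",
      paste(sprintf("%.3f", x$fractional_occupancy), collapse = " "), "\n")
  invisible(x)
}

#' Gait-phase occupancy histogram per hidden state
#'
#' Quantifies the occurrence rate of each state at different gait phases:
#' for every state, the phases of the samples assigned to it are binned
#' into `n_bins` equal bins over `[-pi, pi)` and normalized to a
#' probability vector. Under no phase preference every bin expects
#' `1 / n_bins` (1% with the default 100 bins).
#'
#' @param model a [fit_state_model()] result.
#' @param phase a [phase_series()] on the time base of the data the model
#'   was fitted to (the first `ar_order` samples carry no state).
#' @param n_bins number of phase bins (default 100).
#' @return object of class `occupancy_histograms`: `prob` (states x bins),
#'   `counts`, `samples` (list of per-state phase values), `bin_centers`,
#'   `uniform` (= `1 / n_bins`).
#' @export
occupancy_histograms <- function(model, phase, n_bins = 100) {
  seq_len_t <- length(model$state_sequence)
  fail_if(length(phase$phase) != seq_len_t + model$offset,
          "phase series (%d) does not match the model time base (%d + %d)",
          length(phase$phase), seq_len_t, model$offset)
  ph <- phase$phase[(model$offset + 1):length(phase$phase)]
  ok <- phase$valid[(model$offset + 1):length(phase$phase)]
  fail_if(!any(ok), "no valid phase samples")
  st <- model$state_sequence[ok]
  ph <- ph[ok]
  K <- model$n_states
  prob <- matrix(0, K, n_bins)
  counts <- matrix(0L, K, n_bins)
  samples <- vector("list", K)
  for (k in seq_len(K)) {
    pk <- ph[st == k]
    samples[[k]] <- pk
    cnt <- tabulate(phase_bin_index(pk, n_bins), nbins = n_bins)
    counts[k, ] <- cnt
    prob[k, ] <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, n_bins)
  }
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  structure(list(prob = prob, counts = counts, samples = samples,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 n_bins = n_bins, uniform = 1 / n_bins),
            class = "occupancy_histograms")
}

#' K-medoids clustering of occupancy histograms
#'
#' Clusters per-state phase-occupancy histograms into `k` groups by
#' K-medoids (PAM, Euclidean distance on the histogram vectors). PAM's
#' BUILD + SWAP algorithm is deterministic, so the `seed` argument exists
#' for interface stability only; medoids are members of the input set.
#'
#' @param hists an [occupancy_histograms()] object or a states x bins
#'   matrix of probabilities.
#' @param k number of clusters (default 3).
#' @param seed unused (PAM is deterministic); kept for call-site symmetry
#'   with the stochastic fitters.
#' @return object of class `histogram_clustering`: `labels` (per state),
#'   `medoids` (row indices of medoid states), `k`, `metric`.
#' @export
cluster_histograms <- function(hists, k = 3, seed = 1L) {
  H <- if (inherits(hists, "occupancy_histograms")) hists$prob
       else as.matrix(hists)
  fail_if(nrow(H) < k, "need at least k = %d histograms, got %d",
          k, nrow(H))
  if (nrow(H) == k) {               # trivial: each histogram its own cluster
    return(structure(list(labels = seq_len(k), medoids = seq_len(k),
                          k = as.integer(k), metric = "euclidean"),
                     class = "histogram_clustering"))
  }
  pam_fit <- cluster::pam(H, k = k, metric = "euclidean")
  structure(list(labels = as.integer(pam_fit$clustering),
                 medoids = as.integer(pam_fit$id.med),
                 k = as.integer(k), metric = "euclidean"),
            class = "histogram_clustering")
}

#' Kolmogorov-Smirnov test of phase-occupancy uniformity
#'
#' One-sample KS test of the raw phase values observed while a state was
#' active against the uniform distribution on `[-pi, pi)`.
#'
#' @param hists an [occupancy_histograms()] object.
#' @param state state index.
#' @return list with `p` (KS p-value), `statistic`, `n` (samples behind
#'   the histogram), and `reliable` (`FALSE` with a warning when `n < 10`).
#' @export
ks_uniformity <- function(hists, state) {
  smp <- hists$samples[[state]]
  n <- length(smp)
  reliable <- n >= 10
  if (!reliable) warning(sprintf("only %d samples for state %d", n, state))
  kt <- suppressWarnings(stats::ks.test(smp, stats::punif,
                                        min = -pi, max = pi))
  list(p = kt$p.value, statistic = unname(kt$statistic), n = n,
       reliable = reliable)
}

# --- simulation utilities for validating the state analysis ----------------

#' Simulate a Markov-switching AR process
#'
#' Generates multichannel data from a hidden Markov chain whose states emit
#' univariate-per-channel AR processes with the given coefficient sets, the
#' ground truth for validating [fit_state_model()].
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param coefs list (one entry per state) of AR coefficient vectors (all
#'   the same order), applied to every channel.
#' @param noise_sd per-state innovation SDs (recycled).
#' @param dwell_s expected state dwell time in seconds.
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @return list with `x` (channels x samples matrix), `states`
#'   (per-sample true state), `fs`.
#' @export
simulate_ar_switching <- function(n_samples, fs, coefs,
                                  noise_sd = 1, dwell_s = 0.5,
                                  n_channels = 1, seed = 1L) {
  K <- length(coefs)
  p <- length(coefs[[1]])
  noise_sd <- rep_len(noise_sd, K)
  stay <- 1 - 1 / (dwell_s * fs)
  with_seed(seed, {
    states <- integer(n_samples)
    states[1] <- sample.int(K, 1)
    for (t in 2:n_samples) {
      states[t] <- if (stats::runif(1) < stay) states[t - 1]
                   else sample.int(K, 1)
    }
    x <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels)) {
      v <- numeric(n_samples)
      for (t in seq_len(n_samples)) {
        k <- states[t]
        ar <- 0
        for (l in seq_len(min(p, t - 1))) {
          ar <- ar + coefs[[k]][l] * v[t - l]
        }
        v[t] <- ar + stats::rnorm(1, sd = noise_sd[k])
      }
      x[ch, ] <- v
    }
    list(x = x, states = states, fs = fs)
  })
}

#' Decoded-state accuracy after optimal label matching
#'
#' Fraction of samples on which a decoded state sequence agrees with the
#' ground truth, maximized over all assignments of decoded labels to true
#' labels (greedy over all permutations for small state counts).
#'
#' @param decoded integer vector of decoded states.
#' @param truth integer vector of true states (same length).
#' @return accuracy in `[0, 1]`.
#' @export
state_match_accuracy <- function(decoded, truth) {
  fail_if(length(decoded) != length(truth), "length mismatch")
  ks <- sort(unique(decoded))
  kt <- sort(unique(truth))
  fail_if(length(ks) > 8, "too many states for exhaustive matching")
  perms <- all_permutations(max(length(ks), length(kt)))
  best <- 0
  for (r in seq_len(nrow(perms))) {
    mapped <- kt[perms[r, match(decoded, ks)]]
    best <- max(best, mean(mapped == truth, na.rm = TRUE))
  }
  best
}
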