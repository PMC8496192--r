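# Permutation statistics: within-cycle phase shuffling with cluster-based
# correction, condition contrasts with sign-flip permutation, and the exact
# small-sample Wilcoxon / Spearman tests.

#' Shuffle gait phase within each cycle
#'
#' For every gait cycle the phase-sample sequence is split at a random
#' point and the two segments are swapped (a circular rotation by a random
#' per-cycle offset). The multiset of phase values within each cycle is
#' preserved, as is everything outside the cycles, but the phase-to-time
#' (and hence phase-to-power) alignment is destroyed. This is the null
#' operation behind the modulogram permutation test.
#'
#' Uses the current RNG state; seed the RNG (or use
#' [cluster_perm_modulogram()]) for reproducibility.
#'
#' @param phase a [phase_series()].
#' @param cycles the matching `gait_cycle_table`.
#' @return a new [phase_series()] with within-cycle rotated phase values.
#' @export
shuffle_phase_within_cycles <- function(phase, cycles) {
  out <- phase$phase
  for (r in seq_len(nrow(cycles))) {
    idx <- seq(cycles$lift_sample[r], cycles$next_lift_sample[r] - 1L)
    len <- length(idx)
    if (len < 2) next
    k <- sample.int(len, 1L) - 1L     # rotate left by k (k = 0 allowed)
    if (k > 0) out[idx] <- out[idx][c((k + 1):len, 1:k)]
  }
  phase_series(out, phase$valid, phase$fs, phase$strike_observable)
}

# --- fast within-cycle rotation engine -------------------------------------

# Precompute, per usable cycle, the cumulative power sums over the cycle's
# samples and the run boundaries of each phase bin, so a rotated-bin
# modulogram costs O(n_bins) column operations per cycle.
build_rotation_engine <- function(power, phase, cycles, n_bins, usable_mask) {
  eng <- list()
  for (r in seq_len(nrow(cycles))) {
    idx <- seq(cycles$lift_sample[r], cycles$next_lift_sample[r] - 1L)
    if (!all(usable_mask[idx])) next
    bins <- phase_bin_index(phase[idx], n_bins)
    # within a cycle the phase sweeps -pi -> pi, so bins form monotone runs
    lo <- hi <- integer(n_bins)
    for (b in seq_len(n_bins)) {
      w <- which(bins == b)
      if (length(w) == 0) { lo[b] <- 0L; next }
      lo[b] <- w[1]; hi[b] <- w[length(w)]
    }
    C <- cbind(0, t(apply(power[, idx, drop = FALSE], 1, cumsum)))
    eng[[length(eng) + 1]] <- list(C = C, lo = lo, hi = hi,
                                   len = length(idx))
  }
  eng
}

# Per-bin power sums and sample counts for one engine cycle under a given
# left-rotation offset of the bin labels.
rotated_cycle_sums <- function(cyc, offset, n_bins, nf) {
  sums <- matrix(0, nf, n_bins)
  counts <- integer(n_bins)
  L <- cyc$len
  for (b in seq_len(n_bins)) {
    if (cyc$lo[b] == 0L) next
    a <- ((cyc$lo[b] - 1 - offset) %% L) + 1L
    z <- ((cyc$hi[b] - 1 - offset) %% L) + 1L
    if (a <= z) {
      sums[, b] <- cyc$C[, z + 1] - cyc$C[, a]
      counts[b] <- z - a + 1L
    } else {                                  # wrapped range
      sums[, b] <- (cyc$C[, L + 1] - cyc$C[, a]) + cyc$C[, z + 1]
      counts[b] <- (L - a + 1L) + z
    }
  }
  list(sums = sums, counts = counts)
}

# Raw per-bin mean power across all engine cycles for one permutation
# (offset vector, one entry per cycle; zero offsets give the observed map).
engine_bin_means <- function(eng, offsets, n_bins, nf) {
  total <- matrix(0, nf, n_bins)
  counts <- integer(n_bins)
  for (i in seq_along(eng)) {
    rc <- rotated_cycle_sums(eng[[i]], offsets[i], n_bins, nf)
    total <- total + rc$sums
    counts <- counts + rc$counts
  }
  fail_if(any(counts == 0), "empty phase bin(s): %s",
          paste(which(counts == 0), collapse = ", "))
  sweep(total, 2, counts, "/")
}

# --- cluster utilities -----------------------------------------------------

# Label same-sign suprathreshold cells into 4-connected clusters on a
# frequency x bin grid; the bin dimension is circular when circular = TRUE.
# Returns a list of integer cell-index vectors (column-major indices).
find_clusters <- function(supra, sign_map, circular = TRUE) {
  nf <- nrow(supra); nb <- ncol(supra)
  lab <- matrix(0L, nf, nb)
  clusters <- list()
  nid <- 0L
  for (j in seq_len(nb)) for (i in seq_len(nf)) {
    if (!supra[i, j] || lab[i, j] != 0L) next
    nid <- nid + 1L
    queue <- (j - 1L) * nf + i
    lab[i, j] <- nid
    members <- queue
    while (length(queue) > 0) {
      cell <- queue[length(queue)]; queue <- queue[-length(queue)]
      ci <- ((cell - 1L) %% nf) + 1L
      cj <- ((cell - 1L) %/% nf) + 1L
      s <- sign_map[ci, cj]
      for (d in 1:4) {
        ni <- ci + c(-1L, 1L, 0L, 0L)[d]
        nj <- cj + c(0L, 0L, -1L, 1L)[d]
        if (circular) {
          if (nj == 0L) nj <- nb else if (nj > nb) nj <- 1L
        }
        if (ni < 1L || ni > nf || nj < 1L || nj > nb) next
        if (!supra[ni, nj] || lab[ni, nj] != 0L) next
        if (sign_map[ni, nj] != s) next
        lab[ni, nj] <- nid
        ncell <- (nj - 1L) * nf + ni
        queue <- c(queue, ncell)
        members <- c(members, ncell)
      }
    }
    clusters[[nid]] <- sort(members)
  }
  clusters
}

# Largest same-sign cluster mass (sum of |z|) of a z map under a
# suprathreshold mask; 0 when no cell is suprathreshold.
max_cluster_mass <- function(z, supra, circular = TRUE) {
  if (!any(supra)) return(0)
  cl <- find_clusters(supra, sign(z), circular)
  max(vapply(cl, function(cells) sum(abs(z[cells])), numeric(1)))
}

# Cell-wise suprathreshold mask. Gaussian mode thresholds |z| at the normal
# two-sided alpha quantile; empirical mode thresholds each cell at the
# (1 - alpha) quantile of its own permuted |z| values.
supra_mask <- function(z_abs, alpha, mode, thr_cell = NULL) {
  if (mode == "gaussian") {
    z_abs > stats::qnorm(1 - alpha / 2)
  } else {
    z_abs > thr_cell
  }
}

# --- modulogram permutation test -------------------------------------------

#' Cluster-based permutation test of the gait-phase modulogram
#'
#' Tests, per frequency x phase-bin cell, whether power deviates from what
#' within-cycle phase shuffling would produce. The observed percent
#' modulogram and every permutation sample are z-scored cell-wise against
#' the permutation mean and SD; suprathreshold cells (two-sided,
#' `p < alpha`) of equal sign are joined by 4-connectivity (the phase-bin
#' dimension is circular) and each observed cluster's mass (sum of |z|) is
#' compared against the permutation distribution of the largest cluster
#' masses.
#'
#' Cell-wise thresholds come from the Gaussian tail when
#' `p_mode = "gaussian"` or when fewer than 500 permutations are available
#' under `"auto"`; `"empirical"` uses each cell's own permuted |z|
#' quantile.
#'
#' Only gait cycles that lie wholly inside the valid region (valid phase
#' and edge-clean wavelet coefficients at every frequency) contribute.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param phase a [phase_series()] on the same time base.
#' @param cycles the matching `gait_cycle_table`.
#' @param n_bins number of phase bins (default 18).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha precluster and cluster significance level.
#' @param seed integer seed; same seed and inputs give identical results.
#' @param channel tfr channel.
#' @param p_mode `"auto"`, `"empirical"`, or `"gaussian"` (see above).
#' @return object of class `permutation_result`: `observed` (percent
#'   modulogram), `z_map`, `clusters` (list of `cells`, `mass`,
#'   `p_value`), `null_masses`, `n_perm`, `seed`, `freqs`, `bin_centers`,
#'   plus the observed `mi` and its permutation z-score `mi_z`.
#' @export
cluster_perm_modulogram <- function(tfr, phase, cycles, n_bins = 18,
                                    n_perm = 1000, alpha = 0.05, seed = 1L,
                                    channel = 1,
                                    p_mode = c("auto", "empirical",
                                               "gaussian")) {
  p_mode <- match.arg(p_mode)
  fail_if(n_perm < 100, "n_perm must be >= 100")
  fail_if(length(phase$phase) != tfr$n_time,
          "tfr and phase time bases differ")
  mode <- if (p_mode == "auto") {
    if (n_perm >= 500) "empirical" else "gaussian"
  } else p_mode

  usable <- phase$valid & tfr_all_valid(tfr)
  power <- tfr_power(tfr, channel)
  nf <- length(tfr$freqs)
  eng <- build_rotation_engine(power, phase$phase, cycles, n_bins, usable)
  fail_if(length(eng) < 2, "fewer than two usable gait cycles")

  obs_raw <- engine_bin_means(eng, rep(0L, length(eng)), n_bins, nf)
  obs <- new_modulogram(obs_raw, tfr$freqs, n_bins)
  obs_map <- obs$mean_norm
  obs_mi <- modulation_index(obs)$mi

  with_seed(seed, {
    perm_maps <- array(0, c(n_perm, nf, n_bins))
    perm_mi <- matrix(0, n_perm, nf)
    lens <- vapply(eng, function(e) e$len, integer(1))
    for (r in seq_len(n_perm)) {
      offsets <- vapply(lens, function(L) sample.int(L, 1L) - 1L,
                        integer(1))
      raw <- engine_bin_means(eng, offsets, n_bins, nf)
      m <- new_modulogram(raw, tfr$freqs, n_bins)
      perm_maps[r, , ] <- m$mean_norm
      perm_mi[r, ] <- modulation_index(m)$mi
    }
  })

  mu <- apply(perm_maps, c(2, 3), mean)
  sdv <- apply(perm_maps, c(2, 3), stats::sd)
  sdv[sdv == 0] <- Inf
  z_obs <- (obs_map - mu) / sdv

  thr_cell <- NULL
  z_perm_abs <- NULL
  z_perm <- sweep(sweep(perm_maps, c(2, 3), mu), c(2, 3), sdv, "/")
  if (mode == "empirical") {
    thr_cell <- apply(abs(z_perm), c(2, 3), stats::quantile,
                      probs = 1 - alpha, type = 1)
  }

  supra_obs <- supra_mask(abs(z_obs), alpha, mode, thr_cell)
  clusters <- list()
  if (any(supra_obs)) {
    cells <- find_clusters(supra_obs, sign(z_obs), circular = TRUE)
    clusters <- lapply(cells, function(cc) {
      list(cells = cc, mass = sum(abs(z_obs[cc])), p_value = NA_real_)
    })
  }

  null_masses <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    zr <- z_perm[r, , ]
    null_masses[r] <- max_cluster_mass(zr,
                                       supra_mask(abs(zr), alpha, mode,
                                                  thr_cell),
                                       circular = TRUE)
  }
  for (k in seq_along(clusters)) {
    clusters[[k]]$p_value <-
      (1 + sum(null_masses >= clusters[[k]]$mass)) / (n_perm + 1)
  }

  mi_mu <- colMeans(perm_mi)
  mi_sd <- apply(perm_mi, 2, stats::sd)
  mi_sd[mi_sd == 0] <- Inf

  structure(list(observed = obs_map, z_map = z_obs, clusters = clusters,
                 null_masses = null_masses, n_perm = n_perm, seed = seed,
                 alpha = alpha, mode = mode, freqs = tfr$freqs,
                 bin_centers = obs$bin_centers,
                 mi = obs_mi, mi_z = (obs_mi - mi_mu) / mi_sd,
                 n_cycles_used = length(eng)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  sig <- sum(vapply(x$clusters, function(cl) cl$p_value < x$alpha,
                    logical(1)))
  cat(sprintf("<permutation_result> %d perms, %d cluster(s), %d significant at alpha=%g\n",
              x$n_perm, length(x$clusters), sig, x$alpha))
  invisible(x)
}

#' Smallest cluster p-value of a permutation result
#' @param res a `permutation_result`.
#' @return smallest cluster p, or `1` when no cluster formed.
#' @export
min_cluster_p <- function(res) {
  if (length(res$clusters) == 0) return(1)
  min(vapply(res$clusters, function(cl) cl$p_value, numeric(1)))
}

# --- condition contrast permutation test -----------------------------------

#' Cluster-based permutation test of a paired condition contrast
#'
#' Compares two conditions measured on the same hemispheres (e.g. percent
#' PSD or imaginary coherence spectra, rest vs stepping). The statistic per
#' frequency is the mean paired difference (or the paired t value); the
#' null is built by independently flipping the sign of each hemisphere's
#' difference (equivalently, permuting the condition labels so the order of
#' subtraction changes per hemisphere). Suprathreshold cells of equal sign
#' are joined along contiguous frequencies and cluster masses are tested
#' against the permutation maximum-mass distribution.
#'
#' @param samples_a,samples_b numeric matrices, hemispheres x frequency,
#'   paired by row.
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param statistic `"mean_diff"` or `"paired_t"`.
#' @param freqs optional frequency grid for reporting.
#' @param p_mode as in [cluster_perm_modulogram()].
#' @return a `permutation_result` (1-D: clusters are frequency runs).
#' @export
cluster_perm_conditions <- function(samples_a, samples_b, n_perm = 1000,
                                    alpha = 0.05, seed = 1L,
                                    statistic = c("mean_diff", "paired_t"),
                                    freqs = NULL,
                                    p_mode = c("auto", "empirical",
                                               "gaussian")) {
  statistic <- match.arg(statistic)
  p_mode <- match.arg(p_mode)
  samples_a <- as.matrix(samples_a); samples_b <- as.matrix(samples_b)
  fail_if(!all(dim(samples_a) == dim(samples_b)),
          "unpaired inputs: condition matrices must share hemispheres x frequencies")
  n_h <- nrow(samples_a); nf <- ncol(samples_a)
  fail_if(n_h < 2, "need at least two hemispheres")
  if (is.null(freqs)) freqs <- seq_len(nf)
  mode <- if (p_mode == "auto") {
    if (n_perm >= 500) "empirical" else "gaussian"
  } else p_mode

  d <- samples_a - samples_b
  stat_fun <- if (statistic == "mean_diff") {
    function(dd) colMeans(dd)
  } else {
    function(dd) {
      m <- colMeans(dd)
      se <- apply(dd, 2, stats::sd) / sqrt(nrow(dd))
      ifelse(se == 0, 0, m / se)
    }
  }
  obs <- stat_fun(d)

  with_seed(seed, {
    perm_stats <- matrix(0, n_perm, nf)
    for (r in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), n_h, replace = TRUE)
      perm_stats[r, ] <- stat_fun(d * signs)
    }
  })

  mu <- colMeans(perm_stats)
  sdv <- apply(perm_stats, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  z_obs <- (obs - mu) / sdv
  z_perm <- sweep(sweep(perm_stats, 2, mu), 2, sdv, "/")

  thr_cell <- NULL
  if (mode == "empirical") {
    thr_cell <- apply(abs(z_perm), 2, stats::quantile, probs = 1 - alpha,
                      type = 1)
  }
  as_row <- function(v) matrix(v, nrow = 1)
  supra_obs <- supra_mask(abs(as_row(z_obs)), alpha, mode,
                          if (is.null(thr_cell)) NULL else as_row(thr_cell))
  clusters <- list()
  if (any(supra_obs)) {
    cells <- find_clusters(supra_obs, sign(as_row(z_obs)),
                           circular = FALSE)
    clusters <- lapply(cells, function(cc) {
      list(cells = cc, freq_index = cc,   # 1 x nf grid: cell = frequency
           mass = sum(abs(z_obs[cc])), p_value = NA_real_)
    })
  }
  null_masses <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    zr <- as_row(z_perm[r, ])
    null_masses[r] <- max_cluster_mass(zr,
                                       supra_mask(abs(zr), alpha, mode,
                                                  if (is.null(thr_cell)) NULL
                                                  else as_row(thr_cell)),
                                       circular = FALSE)
  }
  for (k in seq_along(clusters)) {
    clusters[[k]]$p_value <-
      (1 + sum(null_masses >= clusters[[k]]$mass)) / (n_perm + 1)
  }
  structure(list(observed = obs, z_map = z_obs, clusters = clusters,
                 null_masses = null_masses, n_perm = n_perm, seed = seed,
                 alpha = alpha, mode = mode, freqs = freqs,
                 statistic = statistic),
            class = "permutation_result")
}

# --- exact small-sample tests ----------------------------------------------

# Exact null distribution of the positive rank sum: counts over the grid of
# doubled rank sums (doubling keeps midranks integral).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)          # f[s + 1] = #assignments with sum s
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact p-value for paired samples by evaluating the full
#' distribution of the positive rank sum over all `2^n` sign assignments
#' (computed via the generating-function convolution, which enumerates the
#' same distribution). Zero differences are dropped before ranking; ties
#' among `|differences|` receive midranks. The reported `W` is the larger
#' of the positive and negative rank sums.
#'
#' @param x,y paired numeric vectors, `2 <= n <= 25` non-zero differences.
#' @return list with `W` (larger rank sum), `p` (exact two-sided),
#'   `W_plus`, `n` (pairs used).
#' @examples
#' wilcoxon_exact(c(5, 6, 7, 8, 9, 10, 11, 12), c(1, 2, 3, 4, 5, 6, 7, 8))
#' @export
wilcoxon_exact <- function(x, y) {
  fail_if(length(x) != length(y), "x and y must be paired")
  d <- x - y
  d <- d[d != 0]
  fail_if(length(d) == 0, "all differences are zero")
  n <- length(d)
  fail_if(n < 2 || n > 25, "need 2 to 25 non-zero differences, got %d", n)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  r2 <- round(2 * r)
  f <- signed_rank_null(r2)
  tot <- 2^n
  w2 <- round(2 * w_plus)
  p_ge <- sum(f[(w2 + 1):length(f)]) / tot
  p_le <- sum(f[1:(w2 + 1)]) / tot
  p <- min(1, 2 * min(p_ge, p_le))
  list(W = max(w_plus, w_minus), p = p, W_plus = w_plus, n = n)
}

# All permutations of 1..n as an (n!) x n matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    remap <- c(seq_len(n)[-k])
    out[rows, -1] <- matrix(remap[sub], nrow(sub))
  }
  out
}

#' Exact Spearman rank-correlation test
#'
#' Spearman's rho on (mid)ranks with an exact two-sided permutation
#' p-value: the fraction of all `n!` rank permutations whose |rho| reaches
#' the observed |rho|. For untied data rho equals
#' `1 - 6 * sum(d^2) / (n * (n^2 - 1))`. Outside `3 <= n <= 9` the exact
#' enumeration is infeasible and the function falls back to the asymptotic
#' [stats::cor.test()] p-value with a warning and `method = "asymptotic"`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p` (two-sided), `n`, and `method`
#'   (`"exact"` or `"asymptotic"`).
#' @examples
#' spearman_exact(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_exact <- function(x, y) {
  fail_if(length(x) != length(y), "x and y must have equal length")
  n <- length(x)
  if (n < 3 || n > 9) {
    warning(sprintf(
      "n = %d outside the exact range 3..9; falling back to the asymptotic Spearman test",
      n))
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    return(list(rho = unname(ct$estimate), p = ct$p.value, n = n,
                method = "asymptotic"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perms <- all_permutations(n)
  ry_perm <- matrix(ry[perms], nrow(perms))
  num <- ry_perm %*% rx - n * mean(rx) * mean(ry)
  den <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_perm <- as.numeric(num / den)
  p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  list(rho = rho, p = p, n = n, method = "exact")
}
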