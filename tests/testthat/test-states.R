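ar2_slow <- c(1.6, -0.81)   # resonant, slow dynamics
ar2_fast <- c(-0.5, -0.4)   # fast, alternating dynamics

test_that("EM recovers a 2-regime AR switching process", {
  sim <- simulate_ar_switching(15360, fs = 256,
                               coefs = list(ar2_slow, ar2_fast),
                               dwell_s = 0.5, n_channels = 1, seed = 1)
  model <- fit_state_model(sim$x, fs = 256, n_states_max = 2,
                           ar_order = 2, seed = 1)
  truth <- sim$states[(model$offset + 1):length(sim$states)]
  acc <- state_match_accuracy(model$state_sequence, truth)
  expect_gt(acc, 0.85)
  expect_equal(sum(model$fractional_occupancy), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(model$transition) - 1) < 1e-9))
})

test_that("EM log-likelihood never decreases", {
  sim <- simulate_ar_switching(6000, fs = 256,
                               coefs = list(ar2_slow, ar2_fast),
                               dwell_s = 0.5, seed = 2)
  model <- fit_state_model(sim$x, fs = 256, n_states_max = 3,
                           ar_order = 2, seed = 3)
  ll <- model$loglik_trace
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("single-regime data concentrates occupancy in one state", {
  sim <- simulate_ar_switching(8000, fs = 256, coefs = list(ar2_slow),
                               dwell_s = 1, seed = 4)
  # surplus states may stall EM below tolerance; the best model still wins
  model <- suppressWarnings(
    fit_state_model(sim$x, fs = 256, n_states_max = 3,
                    ar_order = 2, seed = 5))
  expect_gt(max(model$fractional_occupancy), 0.9)
})

test_that("occupancy histograms are probability vectors with the right concentration", {
  fs <- 256
  n <- 8000
  phase <- gaitmod::wrap_angle(2 * pi * seq_len(n) / fs / 2)
  ps <- phase_series(phase, fs = fs)
  # fabricated model: state 2 active only when |phase| > 3*pi/4
  st <- ifelse(abs(phase) > 3 * pi / 4, 2L, 1L)
  model <- structure(list(state_sequence = st[4:n], offset = 3L,
                          n_states = 2L, ar_order = 3L, fs = fs),
                     class = "state_model")
  occ <- occupancy_histograms(model, ps)
  expect_equal(rowSums(occ$prob), c(1, 1), tolerance = 1e-12)
  outer_bins <- abs(occ$bin_centers) > 3 * pi / 4
  expect_gt(sum(occ$prob[2, outer_bins]), 0.95)
  expect_equal(occ$uniform, 0.01)

  # a state occupying all samples with uniform phase coverage ~ 1% per bin
  model1 <- structure(list(state_sequence = rep(1L, n - 3), offset = 3L,
                           n_states = 1L, ar_order = 3L, fs = fs),
                      class = "state_model")
  occ1 <- occupancy_histograms(model1, ps)
  expect_equal(max(abs(occ1$prob[1, ] - 0.01)), 0, tolerance = 0.003)
})

test_that("K-medoids recovers planted histogram families exactly", {
  skip_if_not_installed("mclust")
  set.seed(10)
  centers <- seq(-pi, pi, length.out = 101)
  centers <- (centers[-1] + centers[-101]) / 2
  family <- function(mu, kappa = 2) {
    w <- exp(kappa * cos(centers - mu))
    w / sum(w)
  }
  flat <- rep(1 / 100, 100)
  truth <- rep(1:3, each = 6)
  H <- rbind(
    t(replicate(6, family(0) + abs(rnorm(100, 0, 1e-3)))),
    t(replicate(6, family(pi / 2) + abs(rnorm(100, 0, 1e-3)))),
    t(replicate(6, flat + abs(rnorm(100, 0, 1e-3))))
  )
  H <- H / rowSums(H)
  cl <- cluster_histograms(H, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_true(all(cl$medoids %in% seq_len(nrow(H))))

  # k = number of histograms -> every histogram its own cluster
  small <- H[c(1, 7, 13), ]
  cl_all <- cluster_histograms(small, k = 3)
  expect_equal(sort(unique(cl_all$labels)), 1:3)
  expect_equal(length(unique(cl_all$labels)), 3)

  # duplicated histograms co-cluster
  dup <- rbind(H[1:2, ], H[1:2, ], H[7:8, ], H[13:14, ])
  cl_dup <- cluster_histograms(dup, k = 3)
  expect_equal(cl_dup$labels[1:2], cl_dup$labels[3:4])

  expect_error(cluster_histograms(H[1:2, ], k = 3), "at least k")
})

test_that("phase-gated AR regimes reproduce complementary occupancy clusters", {
  # two AR regimes gated by gait-phase half-planes: regime 1 near strike/lift
  # (|phase| > 3pi/4 or |phase| < pi/4), regime 2 near mid-swing/mid-stance
  fs <- 256
  n <- 20480
  phase <- gaitmod::wrap_angle(2 * pi * seq_len(n) / fs / 2)
  gate <- abs(phase) > 3 * pi / 4 | abs(phase) < pi / 4
  with_seed <- gaitmod:::with_seed
  x <- with_seed(11, {
    v <- numeric(n)
    for (t in 3:n) {
      cf <- if (gate[t]) ar2_slow else ar2_fast
      v[t] <- cf[1] * v[t - 1] + cf[2] * v[t - 2] + rnorm(1)
    }
    v
  })
  model <- fit_state_model(matrix(x, 1), fs = fs, n_states_max = 2,
                           ar_order = 2, seed = 12)
  occ <- occupancy_histograms(model, phase_series(phase, fs = fs))
  # the state preferring strike/lift phases should dominate those bins
  anchor_bins <- abs(occ$bin_centers) > 3 * pi / 4 |
    abs(occ$bin_centers) < pi / 4
  pref_anchor <- which.max(occ$prob %*% anchor_bins)
  other <- 3 - pref_anchor
  expect_gt(sum(occ$prob[pref_anchor, anchor_bins]), 0.7)
  expect_gt(sum(occ$prob[other, !anchor_bins]), 0.7)
})

test_that("KS uniformity test behaves at both extremes", {
  set.seed(13)
  hists <- list(samples = list(runif(1e4, -pi, pi), rep(0, 200),
                               runif(5, -pi, pi)))
  u <- ks_uniformity(hists, 1)
  expect_gt(u$p, 0.05)
  expect_true(u$p <= 1)
  z <- ks_uniformity(hists, 2)
  expect_lt(z$p, 1e-6)
  expect_warning(s <- ks_uniformity(hists, 3), "samples")
  expect_false(s$reliable)
})

test_that("uniform phase samples rarely reject uniformity", {
  set.seed(14)
  ps <- replicate(100, {
    hs <- list(samples = list(runif(1e3, -pi, pi)))
    ks_uniformity(hs, 1)$p
  })
  expect_gte(mean(ps > 0.05), 0.9)
})
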