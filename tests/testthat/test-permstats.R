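test_that("within-cycle shuffling rotates and conserves each cycle's phase multiset", {
  fs <- 10
  phase <- gaitmod::wrap_angle(2 * pi * seq(0, 59) / 20)  # 2 s cycles
  valid <- rep(TRUE, 60)
  valid[1:3] <- FALSE
  ps <- phase_series(phase, valid, fs)
  cyc <- gaitmod:::gait_cycle_table(c(11, 31), c(21, 41), c(31, 51), fs)
  set.seed(42)
  sh <- shuffle_phase_within_cycles(ps, cyc)
  for (r in 1:2) {
    idx <- seq(cyc$lift_sample[r], cyc$next_lift_sample[r] - 1)
    expect_equal(sort(sh$phase[idx]), sort(phase[idx]))
    # result is a pure rotation of the original cycle
    L <- length(idx)
    rotations <- vapply(0:(L - 1), function(k) {
      isTRUE(all.equal(sh$phase[idx],
                       phase[idx][c((k + 1):L, seq_len(k))[1:L]]))
    }, logical(1))
    expect_true(any(rotations))
  }
  # everything outside the cycles is untouched
  outside <- setdiff(seq_len(60), unlist(lapply(1:2, function(r)
    seq(cyc$lift_sample[r], cyc$next_lift_sample[r] - 1))))
  expect_equal(sh$phase[outside], phase[outside])
  expect_equal(sh$valid, valid)
})

test_that("shuffling destroys the planted phase locking", {
  sess <- quick_session(seed = 31, duration_s = 60, depth = 0.8)
  tfr <- morlet_tfr(sess$recording, freqs = 18:27, channels = "0")
  m0 <- modulation_index(modulogram(tfr, sess$truth_phase))
  f_star <- which.max(m0$mi)
  set.seed(99)
  mi_sh <- replicate(100, {
    ps <- shuffle_phase_within_cycles(sess$truth_phase, sess$truth_cycles)
    modulation_index(modulogram(tfr, ps))$mi[f_star]
  })
  expect_lt(mean(mi_sh), 0.2 * m0$mi[f_star])
})

test_that("modulogram cluster permutation is deterministic and finds planted modulation", {
  sess <- quick_session(seed = 32, duration_s = 60, depth = 0.8,
                        band = c(20, 25))
  pre <- preprocess_recording(sess$recording)
  bip <- make_bipolar(pre, c("0", "1"))
  ph <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                         pre$fs)
  tfr <- morlet_tfr(bip, freqs = 1:95, channels = 1)
  res1 <- cluster_perm_modulogram(tfr, ph$phase, ph$cycles, n_perm = 200,
                                  seed = 5)
  res2 <- cluster_perm_modulogram(tfr, ph$phase, ph$cycles, n_perm = 200,
                                  seed = 5)
  expect_identical(res1$z_map, res2$z_map)
  expect_identical(res1$null_masses, res2$null_masses)
  expect_identical(lapply(res1$clusters, `[[`, "cells"),
                   lapply(res2$clusters, `[[`, "cells"))
  # at least one significant cluster overlapping the planted 20-25 Hz band
  sig <- Filter(function(cl) cl$p_value < 0.05, res1$clusters)
  expect_gt(length(sig), 0)
  freq_rows <- sort(unique(unlist(lapply(sig, function(cl)
    ((cl$cells - 1) %% length(res1$freqs)) + 1))))
  expect_true(any(res1$freqs[freq_rows] >= 20 &
                    res1$freqs[freq_rows] <= 25))
  # p-values live in (0, 1]
  expect_true(all(vapply(res1$clusters, `[[`, numeric(1), "p_value") > 0))
  expect_true(all(vapply(res1$clusters, `[[`, numeric(1), "p_value") <= 1))
})

test_that("condition contrast nulls identical inputs and flags planted offsets", {
  set.seed(7)
  nf <- 40
  a <- matrix(rnorm(8 * nf), 8, nf)
  same <- cluster_perm_conditions(a, a, n_perm = 200, seed = 2)
  expect_equal(length(same$clusters), 0)
  expect_true(all(same$z_map == 0))

  # planted offset in frequencies 12-24 across 8 hemispheres
  b <- a
  b[, 12:24] <- b[, 12:24] - 1.5
  res <- cluster_perm_conditions(a, b, n_perm = 500, seed = 3,
                                 freqs = 1:nf)
  sig <- Filter(function(cl) cl$p_value < 0.05, res$clusters)
  expect_gt(length(sig), 0)
  covered <- sort(unique(unlist(lapply(sig, `[[`, "cells"))))
  expect_true(all(12:24 %in% covered))

  # flipping the roles of the conditions negates the z map
  swapped <- cluster_perm_conditions(b, a, n_perm = 500, seed = 3,
                                     freqs = 1:nf)
  expect_equal(swapped$z_map, -res$z_map, tolerance = 1e-10)
  expect_error(cluster_perm_conditions(a, a[1:4, ]), "unpaired")
})

test_that("exact Wilcoxon reproduces the closed-form references", {
  # n = 8, all differences one sign -> W = 36, p = 2/256
  all_pos <- wilcoxon_exact(c(5, 9, 3, 7, 12, 15, 2, 8),
                            c(4, 7, 1, 6, 10, 11, 1, 5))
  expect_equal(all_pos$W, 36)
  expect_equal(all_pos$p, 2 / 256)
  expect_equal(round(all_pos$p, 4), 0.0078)

  # n = 8, only the rank-3 difference of opposite sign -> W = 33, p = 10/256
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  y <- c(9, 18, 33, 36, 45, 54, 63, 72)   # diffs 1,2,-3,4,5,6,7,8
  r33 <- wilcoxon_exact(x, y)
  expect_equal(r33$W, 33)
  expect_equal(r33$p, 10 / 256)
  expect_equal(round(r33$p, 4), 0.0391)

  # n = 2, both positive -> p = 0.5
  expect_equal(wilcoxon_exact(c(3, 5), c(1, 2))$p, 0.5)

  expect_error(wilcoxon_exact(c(1, 2), c(1, 2)), "zero")
})

test_that("exact Wilcoxon agrees with literal 2^n enumeration on random inputs", {
  set.seed(8)
  for (n in c(5, 7, 9, 10)) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      expect_equal(wilcoxon_exact(x, y)$p, wilcoxon_brute_force(x, y),
                   tolerance = 1e-12)
    }
  }
  # with tied |differences| (midranks)
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 1, 5, 2, 3, 4)     # diffs 1,1,-2,2,2,2
  expect_equal(wilcoxon_exact(x, y)$p, wilcoxon_brute_force(x, y),
               tolerance = 1e-12)
})

test_that("exact Spearman reproduces the closed-form references", {
  # perfectly reversed ranks, n = 8 -> rho = -1, p = 2/40320
  rev8 <- spearman_exact(1:8, 8:1)
  expect_equal(rev8$rho, -1)
  expect_equal(rev8$p, 2 / factorial(8), tolerance = 1e-12)

  # sum d^2 = 156 -> rho = -6/7; exact p rounds to 0.0107
  y156 <- c(5, 8, 7, 6, 4, 3, 2, 1)
  stopifnot(sum((rank(1:8) - rank(y156))^2) == 156)
  r <- spearman_exact(1:8, y156)
  expect_equal(r$rho, -6 / 7, tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0107)
  expect_equal(r$method, "exact")

  # identical order -> rho = 1
  expect_equal(spearman_exact(1:5, c(10, 20, 30, 40, 50))$rho, 1)

  # outside 3..9: flagged fallback
  expect_warning(big <- spearman_exact(1:12, rnorm(12)), "asymptotic")
  expect_equal(big$method, "asymptotic")
})

test_that("exact Spearman p agrees with full enumeration for n = 6", {
  set.seed(9)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(spearman_exact(x, y)$p, spearman_brute_force(x, y),
               tolerance = 1e-12)
})
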