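test_that("bipolar montage differences adjacent contacts with k-(k+1) labels", {
  fs <- 100
  n <- 500
  set.seed(1)
  base <- matrix(rnorm(4 * n), 4, n)
  rec <- recording(base, fs, labels = c("0", "1", "2", "3"),
                   kinds = rep("lfp", 4))
  bip <- make_bipolar(rec, c("0", "1", "2", "3"))
  expect_equal(bip$labels, c("0-1", "1-2", "2-3"))
  expect_equal(nrow(bip$signals), 3)
  expect_equal(bip$signals[1, ], base[1, ] - base[2, ],
               ignore_attr = TRUE)
  expect_error(make_bipolar(rec, c("0", "9")), "9")

  # identical signal on every contact -> all bipolar channels zero
  same <- recording(matrix(rep(base[1, ], 3), 3, byrow = TRUE), fs,
                    c("a", "b", "c"), rep("lfp", 3))
  expect_true(all(make_bipolar(same, c("a", "b", "c"))$signals == 0))

  # two contacts with b = -a -> bipolar channel = 2a
  two <- recording(rbind(base[1, ], -base[1, ]), fs, c("a", "b"),
                   rep("lfp", 2))
  expect_equal(make_bipolar(two, c("a", "b"))$signals[1, ],
               2 * base[1, ], ignore_attr = TRUE)
})

test_that("adding a common signal to all contacts is a no-op on bipolar outputs", {
  fs <- 100
  set.seed(2)
  base <- matrix(rnorm(3 * 400), 3, 400)
  common <- sin(2 * pi * 7 * seq_len(400) / fs)
  rec0 <- recording(base, fs, c("0", "1", "2"), rep("lfp", 3))
  rec1 <- recording(sweep(base, 2, common, "+"), fs, c("0", "1", "2"),
                    rep("lfp", 3))
  expect_equal(make_bipolar(rec0, c("0", "1", "2"))$signals,
               make_bipolar(rec1, c("0", "1", "2"))$signals,
               tolerance = 1e-12)
})

test_that("line-noise band-stop attenuates a 50 Hz tone by > 40 dB", {
  fs <- 2048
  t <- seq(0, 6, by = 1 / fs)
  rec <- vec_recording(sin(2 * pi * 50 * t), fs = fs)
  out <- apply_filter(rec, filter_spec("bandstop", 8, c(48, 52)))
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  ratio <- sqrt(mean(out$signals[1, mid]^2)) / sqrt(0.5)
  expect_lt(ratio, 0.01)
})

test_that("broadband band-pass removes DC and keeps in-band tones", {
  fs <- 2048
  t <- seq(0, 20, by = 1 / fs)
  rec <- vec_recording(rep(1, length(t)), fs = fs)
  out <- apply_filter(rec, filter_spec("bandpass", 8, c(0.5, 250)))
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  expect_lt(max(abs(out$signals[1, mid])), 0.05)

  tone <- vec_recording(sin(2 * pi * 20 * t), fs = fs)
  keep <- apply_filter(tone, filter_spec("bandpass", 8, c(0.5, 250)))
  expect_equal(sqrt(mean(keep$signals[1, mid]^2)), sqrt(0.5),
               tolerance = 0.01)
})

test_that("zero-phase filtering commutes with time reversal and is linear", {
  fs <- 256
  set.seed(3)
  x <- rnorm(4000)
  y <- rnorm(4000)
  spec <- filter_spec("bandpass", 6, c(0.5, 5))
  filt1 <- function(v) {
    apply_filter(vec_recording(v, fs = fs, kind = "force"), spec)$signals[1, ]
  }
  # reversal contract (away from the padded edges)
  interior <- 500:3500
  expect_equal(filt1(x)[interior], rev(filt1(rev(x)))[interior],
               tolerance = 1e-5)
  # linearity
  expect_equal(filt1(2 * x + 3 * y), 2 * filt1(x) + 3 * filt1(y),
               tolerance = 1e-5)
})

test_that("impulse response of a zero-phase filter is symmetric about the impulse", {
  fs <- 256
  n <- 4096
  imp <- numeric(n); imp[n / 2] <- 1
  out <- apply_filter(vec_recording(imp, fs = fs),
                      filter_spec("bandpass", 8, c(5, 40)))$signals[1, ]
  left <- out[(n / 2 - 1):(n / 2 - 200)]
  right <- out[(n / 2 + 1):(n / 2 + 200)]
  expect_equal(left, right, tolerance = 1e-7)
})

test_that("filter edges outside (0, fs/2) are rejected", {
  rec <- vec_recording(rnorm(1000), fs = 100)
  expect_error(apply_filter(rec, filter_spec("bandpass", 4, c(0.5, 60))),
               "fs/2")
  expect_error(filter_spec("bandpass", 5, c(1, 10)), "even")
  expect_error(filter_spec("bandpass", 4, c(10, 1)), "low")
})

test_that("resampling preserves duration, in-band amplitude, and suppresses aliases", {
  fs <- 2048
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tone10 <- sin(2 * pi * 10 * t)
  tone200 <- sin(2 * pi * 200 * t)
  rec <- vec_recording(tone10, tone200, fs = fs)
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$signals), round(length(t) / 8))    # length contract
  mid <- seq(round(ncol(out$signals) * 0.25), round(ncol(out$signals) * 0.75))
  amp10 <- sqrt(mean(out$signals[1, mid]^2)) / sqrt(0.5)
  expect_gt(amp10, 0.99); expect_lt(amp10, 1.01)
  # 200 Hz lies above the new Nyquist (128 Hz): must not alias in
  amp200 <- sqrt(mean(out$signals[2, mid]^2)) / sqrt(0.5)
  expect_lt(amp200, 0.05)
  expect_error(resample_recording(rec, 4096), "below")
})
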