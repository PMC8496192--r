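test_that("sinusoidal force yields the textbook anchor and interpolation pattern", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  res <- phase_from_force(sin(2 * pi * t / 2), fs)
  at <- function(tt) res$phase$phase[round(tt * fs) + 1]
  # increasing crossings at t = 0, 2, 4, ... -> phase 0
  expect_equal(at(4), 0, tolerance = 0.02)
  expect_equal(at(8), 0, tolerance = 0.02)
  # decreasing crossings at t = 1, 3, ... -> phase +/- pi
  expect_true(abs(abs(at(5)) - pi) < 0.02)
  # quarter-cycle points
  expect_equal(at(4.5), pi / 2, tolerance = 0.02)
  expect_equal(at(5.5), -pi / 2, tolerance = 0.02)
  # cycle table: 2 s cycles, 1 s swing
  expect_equal(median(res$cycles$duration_s), 2, tolerance = 0.02)
  expect_equal(median(res$cycles$lift_duration_s), 1, tolerance = 0.02)
})

test_that("constant force raises a no-cycles error", {
  expect_error(phase_from_force(rep(0.3, 1000), 100), "no gait cycles")
  expect_error(phase_from_force(rep(0, 1000), 100), "no gait cycles")
})

test_that("force phase matches generator truth within 0.1 rad even with jitter", {
  sess <- quick_session(seed = 11, duration_s = 40, jitter = 0.15)
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                          sess$recording$fs)
  ok <- res$phase$valid & sess$truth_phase$valid
  expect_lt(circular_rms(res$phase$phase[ok], sess$truth_phase$phase[ok]),
            0.1)
  expect_equal(nrow(res$cycles), nrow(sess$truth_cycles))
})

test_that("zero-jitter cycle boundaries are recovered within one sample", {
  sess <- quick_session(seed = 12, duration_s = 30, jitter = 0,
                        sensor_noise_sd = 0)
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                          sess$recording$fs)
  truth <- sess$truth_cycles
  det <- res$cycles
  expect_equal(nrow(det), nrow(truth))
  expect_true(all(abs(det$lift_sample - truth$lift_sample) <= 1))
  expect_true(all(abs(det$strike_sample - truth$strike_sample) <= 1))
})

test_that("phase histogram over many cycles is roughly uniform", {
  sess <- quick_session(seed = 13, duration_s = 60, jitter = 0.05)
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                          sess$recording$fs)
  h <- tabulate(gaitmod:::phase_bin_index(
    res$phase$phase[res$phase$valid], 18), 18)
  expect_lt(max(h) / min(h), 1.3)
})

test_that("accelerometer anchors land on the planted minima and interpolate linearly", {
  # noiseless session; the raw traces are already band-limited, so the
  # planted minima can be localized exactly
  sess <- quick_session(seed = 14, duration_s = 30, jitter = 0.05,
                        sensor_noise_sd = 0)
  fs <- sess$recording$fs
  raw <- phase_from_accel(sess$recording$signals["accel_x", ],
                          sess$recording$signals["accel_y", ], fs)
  expect_equal(nrow(raw$cycles), nrow(sess$truth_cycles))
  expect_true(all(abs(raw$cycles$lift_sample -
                        sess$truth_cycles$lift_sample) <= 1))

  # through the standard 0.5-5 Hz chain: interior anchors stay accurate,
  # the outermost sit in the filter-settle region and may drift slightly
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_accel(gaitmod:::channel_signal(pre, "accel_x"),
                          gaitmod:::channel_signal(pre, "accel_y"), fs)
  expect_false(res$phase$strike_observable)
  expect_equal(nrow(res$cycles), nrow(sess$truth_cycles))
  err_s <- (res$cycles$lift_sample - sess$truth_cycles$lift_sample) / fs
  interior <- 2:(length(err_s) - 1)
  expect_lt(max(abs(err_s[interior])), 0.05)
  # with sensor noise the cycle count is still recovered
  noisy <- quick_session(seed = 14, duration_s = 30, jitter = 0.05)
  pre_n <- preprocess_recording(noisy$recording)
  res_n <- phase_from_accel(gaitmod:::channel_signal(pre_n, "accel_x"),
                            gaitmod:::channel_signal(pre_n, "accel_y"),
                            noisy$recording$fs)
  expect_equal(nrow(res_n$cycles), nrow(noisy$truth_cycles))
  # midpoint between consecutive anchors -> phase 0
  mid <- round((res$cycles$lift_sample + res$cycles$next_lift_sample) / 2)
  expect_lt(max(abs(res$phase$phase[mid])), 0.1)
  expect_error(phase_from_accel(rep(0, 500), rep(0, 500), 100), "anchors")
})

test_that("cycle variability is the sample SD of swing durations", {
  cyc <- gaitmod:::gait_cycle_table(c(1, 201), c(91, 311), c(201, 401),
                                    fs = 100)
  # swing durations 0.9 s and 1.1 s -> sample SD = 0.1414
  expect_equal(cycle_variability(cyc), sd(c(0.9, 1.1)))
  expect_equal(cycle_variability(cyc), 0.1414214, tolerance = 1e-6)
  same <- gaitmod:::gait_cycle_table(c(1, 201), c(101, 301), c(201, 401),
                                     fs = 100)
  expect_equal(cycle_variability(same), 0)
  one <- gaitmod:::gait_cycle_table(1, 101, 201, fs = 100)
  expect_error(cycle_variability(one), "2 cycles")

  sess <- quick_session(seed = 15, duration_s = 30, jitter = 0,
                        sensor_noise_sd = 0)
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                          sess$recording$fs)
  expect_lt(cycle_variability(res$cycles), 2 / sess$recording$fs)
})

test_that("regularity split selects the extreme quartiles deterministically", {
  fs <- 100
  durs <- c(2, 2, 1.5, 2, 2.5, 2, 2, 2)
  lifts <- cumsum(c(1, durs[-8] * fs))
  cyc <- gaitmod:::gait_cycle_table(lifts, lifts + durs * fs / 2,
                                    lifts + durs * fs, fs)
  sp <- split_regularity(cyc)
  expect_equal(sum(sp$label == "regular"), 2)
  expect_equal(sort(sp$cycle[sp$label == "less_regular"]), c(3, 5))
  expect_true(all(sp$deviation_s[sp$label == "regular"] <
                    min(sp$deviation_s[sp$label == "less_regular"])))

  # all-equal durations: tie-break still yields 25% per group, disjoint
  lifts2 <- seq(1, by = 200, length.out = 9)[1:8]
  cyc2 <- gaitmod:::gait_cycle_table(lifts2, lifts2 + 100, lifts2 + 200, fs)
  sp2 <- split_regularity(cyc2)
  expect_equal(sum(sp2$label == "regular"), 2)
  expect_equal(sum(sp2$label == "less_regular"), 2)
  expect_equal(length(intersect(sp2$cycle[sp2$label == "regular"],
                                sp2$cycle[sp2$label == "less_regular"])), 0)

  # invariance to row order
  perm <- sample(8)
  sp3 <- split_regularity(cyc[perm, ])
  m <- merge(sp, sp3, by = "cycle")
  expect_equal(m$label.x, m$label.y)

  expect_error(split_regularity(cyc, fraction = 0.6), "fraction")
  expect_error(split_regularity(cyc[1:4, ]), "8 cycles")
})

test_that("jittered sessions put smaller deviations in the regular group", {
  sess <- quick_session(seed = 16, duration_s = 60, jitter = 0.15)
  pre <- preprocess_recording(sess$recording)
  res <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                          sess$recording$fs)
  sp <- split_regularity(res$cycles)
  expect_lt(mean(sp$deviation_s[sp$label == "regular"]),
            mean(sp$deviation_s[sp$label == "less_regular"]))
})
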