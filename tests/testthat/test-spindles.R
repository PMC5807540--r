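# Spindle detection and the density / duration / ISAs metrics.

test_that("rectified sigma amplitude matches closed forms", {
  fs <- 128; n <- fs * 60
  t <- (0:(n - 1)) / fs
  a <- 5
  rec <- new_recording(matrix(a * sin(2 * pi * 13 * t), 1, n), fs)
  env <- sigma_envelope(rec, method = "rectify")
  expect_equal(mean(env$envelope[1, ]), 2 * a / pi, tolerance = 0.01)

  # zero in, zero out
  rec0 <- new_recording(matrix(0, 1, n), fs)
  expect_true(all(sigma_envelope(rec0)$envelope == 0))

  # 3 Hz tone is stop-band: residual < 5% RMS
  rec3 <- new_recording(matrix(sin(2 * pi * 3 * t), 1, n), fs)
  env3 <- sigma_envelope(rec3, method = "rectify")
  expect_lt(sd(env3$filtered[1, ]) / sd(rec3$data[1, ]), 0.05)

  expect_error(sigma_envelope(rec, band = c(11, 70)), "Nyquist")
})

test_that("a constant sinusoid yields no spindles (max/mean below 8x)", {
  fs <- 128; n <- fs * 300
  t <- (0:(n - 1)) / fs
  rec <- new_recording(matrix(10 * sin(2 * pi * 13 * t), 1, n), fs)
  ev <- detect_spindles(sigma_envelope(rec), full_mask(10))
  expect_equal(nrow(ev), 0)
})

test_that("detected bounds equal the brute-force threshold scan", {
  fs <- 128
  for (seed in 1:6) {
    set.seed(seed)
    # envelope-like series: smoothed |noise| with occasional large bumps
    n <- 2L * 30L * fs                 # two whole epochs (7680 samples)
    e <- abs(somnotype:::moving_average(rnorm(n, 0, 3), 9))
    for (b in sample(1000:(n - 1000), 4)) {
      dur <- sample(40:160, 1)
      e[b:(b + dur)] <- e[b:(b + dur)] +
        runif(1, 15, 40) * sin(pi * (0:dur) / dur)
    }
    env <- fake_envelope(e, fs = fs)
    mask <- full_mask(2)
    ev <- detect_spindles(env, mask)
    mu <- mean(e)
    oracle <- brute_spindle_scan(e, 2 * mu, 8 * mu, fs)
    expect_equal(nrow(ev), nrow(oracle), info = paste("seed", seed))
    if (nrow(ev)) {
      got_start <- round(ev$start_s * fs) + 1
      got_end <- round(ev$end_s * fs) + 1
      expect_equal(got_start, pmax(oracle[, 1], 1), info = paste("seed", seed))
      expect_equal(got_end, pmin(oracle[, 2], n), info = paste("seed", seed))
    }
  }
})

test_that("ISAs follows its closed form and density its arithmetic", {
  # rectangular envelope event, mean amplitude 10 uV, in a 10-min mask
  fs <- 128; n <- 10 * 60 * fs
  e <- rep(0.5, n)                      # low floor so mean stays small
  e[1000:1500] <- 10                    # the event is forced by thresholds
  # scale thresholds via explicit params on a known mean
  env <- fake_envelope(e, fs = fs)
  mask <- full_mask(20)
  mu <- mean(e)
  ev <- detect_spindles(env, mask,
                        spindle_params(lower = 2 / mu, upper = 8 / mu))
  expect_equal(nrow(ev), 1)
  sm <- spindle_metrics(ev, mask, labels = "E1")
  expect_equal(sm$isas, ev$mean_amp / 10, tolerance = 1e-9)
  expect_equal(sm$isas, 1.0, tolerance = 0.02)

  # 20 events in 10 minutes -> density 2/min; empty set -> 0 and ISAs 0
  ev20 <- data.frame(channel = "E1", start_s = seq(0, 570, 30),
                     end_s = seq(1, 571, 30), duration = 1,
                     peak_amp = 12, mean_amp = 8, freq = 13)
  sm20 <- spindle_metrics(ev20, mask, labels = "E1")
  expect_equal(sm20$density, 2.0)
  expect_equal(sm20$isas, 20 * 8 / 10)
  sm0 <- spindle_metrics(ev20[0, ], mask, labels = "E1")
  expect_equal(sm0$density, 0)
  expect_equal(sm0$isas, 0)
})

test_that("metrics are scale-equivariant and ranges partition 12-16 Hz", {
  rec <- quiet_recording(nch = 1, dur_s = 600, sd = 2, seed = 41)
  mask <- full_mask(20)
  mu <- mean(sigma_envelope(rec)$rectified[1, ])
  for (tt in c(60.4, 185.2, 330.7, 481.1))
    rec <- insert_burst(rec, 1, tt, 1.0, freq = 12.5 + (tt %% 3), amp = 12 * mu)
  ev1 <- detect_spindles(sigma_envelope(rec), mask)
  rec2 <- rec; rec2$data <- rec2$data * 5
  ev2 <- detect_spindles(sigma_envelope(rec2), mask)
  sm1 <- spindle_metrics(ev1, mask, labels = "E1")
  sm2 <- spindle_metrics(ev2, mask, labels = "E1")
  expect_equal(ev2$start_s, ev1$start_s, tolerance = 1e-9)
  expect_equal(sm2$density, sm1$density)
  expect_equal(sm2$duration, sm1$duration, tolerance = 1e-9)
  expect_equal(sm2$isas, 5 * sm1$isas, tolerance = 1e-6)

  # slow + fast partition the whole range, boundary 14 Hz to fast
  evf <- data.frame(channel = "E1", start_s = 1:5, end_s = 2:6, duration = 1,
                    peak_amp = 1, mean_amp = 1,
                    freq = c(12, 13.9, 14, 15.2, 16))
  s <- spindle_range(evf, "slow"); f <- spindle_range(evf, "fast")
  expect_equal(nrow(s) + nrow(f), nrow(spindle_range(evf, "whole")))
  expect_true(all(s$freq < 14))
  expect_true(14 %in% f$freq)
})
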