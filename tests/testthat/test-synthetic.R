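# Synthetic-data generator: reproducibility, stage statistics, ground-truth
# event recovery.

test_that("hypnogram generator is reproducible and honors forced profiles", {
  h1 <- generate_hypnogram(120, seed = 7)
  h2 <- generate_hypnogram(120, seed = 7)
  expect_identical(h1$stages, h2$stages)

  # profile forcing N2 only (self-transition, no initial wake)
  tr <- matrix(0, 5, 5, dimnames = list(SLEEP <- c("W","N1","N2","N3","REM"),
                                        SLEEP))
  tr[, "N2"] <- 1
  prof <- stage_profile(trans = tr, sleep_latency_min = 0,
                        rem_latency_min = 0)
  h <- generate_hypnogram(60, seed = 1, profile = prof)
  expect_true(all(h$stages == "N2"))

  expect_error(stage_profile(mean_bout_min = c(W=0,N1=0,N2=0,N3=0,REM=0)),
               "degenerate")
  expect_error(generate_hypnogram(10, seed = 1), ">= 30")
})

test_that("default profile stage fractions match stationary targets (MC)", {
  prof <- stage_profile()
  targ <- stationary_stage_fractions(prof)
  lv <- c("W", "N1", "N2", "N3", "REM")
  fr <- vapply(1:200, function(s) {
    h <- generate_hypnogram(420, seed = s, profile = prof)
    tabulate(factor(h$stages, levels = lv), 5) / length(h$stages)
  }, numeric(5))
  dev <- abs(rowMeans(fr) - targ[lv])
  expect_true(all(dev < 0.05))
  # first REM never before 60 min under defaults
  first_rem <- vapply(1:50, function(s) {
    h <- generate_hypnogram(420, seed = s, profile = prof)
    r <- which(h$stages == "REM")[1]
    if (is.na(r)) Inf else r * 0.5
  }, numeric(1))
  expect_true(all(first_rem >= 60))
})

test_that("recordings are reproducible and zero-density configs are eventless", {
  mon <- make_montage(8)
  prof <- stage_profile(sleep_latency_min = 2, rem_latency_min = 15)
  hyp <- generate_hypnogram(30, seed = 3, profile = prof)
  cfg <- synth_config(n_channels = 8)
  g1 <- generate_recording(hyp, mon, cfg, seed = 5)
  g2 <- generate_recording(hyp, mon, cfg, seed = 5)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth, g2$truth)

  cfg0 <- synth_config(n_channels = 8)
  cfg0$spindle$density[] <- 0
  cfg0$slow$density[] <- 0
  cfg0$artifact$rate_per_h <- 0
  g0 <- generate_recording(hyp, mon, cfg0, seed = 5)
  expect_equal(nrow(g0$truth), 0)
  # sigma-band power stays at the background level: far below a config
  # with spindles present
  mask <- full_mask(n_epochs(hyp))
  p0 <- band_power(welch_psd(g0$recording, mask), c(11, 16))
  p1 <- band_power(welch_psd(g1$recording, mask), c(11, 16))
  expect_gt(mean(p1 / p0), 2)
})

test_that("an inserted high-SNR spindle is recovered as exactly one event", {
  # quiet background; envelope peak 8.5x the channel's mean rectified
  # sigma amplitude
  rec <- quiet_recording(nch = 1, dur_s = 300, sd = 2, seed = 21)
  env0 <- sigma_envelope(rec)
  mask <- full_mask(10)
  mu <- mean(env0$rectified[1, ])
  rec <- insert_burst(rec, 1, t0 = 151.2, dur = 1.0, freq = 13,
                      amp = 8.5 * mu)
  env <- sigma_envelope(rec)
  ev <- detect_spindles(env, mask)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 152.2)
  expect_gt(ev$end_s, 151.2)          # overlaps the inserted support
  expect_equal(ev$freq, 13, tolerance = 0.5 / 13)
  # boundaries sit at the 2x-mean crossings of the Hann envelope:
  # expected duration ~ (1 - 2/pi*asin-form) of the support, ~0.68 s
  expect_equal(ev$duration, 0.68, tolerance = 0.22)

  # a burst peaking at 5x the mean stays below the upper threshold
  rec5 <- quiet_recording(nch = 1, dur_s = 300, sd = 2, seed = 22)
  mu5 <- mean(sigma_envelope(rec5)$rectified[1, ])
  rec5 <- insert_burst(rec5, 1, 151.2, 1.0, 13, amp = 5 * mu5)
  expect_equal(nrow(detect_spindles(sigma_envelope(rec5), mask)), 0)
})

test_that("an inserted half-wave is measured at its true amplitude", {
  rec <- quiet_recording(nch = 1, dur_s = 120, sd = 0.5, seed = 31)
  rec <- insert_halfwave(rec, 1, t0 = 60.3, dur = 0.5, npamp_abs = 80)
  sw <- detect_slow_waves(rec, full_mask(4), band = NULL)
  sw <- sw[abs(sw$npamp) > 20, ]
  expect_equal(nrow(sw), 1)
  expect_equal(sw$npamp, -80, tolerance = 5 / 80)
})

test_that("cohort seeds derive deterministically and effects validate", {
  man1 <- cohort_manifest(3, seed = 9)
  man2 <- cohort_manifest(3, seed = 9)
  expect_identical(man1, man2)
  expect_equal(nrow(man1), 6)
  expect_equal(man1$group, rep(c("A", "B"), each = 3))
  expect_error(cohort_effect(spindle_amp = 0), "> 0")
  expect_error(generate_cohort(1), "at least 2")
})

test_that("spindle density is recovered within 10% of configured (multi-seed)", {
  # default SNR, spindle-center channel, averaged over seeds
  mon <- make_montage(4)
  prof <- stage_profile(sleep_latency_min = 2, rem_latency_min = 15)
  cfg <- synth_config(n_channels = 4)
  ratio <- vapply(1:12, function(s) {
    hyp <- generate_hypnogram(30, seed = 100 + s, profile = prof)
    gr <- generate_recording(hyp, mon, cfg, seed = 200 + s)
    rec <- preprocess_recording(gr$recording, rereference = FALSE)
    amask <- reject_artifacts(rec, hyp)
    mask <- stage_mask(hyp, c("N2", "N3"), artifact_mask = amask)
    ev <- detect_spindles(sigma_envelope(rec), mask)
    ctr <- gr$centers$spindle
    # truth restricted to the analyzed (stage- and artifact-retained) epochs
    tr <- gr$truth[gr$truth$kind == "spindle" & gr$truth$channel == ctr, ]
    n_true <- sum((floor(tr$start_s / 30) + 1) %in% which(mask[ctr, ]))
    sum(ev$channel == ctr) / n_true
  }, numeric(1))
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})
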