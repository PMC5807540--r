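# Sleep architecture scoring, NREM cycle detection, masks, group comparison.

test_that("architecture arithmetic on a constructed night", {
  # 480 epochs: 20 W, 400 N2, 60 W; lights span all epochs
  hyp <- hypnogram(rep(c("W", "N2", "W"), c(20, 400, 60)))
  a <- score_architecture(hyp)
  expect_equal(a$TST, 200)
  expect_equal(a$SL, 10)
  expect_equal(a$SE, 100 * 200 / 240, tolerance = 1e-10)
  expect_equal(a$N2, 100)
  expect_equal(a$WASO, 0)
  expect_true(is.na(a$REML))

  # all-wake night
  aw <- score_architecture(hypnogram(rep("W", 100)))
  expect_equal(aw$TST, 0)
  expect_equal(aw$SE, 0)

  # stage percentages always total 100 when TST > 0; stage minutes conserve
  for (seed in 1:5) {
    h <- generate_hypnogram(200, seed = seed)
    a <- score_architecture(h)
    expect_equal(a$N1 + a$N2 + a$N3 + a$REM +
                   100 * (a$TST - a$TST) / a$TST, 100, tolerance = 1e-9)
    mins <- table(factor(h$stages, levels = c("W","N1","N2","N3","REM"))) / 2
    expect_equal(sum(mins), (h$lights_on - h$lights_off) / 60)
  }
})

test_that("cycle detection follows the 15-min NREM / 5-min REM rule", {
  # 90 min N2, 10 min REM, then more N2: first cycle = 100 min
  hyp <- hypnogram(rep(c("N2", "REM", "N2"), c(180, 20, 100)))
  cyc <- detect_cycles(hyp)
  expect_equal(cyc$start_epoch[1], 1)
  expect_equal(cyc$end_epoch[1], 200)
  expect_true(cyc$complete[1])

  # REM before any 15-min NREM block is not a boundary
  hyp2 <- hypnogram(rep(c("N2", "REM", "N2", "REM", "N2"),
                        c(10, 10, 180, 20, 40)))
  cyc2 <- detect_cycles(hyp2)
  expect_equal(cyc2$end_epoch[1], 220)  # closes at the *second* REM episode

  # no REM: one incomplete cycle covering all sleep
  hyp3 <- hypnogram(rep(c("W", "N2", "W"), c(4, 100, 6)))
  cyc3 <- detect_cycles(hyp3)
  expect_equal(nrow(cyc3), 1)
  expect_false(cyc3$complete)
  expect_equal(c(cyc3$start_epoch, cyc3$end_epoch), c(5, 104))

  # cycles tile sleep without overlap
  for (seed in 1:5) {
    h <- generate_hypnogram(420, seed = seed)
    cy <- detect_cycles(h)
    if (nrow(cy) > 1)
      expect_true(all(cy$start_epoch[-1] > cy$end_epoch[-nrow(cy)]))
  }
})

test_that("stage masks intersect stages, cycles and artifact masks", {
  hyp <- hypnogram(rep(c("W", "N2", "N3", "REM", "N2"), c(4, 60, 40, 16, 60)))
  m <- stage_mask(hyp, c("N2", "N3"))
  expect_equal(sum(m), 160)
  expect_equal(unname(which(m[1, ])), c(5:104, 121:180))

  am <- structure(matrix(TRUE, 2, 180, dimnames = list(c("E1","E2"), NULL)),
                  class = c("epoch_mask", "matrix", "array"), epoch_s = 30)
  am["E1", 10] <- FALSE
  m2 <- stage_mask(hyp, c("N2", "N3"), artifact_mask = am)
  expect_equal(sum(m2["E1", ]), 159)
  expect_equal(sum(m2["E2", ]), 160)
  expect_equal(somnotype:::mask_minutes(m2, c("E1", "E2")),
               c(E1 = 79.5, E2 = 80))

  # first-cycle restriction stays within the first cycle
  m3 <- stage_mask(hyp, c("N2", "N3"), cycle = 1)
  cyc <- detect_cycles(hyp)
  expect_true(all(which(m3[1, ]) >= cyc$start_epoch[1]))
  expect_true(all(which(m3[1, ]) <= cyc$end_epoch[1]))

  expect_error(stage_mask(hyp, "N1"), "empty selection")
})

test_that("group architecture comparison reproduces summary arithmetic", {
  h1 <- hypnogram(rep(c("W", "N2", "REM"), c(10, 300, 50)))
  h2 <- hypnogram(rep(c("W", "N2", "REM"), c(20, 280, 60)))
  a <- list(score_architecture(h1), score_architecture(h2))
  cmp0 <- compare_architecture(a, a)
  expect_true(all(cmp0$diff == 0, na.rm = TRUE))
  expect_true(all(cmp0$t == 0, na.rm = TRUE))

  # antisymmetry of the difference column
  b <- list(score_architecture(hypnogram(rep(c("W","N2","REM"), c(5,320,40)))),
            score_architecture(hypnogram(rep(c("W","N2","REM"), c(8,310,45)))))
  cab <- compare_architecture(a, b)
  cba <- compare_architecture(b, a)
  expect_equal(cab$diff, -cba$diff, tolerance = 1e-12)
  expect_error(compare_architecture(a[1], b), "2 subjects")
})

test_that("summary-statistic t-tests match the published table arithmetic", {
  ref <- architecture_reference()
  tst <- ref[ref$parameter == "TST", ]
  t_tst <- t_from_summary(tst$mean_hs, tst$se_hs, 16, tst$mean_fdr,
                          tst$se_fdr, 16)
  expect_equal(t_tst$t, (368.1 - 274.3) / sqrt(9.04^2 + 19.3^2),
               tolerance = 1e-12)
  expect_equal(t_tst$t, 4.40, tolerance = 0.005)

  cyc <- ref[ref$parameter == "Cyc1", ]
  t_cyc <- t_from_summary(cyc$mean_fdr, cyc$se_fdr, 16, cyc$mean_hs,
                          cyc$se_hs, 16)
  expect_equal(abs(t_cyc$t), 0.61, tolerance = 0.01)
  expect_equal(t_cyc$p, 0.55, tolerance = 0.02)
})
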