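# Delineator: closed-form tangent behaviour, baseline estimation, beat
# and lead selection rules, and recovery on synthetic records.

test_that("tangent end of a gaussian limb is center + 2 sigma", {
  tr <- gaussian_t_trace(center_ms = 600, sigma_ms = 40, amp_mv = 0.4)
  end <- tangent_t_end(tr$x, fs = 500, t_peak_ms = 600)
  expect_lt(abs(end - 680), 1.5)
  inv <- tangent_t_end(-tr$x, fs = 500, t_peak_ms = 600)
  expect_equal(inv, end, tolerance = 1e-9)
})

test_that("tangent of an exactly straight limb lands on its crossing", {
  # line from 0.5 mV at 500 ms down to 0 at 700 ms, then flat
  fs <- 500
  t <- seq(0, 1999) / fs * 1000
  x <- pmax(0, pmin(0.5, (700 - t) / 400))
  end <- tangent_t_end(x, fs, t_peak_ms = 520)
  expect_lt(abs(end - 700), 2)
})

test_that("a trailing U wave does not drag the tangent end later", {
  base <- gaussian_t_trace(600, 40, 0.4)
  u <- gaussian_t_trace(600 + 80 + 70, 22, 0.08)
  end_u <- tangent_t_end(base$x + u$x, 500, t_peak_ms = 600)
  end_0 <- tangent_t_end(base$x, 500, t_peak_ms = 600)
  expect_lt(abs(end_u - end_0), 2)
})

test_that("a flat T wave raises a typed unmeasurable condition", {
  x <- numeric(5000)
  expect_error(tangent_t_end(x, 500, t_peak_ms = 600),
               class = "qtc_unmeasurable")
  tiny <- gaussian_t_trace(600, 40, 1e-5)
  expect_error(tangent_t_end(tiny$x, 500, t_peak_ms = 600,
                             min_slope_mv_ms = 1e-3),
               class = "qtc_unmeasurable")
})

test_that("baseline is the median of the pre-QRS window and rejects bad windows", {
  x <- rep(0.17, 1000)
  expect_equal(estimate_baseline(x, 500, c(100, 160)), 0.17)
  x2 <- c(rep(0.1, 500), rep(5, 500))
  expect_equal(estimate_baseline(x2, 500, c(100, 160)), 0.1)
  expect_error(estimate_baseline(x, 500, c(-50, 10)), "outside")
  expect_error(estimate_baseline(x, 500, c(100, 104)), "10 samples")
  expect_error(estimate_baseline(x, 500, c(200, 100)))
})

test_that("an offset baseline shifts the tangent crossing accordingly", {
  tr <- gaussian_t_trace(600, 40, 0.4)
  shifted <- tr$x + 0.1
  end <- tangent_t_end(shifted, 500, t_peak_ms = 600, baseline_mv = 0.1)
  expect_lt(abs(end - 680), 1.5)
})

test_that("beat selection: representative beat, AF averaging, bigeminy exclusion", {
  cls <- rep("normal", 8)
  rr <- c(NA, 800, 810, 790, 1200, 805, 795, 800)
  sel <- select_beats(cls, rr, "sinus")
  expect_equal(sel$n_beats_averaged, 1L)
  expect_false(sel$beats_used %in% c(1, 5)) # NA-RR and outlier beats lose

  af <- select_beats(rep("normal", 8), rr, "af")
  expect_equal(af$n_beats_averaged, 5L)
  expect_equal(af$beats_used, 1:5)
  expect_false(af$fewer_than_five)
  af3 <- select_beats(rep("normal", 3), rr[1:3], "af")
  expect_equal(af3$n_beats_averaged, 3L)
  expect_true(af3$fewer_than_five)

  big <- c("normal", "pvc", "post_ectopic", "pvc", "post_ectopic", "pvc")
  expect_error(select_beats(big, rep(800, 6), "sinus"),
               class = "qtc_excluded")
  expect_error(select_beats(c("pvc", "post_ectopic"), c(NA, 900), "sinus"),
               class = "qtc_excluded")
})

test_that("ectopic and post-ectopic beats are never measured", {
  cls <- c("normal", "pvc", "post_ectopic", "normal", "normal")
  rr <- c(NA, 500, 1100, 800, 800)
  sel <- select_beats(cls, rr, "sinus")
  expect_true(all(unlist(sel$ranked) %in% c(1, 4, 5)))
  af <- select_beats(cls, rr, "af")
  expect_true(all(af$beats_used %in% c(1, 4, 5)))
})

test_that("primary-lead rule: II/V5 unless another lead is measurably longer", {
  rec <- dummy_record()
  # II longest among primaries, no challenger beyond the margin
  fid <- fiducials_from_qts(c(II = 400, V5 = 395, V2 = 405))
  m <- manual_qt(rec, fid)
  expect_equal(m$lead_used, "II")
  expect_equal(m$qt_ms, 400)
  # V5 longer than II -> V5
  fid <- fiducials_from_qts(c(II = 390, V5 = 402, V2 = 380))
  expect_equal(manual_qt(rec, fid)$lead_used, "V5")
  # non-primary lead beyond the comparison margin wins
  fid <- fiducials_from_qts(c(II = 390, V5 = 392, V3 = 420))
  m <- manual_qt(rec, fid)
  expect_equal(m$lead_used, "V3")
  expect_equal(m$qt_ms, 420)
  # tie between II and V5 favours II
  fid <- fiducials_from_qts(c(II = 400, V5 = 400))
  expect_equal(manual_qt(rec, fid)$lead_used, "II")
  # primaries unmeasurable -> longest other lead
  fid <- fiducials_from_qts(c(V2 = 380, V3 = 410))
  fid$fiducials$V2$t_end_ms <- NA
  expect_equal(manual_qt(rec, fid)$lead_used, "V3")
})

test_that("detector recovers QT, QRS and beat count on a clean record", {
  out <- synthesize_record(clean_sinus_config(seed = 11, mean_rr_ms = 900,
                                              true_qt_ms = 400))
  fid <- detect_beats(out$record)
  expect_equal(nrow(fid$beats), nrow(out$truth$beats))
  expect_true(all(fid$beats$beat_class == "normal"))
  m <- manual_qt(out$record, fid)
  expect_lt(abs(m$qt_ms - 400), 4)
  expect_lt(abs(m$qrs_ms - 90), 6)
  expect_equal(m$rr_ms, 900, tolerance = 0.01)
  expect_equal(m$method, "manual_tangent")
})

test_that("detector classifies a forced PVC and avoids it", {
  probs <- c(0, 0, 0, 1, rep(0, 20))
  out <- synthesize_record(synth_config(
    seed = 12, rhythm = rhythm_spec("sinus", mean_rr_ms = 850,
                                    pvc_prob = probs)))
  fid <- detect_beats(out$record)
  k <- which(out$truth$beats$beat_class == "pvc")
  expect_equal(fid$beats$beat_class[k], "pvc")
  expect_equal(fid$beats$beat_class[k + 1], "post_ectopic")
  m <- manual_qt(out$record, fid)
  expect_false(any(m$beats_used %in% c(k, k + 1)))
  expect_lt(abs(m$qt_ms - out$truth$true_qt_ms), 5)
})

test_that("wide-QRS (BBB) records keep a usable QRS estimate", {
  out <- synthesize_record(synth_config(
    seed = 13, bbb = TRUE, bbb_qrs_ms = 140, true_qt_ms = 430,
    rhythm = rhythm_spec("sinus", mean_rr_ms = 900, rr_cv = 0)))
  m <- manual_qt(out$record)
  expect_gte(m$qrs_ms, 120)
  expect_lt(abs(m$qt_ms - 430), 8)
})

test_that("AF reading averages five beats and their preceding RRs", {
  out <- synthesize_record(synth_config(
    seed = 14, rhythm = rhythm_spec("af", mean_rr_ms = 850)))
  fid <- detect_beats(out$record, truth = out$truth)
  m <- manual_qt(out$record, fid, rhythm_kind = "af")
  expect_equal(m$n_beats_averaged, 5L)
  expect_equal(m$rr_ms,
               mean(fid$beats$rr_preceding_ms[m$beats_used], na.rm = TRUE))
})

test_that("truth pass-through reproduces the generator fiducials exactly", {
  out <- synthesize_record(clean_sinus_config(seed = 15))
  fid <- detect_beats(out$record, truth = out$truth)
  expect_equal(fid$fiducials$II$t_end_ms, out$truth$beats$t_tangent_end_ms)
  m <- manual_qt(out$record, fid)
  expect_equal(m$qt_ms, out$truth$true_qt_ms, tolerance = 1e-9)
})
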