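# Small builders shared across the test files.

# A strict-sinus config: fixed RR grid, no noise, no ectopy.
clean_sinus_config <- function(seed = 1, mean_rr_ms = 1000, ...) {
  synth_config(seed = seed,
               rhythm = rhythm_spec("sinus", mean_rr_ms = mean_rr_ms,
                                    rr_cv = 0),
               ...)
}

# Hand-built fiducial structure for lead-rule tests: one normal beat per
# lead, with the QT set per lead via its t_end.
fiducials_from_qts <- function(qts, onset = 100, qrs = 90) {
  fid <- lapply(qts, function(qt) {
    data.frame(beat = 1, qrs_onset_ms = onset, r_peak_ms = onset + 40,
               t_peak_ms = onset + qt - 80, t_end_ms = onset + qt,
               qrs_offset_ms = onset + qrs, baseline_mv = 0)
  })
  beats <- data.frame(beat = 1, r_peak_ms = onset + 40,
                      rr_preceding_ms = 800, qrs_ms = qrs,
                      beat_class = "normal", stringsAsFactors = FALSE)
  list(beats = beats, fiducials = fid,
       ref_lead = if ("II" %in% names(qts)) "II" else names(qts)[1])
}

dummy_record <- function(rhythm = "sinus", sex = "M") {
  structure(list(signal = NULL, lead_names = character(0),
                 sample_rate_hz = 500,
                 meta = list(rhythm = rhythm, sex = sex)),
            class = "ecg_record")
}

# Per-record QT recovery over a cohort: manual error vs ground truth and
# the automated-vs-per-lead dominance check on the measured beat(s).
measure_recovery <- function(cfg) {
  ch <- make_cohort(cfg)
  rows <- list()
  for (i in seq_along(ch$records)) {
    entry <- ch$records[[i]]
    if (is.null(entry)) next
    row <- tryCatch({
      fid <- detect_beats(entry$record)
      m <- manual_qt(entry$record, fid)
      a <- automated_qt(entry$record, fid)
      per_lead <- vapply(fid$fiducials, function(f) {
        qt <- f$t_end_ms[m$beats_used] - f$qrs_onset_ms[m$beats_used]
        qt <- qt[is.finite(qt)]
        if (length(qt) == 0) NA_real_ else mean(qt)
      }, numeric(1))
      data.frame(err_ms = m$qt_ms - entry$truth$true_qt_ms,
                 auto_qt_ms = a$qt_ms,
                 max_per_lead_qt_ms = max(per_lead, na.rm = TRUE),
                 manual_qtc_ms = qtc_result(m$qt_ms, m$rr_ms, m$qrs_ms,
                                            ch$covariates$sex[i])$qtc_adjusted_ms,
                 auto_qtc_ms = a$qtc_ms)
    },
    qtc_excluded = function(e) NULL,
    qtc_unmeasurable = function(e) NULL)
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

# All-sinus, pathology-free cohort config for recovery studies.
recovery_config <- function(n, seed, noise_sd_mv) {
  cohort_config(n, prevalence = list(af = 0, paced = 0, other_rhythm = 0,
                                     bbb = 0, artifact = 0, pvc = 0,
                                     pac = 0, u_wave = 0, female = 0.5),
                noise_sd_mv = noise_sd_mv, seed = seed)
}

# A gaussian T limb on a flat trace, for closed-form tangent tests.
gaussian_t_trace <- function(center_ms, sigma_ms, amp_mv, fs = 500,
                             dur_ms = 12000) {
  t <- seq(0, dur_ms - 1000 / fs, by = 1000 / fs)
  list(t = t, x = amp_mv * exp(-(t - center_ms)^2 / (2 * sigma_ms^2)))
}
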