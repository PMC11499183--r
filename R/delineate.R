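# Algorithmic form of the manual QT protocol: estimate the isoelectric
# baseline from the PR segment, locate per-beat landmarks, define the
# T-wave end as the intersection of the tangent at the steepest terminal
# T limb with the baseline, and apply the reader's lead- and
# beat-selection rules (lead II/V5 primary unless another lead is longer;
# five-beat averaging in AF; post-ectopic beats avoided; bigeminy
# unmeasurable).

stop_unmeasurable <- function(msg) {
  stop(structure(class = c("qtc_unmeasurable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_excluded <- function(msg) {
  stop(structure(class = c("qtc_excluded", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Estimate the isoelectric baseline level
#'
#' Median amplitude over a quiescent window; by convention the 60-20 ms
#' interval before QRS onset (PR-segment proxy).
#'
#' @param x One-lead sample vector, mV.
#' @param fs Sampling rate, Hz.
#' @param window_ms Two-element c(start, end) in ms from record start.
#' @return Baseline level in mV.
#' @export
estimate_baseline <- function(x, fs, window_ms) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  i1 <- floor(window_ms[1] / 1000 * fs) + 1
  i2 <- ceiling(window_ms[2] / 1000 * fs) + 1
  if (i1 < 1 || i2 > length(x))
    stop("baseline window lies outside the record")
  idx <- i1:i2
  if (length(idx) < 10)
    stop("baseline window must contain at least 10 samples")
  stats::median(x[idx])
}

# Smoothed signal value and slope (mV/ms) via local cubic polynomial
# (Savitzky-Golay) fits over ~smooth_ms; raw finite differences are too
# noise-sensitive for tangent placement.
smooth_fields <- function(x, fs, smooth_ms = 20) {
  n <- round(smooth_ms / 1000 * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 5)
  list(val = signal::sgolayfilt(x, p = 3, n = n),
       slope = signal::sgolayfilt(x, p = 3, n = n, m = 1) * fs / 1000)
}

# Shared tangent construction: locate the steepest slope of the
# requested sign on the smoothed derivative, then fit the tangent line
# itself by least squares on the raw samples around that point (the
# limb is locally straight at its inflection, so the fit is unbiased
# and far less noise-sensitive than a pointwise slope), and intersect
# it with the baseline.
tangent_from_slope <- function(x, sm, fs, idx_range, baseline, slope_sign,
                               min_slope, fit_ms = 20) {
  idx_range <- idx_range[idx_range >= 1 & idx_range <= length(x)]
  if (length(idx_range) == 0) stop_unmeasurable("empty tangent search window")
  score <- slope_sign * sm$slope[idx_range]
  i_best <- idx_range[which.max(score)]
  if (max(score) < min_slope)
    stop_unmeasurable("no limb steeper than the slope threshold")
  half <- max(1L, round(fit_ms / 2 / 1000 * fs))
  w <- max(1L, i_best - half):min(length(x), i_best + half)
  tt <- (w - 1) / fs * 1000
  fit <- stats::lm.fit(cbind(1, tt - mean(tt)), x[w])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || slope_sign * b < min_slope)
    stop_unmeasurable("tangent parallel to baseline")
  mean(tt) + (baseline - a) / b
}

#' Tangent-method T-wave end
#'
#' Finds the point of steepest slope toward the baseline on the terminal
#' limb of the T wave (descending for an upright T, ascending for an
#' inverted one), fits the tangent there on a local cubic-polynomial
#' smooth, and returns its intersection with the isoelectric level, with
#' sub-sample interpolation. The search stops at the first baseline
#' crossing after the T peak, so later deflections (U waves) are ignored.
#'
#' @param x One-lead sample vector, mV.
#' @param fs Sampling rate, Hz.
#' @param t_peak_ms T-peak time, ms from record start.
#' @param baseline_mv Isoelectric level (see [estimate_baseline()]).
#' @param search_window_ms Length of the post-peak search window, ms.
#' @param smooth_ms Width of the local polynomial fit, ms.
#' @param min_slope_mv_ms Minimum tangent slope magnitude; flatter T waves
#'   raise an unmeasurable-T error.
#' @return T-end time in ms.
#' @export
tangent_t_end <- function(x, fs, t_peak_ms, baseline_mv = 0,
                          search_window_ms = 260, smooth_ms = 20,
                          min_slope_mv_ms = 1e-3) {
  sm <- smooth_fields(x, fs, smooth_ms)
  ipk <- round(t_peak_ms / 1000 * fs) + 1
  if (ipk < 1 || ipk > length(x)) stop("t_peak outside record")
  t_end_from_smooth(x, sm, fs, ipk, baseline_mv, search_window_ms,
                    min_slope_mv_ms)
}

# tangent_t_end on a precomputed smooth (shared across the beats of a
# lead so the lead is filtered once).
t_end_from_smooth <- function(x, sm, fs, ipk, baseline_mv, search_window_ms,
                              min_slope_mv_ms) {
  polarity <- sign(sm$val[ipk] - baseline_mv)
  if (polarity == 0) stop_unmeasurable("flat T wave at peak")
  i_from <- ipk + max(1, round(0.004 * fs))
  i_to <- min(length(sm$val), ipk + round(search_window_ms / 1000 * fs))
  if (i_from > i_to) stop_unmeasurable("search window after record end")
  rng <- i_from:i_to
  need <- max(1L, round(0.008 * fs))
  trunc_at_run <- function(rng, flag, skip = 0L) {
    # cut the range before the first sustained (>= 8 ms) run of `flag`,
    # ignoring the first `skip` samples
    if (skip > 0) flag[seq_len(min(skip, length(flag)))] <- FALSE
    runs <- rle(flag)
    if (!any(runs$values & runs$lengths >= need)) return(rng)
    k <- which(runs$values & runs$lengths >= need)[1]
    cut <- if (k == 1) 0L else sum(runs$lengths[seq_len(k - 1)])
    if (cut < 1) stop_unmeasurable("terminal limb vanishes at T peak")
    rng[seq_len(cut)]
  }
  # end the terminal limb at the first sustained baseline crossing, so a
  # single noisy dip does not stop it early but later deflections
  # (U waves, the next P) are never entered
  rng <- trunc_at_run(rng, polarity * (sm$val[rng] - baseline_mv) < 0)
  # likewise at the first sustained slope reversal after the limb has
  # developed: the tangent is taken on the terminal limb only
  rng <- trunc_at_run(rng, polarity * sm$slope[rng] > 0,
                      skip = round(0.02 * fs))
  tangent_from_slope(x, sm, fs, rng, baseline_mv,
                     slope_sign = -polarity, min_slope = min_slope_mv_ms)
}

#' QT of one beat on one lead
#'
#' @param fiducials A list or one-row data.frame with `qrs_onset_ms` and
#'   `t_end_ms`.
#' @return QT in ms (T end minus QRS onset).
#' @export
measure_lead_qt <- function(fiducials) {
  qt <- fiducials$t_end_ms - fiducials$qrs_onset_ms
  if (!is.finite(qt) || qt <= 0)
    stop_unmeasurable("non-positive QT from fiducials")
  qt
}

# Landmarks for one beat on one lead, anchored at the reference R peak.
# sm_q is a narrow (QRS-scale) smooth, sm_t the wider T-scale smooth.
delineate_beat <- function(x, sm_q, sm_t, fs, r_idx, next_r_idx, min_slope) {
  ms <- function(i) (i - 1) / fs * 1000
  smp <- function(t_ms) round(t_ms / 1000 * fs)
  win <- function(a, b) max(1L, a):min(length(x), b)

  q_rng <- win(r_idx - smp(70), r_idx - smp(4))
  q_idx <- q_rng[which.min(sm_q$val[q_rng])]
  b1 <- q_idx - smp(68); b2 <- q_idx - smp(28)
  if (b1 < 1) stop_unmeasurable("no pre-QRS baseline window")
  baseline <- stats::median(x[b1:b2])

  onset <- tangent_from_slope(x, sm_q, fs,
                              win(q_idx - smp(20), q_idx - smp(1)),
                              baseline, slope_sign = -1,
                              min_slope = min_slope, fit_ms = 8)
  s_rng <- win(r_idx + smp(4), r_idx + smp(95))
  s_idx <- s_rng[which.min(sm_q$val[s_rng])]
  offset <- tangent_from_slope(x, sm_q, fs,
                               win(s_idx + smp(1), s_idx + smp(26)),
                               baseline, slope_sign = 1,
                               min_slope = min_slope, fit_ms = 8)

  off_idx <- smp(offset) + 1
  t_to <- if (is.finite(next_r_idx))
    min(next_r_idx - smp(90), off_idx + smp(500)) else off_idx + smp(500)
  t_rng <- win(off_idx + smp(40), t_to)
  if (length(t_rng) < 5) stop_unmeasurable("no T-wave search window")
  t_idx <- t_rng[which.max(abs(sm_t$val[t_rng] - baseline))]
  if (abs(sm_t$val[t_idx] - baseline) < 0.15)
    stop_unmeasurable("T wave too flat to read (< 0.15 mV)")
  t_end <- t_end_from_smooth(x, sm_t, fs, t_idx, baseline, 260, min_slope)
  if (t_end <= offset) stop_unmeasurable("T end before QRS offset")

  list(qrs_onset_ms = onset, r_peak_ms = ms(r_idx), t_peak_ms = ms(t_idx),
       t_end_ms = t_end, qrs_offset_ms = offset, baseline_mv = baseline)
}

#' Detect beats and per-lead fiducials
#'
#' R peaks are found on the reference lead (II when present) by
#' peak-picking, then every lead is delineated around those anchors. Beat
#' classes (`normal`, `pvc`, `pac`, `post_ectopic`) are inferred from the
#' RR pattern (prematurity below 85% of the median RR) and QRS width
#' (>= 120 ms for ventricular origin). With `truth` supplied the detector
#' is bypassed and fiducials are taken from the generator ground truth
#' (identical across leads).
#'
#' @param record An `ecg_record`.
#' @param truth Optional `ground_truth` for pass-through mode.
#' @param min_slope_mv_ms Tangent slope threshold.
#' @return A list with `beats` (reference-lead table: `r_peak_ms`,
#'   `rr_preceding_ms`, `qrs_ms`, `beat_class`) and `fiducials` (named
#'   list per lead of per-beat data.frames; unmeasurable entries are NA).
#' @export
detect_beats <- function(record, truth = NULL, min_slope_mv_ms = 1e-3) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.null(truth)) return(truth_fiducials(record, truth))
  fs <- record$sample_rate_hz
  leads <- record$lead_names
  ref_lead <- if ("II" %in% leads) "II" else leads[1]
  ref <- record$signal[, ref_lead]
  gbase <- stats::median(ref)
  pk <- pracma::findpeaks(ref - gbase,
                          minpeakheight = max(0.3, 0.4 * max(ref - gbase)),
                          minpeakdistance = round(0.22 * fs))
  if (is.null(pk) || nrow(pk) == 0)
    stop_unmeasurable("no beats found: unusable record")
  # second pass: re-threshold at half the median peak height so tall T
  # waves riding on noise are not mistaken for QRS complexes
  thr <- max(0.3, 0.55 * stats::median(pk[, 1]))
  pk <- pk[pk[, 1] >= thr, , drop = FALSE]
  if (nrow(pk) == 0) stop_unmeasurable("no beats found: unusable record")
  r_idx <- sort(pk[, 2])

  fiducials <- list()
  for (l in leads) {
    x <- record$signal[, l]
    sm_q <- smooth_fields(x, fs, 8)
    sm_t <- smooth_fields(x, fs, 30)
    rows <- lapply(seq_along(r_idx), function(i) {
      nxt <- if (i < length(r_idx)) r_idx[i + 1] else Inf
      out <- tryCatch(delineate_beat(x, sm_q, sm_t, fs, r_idx[i], nxt,
                                     min_slope_mv_ms),
                      qtc_unmeasurable = function(e) NULL,
                      error = function(e) NULL)
      if (is.null(out))
        out <- list(qrs_onset_ms = NA_real_, r_peak_ms = (r_idx[i] - 1) /
                      fs * 1000, t_peak_ms = NA_real_, t_end_ms = NA_real_,
                    qrs_offset_ms = NA_real_, baseline_mv = NA_real_)
      as.data.frame(out)
    })
    fiducials[[l]] <- cbind(beat = seq_along(r_idx), do.call(rbind, rows))
  }

  ref_fid <- fiducials[[ref_lead]]
  rr <- c(NA_real_, diff(ref_fid$r_peak_ms))
  qrs_w <- ref_fid$qrs_offset_ms - ref_fid$qrs_onset_ms
  med_rr <- stats::median(rr, na.rm = TRUE)
  classes <- character(length(rr))
  for (i in seq_along(rr)) {
    prev <- if (i > 1) classes[i - 1] else "normal"
    premature <- is.finite(rr[i]) && rr[i] < 0.85 * med_rr
    classes[i] <- if (prev %in% c("pvc", "pac")) "post_ectopic"
      else if (premature && is.finite(qrs_w[i]) && qrs_w[i] >= 120) "pvc"
      else if (premature) "pac"
      else "normal"
  }
  beats <- data.frame(beat = seq_along(rr), r_peak_ms = ref_fid$r_peak_ms,
                      rr_preceding_ms = rr, qrs_ms = qrs_w,
                      beat_class = classes, stringsAsFactors = FALSE)
  list(beats = beats, fiducials = fiducials, ref_lead = ref_lead)
}

# Ground-truth pass-through: fiducial tables built directly from the
# generator oracle, identical on every lead.
truth_fiducials <- function(record, truth) {
  tb <- truth$beats
  fid <- data.frame(beat = seq_len(nrow(tb)),
                    qrs_onset_ms = tb$qrs_onset_ms,
                    r_peak_ms = (tb$qrs_onset_ms + tb$qrs_offset_ms) / 2,
                    t_peak_ms = (tb$qrs_offset_ms + tb$t_tangent_end_ms) / 2,
                    t_end_ms = tb$t_tangent_end_ms,
                    qrs_offset_ms = tb$qrs_offset_ms,
                    baseline_mv = 0)
  fiducials <- stats::setNames(
    rep(list(fid), length(record$lead_names)), record$lead_names)
  beats <- data.frame(beat = seq_len(nrow(tb)), r_peak_ms = fid$r_peak_ms,
                      rr_preceding_ms = tb$rr_preceding_ms,
                      qrs_ms = tb$qrs_offset_ms - tb$qrs_onset_ms,
                      beat_class = tb$beat_class, stringsAsFactors = FALSE)
  ref <- if ("II" %in% record$lead_names) "II" else record$lead_names[1]
  list(beats = beats, fiducials = fiducials, ref_lead = ref)
}

#' Apply the reader's beat-selection rules
#'
#' Ectopic beats and the beat immediately following an ectopic are never
#' measured. In atrial fibrillation QT is averaged over the first five
#' usable beats (all usable beats, flagged, when fewer than five exist).
#' In other rhythms one representative beat is measured: the usable beat
#' whose preceding RR is closest to the record's median RR. Records in a
#' bigeminal pattern (>= 40% ectopic beats) are unmeasurable and excluded.
#'
#' @param beat_class Character vector of per-beat classes.
#' @param rr_ms Per-beat preceding RR (NA for the first beat).
#' @param rhythm_kind `"sinus"`, `"af"`, `"paced"` or `"other"`.
#' @return list(`beats_used`, `n_beats_averaged`, `fewer_than_five`).
#' @export
select_beats <- function(beat_class, rr_ms, rhythm_kind = "sinus") {
  stopifnot(length(beat_class) >= 1, length(rr_ms) == length(beat_class))
  ectopic <- beat_class %in% c("pvc", "pac")
  if (sum(ectopic) >= 3 && mean(ectopic) >= 0.4)
    stop_excluded("bigeminal rhythm: QT not measurable")
  usable <- which(beat_class == "normal")
  if (length(usable) < 1)
    stop_excluded("no usable beats")
  if (rhythm_kind == "af") {
    used <- usable[seq_len(min(5, length(usable)))]
    return(list(beats_used = used, n_beats_averaged = length(used),
                fewer_than_five = length(used) < 5,
                ranked = list(used)))
  }
  rr_u <- rr_ms[usable]
  med <- stats::median(rr_u, na.rm = TRUE)
  dev <- abs(rr_u - med)
  dev[!is.finite(dev)] <- Inf
  ord <- if (all(!is.finite(dev)) || is.na(med)) usable
         else usable[order(dev)]
  list(beats_used = ord[1], n_beats_averaged = 1L, fewer_than_five = FALSE,
       ranked = as.list(ord))
}

#' Manual (tangent-method) QT measurement of a record
#'
#' Measures QT on every lead over the selected beats and applies the
#' primary-lead rule: lead II or V5 (whichever is longer; ties favour II)
#' unless another lead has a measurably longer QT. "Measurably longer"
#' means exceeding the primary-lead QT by more than the reader's
#' comparison resolution `lead_margin_ms` (a human comparing leads with
#' calipers cannot resolve arbitrarily small differences; the protocol
#' leaves this resolution unstated). The RR used for correction is the
#' preceding RR of the measured beat (in AF, the mean preceding RR of
#' the five averaged beats).
#'
#' @param record An `ecg_record`.
#' @param fiducials Output of [detect_beats()] (computed when NULL).
#' @param rhythm_kind Rhythm label; defaults to the record metadata.
#' @param primary_leads Primary leads for the lead rule.
#' @param lead_margin_ms Margin by which a non-primary lead must exceed
#'   the best primary-lead QT to be used instead.
#' @return A `measurement` list: `qt_ms`, `rr_ms`, `qrs_ms`, `lead_used`,
#'   `n_beats_averaged`, `beats_used`, `method = "manual_tangent"`.
#' @export
manual_qt <- function(record, fiducials = NULL,
                      rhythm_kind = record$meta$rhythm,
                      primary_leads = c("II", "V5"),
                      lead_margin_ms = 10) {
  if (is.null(fiducials)) fiducials <- detect_beats(record)
  if (is.null(rhythm_kind)) rhythm_kind <- "sinus"
  beats <- fiducials$beats
  sel <- select_beats(beats$beat_class, beats$rr_preceding_ms, rhythm_kind)

  # walk the ranked candidate beats until one is measurable somewhere
  # (a reader skips an illegible beat and takes the next representative)
  lead_qt <- NULL; used <- NULL
  for (cand in sel$ranked) {
    qts <- vapply(fiducials$fiducials, function(fid) {
      qt <- fid$t_end_ms[cand] - fid$qrs_onset_ms[cand]
      qt <- qt[is.finite(qt) & qt > 0]
      if (length(qt) == 0) NA_real_ else mean(qt)
    }, numeric(1))
    if (any(is.finite(qts))) { lead_qt <- qts; used <- cand; break }
  }
  if (is.null(lead_qt))
    stop_excluded("no measurable lead: record excluded")
  measurable <- names(lead_qt)[is.finite(lead_qt)]

  prim <- intersect(primary_leads, measurable)
  others <- setdiff(measurable, primary_leads)
  if (length(prim) > 0) {
    best_p <- max(lead_qt[prim])
    lead_p <- prim[lead_qt[prim] > best_p - 1e-9][1]
    longer <- others[lead_qt[others] > best_p + lead_margin_ms]
    lead_used <- if (length(longer) > 0) {
      best_o <- max(lead_qt[longer])
      longer[lead_qt[longer] > best_o - 1e-9][1]
    } else lead_p
  } else {
    best_o <- max(lead_qt[others])
    lead_used <- others[lead_qt[others] > best_o - 1e-9][1]
  }

  fid <- fiducials$fiducials[[lead_used]]
  qrs <- mean(fid$qrs_offset_ms[used] - fid$qrs_onset_ms[used], na.rm = TRUE)
  rr_used <- beats$rr_preceding_ms[used]
  rr <- if (rhythm_kind == "af") mean(rr_used, na.rm = TRUE)
        else if (is.finite(rr_used[1])) rr_used[1]
        else stats::median(beats$rr_preceding_ms, na.rm = TRUE)
  structure(list(qt_ms = unname(lead_qt[lead_used]), rr_ms = rr,
                 qrs_ms = qrs, lead_used = lead_used,
                 n_beats_averaged = sel$n_beats_averaged,
                 beats_used = used, method = "manual_tangent"),
            class = "measurement")
}
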