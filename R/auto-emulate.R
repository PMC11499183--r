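# Stylized model of the ECG machine's QT algorithm. The real vendor
# algorithm is proprietary; this emulator is a deliberate mechanistic
# caricature built from the two behaviours that drive machine/reader
# discordance: all-lead superimposition (earliest QRS onset to latest
# T end across leads) and heart-rate correction without QRS-duration
# adjustment, with a machine-style global mean RR.

#' Automated (machine-style) QT/QTc of a record
#'
#' On the same representative beat(s) as the manual reading, QT is the
#' latest tangent T end across all measurable leads minus the earliest
#' QRS onset across leads; by construction it is at least as long as any
#' single lead's QT. RR is the global mean over the record and QTc is
#' Bazett-corrected only (no QRS-duration adjustment).
#'
#' @param record An `ecg_record`.
#' @param fiducials Output of [detect_beats()] (computed when NULL).
#' @param rhythm_kind Rhythm label; defaults to the record metadata.
#' @return An `auto_measurement` list: `qt_ms`, `rr_ms`, `qtc_ms`,
#'   `lead_used = "superimposed"`, `n_beats_averaged`,
#'   `method = "automated_global"`.
#' @export
automated_qt <- function(record, fiducials = NULL,
                         rhythm_kind = record$meta$rhythm) {
  if (is.null(fiducials)) fiducials <- detect_beats(record)
  if (is.null(rhythm_kind)) rhythm_kind <- "sinus"
  beats <- fiducials$beats
  sel <- select_beats(beats$beat_class, beats$rr_preceding_ms, rhythm_kind)

  superimposed_qt <- function(b) {
    onsets <- vapply(fiducials$fiducials, function(f) f$qrs_onset_ms[b],
                     numeric(1))
    ends <- vapply(fiducials$fiducials, function(f) f$t_end_ms[b],
                   numeric(1))
    ok <- is.finite(onsets) & is.finite(ends)
    if (!any(ok)) return(NA_real_)
    max(ends[ok]) - min(onsets[ok])
  }
  # same candidate-beat walk as the manual reading
  per_beat_qt <- NULL
  for (cand in sel$ranked) {
    qts <- vapply(cand, superimposed_qt, numeric(1))
    qts <- qts[is.finite(qts)]
    if (length(qts) > 0) { per_beat_qt <- qts; break }
  }
  if (is.null(per_beat_qt))
    stop_unmeasurable("no measurable lead for automated QT")

  rr <- mean(beats$rr_preceding_ms, na.rm = TRUE)
  qt <- mean(per_beat_qt)
  structure(list(qt_ms = qt, rr_ms = rr, qtc_ms = bazett(qt, rr),
                 lead_used = "superimposed",
                 n_beats_averaged = length(per_beat_qt),
                 method = "automated_global"),
            class = "auto_measurement")
}

#' Render the machine interpretation text with possible LQT suppression
#'
#' When the automated QTc meets the sex-specific long-QT threshold, the
#' printed interpretation omits the phrase "prolonged QT" with probability
#' `suppression_prob` (the numeric value still meets the threshold: the
#' diagnosis is "suppressed"). Records below the threshold never mention
#' it. The machine's true suppression logic is unknown; it is modeled as
#' a Bernoulli flag.
#'
#' @param qtc_ms Automated QTc, ms.
#' @param sex `"M"` or `"F"`.
#' @param suppression_prob Probability of suppression given an LQT call
#'   (default 0.75).
#' @return list(`interpretation_text`, `suppressed`, `auto_lqt`).
#' @export
render_interpretation <- function(qtc_ms, sex, suppression_prob = 0.75) {
  stopifnot(suppression_prob >= 0, suppression_prob <= 1)
  lqt <- classify_lqt(qtc_ms, sex)
  if (!lqt)
    return(list(interpretation_text = "Normal ECG", suppressed = FALSE,
                auto_lqt = FALSE))
  suppressed <- stats::runif(1) < suppression_prob
  txt <- if (suppressed) "Nonspecific repolarization abnormality"
         else "prolonged QT"
  list(interpretation_text = txt, suppressed = suppressed, auto_lqt = TRUE)
}
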