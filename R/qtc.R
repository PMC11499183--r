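# Rate and QRS-duration correction of QT, sex-specific long-QT
# classification, and the paired-call labels with the manual reading as
# gold standard.

#' Bazett heart-rate correction
#'
#' QTc = QT / sqrt(RR in seconds). Equal to QT at 60 bpm (RR 1000 ms) and
#' strictly decreasing in RR for fixed QT.
#'
#' @param qt_ms QT interval, ms (> 0).
#' @param rr_ms Preceding RR interval, ms (> 0).
#' @return QTc in ms.
#' @export
bazett <- function(qt_ms, rr_ms) {
  if (any(!is.finite(qt_ms)) || any(!is.finite(rr_ms)) ||
      any(qt_ms <= 0) || any(rr_ms <= 0))
    stop("bazett requires positive qt_ms and rr_ms")
  qt_ms / sqrt(rr_ms / 1000)
}

#' QRS-duration adjustment of QTc
#'
#' With a wide QRS (>= 120 ms, e.g. bundle branch block) the Bazett QTc is
#' reduced by the QRS excess over 100 ms: adjusted = QTc - (QRS - 100).
#' Narrow-QRS values pass through unchanged; the adjustment never
#' increases QTc.
#'
#' @param qtc_ms Bazett QTc, ms (> 0).
#' @param qrs_ms QRS duration, ms (> 0).
#' @param qrs_cutoff_ms Width at which the adjustment engages (120 ms).
#' @return Adjusted QTc in ms.
#' @export
qrs_adjust <- function(qtc_ms, qrs_ms, qrs_cutoff_ms = 120) {
  if (any(!is.finite(qtc_ms)) || any(!is.finite(qrs_ms)) ||
      any(qtc_ms <= 0) || any(qrs_ms <= 0))
    stop("qrs_adjust requires positive qtc_ms and qrs_ms")
  out <- ifelse(qrs_ms >= qrs_cutoff_ms, qtc_ms - (qrs_ms - 100), qtc_ms)
  if (any(out <= 0))
    stop("QRS adjustment produced a non-positive QTc")
  out
}

#' Sex-specific long-QT classification
#'
#' LQT is QTc >= 470 ms for males and >= 480 ms for females (inclusive
#' thresholds). There is no unisex fallback: sex must be known.
#'
#' @param qtc_ms QTc in ms (full precision; no rounding before
#'   comparison by default).
#' @param sex `"M"` or `"F"` (vectorized, recycled).
#' @param male_ms,female_ms Thresholds, ms.
#' @param round_first Round QTc to integer ms before comparing (off by
#'   default).
#' @return Logical LQT flag(s).
#' @export
classify_lqt <- function(qtc_ms, sex, male_ms = 470, female_ms = 480,
                         round_first = FALSE) {
  if (!all(sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (round_first) qtc_ms <- round(qtc_ms)
  ifelse(sex == "M", qtc_ms >= male_ms, qtc_ms >= female_ms)
}

#' Label a paired automated/manual call
#'
#' The manual reading is the gold standard, so a positive automated call
#' without a positive manual call is a false positive.
#'
#' @param auto_lqt,manual_lqt Logical flags (vectorized).
#' @return `"TP"`, `"FP"`, `"TN"` or `"FN"`.
#' @export
label_pair <- function(auto_lqt, manual_lqt) {
  stopifnot(is.logical(auto_lqt), is.logical(manual_lqt))
  ifelse(auto_lqt & manual_lqt, "TP",
  ifelse(auto_lqt & !manual_lqt, "FP",
  ifelse(!auto_lqt & manual_lqt, "FN", "TN")))
}

#' Full manual-pipeline correction of one measurement
#'
#' Applies Bazett then the QRS-duration adjustment and classifies LQT.
#'
#' @param qt_ms,rr_ms,qrs_ms Measured intervals, ms.
#' @param sex `"M"` or `"F"`.
#' @return list(`qt_ms`, `rr_ms`, `qrs_ms`, `qtc_bazett_ms`,
#'   `qtc_adjusted_ms`, `sex`, `lqt`).
#' @export
qtc_result <- function(qt_ms, rr_ms, qrs_ms, sex) {
  qtc_b <- bazett(qt_ms, rr_ms)
  qtc_a <- qrs_adjust(qtc_b, qrs_ms)
  list(qt_ms = qt_ms, rr_ms = rr_ms, qrs_ms = qrs_ms,
       qtc_bazett_ms = qtc_b, qtc_adjusted_ms = qtc_a, sex = sex,
       lqt = classify_lqt(qtc_a, sex))
}
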