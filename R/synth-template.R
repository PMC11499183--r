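# Beat morphology: each deflection (P, Q, R, S, T, U) is a gaussian bump.
# The tangent at a gaussian's inflection point (center + sigma) crosses the
# baseline at exactly center + 2*sigma, which gives every template an
# analytic, tangent-consistent T-wave end and QRS onset/offset.

#' Gaussian wave component of a beat template
#'
#' @param center_ms Time offset of the deflection peak from the beat
#'   reference (the tangent-defined QRS onset sits at 0 ms).
#' @param sigma_ms Gaussian width in ms; must be positive.
#' @param amplitude_mv Signed peak amplitude in mV.
#' @param label Optional wave label ("P", "Q", "R", "S", "T", "U").
#' @return A `wave_component` object.
#' @export
wave_component <- function(center_ms, sigma_ms, amplitude_mv, label = "") {
  stopifnot(is.finite(center_ms), is.finite(sigma_ms), is.finite(amplitude_mv))
  if (sigma_ms <= 0) stop("sigma_ms must be positive")
  structure(
    list(center_ms = center_ms, sigma_ms = sigma_ms,
         amplitude_mv = amplitude_mv, label = label),
    class = "wave_component"
  )
}

#' Build a beat template with tangent-consistent ground truth
#'
#' Places gaussian deflections so that the tangent-method landmarks have
#' closed forms: QRS onset is where the tangent at the steepest initial
#' Q-wave limb meets the baseline (Q center - 2*Q sigma, fixed at 0 ms),
#' QRS offset is the S-limb tangent crossing (S center + 2*S sigma), and
#' the T-wave end is the terminal-limb tangent crossing
#' (T center + 2*T sigma). Hence `true_qt_ms = t_center + 2*t_sigma` and
#' `true_qrs_ms` equals the S-limb crossing.
#'
#' @param true_qt_ms Tangent-consistent QT duration (QRS onset to T end), ms.
#' @param true_qrs_ms Tangent-consistent QRS duration, ms. Values >= 120
#'   model bundle-branch-block widening.
#' @param t_sigma_ms Width of the T gaussian, ms.
#' @param t_amp_mv T amplitude (sign flipped when `invert_t`).
#' @param p_wave Include a P wave (FALSE for atrial fibrillation).
#' @param u_wave Append a small U deflection after the T end.
#' @param invert_t Invert T polarity (discordant T, e.g. with BBB).
#' @param r_amp_mv R-wave amplitude, mV.
#' @return A `beat_template` with `components` and ground-truth fields
#'   `qrs_onset_ms` (0), `qrs_offset_ms`, `t_center_ms`, `t_sigma_ms`,
#'   `true_qt_ms`, `true_qrs_ms`.
#' @export
beat_template <- function(true_qt_ms = 400, true_qrs_ms = 90,
                          t_sigma_ms = 40, t_amp_mv = 0.35,
                          p_wave = TRUE, u_wave = FALSE,
                          invert_t = FALSE, r_amp_mv = 1.0) {
  stopifnot(true_qt_ms > 0, true_qrs_ms > 0, t_sigma_ms > 0)
  q_sigma <- 4
  q_center <- 2 * q_sigma                       # onset tangent crossing at 0
  s_sigma <- max(6, true_qrs_ms / 12)
  s_center <- true_qrs_ms - 2 * s_sigma         # offset crossing at true_qrs
  r_center <- (q_center + s_center) / 2
  r_sigma <- max(6, true_qrs_ms / 11)
  t_center <- true_qt_ms - 2 * t_sigma_ms
  if (t_center <= true_qrs_ms + 20)
    stop("true_qt_ms too short for the requested QRS and T width")
  comps <- list(
    wave_component(q_center, q_sigma, -0.15, "Q"),
    wave_component(r_center, r_sigma, r_amp_mv, "R"),
    wave_component(s_center, s_sigma, -0.25, "S"),
    wave_component(t_center, t_sigma_ms,
                   if (invert_t) -abs(t_amp_mv) else abs(t_amp_mv), "T")
  )
  if (p_wave)
    comps <- c(list(wave_component(-90, 20, 0.12, "P")), comps)
  if (u_wave)
    comps <- c(comps, list(wave_component(true_qt_ms + 70, 22, 0.08, "U")))
  structure(
    list(components = comps,
         qrs_onset_ms = 0,
         qrs_offset_ms = true_qrs_ms,
         t_center_ms = t_center,
         t_sigma_ms = t_sigma_ms,
         true_qt_ms = true_qt_ms,
         true_qrs_ms = true_qrs_ms,
         has_p = p_wave, has_u = u_wave, inverted_t = invert_t),
    class = "beat_template"
  )
}

# Evaluate a template on an absolute time grid (ms), with the beat's
# QRS onset placed at `onset_ms`. Each gaussian is only evaluated on its
# +/- 5 sigma support for speed.
eval_template <- function(template, times_ms, onset_ms) {
  y <- numeric(length(times_ms))
  dt <- if (length(times_ms) > 1) times_ms[2] - times_ms[1] else 1
  for (cm in template$components) {
    c_abs <- onset_ms + cm$center_ms
    lo <- max(1L, ceiling((c_abs - 5 * cm$sigma_ms - times_ms[1]) / dt) + 1L)
    hi <- min(length(times_ms),
              floor((c_abs + 5 * cm$sigma_ms - times_ms[1]) / dt) + 1L)
    if (lo > hi) next
    tt <- times_ms[lo:hi]
    y[lo:hi] <- y[lo:hi] +
      cm$amplitude_mv * exp(-(tt - c_abs)^2 / (2 * cm$sigma_ms^2))
  }
  y
}
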