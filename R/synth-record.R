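#' Rhythm specification for the synthetic generator
#'
#' @param kind One of `"sinus"`, `"af"`, `"paced"`, `"other"`. Atrial
#'   fibrillation implies an irregular RR series (gamma-distributed) and no
#'   P wave.
#' @param mean_rr_ms Mean RR interval, ms.
#' @param rr_cv Coefficient of variation of the RR series. Must be > 0 for
#'   AF; defaults to 0.18 there and to 0.02 (respiratory-scale variability)
#'   in sinus rhythm.
#' @param pvc_prob,pac_prob Per-beat probability of a premature
#'   ventricular/atrial beat; scalar or per-beat vector (recycled). A beat
#'   directly following an ectopic is never itself drawn ectopic.
#' @param bigeminy If TRUE every second beat is a PVC (alternating pattern).
#' @return A `rhythm_spec` object.
#' @export
rhythm_spec <- function(kind = c("sinus", "af", "paced", "other"),
                        mean_rr_ms = 60000 / 72,
                        rr_cv = NULL,
                        pvc_prob = 0, pac_prob = 0,
                        bigeminy = FALSE) {
  kind <- match.arg(kind)
  if (is.null(rr_cv)) rr_cv <- if (kind == "af") 0.18 else 0.02
  stopifnot(mean_rr_ms > 0, rr_cv >= 0,
            all(pvc_prob >= 0 & pvc_prob <= 1),
            all(pac_prob >= 0 & pac_prob <= 1))
  if (kind == "af" && rr_cv <= 0)
    stop("atrial fibrillation requires rr_cv > 0")
  if (bigeminy && kind == "af")
    stop("contradictory rhythm flags: bigeminy cannot be combined with AF")
  structure(list(kind = kind, mean_rr_ms = mean_rr_ms, rr_cv = rr_cv,
                 pvc_prob = pvc_prob, pac_prob = pac_prob,
                 bigeminy = isTRUE(bigeminy)),
            class = "rhythm_spec")
}

#' Configuration for one synthetic 12-lead record
#'
#' @param sample_rate_hz Sampling rate; >= 250 Hz (default 500).
#' @param duration_s Strip length in seconds; >= 10 (standard clinical strip).
#' @param lead_names Lead vocabulary (default the standard 12 leads).
#' @param lead_scale Named per-lead amplitude scale factors; unnamed leads
#'   get 1. Amplitude scaling leaves tangent landmarks unchanged.
#' @param noise_sd_mv White measurement noise, mV.
#' @param baseline_wander_amp_mv Amplitude of a slow (0.25 Hz) sinusoidal
#'   baseline wander.
#' @param artifact Add high-frequency noise bursts on random leads
#'   (no ground-truth change).
#' @param u_wave Append a U deflection after each T wave.
#' @param sex `"M"` or `"F"`. Sex shapes the default T wave (smaller,
#'   narrower T for females) so that the sex covariate has mechanistic
#'   bite downstream; widths are configurable.
#' @param rhythm A [rhythm_spec()].
#' @param bbb Bundle branch block: QRS widened to `bbb_qrs_ms` with
#'   discordant (inverted) T.
#' @param bbb_qrs_ms QRS duration used when `bbb` is TRUE; >= 120 ms.
#' @param true_qt_ms,true_qrs_ms Tangent-consistent ground-truth durations
#'   for normal beats.
#' @param t_sigma_ms,t_amp_mv T-wave geometry; defaults depend on `sex`.
#' @param seed Integer seed; the same config + seed reproduces the record
#'   bit for bit.
#' @return A `synth_config` object.
#' @export
synth_config <- function(sample_rate_hz = 500, duration_s = 10,
                         lead_names = standard_leads(),
                         lead_scale = default_lead_scale(),
                         noise_sd_mv = 0, baseline_wander_amp_mv = 0,
                         artifact = FALSE, u_wave = FALSE,
                         sex = c("M", "F"),
                         rhythm = rhythm_spec(),
                         bbb = FALSE, bbb_qrs_ms = 140,
                         true_qt_ms = 400, true_qrs_ms = 90,
                         t_sigma_ms = NULL, t_amp_mv = NULL,
                         seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(sample_rate_hz >= 250, duration_s >= 10,
            inherits(rhythm, "rhythm_spec"))
  if (bbb && bbb_qrs_ms < 120) stop("bbb_qrs_ms must be >= 120")
  if (is.null(t_sigma_ms)) t_sigma_ms <- if (sex == "F") 36 else 40
  if (is.null(t_amp_mv)) t_amp_mv <- if (sex == "F") 0.30 else 0.35
  scale <- rep(1, length(lead_names))
  names(scale) <- lead_names
  known <- intersect(names(lead_scale), lead_names)
  scale[known] <- lead_scale[known]
  structure(list(sample_rate_hz = sample_rate_hz, duration_s = duration_s,
                 lead_names = lead_names, lead_scale = scale,
                 noise_sd_mv = noise_sd_mv,
                 baseline_wander_amp_mv = baseline_wander_amp_mv,
                 artifact = isTRUE(artifact), u_wave = isTRUE(u_wave),
                 sex = sex, rhythm = rhythm, bbb = isTRUE(bbb),
                 bbb_qrs_ms = bbb_qrs_ms,
                 true_qt_ms = true_qt_ms, true_qrs_ms = true_qrs_ms,
                 t_sigma_ms = t_sigma_ms, t_amp_mv = t_amp_mv,
                 seed = seed),
            class = "synth_config")
}

#' @export
#' @rdname synth_config
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @export
#' @rdname synth_config
default_lead_scale <- function() {
  c(I = 0.70, II = 1.00, III = 0.50, aVR = 0.40, aVL = 0.45, aVF = 0.75,
    V1 = 0.50, V2 = 0.80, V3 = 0.90, V4 = 1.00, V5 = 0.95, V6 = 0.80)
}

# Draw the per-beat RR series and beat classes for one record.
draw_beat_plan <- function(config) {
  rhy <- config$rhythm
  dur_ms <- config$duration_s * 1000
  first_onset <- 250
  tail_margin <- config$true_qt_ms + 150
  if (first_onset + tail_margin > dur_ms)
    stop("record too short to contain a full beat")
  max_beats <- ceiling(dur_ms / (rhy$mean_rr_ms * 0.5)) + 2
  pvc_p <- rep_len(rhy$pvc_prob, max_beats)
  pac_p <- rep_len(rhy$pac_prob, max_beats)

  onsets <- first_onset
  rr <- NA_real_
  classes <- "normal"
  i <- 1L
  repeat {
    i <- i + 1L
    prev_class <- classes[i - 1L]
    base_rr <- if (rhy$rr_cv <= 0) rhy$mean_rr_ms else if (rhy$kind == "af") {
      shape <- 1 / rhy$rr_cv^2
      stats::rgamma(1, shape = shape, scale = rhy$mean_rr_ms / shape)
    } else {
      max(0.5 * rhy$mean_rr_ms,
          stats::rnorm(1, rhy$mean_rr_ms, rhy$rr_cv * rhy$mean_rr_ms))
    }
    if (prev_class %in% c("pvc", "pac")) {
      cls <- "post_ectopic"
      this_rr <- base_rr * if (prev_class == "pvc") 1.35 else 1.2
    } else if (rhy$bigeminy && i %% 2L == 0L) {
      cls <- "pvc"; this_rr <- base_rr * 0.65
    } else if (!rhy$bigeminy && i <= max_beats &&
               stats::runif(1) < pvc_p[i]) {
      cls <- "pvc"; this_rr <- base_rr * 0.65
    } else if (!rhy$bigeminy && i <= max_beats &&
               stats::runif(1) < pac_p[i]) {
      cls <- "pac"; this_rr <- base_rr * 0.8
    } else {
      cls <- "normal"; this_rr <- base_rr
    }
    onset <- onsets[i - 1L] + this_rr
    if (onset + tail_margin > dur_ms) break
    onsets <- c(onsets, onset)
    rr <- c(rr, this_rr)
    classes <- c(classes, cls)
  }
  data.frame(onset_ms = onsets, rr_preceding_ms = rr,
             beat_class = classes, stringsAsFactors = FALSE)
}

#' Synthesize one multi-lead ECG record with known ground truth
#'
#' The waveform is a sum of per-beat gaussian templates placed on the RR
#' grid, plus optional white noise, baseline wander and artifact bursts.
#' Ground-truth fiducials are tangent-consistent (see [beat_template()]),
#' so the tangent-method delineator has an analytic oracle.
#'
#' @param config A [synth_config()].
#' @return A list with `record` (an `ecg_record`: `signal` matrix of mV,
#'   one column per lead; `lead_names`; `sample_rate_hz`; `meta`) and
#'   `truth` (a `ground_truth`: per-beat absolute `qrs_onset_ms`,
#'   `qrs_offset_ms`, `t_tangent_end_ms`, `rr_preceding_ms`, `beat_class`,
#'   plus record-level `true_qt_ms`, `true_qrs_ms`).
#' @export
synthesize_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  times <- (seq_len(n) - 1) / fs * 1000
  rhy <- config$rhythm

  plan <- draw_beat_plan(config)

  normal_tpl <- beat_template(
    true_qt_ms = config$true_qt_ms,
    true_qrs_ms = if (config$bbb) config$bbb_qrs_ms else config$true_qrs_ms,
    t_sigma_ms = config$t_sigma_ms, t_amp_mv = config$t_amp_mv,
    p_wave = rhy$kind == "sinus", u_wave = config$u_wave,
    invert_t = config$bbb)
  pvc_tpl <- beat_template(
    true_qt_ms = max(config$true_qt_ms, 420), true_qrs_ms = 150,
    t_sigma_ms = config$t_sigma_ms + 5, t_amp_mv = 0.5,
    p_wave = FALSE, u_wave = FALSE, invert_t = TRUE, r_amp_mv = 1.2)

  base <- numeric(n)
  truth_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tpl <- if (plan$beat_class[i] == "pvc") pvc_tpl else normal_tpl
    base <- base + eval_template(tpl, times, plan$onset_ms[i])
    truth_rows[[i]] <- data.frame(
      qrs_onset_ms = plan$onset_ms[i],
      qrs_offset_ms = plan$onset_ms[i] + tpl$true_qrs_ms,
      t_tangent_end_ms = plan$onset_ms[i] + tpl$true_qt_ms,
      rr_preceding_ms = plan$rr_preceding_ms[i],
      beat_class = plan$beat_class[i],
      true_qt_ms = tpl$true_qt_ms,
      true_qrs_ms = tpl$true_qrs_ms,
      stringsAsFactors = FALSE)
  }
  truth_beats <- do.call(rbind, truth_rows)

  sig <- outer(base, config$lead_scale)
  if (config$baseline_wander_amp_mv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    wander <- config$baseline_wander_amp_mv *
      sin(2 * pi * 0.25 * times / 1000 + phase)
    sig <- sig + wander
  }
  if (config$noise_sd_mv > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$noise_sd_mv),
                        nrow = n)
  if (config$artifact) {
    for (b in seq_len(3)) {
      leads <- sample(seq_along(config$lead_names),
                      size = min(3, length(config$lead_names)))
      len <- round(stats::runif(1, 0.2, 0.4) * fs)
      start <- sample.int(max(1L, n - len), 1)
      idx <- start:(start + len - 1L)
      sig[idx, leads] <- sig[idx, leads] +
        matrix(stats::rnorm(length(idx) * length(leads), 0, 0.2),
               nrow = length(idx))
    }
  }
  colnames(sig) <- config$lead_names

  record <- structure(
    list(signal = sig, lead_names = config$lead_names,
         sample_rate_hz = fs,
         meta = list(sex = config$sex, rhythm = rhy$kind,
                     bbb = config$bbb, artifact = config$artifact,
                     u_wave = config$u_wave, seed = config$seed)),
    class = "ecg_record")
  truth <- structure(
    list(beats = truth_beats,
         true_qt_ms = normal_tpl$true_qt_ms,
         true_qrs_ms = normal_tpl$true_qrs_ms),
    class = "ground_truth")
  list(record = record, truth = truth)
}
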