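#' Configuration for a synthetic hospital ECG cohort
#'
#' Defaults emulate an unselected hospital cohort: sinus rhythm ~95%, AF
#' 3%, paced 0.2%, other rhythm 1.4%, bundle branch block 4.4%, artifact
#' 16%, PVCs 4%, PACs 1.76%, U waves 0.7%, 52% female, heart rate
#' 83 +/- 19 bpm, age 52 +/- 18 y. The manual (gold-standard) QTc is drawn
#' as N(417, 35) ms and converted to a raw QT at the record's heart rate,
#' so every record has an analytically known QT.
#'
#' @param n_records Number of records (>= 1).
#' @param prevalence Named list of Bernoulli prevalences:
#'   `af`, `paced`, `other_rhythm`, `bbb`, `artifact`, `pvc`, `pac`,
#'   `u_wave`, `female`. All in \[0, 1\].
#' @param hr_mean,hr_sd Heart-rate distribution, bpm (truncated to
#'   \[40, 180\]).
#' @param qtc_mean,qtc_sd Gold-standard (adjusted) QTc distribution, ms.
#' @param age_mean,age_sd Age distribution, years (truncated to \[1, 100\];
#'   the implied pediatric share is ~3%).
#' @param noise_sd_mv,duration_s,sample_rate_hz Passed to [synth_config()].
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_records,
                          prevalence = list(af = 0.03, paced = 0.002,
                                            other_rhythm = 0.014,
                                            bbb = 0.044, artifact = 0.16,
                                            pvc = 0.04, pac = 0.0176,
                                            u_wave = 0.007, female = 0.52),
                          hr_mean = 83, hr_sd = 19,
                          qtc_mean = 417, qtc_sd = 35,
                          age_mean = 52, age_sd = 18,
                          noise_sd_mv = 0.02, duration_s = 10,
                          sample_rate_hz = 500, seed = NULL) {
  stopifnot(n_records >= 1)
  defaults <- list(af = 0.03, paced = 0.002, other_rhythm = 0.014,
                   bbb = 0.044, artifact = 0.16, pvc = 0.04, pac = 0.0176,
                   u_wave = 0.007, female = 0.52)
  defaults[names(prevalence)] <- prevalence
  prevalence <- defaults
  p <- unlist(prevalence)
  if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]")
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 qtc_mean = qtc_mean, qtc_sd = qtc_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 noise_sd_mv = noise_sd_mv, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "cohort_config")
}

#' Draw the per-record covariate table for a cohort
#'
#' Covariates are drawn from independent Bernoulli/normal laws with the
#' configured prevalences; rhythm is categorical (sinus vs AF vs paced vs
#' other). Ectopy flags are suppressed in AF (the irregular baseline makes
#' single premature beats unreadable) and `irregular` is AF or PVC or PAC.
#'
#' @param config A [cohort_config()].
#' @return A data.frame, one row per record: `record_id`, `sex`, `age`,
#'   `hr`, `rhythm`, `af`, `irregular`, `bbb`, `artifact`, `pvc`, `pac`,
#'   `u_wave`, `target_qtc_ms` (gold-standard adjusted QTc), `qrs_ms`.
#' @export
draw_cohort_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_records
  pv <- config$prevalence
  sex <- ifelse(stats::runif(n) < pv$female, "F", "M")
  age <- pmin(100, pmax(1, stats::rnorm(n, config$age_mean, config$age_sd)))
  hr <- pmin(180, pmax(40, stats::rnorm(n, config$hr_mean, config$hr_sd)))
  u <- stats::runif(n)
  p_af <- pv$af; p_paced <- pv$paced; p_other <- pv$other_rhythm
  rhythm <- ifelse(u < p_af, "af",
            ifelse(u < p_af + p_paced, "paced",
            ifelse(u < p_af + p_paced + p_other, "other", "sinus")))
  bbb <- stats::runif(n) < pv$bbb
  artifact <- stats::runif(n) < pv$artifact
  pvc <- stats::runif(n) < pv$pvc & rhythm != "af"
  pac <- stats::runif(n) < pv$pac & rhythm != "af" & !pvc
  u_wave <- stats::runif(n) < pv$u_wave
  target_qtc <- stats::rnorm(n, config$qtc_mean, config$qtc_sd)
  qrs <- ifelse(bbb, 140, 90)
  data.frame(record_id = sprintf("rec%05d", seq_len(n)),
             sex = sex, age = age, hr = hr, rhythm = rhythm,
             af = rhythm == "af",
             irregular = rhythm == "af" | pvc | pac,
             bbb = bbb, artifact = artifact, pvc = pvc, pac = pac,
             u_wave = u_wave, target_qtc_ms = target_qtc, qrs_ms = qrs,
             stringsAsFactors = FALSE)
}

# Translate one covariate row into a synth_config. The gold-standard
# adjusted QTc is mapped back to a raw QT at the record's mean RR:
# QT = (QTc_adj + max(0, QRS - 100)) * sqrt(RR / 1000).
covariates_to_config <- function(row, cohort, seed) {
  mean_rr <- 60000 / row$hr
  qtc_bazett <- row$target_qtc_ms + if (row$qrs_ms >= 120)
    row$qrs_ms - 100 else 0
  true_qt <- qtc_bazett * sqrt(mean_rr / 1000)
  # keep the template geometrically valid at fast rates / short QT
  t_sigma <- if (row$sex == "F") 36 else 40
  t_sigma <- min(t_sigma, floor((true_qt - row$qrs_ms - 30) / 2))
  if (t_sigma < 12) stop("unusable record: QT too short for template")
  kind <- if (row$rhythm %in% c("sinus", "af")) row$rhythm else "sinus"
  rhy <- rhythm_spec(kind = kind, mean_rr_ms = mean_rr,
                     pvc_prob = if (row$pvc) 0.12 else 0,
                     pac_prob = if (row$pac) 0.12 else 0)
  synth_config(sample_rate_hz = cohort$sample_rate_hz,
               duration_s = cohort$duration_s,
               noise_sd_mv = cohort$noise_sd_mv,
               artifact = row$artifact, u_wave = row$u_wave,
               sex = row$sex, rhythm = rhy,
               bbb = row$bbb, bbb_qrs_ms = row$qrs_ms,
               true_qt_ms = true_qt, true_qrs_ms = row$qrs_ms,
               t_sigma_ms = t_sigma, seed = seed)
}

#' Generate a cohort of synthetic records with covariates and truth
#'
#' @param config A [cohort_config()].
#' @param waveforms If FALSE only the covariate table is drawn (fast path
#'   for prevalence studies at large n).
#' @return A list with `covariates` (data.frame) and, when `waveforms`,
#'   `records`: a list of `list(record, truth)` per row (NULL where a draw
#'   produced an unusable geometry, with `usable = FALSE` in the table).
#' @export
make_cohort <- function(config, waveforms = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  cov <- draw_cohort_covariates(config)
  if (!waveforms) return(list(covariates = cov, records = NULL))
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  records <- vector("list", nrow(cov))
  cov$usable <- TRUE
  for (i in seq_len(nrow(cov))) {
    rec_seed <- (base_seed * 7919L + i * 104729L) %% .Machine$integer.max
    records[[i]] <- tryCatch(
      synthesize_record(covariates_to_config(cov[i, ], config, rec_seed)),
      error = function(e) NULL)
    if (is.null(records[[i]])) cov$usable[i] <- FALSE
  }
  list(covariates = cov, records = records)
}
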