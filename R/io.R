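# CSV is the canonical interchange format: waveforms (time column + one
# column per lead), measurements, covariates and report renderings, with
# seed and config hash carried in '#' header comments. Nested fiducials
# and reports go to JSON.

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Write a waveform record as multi-column CSV
#'
#' First column `time_ms`, then one column per lead (header row of lead
#' names). Seed, config hash and sampling rate are stored as `#` comment
#' lines so the file round-trips through [read_waveform_csv()].
#'
#' @param record An `ecg_record`.
#' @param path Output file.
#' @param seed,hash Optional provenance fields for the header.
#' @export
write_waveform_csv <- function(record, path, seed = record$meta$seed,
                               hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
               sprintf("# config_hash: %s",
                       if (is.null(hash)) "NA" else hash),
               sprintf("# sample_rate_hz: %s", record$sample_rate_hz),
               sprintf("# sex: %s", record$meta$sex),
               sprintf("# rhythm: %s", record$meta$rhythm)), con)
  n <- nrow(record$signal)
  df <- data.frame(time_ms = (seq_len(n) - 1) / record$sample_rate_hz * 1000)
  df <- cbind(df, as.data.frame(record$signal))
  # 17 significant digits so the file round-trips bit-identically
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read one waveform CSV back into an `ecg_record`
#'
#' @param path File written by [write_waveform_csv()] (or any CSV with a
#'   `time_ms` column and one column per lead).
#' @return An `ecg_record`; non-standard lead names are kept but flagged
#'   in `meta$nonstandard_leads` (excluded from the primary-lead rule).
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 20)
  meta_lines <- grep("^# ", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_ms" %in% names(df)) stop("missing time_ms column: ", path)
  tm <- df$time_ms
  if (any(diff(tm) <= 0)) stop("non-monotone time column: ", path)
  fs <- if (!is.null(meta$sample_rate_hz)) as.numeric(meta$sample_rate_hz)
        else 1000 / stats::median(diff(tm))
  leads <- setdiff(names(df), "time_ms")
  nonstd <- setdiff(leads, standard_leads())
  if (length(nonstd) > 0)
    warning("non-standard lead name(s) in ", basename(path), ": ",
            paste(nonstd, collapse = ", "),
            " (retained, but excluded from the primary-lead rule)")
  sig <- as.matrix(df[leads])
  structure(list(signal = sig, lead_names = leads, sample_rate_hz = fs,
                 meta = list(sex = meta$sex %||% "M",
                             rhythm = meta$rhythm %||% "sinus",
                             seed = suppressWarnings(as.integer(meta$seed)),
                             nonstandard_leads = nonstd)),
            class = "ecg_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read all waveform CSVs in a directory
#'
#' Malformed files are reported by name (warning) and skipped; the run
#' continues with the readable records.
#'
#' @param path Directory of waveform CSV files.
#' @return Named list of `ecg_record`s.
#' @export
read_waveforms <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("(_truth|_covariates|measurements)", files)]
  if (length(files) == 0) stop("no waveform CSV files in ", path)
  out <- list()
  for (f in files) {
    rec <- tryCatch(read_waveform_csv(f), error = function(e) {
      warning("skipping malformed file ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) out[[sub("\\.csv$", "", basename(f))]] <- rec
  }
  out
}

#' Measure a synthetic cohort with both methods
#'
#' For every usable record: detect fiducials (or take the generator truth
#' in pass-through mode), run the manual tangent pipeline (Bazett + QRS
#' adjustment) and the automated emulator (superimposition + Bazett
#' only), classify LQT with the sex-specific thresholds, and label the
#' paired call. Records the protocol cannot measure (bigeminy, no
#' measurable lead) are excluded and counted.
#'
#' @param cohort Output of [make_cohort()].
#' @param use_truth Pass generator fiducials through instead of running
#'   the detector.
#' @param suppression_prob Probability that a machine LQT call omits
#'   "prolonged QT" from the interpretation text.
#' @return list(`measurements` — one row per included record with both
#'   methods' QT/QTc, LQT flags, pair category, suppression and the
#'   covariates —, `excluded` — record ids and reasons —, `counts`).
#' @export
measure_cohort <- function(cohort, use_truth = FALSE,
                           suppression_prob = 0.75) {
  cov <- cohort$covariates
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(cov))) {
    id <- cov$record_id[i]
    entry <- cohort$records[[i]]
    if (is.null(entry)) {
      excl[[id]] <- "unusable geometry at generation"
      next
    }
    res <- tryCatch({
      fid <- detect_beats(entry$record,
                          truth = if (use_truth) entry$truth else NULL)
      man <- manual_qt(entry$record, fid)
      aut <- automated_qt(entry$record, fid)
      mq <- qtc_result(man$qt_ms, man$rr_ms, man$qrs_ms, cov$sex[i])
      auto_lqt <- classify_lqt(aut$qtc_ms, cov$sex[i])
      interp <- render_interpretation(aut$qtc_ms, cov$sex[i],
                                      suppression_prob)
      data.frame(record_id = id,
                 manual_qt_ms = man$qt_ms, manual_rr_ms = man$rr_ms,
                 manual_qrs_ms = man$qrs_ms,
                 manual_lead = man$lead_used,
                 manual_n_beats = man$n_beats_averaged,
                 manual_qtc_ms = mq$qtc_adjusted_ms,
                 manual_lqt = mq$lqt,
                 auto_qt_ms = aut$qt_ms, auto_rr_ms = aut$rr_ms,
                 auto_qtc_ms = aut$qtc_ms, auto_lqt = auto_lqt,
                 suppressed = interp$suppressed,
                 interpretation = interp$interpretation_text,
                 category = label_pair(auto_lqt, mq$lqt),
                 true_qt_ms = entry$truth$true_qt_ms,
                 stringsAsFactors = FALSE)
    },
    qtc_excluded = function(e) conditionMessage(e),
    qtc_unmeasurable = function(e) conditionMessage(e))
    if (is.character(res)) excl[[id]] <- res else rows[[id]] <- res
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0))
  if (nrow(meas) > 0)
    meas <- merge(meas, cov, by = "record_id", sort = TRUE)
  list(measurements = meas,
       excluded = data.frame(record_id = names(excl),
                             reason = unlist(excl, use.names = FALSE)),
       counts = c(generated = nrow(cov), included = length(rows),
                  excluded = length(excl)))
}

#' Run the full audit pipeline end to end
#'
#' simulate -> measure (manual and automated) -> correct -> classify ->
#' analyze. Deterministic given the seed; artifacts (measurements CSV,
#' paired-call CSV, accuracy/regression report JSON, run log with
#' per-stage counts) are written under `out_dir`, each carrying the seed
#' and config hash.
#'
#' @param config A [cohort_config()] (its `n_records` >= 1).
#' @param out_dir Output directory (created if needed).
#' @param use_truth Use generator fiducials instead of the detector.
#' @param suppression_prob Machine suppression probability.
#' @return Invisibly, list(`measurements`, `excluded`, `report`).
#' @export
run_pipeline <- function(config, out_dir, use_truth = FALSE,
                         suppression_prob = 0.75) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed %||% NA

  cohort <- make_cohort(config)
  mc <- measure_cohort(cohort, use_truth = use_truth,
                       suppression_prob = suppression_prob)
  meas <- mc$measurements

  header <- c(sprintf("# seed: %s", seed),
              sprintf("# config_hash: %s", hash))
  write_with_header <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_with_header(meas, file.path(out_dir, "measurements.csv"))
  write_with_header(mc$excluded, file.path(out_dir, "excluded.csv"))

  report <- list(seed = seed, config_hash = hash, counts = as.list(mc$counts))
  if (nrow(meas) > 0 && length(unique(meas$category)) >= 1) {
    cm <- confusion(meas$category)
    report$confusion <- cm
    dm <- diagnostic_metrics(cm)
    report$metrics <- dm
    report$cells <- attr(dm, "cells")
    write_with_header(
      meas[c("record_id", "auto_lqt", "manual_lqt", "category")],
      file.path(out_dir, "paired_calls.csv"))
    design <- data.frame(male = meas$sex == "M",
                         heart_rate = meas$hr,
                         abnormal_rhythm = meas$rhythm != "sinus",
                         pvc = meas$pvc,
                         bbb = meas$bbb,
                         irregular = meas$irregular,
                         u_wave = meas$u_wave)
    fp <- meas$category == "FP"
    report$regression <- tryCatch(fit_logistic(design, fp),
                                  error = function(e)
                                    list(error = conditionMessage(e)))
  } else {
    report$note <- "no analyzable records: all excluded"
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  log_lines <- c(sprintf("seed: %s | config_hash: %s", seed, hash),
                 sprintf("generated: %d", mc$counts["generated"]),
                 sprintf("included: %d", mc$counts["included"]),
                 sprintf("excluded: %d", mc$counts["excluded"]))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(measurements = meas, excluded = mc$excluded,
                 report = report))
}
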