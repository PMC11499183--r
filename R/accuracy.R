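# Diagnostic-accuracy, agreement and predictor analyses of the paired
# automated/manual long-QT calls.

#' Tally paired calls into a 2x2 confusion table
#'
#' @param categories Character vector of `"TP"`, `"FP"`, `"TN"`, `"FN"`
#'   (from [label_pair()]).
#' @return list(`tp`, `fp`, `tn`, `fn`, `n`).
#' @export
confusion <- function(categories) {
  if (length(categories) == 0) stop("no paired calls to tally")
  if (!all(categories %in% c("TP", "FP", "TN", "FN")))
    stop("unknown pair category")
  out <- list(tp = sum(categories == "TP"), fp = sum(categories == "FP"),
              tn = sum(categories == "TN"), fn = sum(categories == "FN"))
  out$n <- out$tp + out$fp + out$tn + out$fn
  out
}

# Wilson score interval for a binomial proportion (always inside [0, 1]
# and containing the point estimate).
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(max(0, centre - half), min(1, centre + half))
}

#' Sensitivity, specificity and predictive values with Wilson CIs
#'
#' The manual reading is the gold standard. A metric with a zero
#' denominator is reported as NA (undefined), never as 0 or 1. Cell
#' percentages are shares of n.
#'
#' @param counts Output of [confusion()] (or any list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return A data.frame with one row per metric (`sensitivity`,
#'   `specificity`, `ppv`, `npv`): `estimate`, `lo`, `hi`; plus attribute
#'   `"cells"` with per-cell counts and percent shares.
#' @export
diagnostic_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion table")
  one <- function(k, d) {
    if (d == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(k / d, wilson_ci(k, d))
  }
  m <- rbind(sensitivity = one(tp, tp + fn),
             specificity = one(tn, tn + fp),
             ppv = one(tp, tp + fp),
             npv = one(tn, tn + fn))
  out <- data.frame(metric = rownames(m), estimate = m[, 1],
                    lo = m[, 2], hi = m[, 3], row.names = NULL)
  cells <- data.frame(cell = c("tp", "fp", "tn", "fn"),
                      count = c(tp, fp, tn, fn),
                      percent = 100 * c(tp, fp, tn, fn) / n)
  attr(out, "cells") <- cells
  attr(out, "n") <- n
  out
}

#' Inter-reader agreement: Pearson r and Cohen's kappa
#'
#' @param qt1,qt2 Paired continuous QT values (>= 3 pairs for r).
#' @param lqt1,lqt2 Paired binary LQT flags (>= 2 pairs for kappa).
#' @return list(`pearson_r`, `kappa`); NA where undefined (zero variance,
#'   or expected agreement 1).
#' @export
agreement <- function(qt1, qt2, lqt1 = NULL, lqt2 = NULL) {
  r <- NA_real_
  if (!is.null(qt1) && !is.null(qt2)) {
    stopifnot(length(qt1) == length(qt2))
    if (length(qt1) < 3) stop("need >= 3 pairs for Pearson r")
    if (stats::sd(qt1) > 0 && stats::sd(qt2) > 0)
      r <- stats::cor(qt1, qt2)
  }
  kap <- NA_real_
  if (!is.null(lqt1) && !is.null(lqt2)) {
    stopifnot(length(lqt1) == length(lqt2))
    if (length(lqt1) < 2) stop("need >= 2 pairs for kappa")
    a <- as.logical(lqt1); b <- as.logical(lqt2)
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
    if (abs(1 - pe) > 1e-12) kap <- (po - pe) / (1 - pe)
  }
  list(pearson_r = r, kappa = kap)
}

#' Multivariate logistic regression for false-positive predictors
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of a binary outcome on
#' a pre-specified covariate set, with Wald 95% CIs and odds ratios.
#' Complete separation and non-convergence are detected and flagged; no
#' silent estimates.
#'
#' @param design data.frame of covariates (numeric or two-level).
#' @param outcome Logical (or 0/1) outcome with both classes present.
#' @param conf Confidence level for Wald intervals.
#' @return list(`table` — one row per coefficient: `term`, `coef`, `se`,
#'   `or`, `or_lo`, `or_hi`, `p` —, `converged`, `separation`).
#' @export
fit_logistic <- function(design, outcome, conf = 0.95) {
  outcome <- as.logical(outcome)
  stopifnot(is.data.frame(design), length(outcome) == nrow(design))
  if (nrow(design) <= ncol(design))
    stop("need more observations than covariates")
  if (length(unique(outcome)) < 2)
    stop("degenerate outcome: both classes required")
  dat <- cbind(design, .y = outcome)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(term = rownames(sm), coef = sm[, 1], se = sm[, 2],
                    or = exp(sm[, 1]),
                    or_lo = exp(sm[, 1] - z * sm[, 2]),
                    or_hi = exp(sm[, 1] + z * sm[, 2]),
                    p = sm[, 4], row.names = NULL)
  eps <- 1e-8
  separation <- any(abs(sm[, 1]) > 15) ||
    any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps)
  list(table = tab, converged = fit$converged, separation = separation)
}

#' Two-group comparison with the appropriate classical test
#'
#' Continuous covariates: two-sample Student t test. Categorical:
#' chi-square, switching to Fisher's exact test by Cochran's rule — any
#' expected cell count below 5, or a 2x2 table with fewer than 40
#' observations in total.
#'
#' @param x Covariate (numeric, or factor/character/logical).
#' @param group Two-level grouping vector.
#' @return list(`test`, `statistic`, `p`).
#' @export
compare_groups <- function(x, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("exactly two non-empty groups required")
  if (is.numeric(x)) {
    tt <- stats::t.test(x ~ group, var.equal = TRUE)
    return(list(test = "t", statistic = unname(tt$statistic), p = tt$p.value))
  }
  tab <- table(x, group)
  expected <- suppressWarnings(stats::chisq.test(tab)$expected)
  small_2x2 <- all(dim(tab) == 2) && sum(tab) < 40
  if (any(expected < 5) || small_2x2) {
    ft <- stats::fisher.test(tab)
    list(test = "fisher", statistic = NA_real_, p = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chisq", statistic = unname(ct$statistic), p = ct$p.value)
  }
}
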