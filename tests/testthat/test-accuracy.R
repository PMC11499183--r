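# Statistical layer: confusion tallies, Wilson intervals, agreement,
# logistic regression (against an independent likelihood optimizer) and
# the two-group comparison rules.

test_that("confusion tallies and rejects unknown categories", {
  cm <- confusion(c("TP", "FP", "TN", "TN", "FN", "TP"))
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 2); expect_equal(cm$fn, 1)
  expect_equal(cm$n, 6)
  expect_error(confusion(character(0)))
  expect_error(confusion(c("TP", "yes")))
})

test_that("diagnostic metrics match hand-computed values and Wilson bounds", {
  cm <- list(tp = 25, fp = 53, tn = 485, fn = 4)
  dm <- diagnostic_metrics(cm)
  est <- setNames(dm$estimate, dm$metric)
  expect_equal(unname(est["ppv"]), 25 / 78)
  expect_equal(unname(est["npv"]), 485 / 489)
  expect_equal(unname(est["sensitivity"]), 25 / 29)
  expect_equal(unname(est["specificity"]), 485 / 538)
  # Wilson interval properties: contains the estimate, inside [0, 1]
  expect_true(all(dm$lo <= dm$estimate & dm$estimate <= dm$hi))
  expect_true(all(dm$lo >= 0 & dm$hi <= 1))
  # binom.test is a sanity anchor: Wilson and Clopper-Pearson agree to ~2%
  cp <- stats::binom.test(25, 78)$conf.int
  ppv_row <- dm[dm$metric == "ppv", ]
  expect_lt(abs(ppv_row$lo - cp[1]), 0.03)
  expect_lt(abs(ppv_row$hi - cp[2]), 0.03)
  cells <- attr(dm, "cells")
  expect_equal(sum(cells$percent), 100)
  expect_equal(cells$count[cells$cell == "fp"], 53)
})

test_that("zero-denominator metrics are NA, never 0 or 1", {
  dm <- diagnostic_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(dm$estimate[dm$metric == "sensitivity"]))
  expect_true(is.na(dm$estimate[dm$metric == "ppv"]))
  expect_equal(dm$estimate[dm$metric == "specificity"], 1)
  expect_error(diagnostic_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)))
})

test_that("agreement: r and kappa on known configurations", {
  qt1 <- c(400, 420, 440, 460, 480)
  expect_equal(agreement(qt1, qt1 * 2 + 5)$pearson_r, 1)
  expect_equal(agreement(qt1, -qt1)$pearson_r, -1)
  expect_true(is.na(agreement(qt1, rep(400, 5))$pearson_r))
  # perfect binary agreement -> kappa 1; independence -> ~0
  a <- c(TRUE, TRUE, FALSE, FALSE)
  k <- agreement(NULL, NULL, a, a)$kappa
  expect_equal(k, 1)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(agreement(NULL, NULL, a, b)$kappa, 0)
  # all-same flags: expected agreement is 1, kappa undefined
  expect_true(is.na(agreement(NULL, NULL, rep(TRUE, 4), rep(TRUE, 4))$kappa))
  expect_error(agreement(1:2, 1:2), ">= 3")
})

test_that("kappa agrees with e1071's implementation", {
  set.seed(5)
  x <- stats::runif(300) < 0.3
  y <- ifelse(stats::runif(300) < 0.8, x, stats::runif(300) < 0.3)
  k_ours <- agreement(NULL, NULL, x, y)$kappa
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
  k_ref <- e1071::classAgreement(tab)$kappa
  expect_equal(k_ours, k_ref, tolerance = 1e-12)
})

test_that("logistic fit recovers known odds ratios and matches a direct MLE", {
  set.seed(7)
  n <- 4000
  x1 <- stats::runif(n) < 0.5
  x2 <- stats::rnorm(n)
  eta <- -2 + log(2.5) * x1 + 0.4 * x2
  y <- stats::runif(n) < stats::plogis(eta)
  fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  tab <- fit$table
  r1 <- tab[tab$term == "x1TRUE", ]
  expect_true(r1$or_lo < 2.5 && 2.5 < r1$or_hi)
  # independent oracle: direct likelihood maximization
  X <- cbind(1, x1, x2)
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(eta[y])
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(unname(tab$coef), unname(opt$par), tolerance = 1e-3)
})

test_that("separation and degenerate outcomes are flagged, not silently fit", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x == 1
  fit <- fit_logistic(data.frame(x = x), y)
  expect_true(fit$separation)
  expect_error(fit_logistic(data.frame(x = x), rep(TRUE, 40)), "degenerate")
  expect_error(fit_logistic(data.frame(a = 1:3, b = 4:6, c = 7:9),
                            c(TRUE, FALSE, TRUE)), "more observations")
})

test_that("compare_groups picks t, chi-square or Fisher by Cochran's rule", {
  set.seed(11)
  g <- rep(c("a", "b"), each = 100)
  x <- stats::rnorm(200) + (g == "b") * 0.5
  ct <- compare_groups(x, g)
  expect_equal(ct$test, "t")
  expect_equal(ct$p, stats::t.test(x ~ g, var.equal = TRUE)$p.value)
  # large balanced table -> chi-square
  cat_big <- rep(c(TRUE, FALSE), 100)
  cc <- compare_groups(cat_big, g)
  expect_equal(cc$test, "chisq")
  # 2x2 with n < 40 -> Fisher even when expected counts are exactly 5
  g2 <- rep(c("a", "b"), each = 10)
  x2 <- c(rep(TRUE, 10), rep(FALSE, 10))
  cf <- compare_groups(x2, g2)
  expect_equal(cf$test, "fisher")
  expect_equal(cf$p, stats::fisher.test(table(x2, g2))$p.value)
  expect_error(compare_groups(1:5, rep("a", 5)), "two")
})

test_that("t test maintains its nominal type-I error under the null", {
  set.seed(13)
  reps <- 2000
  p <- replicate(reps, {
    g <- rep(c("a", "b"), each = 15)
    compare_groups(stats::rnorm(30), g)$p
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})
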