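fake_profiles <- function(panel, exome, types = "lung") {
  data.frame(sample_id = sprintf("S%03d", seq_along(panel)),
             tumour_type = rep_len(types, length(panel)),
             exome_tmb = exome, P = panel,
             stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("confusion counts match a hand tabulation, ties counting as high", {
  pr <- fake_profiles(c(12, 8, 15, 3, 6), c(11, 9, 20, 2, 14))
  cm <- confusion_at_cutoff(pr, "P", 10)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 0, fn = 1, tn = 2))
  expect_equal(cm$misclassified_pct, cm$fp_pct + cm$fn_pct)
  expect_equal(cm$tp_pct + cm$fp_pct + cm$tn_pct + cm$fn_pct, 100)

  # cutoff 0: everything called high on both sides
  cm0 <- confusion_at_cutoff(pr, "P", 0)
  expect_equal(cm0$fp + cm0$fn, 0)
  expect_equal(cm0$tp, 5)

  # exact boundary counts as high
  cmb <- confusion_at_cutoff(fake_profiles(10, 10), "P", 10)
  expect_equal(cmb$tp, 1)

  expect_error(confusion_at_cutoff(pr, "nope", 10), "unknown panel")
})

test_that("confusion matches brute-force tabulation on random cohorts", {
  set.seed(7)
  for (rep in 1:5) {
    pr <- fake_profiles(rlnorm(200, log(8), 1), rlnorm(200, log(8), 1))
    for (co in c(5, 10, 20)) {
      cm <- confusion_at_cutoff(pr, "P", co)
      tab <- table(factor(pr$P >= co, c(TRUE, FALSE)),
                   factor(pr$exome_tmb >= co, c(TRUE, FALSE)))
      expect_equal(cm$tp, tab[1, 1])
      expect_equal(cm$fp, tab[1, 2])
      expect_equal(cm$fn, tab[2, 1])
      expect_equal(cm$tn, tab[2, 2])
      expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 200)
    }
  }
})

test_that("cutoff sweep covers each panel-cutoff pair and rejects empty cohorts", {
  pr <- fake_profiles(c(12, 8), c(11, 9))
  sw <- cutoff_sweep(pr, cutoffs = c(5, 10, 20, 40))
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$cutoff, c(5, 10, 20, 40))
  expect_error(cutoff_sweep(pr[0, ]), "empty cohort")
  # single-sample cohort: percentages are 0 or 100
  one <- cutoff_sweep(fake_profiles(12, 11), cutoffs = c(5, 40))
  expect_true(all(unlist(one[, grepl("_pct$", names(one))]) %in% c(0, 100)))
})

test_that("ROC endpoints: perfect separation gives AUC 1, pure ties give 0.5", {
  pr <- fake_profiles(c(1, 2, 8, 9, 12, 14), c(1, 2, 8, 15, 20, 30))
  r <- roc_curve(pr, "P", exome_cutoff = 10)
  expect_equal(r$auc, 1.0)
  expect_equal(r$optimal_cutpoint, 8.5)
  expect_equal(r$optimal_accuracy, 1.0)

  tied <- fake_profiles(rep(5, 10), c(rep(1, 5), rep(20, 5)))
  expect_equal(roc_curve(tied, "P", exome_cutoff = 10)$auc, 0.5)

  allpos <- fake_profiles(1:4, rep(20, 4))
  expect_error(roc_curve(allpos, "P"), "ROC undefined")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-count statistic", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(round(rlnorm(n, 2, 0.8), 1))  # rounding induces ties
    labels <- runif(n) < 0.4
    if (all(labels) || !any(labels)) next
    pr <- fake_profiles(scores, ifelse(labels, 100, 0))
    r <- roc_curve(pr, "P", exome_cutoff = 10)
    expect_equal(r$auc, bf_pair_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(21)
  scores <- round(rlnorm(80, 2, 1), 1)
  labels <- runif(80) < 0.35
  pr <- fake_profiles(scores, ifelse(labels, 100, 0))
  r <- roc_curve(pr, "P", exome_cutoff = 10)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("optimal cut-point maximizes accuracy with lowest-threshold ties and midpoint reporting", {
  opt <- optimal_cutpoint(c(1, 2, 8, 9, 12, 14),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(opt$cutpoint, 8.5)
  expect_equal(opt$accuracy, 1)

  # degenerate all-positive labels: threshold below the minimum score
  allpos <- optimal_cutpoint(c(3, 5, 9), c(TRUE, TRUE, TRUE))
  expect_lt(allpos$cutpoint, 3)
  expect_equal(allpos$accuracy, 1)

  # constructed tie: both 2.5 and 6.5 give accuracy 0.75; lowest wins
  tie <- optimal_cutpoint(c(1, 2, 3, 4, 5, 6, 7, 8),
                          c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                            TRUE, TRUE))
  expect_equal(tie$accuracy, 0.75)
  expect_equal(tie$cutpoint, 2.5)
})

test_that("optimal cut-point matches an exhaustive accuracy scan on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(20:100, 1)
    scores <- round(rlnorm(n, 2, 1), 1)
    labels <- runif(n) < 0.5
    opt <- optimal_cutpoint(scores, labels)
    best <- bf_best_accuracy(scores, labels)
    expect_equal(opt$accuracy, best)
    # the reported threshold actually achieves the optimum
    expect_equal(mean((scores >= opt$cutpoint) == labels), best)
  }
})

test_that("calibration tabulates per stratum and skips single-class strata with a warning", {
  pr <- rbind(fake_profiles(c(2, 3, 12, 15), c(1, 4, 13, 16), "lung"),
              fake_profiles(c(2, 3, 4, 5), c(1, 2, 3, 4), "breast"))
  expect_warning(cal <- calibrate_cutpoints(pr, panels = "P"),
                 "skipping stratum 'breast'")
  expect_setequal(cal$stratum, c("pan-cancer", "lung"))
  expect_true(all(cal$auc >= 0 & cal$auc <= 1))
})
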