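test_that("confusion counting follows the positive-is-high convention", {
  cm <- confusion(c(1, 0, 1), c(1, 1, 0))
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]), c(TP = 1, FP = 1,
                                                        FN = 1, TN = 0))
  perfect <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$FP + perfect$FN, 0)
  allneg <- confusion(c(1, 0, 1), c(0, 0, 0))
  expect_equal(allneg$TP + allneg$FP, 0)
  expect_error(confusion(integer(0), integer(0)),
               class = "subgrade_value_error")
  expect_error(confusion(c(1, 2), c(0, 1)), class = "subgrade_label_error")
})

test_that("metrics reproduce the printed diagnostic table from implied counts", {
  # biopsy arm: TP=1, FP=8, TN=9, FN=10 (n = 28, 17 low / 11 high)
  b <- diagnostic_metrics(confusion_counts(TP = 1, FP = 8, TN = 9, FN = 10))
  expect_equal(round(b$ACC, 2), 35.71)
  expect_equal(round(b$SEN, 2), 9.09)
  expect_equal(round(b$SPE, 2), 52.94)
  expect_equal(round(b$AUC, 1), 31.0)
  expect_equal(round(b$MCC, 2), -0.40)
  expect_equal(round(b$F1, 1), 0.1)
  expect_equal(round(b$McN_p, 2), 0.64)
  expect_equal(round(b$ACC_ci, 2), 17.75)
  expect_equal(round(b$SPE_ci, 2), 23.73)
  # internal-validation arm: TP=10, FN=1, FP=0, TN=17
  i <- diagnostic_metrics(confusion_counts(TP = 10, FP = 0, TN = 17, FN = 1))
  expect_equal(round(i$MCC, 2), 0.93)
  expect_equal(round(i$F1, 2), 0.95)
  expect_equal(round(i$McN_p, 2), 0.32)
  # all-correct limit
  p <- diagnostic_metrics(confusion_counts(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(p$MCC, 1)
  expect_equal(p$F1, 1)
  expect_equal(p$AUC, 100)
})

test_that("score-based AUC is the trapezoidal ROC area", {
  withr::with_seed(21, {
    y <- rep(c(0, 1), each = 25)
    s <- y + rnorm(50, sd = 0.8)
  })
  cm <- confusion(y, as.integer(s >= 0.5))
  m <- diagnostic_metrics(cm, scores = s, y_true = y)
  skip_if_not_installed("pROC")
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(m$AUC / 100, ref, tolerance = 1e-12)
})

test_that("McNemar follows the uncorrected discordant chi-square", {
  expect_equal(round(mcnemar_p(confusion_counts(1, 8, 9, 10)), 4), 0.6374)
  expect_equal(mcnemar_p(confusion_counts(5, 3, 5, 3)), 1) # FN == FP
  expect_equal(round(mcnemar_p(confusion_counts(10, 0, 17, 1)), 4), 0.3173)
  expect_equal(mcnemar_p(confusion_counts(5, 0, 5, 0)), 1) # no discordance
  # monotone in the statistic
  p_small <- mcnemar_p(confusion_counts(0, 2, 0, 4))
  p_large <- mcnemar_p(confusion_counts(0, 1, 0, 9))
  expect_gt(p_small, p_large)
})

test_that("chi-squared randomness tests behave at the extremes", {
  dep <- chi2_randomness_p(confusion_counts(20, 0, 20, 0))
  expect_lt(as.numeric(dep), 1e-8)
  uni <- chi2_randomness_p(confusion_counts(5, 5, 5, 5),
                           mode = "goodness_of_fit_uniform")
  expect_equal(as.numeric(uni), 1)
  # 2x2 association by hand for the biopsy-style matrix
  h <- chi2_randomness_p(confusion_counts(1, 8, 9, 10))
  expect_equal(round(as.numeric(h), 3), 0.036)
  expect_true(as.numeric(h) >= 0 && as.numeric(h) <= 1)
})

test_that("biopsy comparison maps indeterminate results against the reference", {
  rec <- data.frame(
    subject_id = sprintf("p%02d", 1:6),
    biopsy_grade = c("high", "low", "indeterminate", "indeterminate",
                     "low", "high"),
    nephrectomy_grade = c("high", "low", "high", "low", "high", "low"),
    stringsAsFactors = FALSE)
  ml <- setNames(c(1L, 0L, 1L, 0L, 1L, 0L), rec$subject_id)
  out <- biopsy_compare(rec, ml)
  # indeterminate + nephrectomy high scored low (an FN); and vice versa
  expect_equal(out$biopsy_labels[3], 0L)
  expect_equal(out$biopsy_labels[4], 1L)
  expect_equal(out$ml$ACC, 100)
  # perfect ML arm vs fallible biopsy arm
  expect_lt(out$biopsy$ACC, out$ml$ACC)
  # missing reference refused
  rec_bad <- rec
  rec_bad$nephrectomy_grade[2] <- NA
  expect_error(biopsy_compare(rec_bad, ml),
               class = "subgrade_reference_error")
})

test_that("clinical covariate tests detect configured group differences", {
  co <- generate_cohort(187, 107 / 187, seed = 30)
  st <- clinical_stats(co)
  expect_true(st$significant[st$variable == "tumour_size_cm"])
  expect_gt(st$rpb[st$variable == "tumour_size_cm"], 0)
  # identical group means: t-test cannot reject
  df <- co$subjects
  df$age_years <- rep(50, nrow(df))
  df$age_years <- df$age_years + rep_len(c(-1, 1), nrow(df))
  st2 <- clinical_stats(df)
  expect_gt(st2$p_value[st2$variable == "age_years"], 0.5)
  # a variable thresholded at its own median correlates with itself
  df2 <- co$subjects
  df2$grade_label <- as.integer(df2$tumour_size_cm >
                                  median(df2$tumour_size_cm))
  st3 <- clinical_stats(df2)
  expect_gt(st3$rpb[st3$variable == "tumour_size_cm"], 0.6)
  expect_error(clinical_stats(transform(co$subjects, grade_label = 1L)),
               class = "subgrade_test_error")
})

test_that("size differences at study-scale cohorts are routinely significant", {
  # power check by simulation at the configured effect sizes (n = 187)
  hits <- 0
  for (s in 1:10) {
    co <- generate_cohort(187, 107 / 187, seed = 100 + s)
    st <- clinical_stats(co)
    hits <- hits + st$significant[st$variable == "tumour_size_cm"]
  }
  expect_gte(hits, 9)
})

test_that("MCC is swap-invariant while F1 is not", {
  cm <- confusion_counts(TP = 30, FP = 10, TN = 5, FN = 2)
  m <- diagnostic_metrics(cm)
  swapped <- confusion_counts(TP = cm$TN, FP = cm$FN, TN = cm$TP,
                              FN = cm$FP)
  ms <- diagnostic_metrics(swapped)
  expect_equal(m$MCC, ms$MCC)
  expect_false(isTRUE(all.equal(m$F1, ms$F1)))
  # MCC sign equals the sign of TP*TN - FP*FN; zero-factor convention
  expect_lt(diagnostic_metrics(confusion_counts(1, 8, 9, 10))$MCC, 0)
  z <- diagnostic_metrics(confusion_counts(0, 0, 10, 5))
  expect_equal(z$MCC, 0)
  expect_true(z$MCC_zero_flag)
})
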