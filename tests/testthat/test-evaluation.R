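test_that("confusion counts and derived rates follow the malignant-positive convention", {
  cc <- confusion_counts(c(1, 1, 1, 1), c(1, 1, 1, 0))
  expect_equal(cc$TP, 3); expect_equal(cc$FN, 1)
  expect_equal(sensitivity(cc), 0.75)

  cc2 <- confusion_counts(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(cc2$FP + cc2$FN, 0)

  cc3 <- confusion_counts(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(sensitivity(cc3), 0)
  expect_equal(specificity(cc3), 1)

  # TN = FP -> specificity 0.5; FN = 0, TP > 0 -> sensitivity 1
  cc4 <- confusion_counts(c(0, 0, 1), c(0, 1, 1))
  expect_equal(specificity(cc4), 0.5)
  expect_equal(sensitivity(cc4), 1)

  # undefined rates are NA, never 0
  expect_true(is.na(sensitivity(confusion_counts(c(0, 0), c(0, 1)))))
  expect_true(is.na(specificity(confusion_counts(c(1, 1), c(0, 1)))))

  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "length")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("patient-level majority matches brute-force enumeration for 1-5 images", {
  for (n in 1:5) {
    patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    for (i in seq_len(nrow(patterns))) {
      v <- as.logical(patterns[i, ])
      out <- patient_level_correct(v)
      expect_identical(out$correct, sum(v) > n / 2)
      lenient <- patient_level_correct(v, strict = FALSE)
      expect_identical(lenient$correct, sum(v) >= n / 2)
    }
  }
  # the worked cases: 3/5 correct, 2/4 tie, 1/2 tie
  expect_true(patient_level_correct(c(TRUE, TRUE, TRUE, FALSE, FALSE))$correct)
  expect_false(patient_level_correct(c(TRUE, TRUE, FALSE, FALSE))$correct)
  expect_false(patient_level_correct(c(TRUE, FALSE))$correct)
  expect_error(patient_level_correct(logical(0)), "no images")
})

test_that("agreement categories partition patients into I/II/III", {
  m <- rbind(all = rep(TRUE, 6),
             half = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
             one = c(TRUE, rep(FALSE, 5)),
             none = rep(FALSE, 6))
  cat_ <- assign_agreement_category(m)
  expect_equal(unname(cat_), c("I", "II", "II", "III"))
  expect_error(assign_agreement_category(matrix(TRUE, 3, 1)), "2 raters")

  # partition property over random matrices
  set.seed(4)
  rm <- matrix(runif(68 * 6) > 0.4, 68, 6)
  cats <- assign_agreement_category(rm)
  expect_equal(length(cats), 68)
  expect_true(all(cats %in% c("I", "II", "III")))
  expect_equal(sum(table(cats)), 68)
})

test_that("misclassification percentages reproduce the published worked examples", {
  # all-observers percentage: 5 of 6 observers wrong on a single patient -> 83
  expect_equal(eq1_rater_misclass(5, 6, 1), 83L)
  expect_equal(eq1_rater_misclass(0, 6, 1), 0L)
  expect_equal(eq1_rater_misclass(1, 6, 2), 8L)  # 8.33 rounds to 8

  # per-classifier percentage
  expect_equal(eq2_classifier_misclass(1, 8), 13L)   # 12.5 rounds half-up
  expect_equal(eq2_classifier_misclass(2, 11), 18L)
  expect_equal(eq2_classifier_misclass(1, 4), 25L)
  expect_equal(eq2_classifier_misclass(0, 7), 0L)

  # all-classifiers percentage
  expect_equal(eq3_all_classifier_misclass(2, 4, 1), 50L)
  expect_equal(eq3_all_classifier_misclass(3, 4, 4), 19L)   # 18.75 -> 19
  expect_equal(eq3_all_classifier_misclass(3, 4, 11), 7L)   # 6.82 -> 7

  # eq2 equals eq3 with a single classifier
  for (k in 0:5) expect_equal(eq2_classifier_misclass(k, 5),
                              eq3_all_classifier_misclass(k, 1, 5))

  # range and integrality over a sweep
  for (n in 1:6) for (k in 0:n) {
    p <- eq2_classifier_misclass(k, n)
    expect_true(p >= 0 && p <= 100)
    expect_true(p == as.integer(p))
  }

  expect_error(eq1_rater_misclass(7, 6, 1), "out of range")
  expect_error(eq2_classifier_misclass(1, 0), "patient")

  # inversion recovers counts from printed percentages
  expect_equal(invert_eq2(13, 8), 1L)
  expect_equal(invert_eq2(100, 1), 1L)
  expect_equal(invert_eq2(0, 11), 0L)
  expect_error(invert_eq2(37, 4), "rounds to")
})

test_that("evaluate_predictions aggregates images to patients correctly", {
  truth <- data.frame(
    patient_id = rep(c("a", "b", "c"), times = c(5, 4, 2)),
    label = rep(c(1L, 0L, 1L), times = c(5, 4, 2)))
  pred <- c(1, 1, 1, 0, 0,   # a: 3/5 correct -> patient correct
            0, 0, 1, 1,      # b: 2/4 tie -> not correct (strict)
            0, 1)            # c: 1/2 tie -> not correct
  rep_ <- evaluate_predictions(truth, pred)
  expect_equal(rep_$patients$correct[rep_$patients$patient_id == "a"], TRUE)
  expect_equal(rep_$patients$correct[rep_$patients$patient_id == "b"], FALSE)
  expect_equal(rep_$patients$correct[rep_$patients$patient_id == "c"], FALSE)
  expect_equal(rep_$patient_accuracy, 1 / 3)
  expect_equal(rep_$confusion$TP, 4)
  expect_equal(rep_$confusion$TN, 2)

  lenient <- evaluate_predictions(truth, pred, strict = FALSE)
  expect_equal(lenient$patient_accuracy, 1)
})

test_that("the per-histopathology table assembles Eq percentages per group", {
  pats <- data.frame(
    patient_id = sprintf("p%d", 1:5),
    histopathology = c("Fibroma", "Hyperkeratosis", "Hyperkeratosis",
                       "Hyperkeratosis", "Hyperkeratosis"))
  cm <- cbind(C1 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
              C2 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
              C3 = c(FALSE, TRUE, TRUE, TRUE, FALSE),
              C4 = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  rm <- matrix(c(rep(FALSE, 5), rep(TRUE, 25)), 5, 6)  # col 1 all wrong
  tab <- misclassification_table(pats, cm, rm)
  fib <- tab[tab$histopathology == "Fibroma", ]
  expect_equal(fib$C3, 100L)
  expect_equal(fib$all_classifiers, 50L)
  hk <- tab[tab$histopathology == "Hyperkeratosis", ]
  expect_equal(hk$C1, 25L)
  expect_equal(hk$all_classifiers, 19L)
  expect_equal(fib$raters, eq1_rater_misclass(1, 6, 1))
})
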