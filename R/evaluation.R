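#' @name evaluation
#' @title Image- and patient-level evaluation
#' @description
#' Image-level performance uses the confusion matrix with malignant as the
#' positive class. Patient-level aggregation follows the majority rule: a
#' patient counts as correctly classified when strictly more than half of
#' the patient's images are classified correctly. Observer agreement splits
#' patients into category I (all observers correct), II (some correct) and
#' III (none correct). Per-histopathology misclassification percentages are
#' integer percents rounded half-up.
NULL

# round-half-up to integer (1/8 -> 12.5 -> 13), unlike base round()
round_half_up <- function(x) floor(x + 0.5)

#' Confusion counts with malignant (1) as positive class
#'
#' @param true_labels,predicted_labels Equal-length 0/1 vectors.
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  t <- as.integer(true_labels); p <- as.integer(predicted_labels)
  if (length(t) != length(p)) stop("label vectors differ in length")
  if (!all(c(t, p) %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(list(
    TP = sum(t == 1 & p == 1), TN = sum(t == 0 & p == 0),
    FP = sum(t == 0 & p == 1), FN = sum(t == 1 & p == 0)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (sens=%s, spec=%s)\n",
              x$TP, x$TN, x$FP, x$FN,
              format(sensitivity(x), digits = 3),
              format(specificity(x), digits = 3)))
  invisible(x)
}

#' Sensitivity TP/(TP+FN)
#'
#' Undefined (no positive cases) is reported as `NA`, never coerced to 0.
#' @param counts A `confusion_counts` object.
#' @return A fraction in `[0, 1]`, or `NA_real_`.
#' @export
sensitivity <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) NA_real_ else counts$TP / d
}

#' Specificity TN/(TN+FP)
#'
#' Undefined (no negative cases) is reported as `NA`.
#' @param counts A `confusion_counts` object.
#' @return A fraction in `[0, 1]`, or `NA_real_`.
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) NA_real_ else counts$TN / d
}

#' Patient-level majority aggregation
#'
#' A patient is correctly classified iff strictly more than half of the
#' patient's images are correct; with `strict = FALSE` an exact tie also
#' counts as correct (lenient reading, for sensitivity analysis).
#'
#' @param per_image_correct Logical vector, one entry per image.
#' @param strict Use the strict "> half" rule (default `TRUE`).
#' @return A list of class `patient_outcome`: `n_images`, `n_correct`,
#'   `correct`.
#' @export
patient_level_correct <- function(per_image_correct, strict = TRUE) {
  v <- as.logical(per_image_correct)
  if (!length(v)) stop("patient has no images")
  if (any(is.na(v))) stop("per-image correctness must not contain NA")
  n <- length(v); k <- sum(v)
  ok <- if (strict) k > n / 2 else k >= n / 2
  structure(list(n_images = n, n_correct = k, correct = ok),
            class = "patient_outcome")
}

#' Observer-agreement categories
#'
#' Category I: all raters classified the patient correctly; III: none did;
#' II: one to (n_raters - 1) did.
#'
#' @param rater_matrix Logical matrix, patients in rows, raters in columns
#'   (`TRUE` = that rater classified that patient correctly). At least 2
#'   raters.
#' @return Character vector (`"I"`, `"II"` or `"III"`), one per patient,
#'   named by rownames if present.
#' @export
assign_agreement_category <- function(rater_matrix) {
  m <- as.matrix(rater_matrix)
  if (ncol(m) < 2) stop("need at least 2 raters")
  if (any(is.na(m))) stop("rater matrix must not contain NA")
  k <- rowSums(m != 0)
  out <- ifelse(k == ncol(m), "I", ifelse(k == 0, "III", "II"))
  stats::setNames(out, rownames(m))
}

#' Misclassification percentage of all observers per patient
#'
#' `100 * n_misclassifications / (n_raters * n_patients)`, rounded half-up
#' to an integer percent.
#'
#' @param n_rater_misclassifications Total observer-patient misclassification
#'   count within the histopathology group.
#' @param n_raters Number of observers.
#' @param n_patients Number of patients in the group.
#' @return Integer percent in `[0, 100]`.
#' @export
eq1_rater_misclass <- function(n_rater_misclassifications, n_raters, n_patients) {
  if (n_raters < 1 || n_patients < 1) stop("need >= 1 rater and >= 1 patient")
  m <- n_rater_misclassifications
  if (m < 0 || m > n_raters * n_patients)
    stop("misclassification count out of range")
  as.integer(round_half_up(100 * m / (n_raters * n_patients)))
}

#' Misclassification percentage of one classifier per patient
#'
#' `100 * n_misclassified_patients / n_patients`, rounded half-up.
#'
#' @param n_misclassified_patients Patients the classifier got wrong.
#' @param n_patients Patients in the group.
#' @return Integer percent in `[0, 100]`.
#' @export
eq2_classifier_misclass <- function(n_misclassified_patients, n_patients) {
  if (n_patients < 1) stop("need >= 1 patient")
  m <- n_misclassified_patients
  if (m < 0 || m > n_patients) stop("misclassified count out of range")
  as.integer(round_half_up(100 * m / n_patients))
}

#' Misclassification percentage of all classifiers per patient
#'
#' `100 * n_pairs / (n_classifiers * n_patients)` where `n_pairs` counts
#' misclassified (patient, classifier) pairs; rounded half-up.
#'
#' @param n_misclassified_pairs Misclassified patient-classifier pairs.
#' @param n_classifiers Number of classifiers.
#' @param n_patients Patients in the group.
#' @return Integer percent in `[0, 100]`.
#' @export
eq3_all_classifier_misclass <- function(n_misclassified_pairs, n_classifiers,
                                        n_patients) {
  if (n_classifiers < 1 || n_patients < 1)
    stop("need >= 1 classifier and >= 1 patient")
  m <- n_misclassified_pairs
  if (m < 0 || m > n_classifiers * n_patients)
    stop("pair count out of range")
  as.integer(round_half_up(100 * m / (n_classifiers * n_patients)))
}

#' Recover the misclassified-patient count behind a printed percentage
#'
#' Inverts [eq2_classifier_misclass()]: finds the integer count `k` in
#' `0..n_patients` whose rounded percentage equals `percent` (the smallest
#' such `k` if several round identically).
#'
#' @param percent Printed integer percent.
#' @param n_patients Patients in the group.
#' @return Integer count of misclassified patients.
#' @export
invert_eq2 <- function(percent, n_patients) {
  ks <- 0:n_patients
  hit <- ks[vapply(ks, function(k)
    eq2_classifier_misclass(k, n_patients) == percent, logical(1))]
  if (!length(hit))
    stop("no patient count in 0..", n_patients, " rounds to ", percent, "%")
  hit[1L]
}

#' Image- and patient-level evaluation report
#'
#' @param truth data.frame with columns `patient_id` and `label` (0/1), one
#'   row per evaluated image.
#' @param predicted 0/1 vector aligned with `truth` rows.
#' @param strict Patient-level majority rule (see [patient_level_correct()]).
#' @return A list of class `evaluation_report`: `confusion`, `sensitivity`,
#'   `specificity`, `accuracy` (image level), `patients` (data.frame with
#'   per-patient `n_images`, `n_correct`, `correct`), and
#'   `patient_accuracy`.
#' @export
evaluate_predictions <- function(truth, predicted, strict = TRUE) {
  stopifnot(is.data.frame(truth), all(c("patient_id", "label") %in% names(truth)))
  p <- as.integer(predicted)
  if (length(p) != nrow(truth)) stop("predictions do not match truth rows")
  cc <- confusion_counts(truth$label, p)
  correct <- as.integer(truth$label) == p
  per_pat <- lapply(split(correct, truth$patient_id), patient_level_correct,
                    strict = strict)
  pats <- data.frame(
    patient_id = names(per_pat),
    n_images = vapply(per_pat, `[[`, numeric(1), "n_images"),
    n_correct = vapply(per_pat, `[[`, numeric(1), "n_correct"),
    correct = vapply(per_pat, `[[`, logical(1), "correct"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    confusion = cc,
    sensitivity = sensitivity(cc),
    specificity = specificity(cc),
    accuracy = mean(correct),
    patients = pats,
    patient_accuracy = mean(pats$correct)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "image level: acc %.3f, sens %s, spec %s | patient level: acc %.3f (%d/%d)\n",
    x$accuracy, format(x$sensitivity, digits = 3),
    format(x$specificity, digits = 3), x$patient_accuracy,
    sum(x$patients$correct), nrow(x$patients)))
  invisible(x)
}

#' Per-histopathology misclassification table
#'
#' Combines patient-level outcomes of several classifiers (and optionally an
#' observer matrix) into integer misclassification percentages per
#' histopathology group: one column per classifier
#' ([eq2_classifier_misclass()]), an all-classifiers column
#' ([eq3_all_classifier_misclass()]) and, if observers are given, an
#' all-observers column ([eq1_rater_misclass()]).
#'
#' @param patients data.frame with columns `patient_id`, `histopathology`.
#' @param classifier_correct Logical matrix, patients x classifiers
#'   (`TRUE` = patient correctly classified), rows aligned with `patients`.
#' @param rater_correct Optional logical matrix, patients x raters.
#' @return data.frame with one row per histopathology present.
#' @export
misclassification_table <- function(patients, classifier_correct,
                                    rater_correct = NULL) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "histopathology") %in% names(patients)))
  cm <- as.matrix(classifier_correct)
  if (nrow(cm) != nrow(patients)) stop("classifier matrix rows must match patients")
  ncl <- ncol(cm)
  cl_names <- colnames(cm)
  if (is.null(cl_names)) cl_names <- paste0("C", seq_len(ncl))
  groups <- unique(patients$histopathology)
  rows <- lapply(groups, function(g) {
    sel <- patients$histopathology == g
    np <- sum(sel)
    out <- list(histopathology = g, n_patients = np)
    if (!is.null(rater_correct)) {
      rm <- as.matrix(rater_correct)[sel, , drop = FALSE]
      out$raters <- eq1_rater_misclass(sum(!rm), ncol(rm), np)
    }
    per_cl <- vapply(seq_len(ncl), function(j)
      eq2_classifier_misclass(sum(!cm[sel, j]), np), integer(1))
    names(per_cl) <- cl_names
    out <- c(out, as.list(per_cl))
    out$all_classifiers <- eq3_all_classifier_misclass(sum(!cm[sel, ]), ncl, np)
    out
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
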