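#' Features for every image of a cohort
#'
#' Applies [image_features()] to each record of a manifest, reading images
#' from disk (paths resolved against `image_dir`) or from an in-memory list
#' keyed by `image_id`.
#'
#' @param manifest A `cenbi_manifest`.
#' @param images Optional named list of image matrices (keys = `image_id`);
#'   if `NULL`, images are loaded from `manifest$filepath`.
#' @param config A [pipeline_config()].
#' @param image_dir Directory that `filepath` entries are relative to.
#' @return A numeric matrix, one row per record (rownames = `image_id`),
#'   24 columns.
#' @export
cohort_features <- function(manifest, images = NULL,
                            config = pipeline_config(), image_dir = ".") {
  X <- matrix(NA_real_, nrow(manifest), 24,
              dimnames = list(manifest$image_id, feature_names()))
  for (i in seq_len(nrow(manifest))) {
    img <- if (!is.null(images)) images[[manifest$image_id[i]]]
    else load_image_gray(file.path(image_dir, manifest$filepath[i]),
                         channel = config$channel)
    if (is.null(img)) stop("no image for record ", manifest$image_id[i])
    X[i, ] <- image_features(img, config)
  }
  X
}

#' End-to-end classification experiment on a cohort
#'
#' Computes features for every image, applies the patient-wise train/test
#' split ([split_by_patient()]), trains each classifier on the training
#' images and evaluates it on the held-out test images at image and patient
#' level.
#'
#' @param cohort A `cenbi_cohort` from [generate_cohort()], or a list with
#'   elements `manifest` and either `images` or `out_dir`.
#' @param config A [pipeline_config()] with `seed` set (drives the split).
#' @param classifiers List of [classifier_spec()]s; defaults to the four
#'   tuned classifiers.
#' @param features Optional precomputed feature matrix from
#'   [cohort_features()] (rows aligned with the manifest).
#' @return A list of class `cohort_experiment`: `reports` (named list of
#'   [evaluate_predictions()] results per classifier), `manifest` (with the
#'   split applied), `features`.
#' @export
cohort_experiment <- function(cohort, config = pipeline_config(seed = 1L),
                              classifiers = default_classifiers(),
                              features = NULL) {
  manifest <- cohort$manifest
  if (is.null(features))
    features <- cohort_features(manifest, images = cohort$images,
                                config = config,
                                image_dir = if (is.null(cohort$out_dir)) "."
                                else cohort$out_dir)
  manifest <- split_by_patient(manifest, config)
  tr <- manifest$subset == "train"
  te <- manifest$subset == "test"
  if (!any(tr) || !any(te)) stop("split produced an empty train or test set")
  seed <- need_seed(config)
  reports <- list()
  for (spec in classifiers) {
    model <- fit_classifier(features[tr, , drop = FALSE],
                            manifest$label[tr], spec, seed = seed)
    pred <- predict(model, features[te, , drop = FALSE])
    reports[[spec$kind]] <- evaluate_predictions(
      manifest[te, c("patient_id", "label")], pred,
      strict = config$strict_majority)
  }
  structure(list(reports = reports, manifest = manifest, features = features),
            class = "cohort_experiment")
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat("cohort experiment:",
      sum(x$manifest$subset == "train"), "train /",
      sum(x$manifest$subset == "test"), "test images\n")
  for (nm in names(x$reports)) {
    cat(sprintf("  %-9s ", nm))
    print(x$reports[[nm]])
  }
  invisible(x)
}
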