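#' Histopathology groups of the CE-NBI dataset
#'
#' The 15 histological diagnoses of the study cohort with their lesion type
#' (benign vs (pre)malignant) and the published per-group patient and image
#' counts. The name set is the closed vocabulary accepted in dataset
#' manifests.
#'
#' @return A data.frame with columns `histopathology`, `lesion_type`
#'   (`"benign"` or `"malignant"`), `n_patients`, `n_images`.
#' @examples
#' tab <- histopathology_table()
#' sum(tab$n_patients)  # 68
#' sum(tab$n_images)    # 1632
#' @export
histopathology_table <- function() {
  data.frame(
    histopathology = c(
      "Cyst", "Polyp", "Reinke's edema", "Hyperkeratosis",
      "Squamous Hyperplasia", "Papillomatosis", "Amyloidosis", "Nodule",
      "Granuloma", "Fibroma",
      "Mild Dysplasia", "Moderate Dysplasia", "Severe Dysplasia",
      "Carcinoma In Situ", "SCC"),
    lesion_type = c(rep("benign", 10), rep("malignant", 5)),
    n_patients = c(3, 5, 12, 4, 3, 11, 2, 1, 1, 1, 3, 2, 3, 9, 8),
    n_images = c(90, 71, 329, 82, 75, 286, 32, 26, 28, 2,
                 77, 49, 68, 249, 168),
    stringsAsFactors = FALSE
  )
}

manifest_columns <- c("image_id", "patient_id", "filepath", "histopathology",
                      "lesion_type", "label", "subset")

validate_manifest <- function(df) {
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, manifest_columns, drop = FALSE]
  for (col in c("image_id", "patient_id", "filepath", "histopathology",
                "lesion_type", "subset"))
    df[[col]] <- as.character(df[[col]])
  df$label <- as.integer(df$label)
  if (nrow(df) == 0) return(structure(df, class = c("cenbi_manifest", "data.frame")))

  dup <- duplicated(df$image_id)
  if (any(dup))
    stop("duplicate image_id: ", paste(unique(df$image_id[dup]), collapse = ", "))

  tab <- histopathology_table()
  unknown <- !(df$histopathology %in% tab$histopathology)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf(
      "row %d: unknown histopathology \"%s\"; valid names are: %s",
      i, df$histopathology[i], paste(tab$histopathology, collapse = ", ")))
  }
  expected_type <- tab$lesion_type[match(df$histopathology, tab$histopathology)]
  bad_type <- df$lesion_type != expected_type
  if (any(bad_type)) {
    i <- which(bad_type)[1L]
    stop(sprintf("row %d: histopathology \"%s\" implies lesion_type \"%s\", got \"%s\"",
                 i, df$histopathology[i], expected_type[i], df$lesion_type[i]))
  }
  expected_label <- ifelse(df$lesion_type == "malignant", 1L, 0L)
  bad_label <- is.na(df$label) | df$label != expected_label
  if (any(bad_label)) {
    i <- which(bad_label)[1L]
    stop(sprintf("row %d: lesion_type \"%s\" requires label %d",
                 i, df$lesion_type[i], expected_label[i]))
  }
  bad_subset <- !(df$subset %in% c("train", "test", "unassigned"))
  if (any(bad_subset))
    stop("subset must be one of train/test/unassigned (row ",
         which(bad_subset)[1L], ")")
  per_pat <- split(df$histopathology, df$patient_id)
  inconsistent <- vapply(per_pat, function(h) length(unique(h)) > 1, logical(1))
  if (any(inconsistent))
    stop("patients with inconsistent histopathology: ",
         paste(names(per_pat)[inconsistent], collapse = ", "))
  structure(df, class = c("cenbi_manifest", "data.frame"))
}

#' Read and validate a dataset manifest
#'
#' The manifest is a UTF-8 comma-separated file with a mandatory header and
#' columns `image_id,patient_id,filepath,histopathology,lesion_type,label,subset`.
#' Validation enforces unique image ids, the closed histopathology vocabulary
#' of [histopathology_table()], agreement between histopathology, lesion type
#' and the 0/1 label (0 benign, 1 malignant), per-patient consistency, and a
#' subset value in `train`/`test`/`unassigned`.
#'
#' @param path Path to the CSV manifest.
#' @return A validated manifest (data.frame of class `cenbi_manifest`).
#' @seealso [write_manifest()], [split_by_patient()]
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  validate_manifest(df)
}

#' Write a dataset manifest to CSV
#'
#' @param manifest A validated manifest.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(as.data.frame(manifest))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct an in-memory manifest from a table of group counts
#'
#' Expands per-histopathology patient and image counts into one record per
#' image, with deterministic synthetic ids and file paths. With the default
#' `counts`, reproduces the bookkeeping of the study cohort: 68 patients and
#' 1632 images. Image counts are distributed over a group's patients as
#' evenly as possible (every patient receives at least 2 images).
#'
#' @param counts A data.frame like [histopathology_table()].
#' @return A validated `cenbi_manifest`.
#' @examples
#' m <- cohort_manifest()
#' nrow(m)                         # 1632
#' length(unique(m$patient_id))    # 68
#' @export
cohort_manifest <- function(counts = histopathology_table()) {
  rows <- vector("list", nrow(counts))
  pat_no <- 0L
  for (g in seq_len(nrow(counts))) {
    np <- counts$n_patients[g]
    ni <- counts$n_images[g]
    base <- ni %/% np
    extra <- ni %% np
    per_pat <- rep(base, np) + c(rep(1L, extra), rep(0L, np - extra))
    if (any(per_pat < 2))
      stop("group ", counts$histopathology[g],
           ": cannot give every patient >= 2 images")
    recs <- lapply(seq_len(np), function(p) {
      pid <- sprintf("p%02d", pat_no + p)
      n <- per_pat[p]
      data.frame(
        image_id = sprintf("%s_i%03d", pid, seq_len(n)),
        patient_id = pid,
        filepath = sprintf("images/%s_i%03d.png", pid, seq_len(n)),
        histopathology = counts$histopathology[g],
        lesion_type = counts$lesion_type[g],
        label = if (counts$lesion_type[g] == "malignant") 1L else 0L,
        subset = "unassigned",
        stringsAsFactors = FALSE)
    })
    pat_no <- pat_no + np
    rows[[g]] <- do.call(rbind, recs)
  }
  validate_manifest(do.call(rbind, rows))
}

#' Patient-wise train/test split
#'
#' For each patient with `n` images, `k = clamp(round(test_fraction * n), 2, 5)`
#' images are drawn without replacement into the test subset and the rest
#' into the training subset, reproducing a held-out series of two to five
#' images per patient (about 20% of the cohort by default). The draw is
#' deterministic given `config$seed`.
#'
#' @param manifest A validated manifest; every patient needs >= 2 images.
#' @param config A [pipeline_config()] with `seed` set.
#' @return The manifest with `subset` filled in (`"train"`/`"test"`).
#' @export
split_by_patient <- function(manifest, config = pipeline_config(seed = 1L)) {
  manifest <- validate_manifest(as.data.frame(manifest))
  seed <- need_seed(config)
  n_per <- table(manifest$patient_id)
  if (any(n_per < 2))
    stop("patients with fewer than 2 images cannot satisfy the 2-5 test-image rule: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  manifest$subset <- "train"
  set.seed(seed)
  for (pid in sort(unique(manifest$patient_id))) {
    idx <- which(manifest$patient_id == pid)
    n <- length(idx)
    k <- max(2L, min(5L, as.integer(round(config$test_fraction * n))))
    k <- min(k, n)
    test_idx <- if (k == n) idx else sample(idx, k)
    manifest$subset[test_idx] <- "test"
  }
  validate_manifest(manifest)
}
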