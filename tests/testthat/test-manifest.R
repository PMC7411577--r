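test_that("manifest round-trips through CSV and validates its invariants", {
  m <- cohort_manifest()
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_equal(as.data.frame(m2), as.data.frame(m))

  # header-only file gives an empty manifest
  writeLines(paste(c("image_id", "patient_id", "filepath", "histopathology",
                     "lesion_type", "label", "subset"), collapse = ","), f)
  expect_equal(nrow(read_manifest(f)), 0)
})

test_that("cohort bookkeeping reproduces the published totals", {
  m <- cohort_manifest()
  expect_equal(nrow(m), 1632)
  expect_equal(length(unique(m$patient_id)), 68)
  tab <- histopathology_table()
  per_group <- table(m$histopathology)
  expect_equal(unname(per_group[tab$histopathology]),
               as.table(setNames(tab$n_images, NULL)),
               ignore_attr = TRUE)
  # benign/malignant split of images
  expect_equal(sum(m$label == 0), sum(tab$n_images[tab$lesion_type == "benign"]))
})

test_that("manifest validation rejects malformed rows with informative errors", {
  m <- as.data.frame(cohort_manifest()[1:4, ])
  bad <- m; bad$image_id[2] <- bad$image_id[1]
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "duplicate image_id")

  bad <- m; bad$histopathology[3] <- "Papiloma"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "Papillomatosis")  # error lists valid names

  bad <- m; bad$label[1] <- 1L
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "requires label")

  bad <- m; bad$lesion_type[4] <- "malignant"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "implies lesion_type")
})

test_that("patient-wise split obeys the 2-5 rule, partitions, and is deterministic", {
  m <- cohort_manifest()
  cfg <- pipeline_config(seed = 7)
  s1 <- split_by_patient(m, cfg)
  s2 <- split_by_patient(m, cfg)
  expect_identical(s1$subset, s2$subset)
  expect_true(all(s1$subset %in% c("train", "test")))
  per_pat <- tapply(s1$subset == "test", s1$patient_id, sum)
  expect_true(all(per_pat >= 2 & per_pat <= 5))
  # total test size within [2*68, 5*68]
  expect_gte(sum(s1$subset == "test"), 136)
  expect_lte(sum(s1$subset == "test"), 340)
  # ~20% rule: clamp(round(0.2 n), 2, 5)
  n_per <- tapply(s1$patient_id, s1$patient_id, length)
  expect_equal(unname(per_pat),
               unname(pmin(pmax(round(0.2 * n_per), 2), 5)))

  # a patient with exactly 2 images contributes both to the test set
  two <- as.data.frame(m[m$patient_id %in% c("p01", "p02"), ])
  two <- rbind(two[two$patient_id == "p01", ][1:2, ], two[two$patient_id == "p02", ])
  s <- split_by_patient(two, cfg)
  expect_equal(sum(s$subset[s$patient_id == "p01"] == "test"), 2)
  expect_equal(sum(s$subset[s$patient_id == "p01"] == "train"), 0)

  # a patient with 30 images gets the clamped maximum of 5
  big <- as.data.frame(m[m$patient_id == "p03", ])[1:30, ]
  big$patient_id <- "pbig"
  big$image_id <- sprintf("pbig_%02d", 1:30)
  both <- rbind(big, as.data.frame(m[m$patient_id == "p04", ]))
  s <- split_by_patient(both, cfg)
  expect_equal(sum(s$subset[s$patient_id == "pbig"] == "test"), 5)

  # single-image patients are rejected
  one <- as.data.frame(m[1, ])
  expect_error(split_by_patient(rbind(one, as.data.frame(m[m$patient_id == "p02", ])), cfg),
               "fewer than 2 images")
})

test_that("grayscale loading uses the green channel and preserves shape", {
  tdir <- withr::local_tempdir()
  # RGB image with distinct channels
  arr <- array(0, c(20, 30, 3))  # EBImage order: x (cols), y (rows)
  arr[, , 1] <- 0.9
  arr[, , 2] <- matrix(seq(0, 1, length.out = 20 * 30), 20, 30)
  arr[, , 3] <- 0.1
  f <- file.path(tdir, "rgb.png")
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), f)
  g <- load_image_gray(f, channel = "green")
  expect_equal(dim(g), c(30, 20))  # rows x cols
  expect_equal(max(abs(g - t(arr[, , 2]))), 0, tolerance = 0.005)
  lum <- load_image_gray(f, channel = "luminance")
  expect_equal(lum[1, 1], 0.299 * 0.9 + 0.587 * arr[1, 1, 2] + 0.114 * 0.1,
               tolerance = 0.01)

  # all-black image -> all-zero field
  fz <- file.path(tdir, "black.png")
  EBImage::writeImage(EBImage::Image(matrix(0, 15, 10)), fz)
  expect_true(all(load_image_gray(fz) == 0))

  # grayscale round trip up to 8-bit quantization
  m <- matrix(seq(0, 1, length.out = 300), 15, 20)
  fg <- file.path(tdir, "gray.png")
  write_image_gray(m, fg)
  expect_lt(max(abs(load_image_gray(fg) - m)), 1 / 255)

  expect_error(load_image_gray(file.path(tdir, "missing.png")), "not found")
})

test_that("config validation catches inconsistent parameters", {
  expect_error(pipeline_config(sigmas = c(2, 1)), "increasing")
  expect_error(pipeline_config(tau = 0), "tau")
  expect_error(pipeline_config(hysteresis_low = 0.5, hysteresis_high = 0.2),
               "hysteresis")
  expect_error(pipeline_config(smooth_window = 4), "odd")
  cfg <- pipeline_config(seed = 3)
  expect_s3_class(cfg, "cenbi_config")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tau: 0.5", "seed: 11", "hysteresis_high: 0.3"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$tau, 0.5)
  expect_equal(cfg2$seed, 11L)
  expect_equal(cfg2$sigmas, c(0.5, 1, 1.5, 2, 2.5))
  writeLines("nonsense_key: 1", f)
  expect_error(read_config(f), "unknown config key")
})
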