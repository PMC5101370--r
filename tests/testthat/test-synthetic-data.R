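# Synthetic cohort generator: structure, determinism, difficulty scaling,
# disk round trip.

test_that("cohort spec validation rejects malformed parameters", {
  expect_error(cohort_spec(difficulty = 1.2), "difficulty")
  expect_error(cohort_spec(difficulty = -0.1), "difficulty")
  expect_error(cohort_spec(n_patients = -1), "n_patients")
  expect_error(cohort_spec(n_patients = 10, n_images = 5), "n_images")
  expect_error(cohort_spec(image_size = 4), "image_size")
  expect_error(cohort_spec(texture_params = list(
    healthy = list(density = 1, radius_mean = 1, radius_sd = 1,
                   elongation = 0.5, contrast = 0.1),
    abnormal = default_texture_params()$abnormal)), "elongation")
})

test_that("zero patients give an empty cohort with empty metadata", {
  co <- generate_cohort(cohort_spec(n_patients = 0, n_images = NULL,
                                    images_per_patient = c(1, 2)))
  expect_s3_class(co, "polyp_cohort")
  expect_length(co$images, 0)
  expect_identical(nrow(co$metadata), 0L)
})

test_that("a 62-patient, 100-image spec yields exactly that structure", {
  co <- generate_cohort(cohort_spec(n_patients = 62, n_images = 100,
                                    image_size = 32, seed = 5))
  expect_identical(nrow(co$metadata), 100L)
  expect_identical(length(unique(co$metadata$patient_id)), 62L)
  expect_true(all(table(co$metadata$patient_id) >= 1))
  expect_setequal(unique(co$metadata$label), c(0L, 1L))
})

test_that("generation is bit-reproducible and images satisfy invariants", {
  spec <- cohort_spec(n_patients = 4, n_images = 8, image_size = 24,
                      seed = 11)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$images, co2$images)
  for (img in co1$images) {
    expect_identical(dim(img$pixels), c(24L, 24L, 3L))
    expect_true(all(is.finite(img$pixels)))
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  }
  expect_false(anyDuplicated(co1$metadata$image_id) > 0)
})

test_that("switching nuisances off changes pixels but never metadata", {
  base <- cohort_spec(n_patients = 3, n_images = 6, image_size = 24,
                      seed = 21)
  clean <- base
  clean$nuisance <- list(illumination = 0, blur_sigma = c(0, 0),
                         specular = c(0, 0))
  co_n <- generate_cohort(base)
  co_c <- generate_cohort(clean)
  expect_identical(co_n$metadata, co_c$metadata)
  expect_false(identical(co_n$images[[1]]$pixels, co_c$images[[1]]$pixels))
})

test_that("extending a cohort never reshuffles earlier patients' images", {
  s1 <- cohort_spec(n_patients = 3, n_images = 6, image_size = 24, seed = 33)
  s2 <- cohort_spec(n_patients = 4, n_images = 8, image_size = 24, seed = 33)
  co1 <- generate_cohort(s1)
  co2 <- generate_cohort(s2)
  expect_identical(co1$images[[1]]$pixels, co2$images[[1]]$pixels)
})

test_that("difficulty 0 is blob-separable; difficulty 1 is near chance", {
  # oracle: brute-force blob segmentation, independent of the renderer
  co0 <- generate_cohort(cohort_spec(n_patients = 10, n_images = 40,
                                     image_size = 128,
                                     class_assignment = 0.5,
                                     difficulty = 0, seed = 42))
  st0 <- vapply(co0$images, function(im) blob_elongation_stat(im$pixels), 0)
  lab0 <- co0$metadata$label
  expect_true(all(table(lab0) > 5))
  # some threshold classifies all images correctly
  expect_lt(max(st0[lab0 == 0]), min(st0[lab0 == 1]))

  co1 <- generate_cohort(cohort_spec(n_patients = 25, n_images = 200,
                                     image_size = 128,
                                     class_assignment = 0.5,
                                     difficulty = 1, seed = 42))
  st1 <- vapply(co1$images, function(im) blob_elongation_stat(im$pixels), 0)
  lab1 <- co1$metadata$label
  thr <- mean(tapply(st1, lab1, mean))
  acc <- mean((st1 > thr) == (lab1 == 1))
  expect_lte(acc, 0.65)
})

test_that("write/read round trip preserves metadata and 8-bit pixels", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_patients = 2, n_images = 3,
                                    image_size = 24, seed = 9))
  write_cohort(co, dir)
  expect_identical(sort(list.files(dir, pattern = "png$")),
                   sort(paste0(co$metadata$image_id, ".png")))
  back <- read_cohort(dir)
  expect_identical(back$metadata, co$metadata)
  for (i in seq_along(co$images))
    expect_lte(max(abs(back$images[[i]]$pixels - co$images[[i]]$pixels)),
               1 / 255)
})

test_that("an empty cohort writes a header-only manifest and no PNGs", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_patients = 0, n_images = NULL,
                                    images_per_patient = c(1, 1)))
  write_cohort(co, dir)
  expect_length(list.files(dir, pattern = "png$"), 0)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_identical(nrow(meta), 0L)
  expect_setequal(names(meta),
                  c("image_id", "patient_id", "label", "modality"))
})

test_that("read_cohort flags missing files and duplicate ids", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_patients = 2, n_images = 3,
                                    image_size = 24, seed = 10))
  write_cohort(co, dir)
  file.remove(file.path(dir, paste0(co$metadata$image_id[2], ".png")))
  expect_error(read_cohort(dir), co$metadata$image_id[2])

  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  meta <- read.csv(file.path(dir2, "metadata.csv"),
                   colClasses = c(image_id = "character",
                                  patient_id = "character"))
  meta$image_id[2] <- meta$image_id[1]
  write.csv(meta, file.path(dir2, "metadata.csv"), row.names = FALSE)
  expect_error(read_cohort(dir2), "duplicate")
})
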