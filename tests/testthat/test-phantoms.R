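test_that("grade bins partition coverage and map back bijectively", {
  b <- grade_bin(0:3)
  expect_equal(b[1, ], c(lower = 0, upper = 0))
  expect_equal(b[4, ], c(lower = 0.66, upper = 1))
  # bins tile (0, 1]
  expect_equal(b[-1, "lower"], c(0, 0.33, 0.66))
  expect_equal(b[-4, "upper"][-1], c(0.33, 0.66))
  expect_error(grade_bin(4), class = "cxr_input_error")
})

test_that("clear lungs realize exactly zero coverage", {
  ph <- generate_phantom(0, 0, image_size = 64, seed = 3)
  expect_identical(ph$truth$left_fraction, 0)
  expect_identical(ph$truth$right_fraction, 0)
})

test_that("realized coverage lies in the requested bin for every grade and seed", {
  for (g in 0:3) {
    bin <- grade_bin(g)
    for (s in 1:20) {
      ph <- generate_phantom(g, 0, image_size = 64, seed = 100 * g + s)
      f <- ph$truth$left_fraction
      if (g == 0) expect_identical(f, 0)
      else expect_true(f > bin[1] && f <= bin[2],
                       label = sprintf("grade %d seed %d fraction %.3f",
                                       g, s, f))
    }
  }
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_phantom(2, 1, image_size = 64, noise_sigma = 0.05, seed = 9)
  b <- generate_phantom(2, 1, image_size = 64, noise_sigma = 0.05, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("lung masks are disjoint, sized, and lateralized in patient coordinates", {
  ph <- generate_phantom(1, 2, image_size = 128, seed = 4)
  t <- ph$truth
  expect_false(any(t$left_mask & t$right_mask))
  expect_gte(sum(t$left_mask) / 128^2, 0.05)
  expect_gte(sum(t$right_mask) / 128^2, 0.05)
  # patient-left lung renders on the viewer-right half
  expect_gt(mean(which(t$left_mask, arr.ind = TRUE)[, 2]), 64)
  expect_lt(mean(which(t$right_mask, arr.ind = TRUE)[, 2]), 64)
})

test_that("artifact renderings behave as flagged", {
  base <- generate_phantom(1, 1, image_size = 64, seed = 5)
  neg <- generate_phantom(1, 1, image_size = 64, seed = 5,
                          artifact_flags = "negative")
  expect_equal(neg$image, 1 - base$image, tolerance = 1e-12)
  doc <- generate_phantom(0, 0, image_size = 64, seed = 5,
                          artifact_flags = "document")
  expect_false(any(doc$truth$left_mask))
  expect_true(is.na(doc$truth$left_fraction))
})

test_that("invalid phantom specs are rejected", {
  expect_error(generate_phantom(1, 1, image_size = 32),
               class = "cxr_input_error")
  expect_error(generate_phantom(1, 1, noise_sigma = -0.1),
               class = "cxr_input_error")
})

test_that("cohort generation honors artifact rates, priors, and uniqueness", {
  expect_error(generate_cohort(0), class = "cxr_input_error")
  clean <- generate_cohort(1, seed = 8)
  expect_gte(nrow(clean), 1)
  expect_equal(length(unique(clean$patient_id)), 1)
  expect_true(all(clean$artifact == ""))
  # rows unique on (patient, accession, time)
  man <- meta_cohort(60, seed = 21)
  key <- paste(man$patient_id, man$accession_id, man$acquisition_time)
  expect_false(anyDuplicated(key) > 0)
  # grade marginals approach uniform priors at n = 400 patients
  big <- generate_cohort(400, class_priors = rep(0.25, 4), seed = 30)
  for (col in c("left_grade", "right_grade")) {
    p <- as.vector(table(factor(big[[col]], 0:3))) / nrow(big)
    expect_true(all(abs(p - 0.25) < 0.08), label = col)
  }
  # artifact injection produces flagged rows of every requested kind
  art <- generate_cohort(80, artifact_rates = list(duplicate_copy = 0.2,
                                                   negative = 0.1,
                                                   document = 0.1,
                                                   filtered = 0.1,
                                                   pediatric = 0.2),
                         seed = 31)
  expect_true(all(c("duplicate_copy", "negative", "document", "filtered")
                  %in% art$artifact))
  expect_gt(sum(art$age < 18), 0)
})

test_that("manifest round-trips through CSV without field loss", {
  man <- generate_cohort(15, artifact_rates = list(missing_time = 0.2),
                         seed = 44)
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(names(back), names(man))
  expect_identical(back$patient_id, man$patient_id)
  expect_identical(back$left_grade, man$left_grade)
  expect_identical(is.na(back$acquisition_time),
                   is.na(man$acquisition_time))
  expect_equal(back$age, man$age)
})
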