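mk_rows <- function(times, acc = "A1", pid = "P1") {
  data.frame(patient_id = pid, accession_id = acc,
             acquisition_time = times, age = 40, sex = "F",
             race = "White", patient_status = "IP",
             covid_status = "negative", view = "AP",
             left_grade = 1L, right_grade = 0L, image_path = "",
             artifact = "", stringsAsFactors = FALSE)
}

test_that("deduplication keeps the earliest acquisition per accession", {
  one <- mk_rows("2020-04-01 10:00:00")
  expect_equal(nrow(deduplicate_by_accession(one)$manifest), 1)

  three <- mk_rows(c("2020-04-01 12:00:00", "2020-04-01 10:00:00",
                     "2020-04-01 11:00:00"))
  dd <- deduplicate_by_accession(three)
  expect_equal(nrow(dd$manifest), 1)
  expect_equal(dd$manifest$acquisition_time, "2020-04-01 10:00:00")
  expect_equal(dd$report$duplicates_removed, 2)
})

test_that("ten rows over four accessions (3,3,2,2) leave four survivors", {
  rows <- rbind(
    mk_rows(sprintf("2020-04-01 %02d:00:00", 1:3), acc = "A1"),
    mk_rows(sprintf("2020-04-01 %02d:00:00", 4:6), acc = "A2"),
    mk_rows(sprintf("2020-04-01 %02d:00:00", 7:8), acc = "A3"),
    mk_rows(sprintf("2020-04-01 %02d:00:00", 9:10), acc = "A4"))
  dd <- deduplicate_by_accession(rows)
  expect_equal(nrow(dd$manifest), 4)
  expect_equal(dd$report$duplicates_removed, 6)
})

test_that("missing acquisition times route to read errors", {
  rows <- mk_rows(c(NA, NA))
  dd <- deduplicate_by_accession(rows)
  expect_equal(nrow(dd$manifest), 0)
  expect_equal(dd$report$read_error_removed, 2)
  # strict mode discards multi-time accessions entirely
  multi <- mk_rows(c("2020-04-01 10:00:00", "2020-04-01 11:00:00"))
  st <- deduplicate_by_accession(multi, strict = TRUE)
  expect_equal(nrow(st$manifest), 0)
  expect_equal(st$report$read_error_removed, 2)
})

test_that("exclusion rules remove the right rows and reconcile", {
  empty <- mk_rows("2020-04-01 10:00:00")[0, ]
  r0 <- apply_exclusions(empty)
  expect_equal(nrow(r0$manifest), 0)
  expect_true(all(unlist(r0$report) == 0))

  rows <- rbind(mk_rows("2020-04-01 10:00:00", acc = "A1", pid = "P1"),
                mk_rows("2020-04-01 10:00:00", acc = "A2", pid = "P2"),
                mk_rows("2020-04-01 10:00:00", acc = "A3", pid = "P3"),
                mk_rows("2020-04-01 10:00:00", acc = "A4", pid = "P4"),
                mk_rows("2020-04-01 10:00:00", acc = "A5", pid = "P5"))
  rows$age[1] <- 17
  rows$artifact[2] <- "document"
  res <- apply_exclusions(rows)
  expect_equal(nrow(res$manifest), 3)
  expect_equal(res$report$pediatric_removed, 1)
  expect_equal(res$report$documents_removed, 1)
  # conservation: every input row accounted for exactly once
  rep <- res$report
  removed <- rep$duplicates_removed + rep$documents_removed +
    rep$read_error_removed + rep$pediatric_removed + rep$filtered_removed
  expect_equal(nrow(rows), rep$surviving_images + removed)
  # age exactly 18 is retained
  r18 <- mk_rows("2020-04-01 10:00:00")
  r18$age <- 18
  expect_equal(nrow(apply_exclusions(r18)$manifest), 1)
})

test_that("negatives are inverted in place, not removed, and inversion is an involution", {
  dir <- tempfile(); dir.create(dir)
  ph <- generate_phantom(1, 2, image_size = 64, seed = 50)
  path <- file.path(dir, "img.png")
  cxrgrade:::write_gray_png(1 - ph$image, path)  # store the negative
  rows <- mk_rows("2020-04-01 10:00:00")
  rows$image_path <- path
  rows$artifact <- "negative"
  res <- apply_exclusions(rows)
  expect_equal(nrow(res$manifest), 1)
  expect_equal(res$report$negatives_transformed, 1)
  restored <- read_gray_png(path)
  expect_equal(restored, cxrgrade:::quantize8(ph$image), tolerance = 1e-6)
  # inverting twice returns the original pixels
  cxrgrade:::invert_png_in_place(path)
  cxrgrade:::invert_png_in_place(path)
  expect_equal(read_gray_png(path), restored, tolerance = 1e-12)
  # heuristic flags a border-bright image as negative
  expect_true(cxrgrade:::looks_negative(1 - ph$image))
  expect_false(cxrgrade:::looks_negative(ph$image))
})

test_that("unreadable image files route to read errors without crashing", {
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  rows <- mk_rows("2020-04-01 10:00:00")
  rows$image_path <- bad
  res <- apply_exclusions(rows)
  expect_equal(nrow(res$manifest), 0)
  expect_equal(res$report$read_error_removed, 1)
})

test_that("the full preparation pipeline is idempotent on a cleaned cohort", {
  man <- generate_cohort(40, artifact_rates = list(duplicate_copy = 0.3,
                                                   document = 0.1,
                                                   filtered = 0.1,
                                                   pediatric = 0.15,
                                                   missing_time = 0.05),
                         seed = 60)
  first <- prepare_cohort(man)
  rep <- first$report
  removed <- rep$duplicates_removed + rep$documents_removed +
    rep$read_error_removed + rep$pediatric_removed + rep$filtered_removed
  expect_equal(nrow(man), rep$surviving_images + removed)
  second <- prepare_cohort(first$manifest)
  expect_equal(nrow(second$manifest), nrow(first$manifest))
  srep <- second$report
  expect_equal(srep$duplicates_removed + srep$documents_removed +
                 srep$read_error_removed + srep$pediatric_removed +
                 srep$filtered_removed, 0)
  # report serializes to JSON
  path <- tempfile(fileext = ".json")
  write_exclusion_report(rep, path)
  expect_equal(jsonlite::read_json(path)$surviving_images,
               rep$surviving_images)
})
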