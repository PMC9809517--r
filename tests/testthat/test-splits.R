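test_that("patient-level splits have zero leakage and exact counts", {
  man <- meta_cohort(100, seed = 5)
  # pad so every patient has one image row count
  fs <- make_patient_splits(man, oob_n_images = 0, ratios = c(0.8, 0.1, 0.1),
                            n_folds = 5, seed = 1)
  for (f in seq_along(fs$folds)) {
    parts <- fs$folds[[f]]
    expect_equal(length(intersect(parts$train, parts$val)), 0)
    expect_equal(length(intersect(parts$train, parts$test)), 0)
    expect_equal(length(intersect(parts$val, parts$test)), 0)
    expect_setequal(c(parts$train, parts$val, parts$test),
                    unique(man$patient_id))
  }
  expect_equal(length(fs$folds[[1]]$train), 80)
  expect_equal(length(fs$folds[[1]]$val), 10)
  expect_equal(length(fs$folds[[1]]$test), 10)
})

test_that("the OOB hold-out is drawn by whole patients to an image quota", {
  man <- meta_cohort(120, seed = 6)
  fs <- make_patient_splits(man, oob_n_images = 25, seed = 2)
  oob_imgs <- sum(man$patient_id %in% fs$oob)
  expect_gte(oob_imgs, 25)
  for (f in seq_along(fs$folds))
    expect_equal(length(intersect(fs$oob,
                                  unlist(fs$folds[[f]]))), 0)
  # deterministic given the seed
  fs2 <- make_patient_splits(man, oob_n_images = 25, seed = 2)
  expect_identical(fs, fs2)
  expect_error(make_patient_splits(man, ratios = c(0.7, 0.1, 0.1)),
               class = "cxr_input_error")
  expect_error(make_patient_splits(man[1:5, ]), class = "cxr_input_error")
})

test_that("fold sets round-trip through JSON", {
  man <- meta_cohort(40, seed = 7)
  fs <- make_patient_splits(man, oob_n_images = 5, n_folds = 2, seed = 3)
  path <- tempfile(fileext = ".json")
  write_fold_set(fs, path)
  back <- read_fold_set(path)
  expect_setequal(back$oob, fs$oob)
  expect_setequal(back$folds[[2]]$test, fs$folds[[2]]$test)
})

test_that("undersampling equalizes to the minority class count", {
  man <- meta_cohort(200, seed = 8)
  plan <- balance_classes(man, "UNDER", "left_grade", seed = 4)
  counts <- table(plan$stage1$left_grade)
  expect_true(all(counts == min(table(man$left_grade))))
  expect_null(plan$stage2)
  expect_true(all(!plan$stage1$synthetic))
})

test_that("oversampling reaches the majority count with synthetic-flagged rows", {
  man <- meta_cohort(200, seed = 9)
  plan <- balance_classes(man, "OVER", "right_grade", seed = 5)
  counts <- table(plan$stage1$right_grade)
  maj <- max(table(man$right_grade))
  expect_true(all(counts == maj))
  expect_equal(sum(plan$stage1$synthetic), 4 * maj - nrow(man))
  syn <- plan$stage1[plan$stage1$synthetic, ]
  expect_true(all(c("aug_rotation", "aug_scale", "aug_tx", "aug_ty")
                  %in% names(syn)))
  expect_true(all(abs(syn$aug_rotation) <= 10))
  expect_true(all(syn$aug_scale >= 0.9 & syn$aug_scale <= 1.1))
  # synthetic rows keep their source's label and patient id
  expect_true(all(syn$patient_id %in% man$patient_id))
})

test_that("double-stage balancing pairs an undersampled stage 1 with the full set", {
  man <- meta_cohort(150, seed = 10)
  plan <- balance_classes(man, "DOUBLE", "left_grade", seed = 6)
  expect_true(all(table(plan$stage1$left_grade) ==
                    min(table(man$left_grade))))
  expect_equal(nrow(plan$stage2), nrow(man))
  expect_true(all(plan$stage2$stage == 2))
  path <- tempfile(fileext = ".csv")
  write_training_plan(plan, path)
  both <- read.csv(path)
  expect_setequal(unique(both$stage), c(1, 2))
})

test_that("a class with zero rows is rejected by name", {
  man <- meta_cohort(30, seed = 11)
  man <- man[man$left_grade != 3, ]
  expect_error(balance_classes(man, "UNDER", "left_grade"),
               "class 3", class = "cxr_input_error")
})

test_that("augmented images differ pixelwise from their source", {
  ph <- generate_phantom(2, 2, image_size = 64, seed = 12)
  aug <- augment_image(ph$image, rotation = 5, scale = 1.05,
                       translate = c(0.02, -0.03))
  expect_equal(dim(aug), dim(ph$image))
  expect_gt(mean(abs(aug - ph$image)), 0)
})

test_that("balancing is per lung side", {
  man <- meta_cohort(150, seed = 13)
  pl <- balance_classes(man, "UNDER", "left_grade", seed = 7)
  pr <- balance_classes(man, "UNDER", "right_grade", seed = 7)
  expect_true(all(table(pl$stage1$left_grade) ==
                    min(table(man$left_grade))))
  expect_true(all(table(pr$stage1$right_grade) ==
                    min(table(man$right_grade))))
})
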