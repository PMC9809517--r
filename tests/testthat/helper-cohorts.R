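# Shared fixtures, built once per test run and cached in this environment.
# Phantom cohorts are generated at 64 px so the compiled backend trains in
# seconds; the phantom geometry itself is identical at every resolution.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 600-image phantom cohort with images on disk (the learnability corpus)
learn_cohort <- function() {
  memo("learn_cohort", {
    dir <- file.path(tempdir(), "cxrgrade-learn-cohort")
    generate_cohort(420, dir = dir, image_size = 64,
                    mean_extra_accessions = 0.45, seed = 2024)
  })
}

# small cohort with images, for segmentation / loader / e2e tests
small_cohort <- function() {
  memo("small_cohort", {
    dir <- file.path(tempdir(), "cxrgrade-small-cohort")
    generate_cohort(90, dir = dir, image_size = 64,
                    mean_extra_accessions = 0.6, seed = 77)
  })
}

# metadata-only manifest (no files) for split/balance logic
meta_cohort <- function(n_patients = 80, seed = 5) {
  generate_cohort(n_patients, seed = seed,
                  mean_extra_accessions = 0.5)
}

phantom_pairs <- function(n, target = c("lungs", "spine"), seed0 = 300) {
  target <- match.arg(target)
  imgs <- list(); masks <- list()
  for (i in seq_len(n)) {
    ph <- generate_phantom(sample(0:3, 1), sample(0:3, 1), image_size = 64,
                           seed = seed0 + i)
    imgs[[i]] <- ph$image
    masks[[i]] <- if (target == "lungs")
      ph$truth$left_mask | ph$truth$right_mask else ph$truth$spine_mask
  }
  list(images = imgs, masks = masks)
}

lung_segmenter <- function() {
  memo("lung_segmenter", {
    p <- phantom_pairs(40, "lungs")
    train_segmenter(p$images, p$masks, "lungs", epochs = 25,
                    input_size = 64, seed = 42)
  })
}

spine_segmenter <- function() {
  memo("spine_segmenter", {
    p <- phantom_pairs(40, "spine", seed0 = 500)
    train_segmenter(p$images, p$masks, "spine", epochs = 25,
                    input_size = 64, seed = 43)
  })
}

# The two-stage fine-tuned pair of tiny classifiers used by the
# learnability and saliency-concordance checks: side-specific pretrained
# backbones, UNDER balancing, NONE ROI, default schedule.
trained_tiny_pair <- function() {
  memo("trained_tiny_pair", {
    man <- learn_cohort()
    fs <- make_patient_splits(man, oob_n_images = 0, n_folds = 1,
                              seed = 11)
    tr <- fold_rows(man, fs, 1, "train")
    va <- fold_rows(man, fs, 1, "val")
    te <- fold_rows(man, fs, 1, "test")
    out <- list(test_rows = te, fold_set = fs)
    for (side in c("left", "right")) {
      pre <- pretrain_backbone("tiny", side, n_images = 640, epochs = 20,
                               seed = 314)
      loader <- make_roi_loader("NONE", side, input_size = 64)
      plan <- balance_classes(tr, "UNDER", paste0(side, "_grade"),
                              seed = 15)
      model <- build_classifier("tiny", side, seed = 16, pretrained = pre)
      out[[paste0("initial_", side)]] <- model
      out[[side]] <- fit_two_stage(model, plan, va,
                                   training_schedule(seed = 17), loader)
    }
    out
  })
}
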