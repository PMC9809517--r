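test_that("backbone registry carries conv-layer counts and unfreeze rules", {
  expect_equal(backbone_spec("resnet50")$total_conv_layers, 53L)
  expect_equal(backbone_spec("resnet50")$unfreeze_n, 48L)  # T - 5
  expect_equal(backbone_spec("vgg16")$unfreeze_n, 8L)      # T - 5
  expect_equal(backbone_spec("chexnet121")$unfreeze_n, 15L)  # override
  expect_gte(backbone_spec("tiny")$total_conv_layers, 6L)
  expect_error(backbone_spec("alexnet"), class = "cxr_input_error")
  expect_error(build_classifier("resnet50", "left"),
               class = "cxr_input_error")
})

test_that("a tiny classifier builds quickly with a frozen conv stack", {
  t0 <- Sys.time()
  m <- build_classifier("tiny", "left", seed = 1)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  conv_trainable <- vapply(m$net$layers[m$conv_ix],
                           function(l) isTRUE(l$trainable), logical(1))
  expect_false(any(conv_trainable))
  head_types <- vapply(m$net$layers[-m$conv_ix], `[[`, "", "type")
  expect_true(all(vapply(m$net$layers, function(l)
    is.null(l$W) || l$type != "conv" || !isTRUE(l$trainable), logical(1))))
  # probabilities sum to 1 on random input
  p <- predict(m, matrix(runif(64 * 64), 64, 64))
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-5)
})

test_that("prediction returns argmax grades with ties toward the lower grade", {
  m <- build_classifier("tiny", "left", seed = 2)
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  p <- predict(m, imgs)
  expect_equal(length(p$grades), 3)
  expect_equal(dim(p$probabilities), c(3, 4))
  expect_true(all(abs(rowSums(p$probabilities) - 1) < 1e-5))
  expect_equal(p$grades, max.col(p$probabilities,
                                 ties.method = "first") - 1L)
  # documented tie rule on a constructed tie
  tie <- matrix(0.25, 1, 4)
  expect_equal(max.col(tie, ties.method = "first") - 1L, 0L)
})

test_that("the training schedule validates patiences and rates", {
  sch <- training_schedule()
  expect_equal(sch$batch_size, 32)
  expect_equal(sch$lr_stage1, 1e-3)
  expect_equal(sch$lr_stage2, 1e-4)
  expect_equal(sch$lr_reduce_patience, 7)
  expect_equal(sch$early_stop_patience, 10)
  expect_error(training_schedule(lr_stage1 = 0), class = "cxr_input_error")
  expect_error(training_schedule(stage1_epochs_max = 3,
                                 stage2_epochs_max = 3),
               class = "cxr_input_error")
})

test_that("two-stage fine-tuning freezes convs in stage 1 and learns", {
  pair <- trained_tiny_pair()
  model <- pair$left
  initial <- pair$initial_left
  hist <- model$history
  # stage 1 and stage 2 both ran within their epoch caps
  expect_true(all(hist$stage %in% 1:2))
  expect_lte(max(hist$epoch[hist$stage == 1]), 20)
  expect_lte(max(hist$epoch[hist$stage == 2]), 20)
  # stage-2 learning rate starts lower
  expect_equal(hist$lr[hist$stage == 2][1], 1e-4)
  # training reduced the validation loss below the first epoch's
  expect_lt(min(hist$val_loss), hist$val_loss[1])
  # only the last T-5 conv layers may differ from initial weights
  n_unfreeze <- model$unfreeze_n
  frozen_ix <- head(model$conv_ix, length(model$conv_ix) - n_unfreeze)
  for (i in frozen_ix)
    expect_identical(model$net$layers[[i]]$W, initial$net$layers[[i]]$W)
  unfrozen_ix <- tail(model$conv_ix, n_unfreeze)
  expect_false(identical(model$net$layers[[unfrozen_ix[1]]]$W,
                         initial$net$layers[[unfrozen_ix[1]]]$W))
})

test_that("fit_two_stage rejects empty inputs", {
  man <- small_cohort()
  loader <- make_roi_loader("NONE", "left", input_size = 64)
  m <- build_classifier("tiny", "left", seed = 3)
  plan <- balance_classes(man, "UNDER", "left_grade", seed = 1)
  empty_plan <- plan
  empty_plan$stage1 <- plan$stage1[0, ]
  expect_error(fit_two_stage(m, empty_plan, man[1:3, ],
                             training_schedule(), loader),
               class = "cxr_input_error")
  expect_error(fit_two_stage(m, plan, man[0, ], training_schedule(),
                             loader),
               class = "cxr_input_error")
})

test_that("pretrained backbones transfer conv weights into fresh classifiers", {
  pre <- pretrain_backbone("tiny", "left", n_images = 48, epochs = 1,
                           seed = 5)
  m <- build_classifier("tiny", "left", seed = 6, pretrained = pre)
  expect_identical(m$net$layers[[m$conv_ix[1]]]$W,
                   pre$net$layers[[m$conv_ix[1]]]$W)
  # architecture mismatch is refused
  expect_error(build_classifier("tiny2", "left", pretrained = pre),
               class = "cxr_input_error")
})

test_that("ROI loaders feed scheme-consistent normalized batches", {
  man <- small_cohort()
  rows <- man[1:4, ]
  for (scheme in c("NONE", "LUNG", "SPINE")) {
    loader <- make_roi_loader(scheme, "left", input_size = 64)
    b <- loader(rows)
    expect_equal(dim(b$x), c(64, 64, 1, 4))
    expect_true(all(b$x >= 0 & b$x <= 1))
    expect_identical(b$y, rows$left_grade)
  }
})
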