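# Per-lung ordinal classifiers and the two-stage fine-tuning protocol.
#
# Stage 1 trains the new fully connected head alone (all convolutional
# layers frozen). Stage 2 unfreezes the last N convolutional layers,
# N = T - 5 by default where T is the backbone's total conv-layer count
# (CheXNet-121 overrides N = 15), and fine-tunes at a lower learning rate.
# Plateau-based learning-rate reduction, early stopping, and
# best-validation-loss checkpointing follow the stated schedule.

backbone_registry <- function() {
  data.frame(
    name = c("resnet50", "vgg16", "chexnet121", "tiny", "tiny2"),
    total_conv_layers = c(53L, 13L, 120L, 6L, 7L),
    input_size = c(224L, 224L, 224L, 64L, 64L),
    input_channels = c(1L, 1L, 1L, 1L, 1L),
    unfreeze_n = c(48L, 8L, 15L, 1L, 2L),  # T-5, CheXNet override 15
    buildable = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# Fixed lateral-coordinate channel (-1 viewer-left .. +1 viewer-right)
# appended to the gray channel so that side-specific evidence survives the
# global average pooling of the classification head (CoordConv-style).
coord_channel <- function(size)
  matrix(seq(-1, 1, length.out = size), size, size, byrow = TRUE)

# normalized model input for one ROI matrix
prep_input <- function(image, size, channels) {
  x <- array(0, c(size, size, channels))
  x[, , 1] <- normalize_for_net(image, size)[, , 1]
  if (channels >= 2) x[, , 2] <- coord_channel(size)
  x
}

#' Backbone specification
#'
#' @param name one of `"resnet50"`, `"vgg16"`, `"chexnet121"`, `"tiny"`,
#'   `"tiny2"`. The `tiny` family (6-7 conv layers, 64x64 input) is the
#'   desk-scale test vehicle; the named large architectures carry their
#'   conv-layer counts for enumeration and the T-5 unfreezing rule.
#' @return one-row data frame: `name`, `total_conv_layers` (T),
#'   `input_size`, `unfreeze_n` (stage-2 unfrozen conv layers), and
#'   whether the compiled backend can construct it.
#' @export
backbone_spec <- function(name) {
  reg <- backbone_registry()
  if (!name %in% reg$name)
    stop_input("unknown backbone: ", name)
  reg[reg$name == name, , drop = FALSE]
}

# The tiny backbones end in global average pooling, as the residual/dense
# architectures they stand in for do; this also gives Grad-CAM its sharp
# class-specific localization.
tiny_arch <- function() {
  list(nn_conv(3, 1, 8, trainable = FALSE), nn_pool(),
       nn_conv(3, 8, 16, trainable = FALSE), nn_pool(),
       nn_conv(3, 16, 24, trainable = FALSE),
       nn_conv(3, 24, 32, trainable = FALSE),
       nn_conv(3, 32, 48, trainable = FALSE),
       nn_conv(3, 48, 64, trainable = FALSE),
       nn_gap(), nn_bnorm(64),
       nn_dense(64, 32), nn_dense(32, 4, act = "linear"))
}

tiny2_arch <- function() {
  list(nn_conv(3, 1, 8, trainable = FALSE), nn_pool(),
       nn_conv(3, 8, 16, trainable = FALSE), nn_pool(),
       nn_conv(3, 16, 16, trainable = FALSE),
       nn_conv(3, 16, 24, trainable = FALSE), nn_pool(),
       nn_conv(3, 24, 32, trainable = FALSE),
       nn_conv(3, 32, 48, trainable = FALSE),
       nn_conv(3, 48, 64, trainable = FALSE),
       nn_gap(), nn_bnorm(64),
       nn_dense(64, 32), nn_dense(32, 4, act = "linear"))
}

vgg16_arch <- function() {
  cfg <- list(c(64, 64), c(128, 128), c(256, 256, 256),
              c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  cin <- 1
  for (block in cfg) {
    for (cout in block) {
      layers[[length(layers) + 1L]] <- nn_conv(3, cin, cout,
                                               trainable = FALSE)
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- nn_pool()
  }
  c(layers, list(nn_flatten(), nn_dense(7 * 7 * 512, 64),
                 nn_dense(64, 4, act = "linear")))
}

# One source-domain image for backbone pretraining: two randomly placed
# dark regions separated by a bright vertical band on a brighter surround,
# with medium-bright blobs covering an independently graded fraction of
# each region. The label is the coverage grade of the region on the
# requested patient side (patient-left region sits viewer-right of the
# band), so pretrained features respond to "opacity inside the
# radiolucent field on one side of the midline" — the abstract structure
# of the per-lung grading task without its fixed anatomy.
source_phantom <- function(size, grade_left, grade_right) {
  xg <- matrix(seq_len(size), size, size, byrow = TRUE)
  yg <- matrix(seq_len(size), size, size)
  # dark surround, brighter randomized body, as in the deployment domain
  base <- matrix(0.12, size, size)
  body <- abs(xg - runif(1, 0.46, 0.54) * size) <=
    runif(1, 0.36, 0.46) * size & yg >= runif(1, 0.02, 0.12) * size
  base[body] <- runif(1, 0.4, 0.6)
  bandw <- runif(1, 0.03, 0.06) * size
  bandc <- runif(1, 0.45, 0.55) * size
  cy <- runif(2, 0.35, 0.65) * size
  aL <- runif(1, 0.08, 0.16) * size; bL <- runif(1, 0.15, 0.32) * size
  aR <- runif(1, 0.08, 0.16) * size; bR <- runif(1, 0.15, 0.32) * size
  reg_right <- ellipse_mask(size, runif(1, 0.2, 0.36) * size, cy[1], aR, bR)
  reg_left <- ellipse_mask(size, runif(1, 0.64, 0.8) * size, cy[2], aL, bL)
  base[reg_left | reg_right] <- base[reg_left | reg_right] - 0.3
  fill <- function(base, region, grade) {
    if (grade == 0 || sum(region) < 20) return(base)
    rng <- rbind(c(0.03, 0.30), c(0.36, 0.63), c(0.69, 0.97))[grade, ]
    f <- runif(1, rng[1], rng[2])
    idx <- which(region, arr.ind = TRUE)
    centers <- idx[sample.int(nrow(idx), 3, replace = TRUE), , drop = FALSE]
    sig <- runif(3, 0.08, 0.2) * size
    field <- matrix(0, size, size)
    for (j in 1:3)
      field <- field + exp(-((xg - centers[j, 2])^2 +
                               (yg - centers[j, 1])^2) / (2 * sig[j]^2))
    thr <- quantile(field[region], 1 - f)
    sel <- region & field > thr
    base[sel] <- base[sel] + 0.32
    base
  }
  base <- fill(base, reg_left, grade_left)
  base <- fill(base, reg_right, grade_right)
  band <- abs(xg - bandc) <= bandw
  base[band] <- base[band] + 0.22
  pmin(pmax(base + matrix(rnorm(size^2, 0, 0.03), size, size), 0), 1)
}

#' Pretrain a side-specific backbone on a synthetic source domain
#'
#' Supervised pretraining of the whole conv stack (nothing frozen) on
#' randomized two-region images graded by the coverage of the requested
#' patient side's region, standing in for the large pretraining corpus
#' that published transfer-learning pipelines take their weights from.
#' The returned weights initialize [build_classifier()], whose
#' convolutional layers are then frozen for stage-1 fine-tuning as usual.
#'
#' @param backbone a buildable backbone name.
#' @param side `"left"` or `"right"` (patient coordinates).
#' @param n_images source-domain images to generate.
#' @param epochs pretraining epochs.
#' @param seed integer seed.
#' @return a `pretrained_backbone` weights object.
#' @export
pretrain_backbone <- function(backbone = "tiny", side = c("left", "right"),
                              n_images = 320, epochs = 12, seed = NULL) {
  side <- match.arg(side)
  spec <- backbone_spec(backbone)
  if (!spec$buildable) stop_input("backbone not constructible: ", backbone)
  s <- spec$input_size
  layers <- switch(backbone, tiny = tiny_arch(), tiny2 = tiny2_arch(),
                   vgg16 = vgg16_arch())
  for (i in seq_along(layers))
    if (layers[[i]]$type == "conv") layers[[i]]$trainable <- TRUE
  net <- nn_init(list(layers = layers),
                 seed = derive_seed(seed %||% 0, "pre-init", backbone, side))
  with_seed(derive_seed(seed %||% 0, "pre-data", backbone, side), {
    grades <- rep(0:3, length.out = n_images)[sample.int(n_images)]
    other <- sample(0:3, n_images, replace = TRUE)
    x <- array(0, c(s, s, spec$input_channels, n_images))
    if (spec$input_channels >= 2) x[, , 2, ] <- coord_channel(s)
    for (i in seq_len(n_images))
      x[, , 1, i] <- if (side == "left")
        source_phantom(s, grades[i], other[i])
      else source_phantom(s, other[i], grades[i])
  })
  y <- onehot4(grades)
  nval <- max(8L, n_images %/% 8L)
  vix <- seq(n_images - nval + 1L, n_images)
  fit <- nn_fit(net, x[, , , -vix, drop = FALSE], y[, -vix, drop = FALSE],
                x[, , , vix, drop = FALSE], y[, vix, drop = FALSE],
                loss = "softmax", epochs = epochs, batch_size = 32L,
                lr = 1e-3, lr_patience = 7L, stop_patience = 10L,
                seed = derive_seed(seed %||% 0, "pre-fit", backbone, side))
  structure(list(net = fit$net, backbone = backbone, side = side,
                 seed = seed, history = fit$history),
            class = "pretrained_backbone")
}

#' Build an opacity classifier for one lung side
#'
#' Constructs the backbone with a fresh 4-output fully connected head.
#' All convolutional layers start frozen; only the head is trainable until
#' stage 2 of [fit_two_stage()] unfreezes the last N conv layers. Output
#' probabilities (softmax over the head logits) sum to 1.
#'
#' @param backbone backbone name (see [backbone_spec()]).
#' @param side `"left"` or `"right"` (patient coordinates).
#' @param seed weight-initialization seed.
#' @param pretrained optional [pretrain_backbone()] weights for the same
#'   architecture; conv weights are copied in (and stay frozen), the head
#'   stays fresh.
#' @return an `opacity_classifier`.
#' @export
build_classifier <- function(backbone = "tiny", side = c("left", "right"),
                             seed = NULL, pretrained = NULL) {
  side <- match.arg(side)
  spec <- backbone_spec(backbone)
  if (!spec$buildable)
    stop_input("architecture '", backbone, "' needs residual/dense ",
               "connectivity the compiled backend does not model; ",
               "constructible backbones: ",
               paste(backbone_registry()$name[backbone_registry()$buildable],
                     collapse = ", "))
  layers <- switch(backbone, tiny = tiny_arch(), tiny2 = tiny2_arch(),
                   vgg16 = vgg16_arch())
  net <- nn_init(list(layers = layers),
                 seed = derive_seed(seed %||% 0, "clf-init", backbone, side))
  conv_ix <- which(vapply(net$layers, function(l) l$type == "conv",
                          logical(1)))
  if (!is.null(pretrained)) {
    if (!identical(pretrained$backbone, backbone))
      stop_input("pretrained weights are for backbone ",
                 pretrained$backbone)
    for (i in conv_ix) {
      net$layers[[i]]$W <- pretrained$net$layers[[i]]$W
      net$layers[[i]]$b <- pretrained$net$layers[[i]]$b
    }
  }
  structure(list(net = net, backbone = backbone, side = side,
                 input_size = spec$input_size,
                 channels = spec$input_channels,
                 total_conv_layers = spec$total_conv_layers,
                 unfreeze_n = spec$unfreeze_n, conv_ix = conv_ix,
                 last_conv = max(conv_ix), seed = seed,
                 config = NULL, history = NULL),
            class = "opacity_classifier")
}

#' @export
print.opacity_classifier <- function(x, ...) {
  cat(sprintf("Opacity classifier (%s, %s lung, input %dx%d)\n",
              x$backbone, x$side, x$input_size, x$input_size))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs over %d stage(s), best val loss %.4f\n",
                nrow(x$history), max(x$history$stage),
                min(x$history$val_loss)))
  else cat("  untrained (head randomly initialized, convs frozen)\n")
  invisible(x)
}

#' Two-stage fine-tuning schedule
#'
#' Defaults follow the protocol: up to 20 epochs per stage, batch size 32,
#' Adam at 1e-3 (stage 1) and 1e-4 (stage 2), learning-rate reduction
#' (factor 0.1) after 7 stalled epochs, early stopping after 10, and the
#' lowest-validation-loss weights kept.
#'
#' @param stage1_epochs_max,stage2_epochs_max epoch caps per stage.
#' @param batch_size minibatch size.
#' @param lr_stage1,lr_stage2 Adam learning rates.
#' @param lr_reduce_patience,early_stop_patience stalled-epoch patiences.
#' @param lr_factor,min_lr reduction factor and floor.
#' @param seed shuffling seed.
#' @export
training_schedule <- function(stage1_epochs_max = 20, stage2_epochs_max = 20,
                              batch_size = 32, lr_stage1 = 1e-3,
                              lr_stage2 = 1e-4, lr_reduce_patience = 7,
                              early_stop_patience = 10, lr_factor = 0.1,
                              min_lr = 1e-6, seed = NULL) {
  if (lr_stage1 <= 0 || lr_stage2 <= 0) stop_input("learning rates must be > 0")
  if (max(lr_reduce_patience, early_stop_patience) >=
      max(stage1_epochs_max, stage2_epochs_max))
    stop_input("patience values must be below the epoch maxima")
  list(stage1_epochs_max = stage1_epochs_max,
       stage2_epochs_max = stage2_epochs_max, batch_size = batch_size,
       lr_stage1 = lr_stage1, lr_stage2 = lr_stage2,
       lr_reduce_patience = lr_reduce_patience,
       early_stop_patience = early_stop_patience, lr_factor = lr_factor,
       min_lr = min_lr, seed = seed)
}

#' ROI image loader for training and prediction
#'
#' Returns a function mapping manifest rows to a normalized batch array
#' and the side's grade labels. ROIs follow the requested scheme using the
#' ground-truth masks recorded in the manifest (`masks = "truth"`) or
#' fitted segmenters. Synthetic (oversampled) rows re-apply their stored
#' augmentation transform. Loaded ROIs are cached.
#'
#' @param scheme `"NONE"`, `"LUNG"` or `"SPINE"`.
#' @param side `"left"` or `"right"`.
#' @param input_size network input resolution.
#' @param channels input channel count expected by the backbone.
#' @param masks `"truth"` (manifest mask paths) or `"model"` (use
#'   `lung_model` / `spine_model`).
#' @param lung_model,spine_model fitted [train_segmenter()] models when
#'   `masks = "model"`.
#' @param cache environment used as ROI cache.
#' @export
make_roi_loader <- function(scheme = "NONE", side = "left", input_size = 64,
                            channels = 1L, masks = c("truth", "model"),
                            lung_model = NULL, spine_model = NULL,
                            cache = new.env()) {
  masks <- match.arg(masks)
  load_one <- function(row) {
    key <- paste0(row$image_path, "|", row$synthetic %||% FALSE, "|",
                  paste(row$aug_rotation %||% 0, row$aug_scale %||% 1,
                        row$aug_tx %||% 0, row$aug_ty %||% 0))
    if (!is.null(cache[[key]])) return(cache[[key]])
    img <- read_gray_png(row$image_path)
    roi <- if (scheme == "NONE") img
    else if (scheme == "LUNG") {
      mk <- if (masks == "truth") {
        path <- if (side == "left") row$left_mask_path else row$right_mask_path
        m <- read_gray_png(path) > 0.5
        list(left = m, right = m)[side]
      } else {
        segment_lungs(lung_model, img)[side]
      }
      extract_roi(img, "LUNG", side, masks = mk)
    } else {
      sp <- if (masks == "truth")
        split_from_mask(img, read_gray_png(row$spine_mask_path) > 0.5)
      else split_by_spine(spine_model, img)
      extract_roi(img, "SPINE", side,
                  masks = list(left = sp$left_mask, right = sp$right_mask))
    }
    x <- normalize_for_net(roi, size = input_size)[, , 1]
    if (isTRUE(as.logical(row$synthetic %||% FALSE)))
      x <- augment_image(x, row$aug_rotation, row$aug_scale,
                         c(row$aug_tx, row$aug_ty))
    cache[[key]] <- x
    x
  }
  function(rows) {
    n <- nrow(rows)
    x <- array(0, c(input_size, input_size, channels, n))
    if (channels >= 2) x[, , 2, ] <- coord_channel(input_size)
    for (i in seq_len(n)) x[, , 1, i] <- load_one(rows[i, , drop = FALSE])
    y <- rows[[paste0(side, "_grade")]]
    list(x = x, y = as.integer(y))
  }
}

# lateral split from a known spine mask (same geometry as split_by_spine)
split_from_mask <- function(image, spine_mask) {
  H <- nrow(image); W <- ncol(image)
  cent <- vapply(seq_len(H), function(r) {
    cols <- which(spine_mask[r, ])
    if (length(cols)) mean(cols) else NA_real_
  }, numeric(1))
  curve <- if (all(is.na(cent))) rep((W + 1) / 2, H)
           else approx(which(!is.na(cent)), cent[!is.na(cent)],
                       xout = seq_len(H), rule = 2)$y
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  left_mask <- cols > curve
  list(left_mask = left_mask, right_mask = !left_mask, split_curve = curve)
}

onehot4 <- function(y) {
  m <- matrix(0, 4, length(y))
  m[cbind(y + 1L, seq_along(y))] <- 1
  m
}

#' Two-stage fine-tuning of an opacity classifier
#'
#' Stage 1 trains the fully connected head on the plan's stage-1 rows at
#' the stage-1 learning rate with every convolutional layer frozen. Stage
#' 2 unfreezes the last N convolutional layers (N from the backbone's
#' T-5 rule or its override) and fine-tunes on the stage-2 rows (DOUBLE)
#' or again on the stage-1 rows (UNDER/OVER) at the lower rate with a
#' fresh optimizer. Each stage applies plateau LR reduction, early
#' stopping, and keeps the lowest-validation-loss weights.
#'
#' @param model an [build_classifier()] object.
#' @param plan a [balance_classes()] training plan.
#' @param val_rows manifest rows of the validation split.
#' @param schedule a [training_schedule()].
#' @param loader a [make_roi_loader()] matching the model's scheme/side.
#' @return the trained model, with `history` (per-epoch stage, epoch,
#'   learning rate, train and validation loss).
#' @export
fit_two_stage <- function(model, plan, val_rows,
                          schedule = training_schedule(), loader) {
  if (nrow(plan$stage1) == 0) stop_input("empty stage-1 rows")
  if (nrow(val_rows) == 0) stop_input("empty validation rows")
  tr1 <- loader(plan$stage1)
  va <- loader(val_rows)
  yva <- onehot4(va$y)
  net <- model$net
  fit1 <- nn_fit(net, tr1$x, onehot4(tr1$y), va$x, yva, loss = "softmax",
                 epochs = schedule$stage1_epochs_max,
                 batch_size = schedule$batch_size, lr = schedule$lr_stage1,
                 lr_patience = schedule$lr_reduce_patience,
                 stop_patience = schedule$early_stop_patience,
                 lr_factor = schedule$lr_factor, min_lr = schedule$min_lr,
                 seed = derive_seed(schedule$seed %||% 0, "stage1",
                                    model$side),
                 stage = 1L)
  net <- fit1$net
  # unfreeze the last N convolutional layers for stage 2
  n_unfreeze <- min(model$unfreeze_n, length(model$conv_ix))
  for (i in utils::tail(model$conv_ix, n_unfreeze))
    net$layers[[i]]$trainable <- TRUE
  tr2 <- if (!is.null(plan$stage2)) loader(plan$stage2) else tr1
  fit2 <- if (schedule$stage2_epochs_max > 0)
    nn_fit(net, tr2$x, onehot4(tr2$y), va$x, yva, loss = "softmax",
           epochs = schedule$stage2_epochs_max,
           batch_size = schedule$batch_size, lr = schedule$lr_stage2,
           lr_patience = schedule$lr_reduce_patience,
           stop_patience = schedule$early_stop_patience,
           lr_factor = schedule$lr_factor, min_lr = schedule$min_lr,
           seed = derive_seed(schedule$seed %||% 0, "stage2", model$side),
           stage = 2L)
  else list(net = net, history = NULL)
  model$net <- fit2$net
  model$history <- rbind(fit1$history, fit2$history)
  model$schedule <- schedule
  model$plan_scheme <- plan$scheme
  model
}

#' Predict ordinal grades
#'
#' @param object an `opacity_classifier`.
#' @param images a batch array `(size, size, 1, n)`, a single ROI matrix,
#'   or a list of ROI matrices (normalized to the model input size as
#'   needed).
#' @param ... unused.
#' @return list of `probabilities` (n x 4, rows sum to 1) and `grades`
#'   (integer 0-3; argmax with ties broken toward the lower grade).
#' @export
predict.opacity_classifier <- function(object, images, ...) {
  s <- object$input_size
  x <- if (is.array(images) && length(dim(images)) == 4) images
  else {
    if (is.matrix(images)) images <- list(images)
    n <- length(images)
    b <- array(0, c(s, s, object$channels, n))
    for (i in seq_len(n))
      b[, , , i] <- prep_input(images[[i]], s, object$channels)
    b
  }
  if (dim(x)[1] != s || dim(x)[2] != s || dim(x)[3] != object$channels)
    stop_input("batch dims do not match model input ", s, "x", s, "x",
               object$channels)
  out <- nn_forward(object$net, x)$out
  z <- sweep(out, 2, apply(out, 2, max))
  e <- exp(z)
  p <- t(sweep(e, 2, colSums(e), "/"))
  grades <- max.col(p, ties.method = "first") - 1L
  list(probabilities = p, grades = grades)
}
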