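# Patient-level data splits and class balancing.
#
# Whole patients are the unit of assignment everywhere, so no patient's
# images can leak across train/validation/test or into the out-of-the-box
# (OOB) hold-out. The OOB set is drawn first, by whole patients, until its
# image count reaches the requested size; the remaining patients are
# re-partitioned 80/10/10 independently for each fold.

#' Build the OOB hold-out and five patient-level folds
#'
#' @param manifest cohort manifest (one row per image).
#' @param oob_n_images minimum number of images in the OOB hold-out
#'   (whole patients are added until the count is reached; 0 disables).
#' @param ratios train/validation/test proportions of patients, summing
#'   to 1.
#' @param n_folds number of independent re-partitions.
#' @param seed integer; the fold set is reproducible given the seed.
#' @return a `fold_set`: `oob` (patient ids), `folds` (list of
#'   train/val/test patient-id vectors), plus the generating parameters.
#' @export
make_patient_splits <- function(manifest, oob_n_images = 0,
                                ratios = c(0.8, 0.1, 0.1), n_folds = 5,
                                seed = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3)
    stop_input("ratios must be three proportions summing to 1")
  patients <- unique(manifest$patient_id)
  if (length(patients) < 20) stop_input("need at least 20 patients")
  img_count <- table(manifest$patient_id)
  with_seed(seed, {
    pool <- sample(patients)
    oob <- character(0)
    if (oob_n_images > 0) {
      tot <- 0L
      i <- 0L
      while (tot < oob_n_images && i < length(pool) - 20L) {
        i <- i + 1L
        oob <- c(oob, pool[i])
        tot <- tot + as.integer(img_count[[pool[i]]])
      }
      pool <- pool[-seq_len(i)]
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      p <- sample(pool)
      n <- length(p)
      n_tr <- round(ratios[1] * n)
      n_va <- round(ratios[2] * n)
      list(train = p[seq_len(n_tr)],
           val = p[n_tr + seq_len(n_va)],
           test = p[(n_tr + n_va + 1):n])
    })
  })
  structure(list(oob = oob, folds = folds, ratios = ratios,
                 n_folds = n_folds, seed = seed),
            class = "fold_set")
}

#' @export
print.fold_set <- function(x, ...) {
  cat(sprintf("Patient-level fold set: %d folds, OOB %d patients\n",
              length(x$folds), length(x$oob)))
  for (f in seq_along(x$folds))
    cat(sprintf("  fold %d: %d/%d/%d train/val/test patients\n", f,
                length(x$folds[[f]]$train), length(x$folds[[f]]$val),
                length(x$folds[[f]]$test)))
  invisible(x)
}

#' Serialize / load a fold set as JSON
#' @param fold_set a `fold_set`.
#' @param path JSON path.
#' @export
write_fold_set <- function(fold_set, path) {
  jsonlite::write_json(unclass(fold_set), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_set
#' @export
read_fold_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$folds <- if (is.data.frame(x$folds))
    lapply(seq_len(nrow(x$folds)), function(i)
      list(train = x$folds$train[[i]], val = x$folds$val[[i]],
           test = x$folds$test[[i]]))
  else x$folds
  structure(x, class = "fold_set")
}

#' Manifest rows belonging to one part of one fold
#' @param manifest cohort manifest.
#' @param fold_set a `fold_set`.
#' @param fold fold index, or `"oob"`.
#' @param part `"train"`, `"val"` or `"test"` (ignored for `"oob"`).
#' @export
fold_rows <- function(manifest, fold_set, fold, part = "train") {
  ids <- if (identical(fold, "oob")) fold_set$oob
         else fold_set$folds[[fold]][[part]]
  manifest[manifest$patient_id %in% ids, , drop = FALSE]
}

default_aug_params <- function()
  list(rotation = 10, scale = c(0.9, 1.1), translate = 0.05)

sample_aug <- function(params) {
  list(rotation = runif(1, -params$rotation, params$rotation),
       scale = runif(1, params$scale[1], params$scale[2]),
       translate = runif(2, -params$translate, params$translate))
}

#' Apply a stored augmentation transform to an image
#' @param image grayscale matrix.
#' @param rotation degrees; @param scale isotropic factor;
#' @param translate length-2 fraction of width/height.
#' @export
augment_image <- function(image, rotation, scale, translate) {
  .affine_warp(image, rotation, scale,
               translate[1] * ncol(image), translate[2] * nrow(image))
}

#' Balance a training manifest for one lung side
#'
#' `UNDER` randomly downsamples every class to the minority count. `OVER`
#' brings every class to the majority count by adding augmented copies
#' (rotation, scaling, translation; transform parameters are stored on the
#' row and applied at image-load time) flagged `synthetic`. `DOUBLE`
#' prepares the two-stage plan: stage 1 is the undersampled set, stage 2
#' the full unbalanced training set.
#'
#' @param train_rows manifest rows of the training split.
#' @param scheme `"UNDER"`, `"OVER"` or `"DOUBLE"`.
#' @param label_column the side's grade column (`"left_grade"` or
#'   `"right_grade"`); balancing is per lung side.
#' @param seed sampling seed.
#' @param aug_params list with `rotation` (max degrees), `scale` (range),
#'   `translate` (max fraction); defaults ±10°, 0.9-1.1, ±5%.
#' @return a `training_plan`: `stage1` rows, `stage2` rows (or `NULL`),
#'   scheme and augmentation ranges. Row columns `synthetic`, `stage`, and
#'   `aug_*` are added.
#' @export
balance_classes <- function(train_rows, scheme = c("UNDER", "OVER", "DOUBLE"),
                            label_column = "left_grade", seed = NULL,
                            aug_params = default_aug_params()) {
  scheme <- match.arg(scheme)
  y <- train_rows[[label_column]]
  counts <- vapply(0:3, function(g) sum(y == g, na.rm = TRUE), integer(1))
  if (any(counts == 0))
    stop_input("class ", paste(which(counts == 0) - 1, collapse = ","),
               " has zero training rows")
  decorate <- function(df, stage) {
    df$synthetic <- df$synthetic %||% rep(FALSE, nrow(df))
    df$stage <- stage
    df
  }
  with_seed(seed, {
    if (scheme %in% c("UNDER", "DOUBLE")) {
      m <- min(counts)
      keep <- unlist(lapply(0:3, function(g)
        sample(which(y == g), m)), use.names = FALSE)
      stage1 <- decorate(train_rows[sort(keep), , drop = FALSE], 1L)
      stage2 <- if (scheme == "DOUBLE")
        decorate(train_rows, 2L) else NULL
    } else {
      M <- max(counts)
      extra <- list()
      for (g in 0:3) {
        need <- M - counts[g + 1]
        if (need == 0) next
        src <- sample(which(y == g), need, replace = TRUE)
        add <- train_rows[src, , drop = FALSE]
        add$synthetic <- TRUE
        aug <- t(vapply(seq_len(need), function(i) {
          a <- sample_aug(aug_params)
          c(a$rotation, a$scale, a$translate)
        }, numeric(4)))
        add$aug_rotation <- aug[, 1]
        add$aug_scale <- aug[, 2]
        add$aug_tx <- aug[, 3]
        add$aug_ty <- aug[, 4]
        extra[[length(extra) + 1L]] <- add
      }
      base <- train_rows
      base$synthetic <- FALSE
      base$aug_rotation <- 0; base$aug_scale <- 1
      base$aug_tx <- 0; base$aug_ty <- 0
      stage1 <- decorate(rbind(base, do.call(rbind, extra)), 1L)
      stage2 <- NULL
    }
  })
  structure(list(stage1 = stage1, stage2 = stage2, scheme = scheme,
                 label_column = label_column, aug_params = aug_params,
                 seed = seed),
            class = "training_plan")
}

#' @export
print.training_plan <- function(x, ...) {
  cat(sprintf("Training plan (%s, %s): stage1 %d rows%s\n", x$scheme,
              x$label_column, nrow(x$stage1),
              if (is.null(x$stage2)) ""
              else sprintf(", stage2 %d rows", nrow(x$stage2))))
  invisible(x)
}

#' Write a training plan's manifests as CSV
#' @param plan a `training_plan`.
#' @param path CSV path (stage recorded in the `stage` column).
#' @export
write_training_plan <- function(plan, path) {
  rows <- plan$stage1
  if (!is.null(plan$stage2)) {
    common <- intersect(names(rows), names(plan$stage2))
    rows <- rbind(rows[common], plan$stage2[common])
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
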