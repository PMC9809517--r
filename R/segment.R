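# ROI extraction: three schemes are supported. NONE passes the full
# radiograph through; LUNG masks the image to one lung via an
# encoder-decoder semantic segmenter; SPINE splits the image laterally
# along the segmented spine. The segmenter is a compact U-Net-style
# encoder-decoder (additive skip connections) trained on phantom masks.

segmenter_arch <- function() {
  list(nn_conv(3, 1, 8), nn_conv(3, 8, 8), nn_stash(), nn_pool(),
       nn_conv(3, 8, 16), nn_stash(), nn_pool(),
       nn_conv(3, 16, 32), nn_conv(3, 32, 32),
       nn_upsample(), nn_conv(3, 32, 16), nn_addpop(),
       nn_upsample(), nn_conv(3, 16, 8), nn_addpop(),
       nn_conv(3, 8, 8), nn_conv(3, 8, 1, act = "linear"))
}

as_batch <- function(mats, size) {
  x <- array(0, c(size, size, 1, length(mats)))
  for (i in seq_along(mats))
    x[, , 1, i] <- if (all(dim(mats[[i]]) == size)) mats[[i]]
                   else .resize_bilinear(mats[[i]], size, size)
  x
}

#' Train the lung / spine segmenter
#'
#' Fits a compact encoder-decoder semantic-segmentation network (U-Net
#' style, additive skips) with pixelwise binary cross-entropy. Images and
#' masks are resized to the model's working resolution; one eighth of the
#' pairs is held out to drive early stopping.
#'
#' @param images list of grayscale matrices in \[0,1\].
#' @param masks list of binary matrices (same sizes as `images`); for
#'   `target = "lungs"` the union of both lung fields, for `"spine"` the
#'   spine band.
#' @param target `"lungs"` or `"spine"`.
#' @param epochs maximum training epochs.
#' @param input_size working resolution (square, divisible by 4).
#' @param seed training seed (initialization and shuffling).
#' @return a `segmenter_model` object.
#' @export
train_segmenter <- function(images, masks, target = c("lungs", "spine"),
                            epochs = 40, input_size = 256, seed = NULL) {
  target <- match.arg(target)
  if (length(images) == 0) stop_input("empty training set")
  if (length(images) != length(masks))
    stop_input("images and masks must pair up")
  if (length(images) < 8) stop_input("need >= 8 image/mask pairs")
  for (i in seq_along(images))
    if (!all(dim(images[[i]]) == dim(masks[[i]])))
      stop_input("image/mask shape mismatch at pair ", i)
  if (input_size %% 4 != 0) stop_input("input_size must be divisible by 4")
  x <- as_batch(images, input_size)
  y <- as_batch(lapply(masks, function(m) (m > 0.5) * 1), input_size)
  y <- (y > 0.5) * 1
  n <- dim(x)[4]
  nval <- max(1L, n %/% 8L)
  vix <- seq(n - nval + 1L, n)
  net <- nn_init(list(layers = segmenter_arch()),
                 seed = derive_seed(seed %||% 0, "seg-init"))
  fit <- if (epochs > 0)
    nn_fit(net, x[, , , -vix, drop = FALSE], y[, , , -vix, drop = FALSE],
           x[, , , vix, drop = FALSE], y[, , , vix, drop = FALSE],
           loss = "bce", epochs = epochs, batch_size = 8L, lr = 2e-3,
           lr_patience = 7L, stop_patience = 10L,
           seed = derive_seed(seed %||% 0, "seg-fit"))
  else list(net = net, history = NULL, best_epoch = 0L)
  structure(list(net = fit$net, target = target, input_size = input_size,
                 seed = seed, history = fit$history,
                 best_epoch = fit$best_epoch),
            class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("Encoder-decoder segmenter (target: %s, input %dx%d)\n",
              x$target, x$input_size, x$input_size))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; best val loss %.4f at epoch %d\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict a probability raster from a segmenter
#' @param model a `segmenter_model`.
#' @param image grayscale matrix in \[0,1\].
#' @return matrix of probabilities in \[0,1\] at the image's resolution.
#' @export
predict_segmenter <- function(model, image) {
  s <- model$input_size
  x <- array(.resize_bilinear(image, s, s), c(s, s, 1, 1))
  z <- nn_forward(model$net, x)$out
  p <- 1 / (1 + exp(-z[, , 1, 1]))
  if (!all(dim(image) == s))
    p <- .resize_bilinear(p, nrow(image), ncol(image))
  p
}

seg_failure <- function(side) {
  stop(structure(class = c("cxr_segmentation_failure", "error", "condition"),
                 list(message = paste0("empty ", side, " lung segmentation"),
                      call = NULL, side = side)))
}

#' Segment the two lung fields
#'
#' Thresholds the segmenter prediction at 0.5, keeps the two largest
#' connected components, and assigns them to patient sides by centroid
#' (patient-left lung sits on the viewer-right image half). An empty side
#' raises a segmentation-failure condition identifying the side.
#'
#' @inheritParams predict_segmenter
#' @param threshold probability cut for the foreground.
#' @param min_area minimum component area in pixels.
#' @return list of disjoint logical `left` and `right` masks (patient
#'   coordinates).
#' @export
segment_lungs <- function(model, image, threshold = 0.5, min_area = 25) {
  p <- predict_segmenter(model, image)
  bin <- p > threshold
  lab <- .label_components(bin)
  ncomp <- attr(lab, "n")
  if (ncomp == 0) seg_failure("both")
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- order(areas, decreasing = TRUE)[seq_len(min(2L, ncomp))]
  keep <- keep[areas[keep] >= min_area]
  if (length(keep) == 0) seg_failure("both")
  W <- ncol(image)
  cent <- vapply(keep, function(k) mean(which(lab == k, arr.ind = TRUE)[, 2]),
                 numeric(1))
  left <- right <- matrix(FALSE, nrow(image), W)   # patient coordinates
  if (length(keep) == 1) {
    if (cent[1] > W / 2) left <- lab == keep[1] else right <- lab == keep[1]
  } else {
    ord <- keep[order(cent)]
    right <- lab == ord[1]          # viewer-left component
    left <- lab == ord[2]           # viewer-right component
  }
  if (!any(left)) seg_failure("left")
  if (!any(right)) seg_failure("right")
  list(left = left, right = right)
}

#' Split a radiograph laterally along the segmented spine
#'
#' The per-row centroid of the predicted spine mask, median-smoothed and
#' interpolated across empty rows, defines a vertical split curve. Columns
#' right of the curve form the patient-left half; the two halves partition
#' the image. An everywhere-empty spine prediction falls back to the
#' vertical midline with a warning.
#'
#' @inheritParams segment_lungs
#' @return list of `left_half`, `right_half` (matrices, zero outside their
#'   half), logical `left_mask`, `right_mask`, and the `split_curve`
#'   (numeric, one column index per row).
#' @export
split_by_spine <- function(model, image, threshold = 0.5) {
  H <- nrow(image); W <- ncol(image)
  p <- predict_segmenter(model, image)
  bin <- p > threshold
  cent <- vapply(seq_len(H), function(r) {
    cols <- which(bin[r, ])
    if (length(cols)) mean(cols) else NA_real_
  }, numeric(1))
  if (all(is.na(cent))) {
    warning("empty spine prediction; falling back to midline split")
    curve <- rep((W + 1) / 2, H)
  } else {
    sm <- cent
    ok <- !is.na(sm)
    sm[ok] <- stats::runmed(sm[ok], k = min(9L, sum(ok) - (1 - sum(ok) %% 2)))
    curve <- approx(which(ok), sm[ok], xout = seq_len(H), rule = 2)$y
  }
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  left_mask <- cols > curve          # viewer right = patient left
  right_mask <- !left_mask
  list(left_half = image * left_mask, right_half = image * right_mask,
       left_mask = left_mask, right_mask = right_mask, split_curve = curve)
}

crop_bbox <- function(image, mask) {
  ix <- which(mask, arr.ind = TRUE)
  image[min(ix[, 1]):max(ix[, 1]), min(ix[, 2]):max(ix[, 2]), drop = FALSE]
}

#' Extract the ROI for one lung under a segmentation scheme
#'
#' @param image grayscale matrix.
#' @param scheme `"NONE"` (full image), `"LUNG"` (zero outside that side's
#'   lung mask, optionally cropped to its bounding box), or `"SPINE"`
#'   (that side's lateral half).
#' @param side `"left"` or `"right"` in patient coordinates.
#' @param masks for `LUNG`/`SPINE`: list with logical `left` and `right`
#'   masks (lung masks, or the lateral half-masks from [split_by_spine()]).
#' @param crop crop the masked image to the mask bounding box.
#' @return the ROI image matrix.
#' @export
extract_roi <- function(image, scheme = c("NONE", "LUNG", "SPINE"),
                        side = c("left", "right"), masks = NULL,
                        crop = TRUE) {
  scheme <- match.arg(scheme)
  side <- match.arg(side)
  if (scheme == "NONE") return(image)
  if (is.null(masks) || is.null(masks[[side]]))
    stop_input("scheme ", scheme, " needs a mask for side ", side)
  m <- masks[[side]]
  if (!all(dim(m) == dim(image))) stop_input("mask/image shape mismatch")
  if (!any(m)) stop_input("empty ", side, " mask")
  out <- image * m
  if (crop) out <- crop_bbox(out, m)
  out
}

#' Normalize an image for the classifier
#'
#' Resizes to the network input resolution and scales intensities to
#' \[0,1\] by the dtype maximum (255 for 8-bit integer input; images
#' already on the unit scale pass through), then replicates the gray
#' channel.
#'
#' @param image 2-D matrix (unit-scale or 8-bit values).
#' @param size output side length (default 224).
#' @param channels channel replication count expected by the backbone.
#' @return array dim `c(size, size, channels)` with values in \[0,1\].
#' @export
normalize_for_net <- function(image, size = 224, channels = 1) {
  if (length(dim(image)) != 2) stop_input("expected a 2-D grayscale raster")
  if (max(image) > 1) image <- image / 255
  r <- .resize_bilinear(image, size, size)
  r <- pmin(pmax(r, 0), 1)
  array(rep(r, channels), c(size, size, channels))
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
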