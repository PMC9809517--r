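# Grad-CAM saliency, probability-weighted attention heatmaps, and the
# Heatmap Concordance Score (HCS).
#
# Grad-CAM weights the activations of the last convolutional layer by the
# spatial mean of the class-score gradient flowing back into that layer;
# the rectified weighted sum, upsampled to image size and min-max scaled,
# is the class saliency map. The network-attention heatmap averages the
# four class maps with the predicted class probabilities as weights; the
# left- and right-lung model heatmaps are averaged into a whole-lung map.
# HCS measures how much of the heatmap falls inside the lung boundary.

#' Grad-CAM saliency map for one class
#'
#' @param model a trained or untrained `opacity_classifier`.
#' @param image ROI matrix (normalized internally to the model input).
#' @param class_index class in 0..3 whose score is differentiated.
#' @return saliency matrix at the image's resolution, values in \[0,1\]
#'   (an all-zero map stays all-zero).
#' @export
grad_cam <- function(model, image, class_index) {
  if (!class_index %in% 0:3) stop_input("class_index must be in 0..3")
  if (length(model$conv_ix) == 0) stop_input("model has no conv layers")
  s <- model$input_size
  x <- array(prep_input(image, s, model$channels),
             c(s, s, model$channels, 1))
  fw <- nn_forward(model$net, x, keep_cache = TRUE)
  gout <- matrix(0, 4, 1)
  gout[class_index + 1, 1] <- 1   # gradient of the class logit
  bw <- nn_backward(model$net, fw$cache, gout, capture = model$last_conv)
  acts <- fw$cache[[model$last_conv]]$out[, , , 1, drop = FALSE]
  grads <- bw$captured[, , , 1, drop = FALSE]
  alpha <- apply(grads, 3, mean)                 # pooled channel weights
  cam <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (c in seq_along(alpha)) cam <- cam + alpha[c] * acts[, , c, 1]
  cam <- pmax(cam, 0)
  cam <- .resize_bilinear(cam, nrow(image), ncol(image))
  mx <- max(cam)
  if (mx > 0) cam <- (cam - min(cam)) / (mx - min(cam))
  cam
}

#' Probability-weighted network-attention heatmap
#'
#' Pixelwise sum of the per-class saliency maps weighted by the model's
#' output probabilities.
#'
#' @param maps list of 4 class saliency matrices (same shape).
#' @param probabilities length-4 probability vector (sums to 1).
#' @export
weighted_heatmap <- function(maps, probabilities) {
  if (length(maps) != length(probabilities))
    stop_input("one probability per saliency map required")
  if (abs(sum(probabilities) - 1) > 1e-5)
    stop_input("probabilities must sum to 1")
  out <- maps[[1]] * probabilities[1]
  for (i in seq_along(maps)[-1]) out <- out + maps[[i]] * probabilities[i]
  out
}

#' Average the left- and right-lung model heatmaps
#' @param h_left,h_right heatmap matrices of equal shape.
#' @export
combine_lr <- function(h_left, h_right) {
  if (!all(dim(h_left) == dim(h_right))) stop_input("heatmap shape mismatch")
  (h_left + h_right) / 2
}

#' Heatmap Concordance Score
#'
#' Fraction of heatmap salience inside the lung boundary mask. The default
#' `intensity` mode is the intensity-weighted ratio
#' `sum(mask * heatmap) / sum(heatmap)`; `count` mode is the fraction of
#' non-zero heatmap pixels lying inside the mask. The two agree on binary
#' heatmaps. An all-zero heatmap has no defined score and raises an error.
#'
#' @param heatmap matrix in \[0,1\].
#' @param lung_mask logical matrix (typically the union of both lung
#'   fields), same shape.
#' @param mode `"intensity"` or `"count"`.
#' @return scalar in \[0,1\].
#' @export
hcs <- function(heatmap, lung_mask, mode = c("intensity", "count")) {
  mode <- match.arg(mode)
  if (!all(dim(heatmap) == dim(lung_mask)))
    stop_input("heatmap/mask shape mismatch")
  nz <- heatmap > 0
  if (!any(nz))
    stop(structure(class = c("cxr_undefined_hcs", "error", "condition"),
                   list(message = "all-zero heatmap: HCS undefined",
                        call = NULL)))
  m <- lung_mask > 0.5
  if (mode == "intensity") sum(heatmap * m) / sum(heatmap)
  else sum(nz & m) / sum(nz)
}

#' Macro-averaged HCS over true classes
#'
#' Averages per-image HCS within each true grade, then takes the
#' unweighted mean over the classes present (`by = "true"`, the default);
#' `by = "pred"` groups by predicted grade and `by = "image"` is the plain
#' image mean.
#'
#' @param hcs_values numeric vector of per-image scores.
#' @param classes parallel integer grades in 0..3 (ignored for
#'   `by = "image"`).
#' @param by macro-averaging axis.
#' @return an `hcs_report`: `per_class_mean` (length 4, `NA` when absent),
#'   `ma_hcs`, `n_per_class`.
#' @export
macro_hcs <- function(hcs_values, classes = NULL,
                      by = c("true", "pred", "image")) {
  by <- match.arg(by)
  if (length(hcs_values) == 0) stop_input("empty HCS input")
  if (by == "image")
    return(structure(list(per_class_mean = rep(NA_real_, 4),
                          ma_hcs = mean(hcs_values),
                          n_per_class = rep(NA_integer_, 4), by = by),
                     class = "hcs_report"))
  if (is.null(classes) || length(classes) != length(hcs_values))
    stop_input("classes must parallel hcs_values")
  if (any(!classes %in% 0:3)) stop_input("classes must be in 0..3")
  per <- vapply(0:3, function(c)
    if (any(classes == c)) mean(hcs_values[classes == c]) else NA_real_,
    numeric(1))
  structure(list(per_class_mean = per, ma_hcs = mean(per, na.rm = TRUE),
                 n_per_class = vapply(0:3, function(c) sum(classes == c),
                                      integer(1)), by = by),
            class = "hcs_report")
}

#' @export
print.hcs_report <- function(x, ...) {
  cat(sprintf("MA-HCS %.4f (per class: %s; by %s)\n", x$ma_hcs,
              paste(sprintf("%.3f", x$per_class_mean), collapse = ", "),
              x$by))
  invisible(x)
}

#' Attention heatmap of a classifier on one image
#'
#' Convenience wrapper: per-class Grad-CAM maps weighted by the predicted
#' probabilities.
#'
#' @inheritParams grad_cam
#' @export
attention_heatmap <- function(model, image) {
  pr <- predict(model, image)$probabilities[1, ]
  maps <- lapply(0:3, function(c) grad_cam(model, image, c))
  weighted_heatmap(maps, pr)
}
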