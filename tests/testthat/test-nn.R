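# The compiled backend's gradients are checked against central finite
# differences through every layer type used by the package.

test_that("backpropagated gradients match finite differences (softmax head)", {
  set.seed(1)
  net <- cxrgrade:::nn_init(list(layers = list(
    cxrgrade:::nn_conv(3, 1, 2), cxrgrade:::nn_pool(),
    cxrgrade:::nn_conv(3, 2, 3),
    cxrgrade:::nn_gap(), cxrgrade:::nn_bnorm(3),
    cxrgrade:::nn_dense(3, 4, act = "linear"))), seed = 7)
  x <- array(rnorm(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  y <- cxrgrade:::onehot4(c(1L, 3L, 0L))
  lossfun <- function(net) {
    fw <- cxrgrade:::nn_forward(net, x, train = TRUE)
    cxrgrade:::nn_loss_grad(fw$out, y, "softmax")$loss
  }
  fw <- cxrgrade:::nn_forward(net, x, keep_cache = TRUE, train = TRUE)
  lg <- cxrgrade:::nn_loss_grad(fw$out, y, "softmax")
  bw <- cxrgrade:::nn_backward(net, fw$cache, lg$grad)
  for (li in c(1, 3, 5, 6)) {
    W <- net$layers[[li]]$W
    for (j in sample(length(W), min(4, length(W)))) {
      eps <- 1e-6
      np <- net; np$layers[[li]]$W[j] <- W[j] + eps
      nm <- net; nm$layers[[li]]$W[j] <- W[j] - eps
      num <- (lossfun(np) - lossfun(nm)) / (2 * eps)
      expect_equal(bw$grads[[li]]$gW[j], num, tolerance = 1e-5,
                   label = sprintf("layer %d param %d", li, j))
    }
  }
})

test_that("segmenter-style nets (skips, upsampling, BCE) backpropagate correctly", {
  set.seed(2)
  net <- cxrgrade:::nn_init(list(layers = list(
    cxrgrade:::nn_conv(3, 1, 2), cxrgrade:::nn_stash(),
    cxrgrade:::nn_pool(), cxrgrade:::nn_conv(3, 2, 2),
    cxrgrade:::nn_upsample(), cxrgrade:::nn_addpop(),
    cxrgrade:::nn_conv(3, 2, 1, act = "linear"))), seed = 8)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 1 * 2, 1, 0.4), c(8, 8, 1, 2))
  lossfun <- function(net) {
    fw <- cxrgrade:::nn_forward(net, x)
    cxrgrade:::nn_loss_grad(fw$out, y, "bce")$loss
  }
  fw <- cxrgrade:::nn_forward(net, x, keep_cache = TRUE)
  lg <- cxrgrade:::nn_loss_grad(fw$out, y, "bce")
  bw <- cxrgrade:::nn_backward(net, fw$cache, lg$grad)
  for (li in c(1, 4, 7)) {
    W <- net$layers[[li]]$W
    for (j in sample(length(W), 4)) {
      eps <- 1e-6
      np <- net; np$layers[[li]]$W[j] <- W[j] + eps
      nm <- net; nm$layers[[li]]$W[j] <- W[j] - eps
      num <- (lossfun(np) - lossfun(nm)) / (2 * eps)
      expect_equal(bw$grads[[li]]$gW[j], num, tolerance = 1e-5)
    }
  }
})

test_that("raster kernels behave geometrically", {
  # bilinear resize preserves constants and range
  m <- matrix(runif(64 * 64), 64, 64)
  r <- cxrgrade:::.resize_bilinear(m, 32, 48)
  expect_equal(dim(r), c(32, 48))
  expect_true(all(r >= min(m) - 1e-12 & r <= max(m) + 1e-12))
  expect_equal(cxrgrade:::.resize_bilinear(matrix(0.7, 16, 16), 24, 24),
               matrix(0.7, 24, 24), tolerance = 1e-12)
  # identity affine warp returns the image
  expect_equal(cxrgrade:::.affine_warp(m, 0, 1, 0, 0), m,
               tolerance = 1e-12)
  # rotation changes pixels but keeps shape
  w <- cxrgrade:::.affine_warp(m, 10, 1, 0, 0)
  expect_equal(dim(w), dim(m))
  expect_gt(sum(abs(w - m)), 0)
  # connected components: two separated squares
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2:4] <- TRUE
  mask[7:9, 7:9] <- TRUE
  lab <- cxrgrade:::.label_components(mask)
  expect_equal(attr(lab, "n"), 2)
  expect_equal(sort(unique(as.vector(lab))), 0:2)
})

test_that("early stopping halts within the patience window of the best epoch", {
  set.seed(3)
  net <- cxrgrade:::nn_init(list(layers = list(
    cxrgrade:::nn_gap(), cxrgrade:::nn_dense(1, 4, act = "linear"))),
    seed = 5)
  x <- array(rnorm(4 * 4 * 1 * 8), c(4, 4, 1, 8))
  y <- cxrgrade:::onehot4(sample(0:3, 8, replace = TRUE))
  # a vanishing learning rate freezes the net: epoch 1 is the best epoch
  fit <- cxrgrade:::nn_fit(net, x, y, x, y, loss = "softmax", epochs = 40,
                           batch_size = 8, lr = 1e-15, lr_patience = 7,
                           stop_patience = 10, min_lr = 1e-20, seed = 6)
  expect_lte(nrow(fit$history), 1 + 10)
  expect_equal(fit$best_epoch, 1)
  # learning-rate reduction kicked in after 7 stalled epochs
  expect_lt(fit$history$lr[nrow(fit$history)], 1e-15)
})

test_that("non-finite losses raise a training-failure signal with the epoch", {
  net <- cxrgrade:::nn_init(list(layers = list(
    cxrgrade:::nn_gap(), cxrgrade:::nn_dense(1, 4, act = "linear"))),
    seed = 5)
  x <- array(NaN, c(4, 4, 1, 4))
  y <- cxrgrade:::onehot4(c(0L, 1L, 2L, 3L))
  expect_error(
    cxrgrade:::nn_fit(net, x, y, x, y, loss = "softmax", epochs = 2,
                      batch_size = 4, lr = 1e-3, lr_patience = 7,
                      stop_patience = 10, seed = 1),
    class = "cxr_training_failure")
})
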