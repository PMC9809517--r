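# Minimal dense/convolutional network backend used by the segmenter, the
# opacity classifiers, and Grad-CAM. Networks are plain lists of layers;
# batches are arrays dim (H, W, C, N). Only what the pipeline needs is
# implemented: 'same' convolutions (odd kernel), 2x2 max pooling, nearest
# 2x upsampling, additive skip connections, flatten and dense layers,
# softmax cross-entropy / pixelwise sigmoid BCE losses, and Adam.

nn_conv <- function(k, cin, cout, act = "relu", trainable = TRUE) {
  list(type = "conv", k = k, cin = cin, cout = cout, act = act,
       trainable = trainable, W = NULL, b = NULL)
}
nn_pool <- function() list(type = "maxpool")
nn_upsample <- function() list(type = "upsample")
nn_stash <- function() list(type = "stash")      # push activation
nn_addpop <- function() list(type = "addpop")    # pop last stash, add
nn_flatten <- function() list(type = "flatten")
nn_gap <- function() list(type = "gap")  # global average pooling
nn_dense <- function(nin, nout, act = "relu", trainable = TRUE) {
  list(type = "dense", nin = nin, nout = nout, act = act,
       trainable = trainable, W = NULL, b = NULL)
}
# channelwise batch normalization on feature matrices (C x N); W = gamma,
# b = beta so the generic Adam step applies
nn_bnorm <- function(n, momentum = 0.9, eps = 1e-5, trainable = TRUE) {
  list(type = "bnorm", n = n, momentum = momentum, eps = eps,
       trainable = trainable, W = NULL, b = NULL,
       run_mean = NULL, run_var = NULL)
}

# He-normal initialization of every parameterized layer, in place.
nn_init <- function(net, seed) {
  with_seed(seed, {
    for (i in seq_along(net$layers)) {
      l <- net$layers[[i]]
      if (l$type == "conv") {
        fan_in <- l$k * l$k * l$cin
        l$W <- matrix(stats::rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)),
                      fan_in, l$cout)
        l$b <- numeric(l$cout)
      } else if (l$type == "dense") {
        l$W <- matrix(stats::rnorm(l$nin * l$nout, sd = sqrt(2 / l$nin)),
                      l$nout, l$nin)
        l$b <- numeric(l$nout)
      } else if (l$type == "bnorm") {
        l$W <- rep(1, l$n)
        l$b <- numeric(l$n)
        l$run_mean <- numeric(l$n)
        l$run_var <- rep(1, l$n)
      }
      net$layers[[i]] <- l
    }
  })
  net
}

nn_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation: ", act))
}

# Forward pass. Returns list(out, cache, net); cache[[i]] keeps what layer
# i needs for backward (inputs, pre-activations, pool indices); net comes
# back with updated batch-norm running statistics when train = TRUE.
nn_forward <- function(net, x, keep_cache = FALSE, train = FALSE) {
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  stash <- list()
  a <- x
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      z <- .conv_fw(a, l$W, l$b, l$k)
      out <- nn_act(z, l$act)
      if (keep_cache) cache[[i]] <- list(x = a, z = z, out = out)
      a <- out
    } else if (l$type == "maxpool") {
      mp <- .maxpool_fw(a)
      if (keep_cache) cache[[i]] <- list(idx = mp$idx, H = dim(a)[1],
                                         W = dim(a)[2])
      a <- mp$y
    } else if (l$type == "upsample") {
      a <- .upsample_fw(a)
    } else if (l$type == "stash") {
      stash[[length(stash) + 1L]] <- a
    } else if (l$type == "addpop") {
      s <- stash[[length(stash)]]
      stash[[length(stash)]] <- NULL
      a <- a + s
    } else if (l$type == "flatten") {
      if (keep_cache) cache[[i]] <- list(d = dim(a))
      a <- matrix(a, prod(dim(a)[1:3]), dim(a)[4])
    } else if (l$type == "gap") {
      if (keep_cache) cache[[i]] <- list(d = dim(a))
      a <- matrix(colMeans(matrix(a, prod(dim(a)[1:2]),
                                  prod(dim(a)[3:4]))),
                  dim(a)[3], dim(a)[4])
    } else if (l$type == "bnorm") {
      if (train) {
        mu <- rowMeans(a)
        v <- rowMeans((a - mu)^2)
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
        net$layers[[i]] <- l
      } else {
        mu <- l$run_mean
        v <- l$run_var
      }
      sdv <- sqrt(v + l$eps)
      xhat <- (a - mu) / sdv
      if (keep_cache) cache[[i]] <- list(xhat = xhat, sdv = sdv,
                                         train = train)
      a <- l$W * xhat + l$b
    } else if (l$type == "dense") {
      z <- l$W %*% a + l$b
      out <- nn_act(z, l$act)
      if (keep_cache) cache[[i]] <- list(x = a, z = z)
      a <- out
    }
  }
  list(out = a, cache = cache, net = net)
}

# Backward pass from a gradient w.r.t. the network output. Returns
# per-layer parameter gradients and, when requested via `capture`, the
# gradient arriving at the *output* of the given layer index (Grad-CAM).
nn_backward <- function(net, cache, gout, need_gx = FALSE, capture = 0L) {
  L <- length(net$layers)
  grads <- vector("list", L)
  gstash <- list()
  captured <- NULL
  g <- gout
  for (i in rev(seq_len(L))) {
    l <- net$layers[[i]]
    if (i == capture) captured <- g
    if (l$type == "conv") {
      cc <- cache[[i]]
      gz <- if (l$act == "relu") g * (cc$z > 0) else g
      bw <- .conv_bw(cc$x, l$W, gz, l$k, need_gx || i > 1)
      grads[[i]] <- list(gW = bw$gW, gb = bw$gb)
      g <- if (!is.null(bw$gx)) bw$gx else NULL
    } else if (l$type == "maxpool") {
      cc <- cache[[i]]
      g <- .maxpool_bw(g, cc$idx, cc$H, cc$W)
    } else if (l$type == "upsample") {
      g <- .upsample_bw(g)
    } else if (l$type == "addpop") {
      gstash[[length(gstash) + 1L]] <- g
    } else if (l$type == "stash") {
      g <- g + gstash[[length(gstash)]]
      gstash[[length(gstash)]] <- NULL
    } else if (l$type == "flatten") {
      dim(g) <- cache[[i]]$d
    } else if (l$type == "gap") {
      d <- cache[[i]]$d
      g <- array(rep(g, each = d[1] * d[2]) / (d[1] * d[2]), d)
    } else if (l$type == "bnorm") {
      cc <- cache[[i]]
      grads[[i]] <- list(gW = rowSums(g * cc$xhat), gb = rowSums(g))
      dxh <- g * l$W
      if (isTRUE(cc$train)) {
        nb <- ncol(dxh)
        g <- (dxh * nb - rowSums(dxh) -
                cc$xhat * rowSums(dxh * cc$xhat)) / (nb * cc$sdv)
      } else {
        g <- dxh / cc$sdv
      }
    } else if (l$type == "dense") {
      cc <- cache[[i]]
      gz <- switch(l$act,
                   relu = g * (cc$z > 0),
                   linear = g,
                   sigmoid = { s <- nn_act(cc$z, "sigmoid"); g * s * (1 - s) })
      grads[[i]] <- list(gW = gz %*% t(cc$x), gb = rowSums(gz))
      g <- if (i > 1 || need_gx) t(l$W) %*% gz else NULL
    }
  }
  list(grads = grads, gx = g, captured = captured)
}

nn_adam_state <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

nn_adam_step <- function(net, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (is.null(grads[[i]]) || is.null(l$W) || !isTRUE(l$trainable)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$gb^2
    l$W <- l$W - lr * (s$mW / b1t) / (sqrt(s$vW / b2t) + eps)
    l$b <- l$b - lr * (s$mb / b1t) / (sqrt(s$vb / b2t) + eps)
    net$layers[[i]] <- l
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# loss + output-gradient for the two heads used in the package
nn_loss_grad <- function(out, y, loss) {
  n <- ncol(out) %||% dim(out)[4]
  if (loss == "softmax") {
    z <- sweep(out, 2, apply(out, 2, max))
    e <- exp(z)
    p <- sweep(e, 2, colSums(e), "/")
    eps <- 1e-12
    list(loss = -mean(log(pmax(colSums(p * y), eps))),
         grad = (p - y) / n, prob = p)
  } else if (loss == "bce") {
    p <- 1 / (1 + exp(-out))
    m <- length(out)
    eps <- 1e-12
    list(loss = -sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) / m,
         grad = (p - y) / m, prob = p)
  } else stop("unknown loss")
}

nn_eval_loss <- function(net, x, y, loss, batch_size = 32L) {
  n <- dim(x)[4]
  tot <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- x[, , , ix, drop = FALSE]
    yb <- if (loss == "softmax") y[, ix, drop = FALSE]
          else y[, , , ix, drop = FALSE]
    fw <- nn_forward(net, xb)
    tot <- tot + nn_loss_grad(fw$out, yb, loss)$loss * length(ix)
  }
  tot / n
}

nn_get_params <- function(net)
  lapply(net$layers, function(l) if (is.null(l$W)) NULL
         else list(W = l$W, b = l$b, run_mean = l$run_mean,
                   run_var = l$run_var))

nn_set_params <- function(net, params) {
  for (i in seq_along(params))
    if (!is.null(params[[i]])) {
      net$layers[[i]]$W <- params[[i]]$W
      net$layers[[i]]$b <- params[[i]]$b
      if (!is.null(params[[i]]$run_mean)) {
        net$layers[[i]]$run_mean <- params[[i]]$run_mean
        net$layers[[i]]$run_var <- params[[i]]$run_var
      }
    }
  net
}

# One optimisation run: Adam, plateau LR reduction, early stopping, and
# restoration of the best-validation-loss weights. Returns the trained net
# plus a per-epoch history data frame.
nn_fit <- function(net, x, y, xval, yval, loss,
                   epochs, batch_size = 32L, lr = 1e-3,
                   lr_patience = 7L, stop_patience = 10L,
                   lr_factor = 0.1, min_lr = 1e-6, seed = NULL,
                   stage = 1L) {
  n <- dim(x)[4]
  state <- nn_adam_state(net)
  hist <- NULL
  best <- list(loss = Inf, params = nn_get_params(net), epoch = 0L)
  stall_lr <- 0L; stall_stop <- 0L; t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      for (ix in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- x[, , , ix, drop = FALSE]
        yb <- if (loss == "softmax") y[, ix, drop = FALSE]
              else y[, , , ix, drop = FALSE]
        fw <- nn_forward(net, xb, keep_cache = TRUE, train = TRUE)
        net <- fw$net
        lg <- nn_loss_grad(fw$out, yb, loss)
        if (!is.finite(lg$loss))
          stop(structure(class = c("cxr_training_failure", "error",
                                   "condition"),
                         list(message = sprintf(
                           "non-finite loss at epoch %d", ep),
                           call = NULL, epoch = ep)))
        bw <- nn_backward(net, fw$cache, lg$grad)
        t <- t + 1L
        up <- nn_adam_step(net, bw$grads, state, lr, t)
        net <- up$net; state <- up$state
        tr_loss <- tr_loss + lg$loss * length(ix)
      }
      tr_loss <- tr_loss / n
      val_loss <- nn_eval_loss(net, xval, yval, loss, batch_size)
      hist <- rbind(hist, data.frame(stage = stage, epoch = ep, lr = lr,
                                     train_loss = tr_loss,
                                     val_loss = val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = nn_get_params(net),
                     epoch = ep)
        stall_lr <- 0L; stall_stop <- 0L
      } else {
        stall_lr <- stall_lr + 1L
        stall_stop <- stall_stop + 1L
        if (stall_lr >= lr_patience && lr > min_lr) {
          lr <- max(lr * lr_factor, min_lr)
          stall_lr <- 0L
        }
        if (stall_stop >= stop_patience) break
      }
    }
  })
  net <- nn_set_params(net, best$params)
  list(net = net, history = hist, best_epoch = best$epoch,
       best_val_loss = best$loss)
}
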