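## Minimal dense/convolutional network engine used by the learned model
## observers. Batches are matrices with one vectorized image per column
## (layout r + H*c + H*W*ch). Networks output raw logits; the sigmoid lives
## in the loss (numerically stable binary cross-entropy with logits) and in
## the user-facing score functions. Backpropagation is verified against
## finite differences in the test suite.

lrelu_slope <- 0.01

act_forward <- function(z, act) {
  switch(act,
    linear = z,
    lrelu = .lrelu_fwd(z, lrelu_slope),
    stop_taskmo("unknown activation: ", act)
  )
}

## Fan-in scaled uniform initialization, drawn from the current RNG stream.
init_weights <- function(fan_in, n) {
  a <- sqrt(6 / fan_in)
  runif(n, -a, a)
}

nn_conv_layer <- function(H, W, Cin, F, act = "lrelu") {
  list(
    type = "conv", H = H, W = W, Cin = Cin, F = F, act = act,
    W_ = matrix(init_weights(9 * Cin, 9 * Cin * F), 9 * Cin, F),
    b = numeric(F)
  )
}

nn_dense_layer <- function(D, K, act = "linear") {
  list(
    type = "dense", D = D, K = K, act = act,
    W_ = matrix(init_weights(D, D * K), D, K),
    b = numeric(K)
  )
}

## The per-layer cache stores the layer input and its *activated* output;
## for LeakyReLU the pre-activation sign equals the output sign, so the
## activation gradient can be recovered from the output (this permits fusing
## the activation into the C++ conv kernel).
nn_forward <- function(net, x, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    a <- if (ly$type == "conv") {
      .conv3x3_forward(x, ly$W_, ly$b, ly$H, ly$W, ly$Cin,
                       act = if (ly$act == "lrelu") 1L else 0L,
                       slope = lrelu_slope)
    } else {
      act_forward(crossprod(ly$W_, x) + ly$b, ly$act)
    }
    if (keep_cache) cache[[i]] <- list(x = x, a = a)
    x <- a
  }
  list(out = x, cache = cache)
}

## dout is the gradient wrt the final activation output.
nn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  g <- dout
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    dz <- if (ly$act == "lrelu") .lrelu_bwd(cc$a, g, lrelu_slope) else g
    if (ly$type == "conv") {
      bk <- .conv3x3_backward(cc$x, ly$W_, dz, ly$H, ly$W, ly$Cin,
                              need_gx = i > 1L)
      grads[[i]] <- list(W_ = bk$gw, b = as.numeric(bk$gb))
      g <- bk$gx
    } else {
      grads[[i]] <- list(W_ = cc$x %*% t(dz), b = rowSums(dz))
      g <- ly$W_ %*% dz
    }
  }
  grads
}

n_parameters <- function(net) {
  sum(vapply(net$layers, function(ly) length(ly$W_) + length(ly$b), numeric(1)))
}

## Sum of squared weight-matrix entries (biases excluded): the weight-decay
## penalty term.
weight_sq_norm <- function(net) {
  sum(vapply(net$layers, function(ly) sum(ly$W_^2), numeric(1)))
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

## Mean binary cross-entropy with logits; targets y in [0,1] (scalar labels
## or pixel images). Returns loss and gradient wrt logits.
bce_with_logits <- function(z, y) {
  n <- length(z)
  list(
    loss = sum(softplus(z) - y * z) / n,
    dz = (stats::plogis(z) - y) / n
  )
}

mse_loss <- function(z, y) {
  n <- length(z)
  list(loss = sum((z - y)^2) / n, dz = 2 * (z - y) / n)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    list(mW = ly$W_ * 0, vW = ly$W_ * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

## Force fresh copies of all parameter arrays so that the in-place Adam
## kernel never mutates arrays the caller still references.
deep_copy_net <- function(net) {
  net$layers <- lapply(net$layers, function(ly) {
    ly$W_ <- ly$W_ + 0
    ly$b <- ly$b + 0
    ly
  })
  net
}

## Updates net parameters and optimizer state IN PLACE (C++ kernel); the
## weight-decay gradient 2*lambda*W applies to weight matrices, not biases.
adam_step_inplace <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                              beta2 = 0.999, eps = 1e-8, lambda = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    .adam_update(net$layers[[i]]$W_, state[[i]]$mW, state[[i]]$vW,
                 grads[[i]]$W_, lr, beta1, beta2, eps, bc1, bc2, 2 * lambda)
    .adam_update(net$layers[[i]]$b, state[[i]]$mb, state[[i]]$vb,
                 grads[[i]]$b, lr, beta1, beta2, eps, bc1, bc2, 0)
  }
  invisible(NULL)
}

## Generic mini-batch Adam loop. `loss_fn(net, xb, i_batch)` returns
## list(loss, grads). `monitor(net)` returns a validation loss after each
## epoch; training stops early when it has not improved for `patience`
## epochs (patience = Inf disables early stopping). Returns the best
## (lowest-monitor) network when early stopping is active, else the final
## one.
nn_train_loop <- function(net, n_obs, batch_size, epochs, loss_fn,
                          monitor = NULL, patience = Inf, lr = 1e-3,
                          lambda = 0, verbose = FALSE, monitor_every = 1) {
  net <- deep_copy_net(net) # in-place updates must not touch the caller's copy
  state <- adam_init(net)
  t <- 0
  history <- data.frame(
    epoch = integer(), train_loss = numeric(), val_loss = numeric()
  )
  best <- list(val = Inf, net = net, epoch = 0)
  wait <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n_obs)
    starts <- seq(1, n_obs, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      b <- idx[s:min(s + batch_size - 1, n_obs)]
      lf <- loss_fn(net, b)
      if (!is.finite(lf$loss)) {
        stop_taskmo(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep))
      }
      t <- t + 1
      adam_step_inplace(net, lf$grads, state, t, lr = lr, lambda = lambda)
      ep_loss <- ep_loss + lf$loss * length(b)
    }
    val <- if (is.null(monitor) || (ep %% monitor_every != 0 && ep != epochs)) {
      NA_real_
    } else {
      monitor(net)
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / n_obs, val_loss = val
    ))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss / n_obs, val))
    }
    if (!is.null(monitor) && !is.na(val) && is.finite(patience)) {
      if (val < best$val - 1e-7) {
        best <- list(val = val, net = deep_copy_net(net), epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    } else if (!is.null(monitor) && !is.na(val) && val < best$val) {
      best <- list(val = val, net = deep_copy_net(net), epoch = ep)
    }
  }
  final_net <- if (!is.null(monitor) && is.finite(patience) && best$epoch > 0) {
    best$net
  } else {
    net
  }
  list(net = final_net, history = history, best_epoch = best$epoch)
}
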