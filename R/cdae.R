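#' Convolutional denoising autoencoder configuration
#'
#' The encoder stacks `depth` 3x3 zero-padded convolutional layers
#' (LeakyReLU) and a fully connected bottleneck of `latent_units`; the
#' decoder mirrors it back to the image, ending in a sigmoid so
#' reconstructions live in [0, 1] like the normalized inputs. Training
#' corrupts inputs by zeroing random pixels and reconstructs the clean image
#' under a pixelwise cross-entropy plus an l2 weight-decay penalty
#' `lambda * ||W||^2` (weight matrices only, biases excluded).
#'
#' The shipped defaults are the selected architecture for this family of
#' tasks: one convolutional layer with 16 filters, 25 latent units and
#' `lambda = 0.001`.
#'
#' @param depth encoder convolutional layers (1-8).
#' @param filters filters per layer (4, 8 or 16).
#' @param latent_units bottleneck dimension (2-32).
#' @param corruption_rate fraction of input pixels zeroed during training.
#' @param lambda weight-decay strength (>= 0, classically in [0, 0.1]).
#' @return a `cdae_config`.
#' @export
cdae_config <- function(depth = 1, filters = 16, latent_units = 25,
                        corruption_rate = 0.2, lambda = 0.001) {
  if (!(depth %in% 1:8)) stop_taskmo("CDAE depth must be in 1..8")
  if (!(filters %in% c(4, 8, 16))) stop_taskmo("filters must be 4, 8 or 16")
  if (latent_units < 2 || latent_units > 32) {
    stop_taskmo("latent_units must be in 2..32")
  }
  if (corruption_rate < 0 || corruption_rate > 1) {
    stop_taskmo("corruption_rate must be in [0, 1]")
  }
  if (lambda < 0) stop_taskmo("lambda must be >= 0")
  structure(
    list(depth = as.integer(depth), filters = as.integer(filters),
         latent_units = as.integer(latent_units),
         corruption_rate = corruption_rate, lambda = lambda),
    class = "cdae_config"
  )
}

#' CDAE training configuration
#'
#' @param max_epochs epoch cap; early stopping usually halts sooner.
#' @param patience epochs without validation-reconstruction improvement
#'   before stopping.
#' @param batch_size,lr mini-batch size and Adam learning rate.
#' @param seed seed for corruption, batching (initialization is seeded by
#'   [build_cdae()]).
#' @return a `cdae_train_config`.
#' @export
cdae_train_config <- function(max_epochs = 200, patience = 5, batch_size = 64,
                              lr = 1e-3, seed = 1) {
  structure(
    list(max_epochs = as.integer(max_epochs), patience = patience,
         batch_size = as.integer(batch_size), lr = lr, seed = as.integer(seed)),
    class = "cdae_train_config"
  )
}

#' Corrupt images by zeroing random pixels
#'
#' The denoising pretext task: each pixel is independently set to zero with
#' probability `rate`. The input is not modified in place.
#'
#' @param images `M x n` matrix.
#' @param rate corruption probability in [0, 1].
#' @param seed RNG seed.
#' @return corrupted copy of `images`.
#' @export
corrupt_inputs <- function(images, rate, seed) {
  if (rate < 0 || rate > 1) stop_taskmo("corruption rate must be in [0, 1]")
  if (rate == 0) return(images)
  with_seed(seed, {
    mask <- matrix(runif(length(images)) < rate, nrow(images), ncol(images))
    images[mask] <- 0
    images
  })
}

#' Build an untrained convolutional denoising autoencoder
#'
#' @param grid the [pixel_grid()] of the images.
#' @param config a [cdae_config()].
#' @param seed weight-initialization seed.
#' @return a `cdae_model`.
#' @export
build_cdae <- function(grid, config = cdae_config(), seed = 1) {
  stopifnot(inherits(config, "cdae_config"))
  H <- grid$n_rows
  W <- grid$n_cols
  net <- with_seed(derive_seed(seed, "cdae-init"), {
    layers <- list()
    cin <- 1L
    for (i in seq_len(config$depth)) {
      layers[[length(layers) + 1]] <- nn_conv_layer(H, W, cin, config$filters, act = "lrelu")
      cin <- config$filters
    }
    layers[[length(layers) + 1]] <-
      nn_dense_layer(H * W * cin, config$latent_units, act = "linear")
    n_enc <- length(layers)
    layers[[length(layers) + 1]] <-
      nn_dense_layer(config$latent_units, H * W * cin, act = "lrelu")
    for (i in seq_len(config$depth - 1)) {
      layers[[length(layers) + 1]] <- nn_conv_layer(H, W, cin, config$filters, act = "lrelu")
    }
    layers[[length(layers) + 1]] <- nn_conv_layer(H, W, cin, 1L, act = "linear")
    list(layers = layers, n_enc = n_enc)
  })
  structure(
    list(grid = grid, config = config, net = net, n_enc = net$n_enc,
         trained = FALSE, history = NULL, seed = as.integer(seed)),
    class = "cdae_model"
  )
}

#' Train a CDAE on unlabeled images
#'
#' Self-supervised pretext training: inputs are corrupted by pixel zeroing
#' (re-drawn every mini-batch) and the network minimizes the pixelwise
#' cross-entropy between the clean image and the reconstruction of the
#' corrupted input, plus the weight-decay penalty. Labels are never consumed.
#' Early stopping monitors the reconstruction loss on held-out images; the
#' weights from the best validation epoch are kept.
#'
#' @param model a `cdae_model` from [build_cdae()].
#' @param images training images, `M x n` matrix with values in [0, 1].
#' @param val_images validation images for early stopping.
#' @param cfg a [cdae_train_config()].
#' @return the trained `cdae_model` with a `history` data frame.
#' @export
train_cdae <- function(model, images, val_images, cfg = cdae_train_config()) {
  stopifnot(inherits(model, "cdae_model"))
  if (inherits(images, "detection_dataset")) images <- images$images
  if (inherits(val_images, "detection_dataset")) val_images <- val_images$images
  rng <- range(images, val_images)
  if (rng[1] < 0 || rng[2] > 1) {
    stop_taskmo("CDAE inputs must be normalized to [0, 1] (cross-entropy targets)")
  }
  lam <- model$config$lambda
  rate <- model$config$corruption_rate
  xv_cor <- corrupt_inputs(val_images, rate, derive_seed(cfg$seed, "val-corrupt"))
  res <- with_seed(derive_seed(cfg$seed, "cdae-train"), {
    nn_train_loop(
      model$net, n_obs = ncol(images), batch_size = cfg$batch_size,
      epochs = cfg$max_epochs, lr = cfg$lr, lambda = lam,
      patience = cfg$patience,
      loss_fn = function(net, b) {
        xb <- images[, b, drop = FALSE]
        xc <- xb
        if (rate > 0) {
          mask <- matrix(runif(length(xb)) < rate, nrow(xb), ncol(xb))
          xc[mask] <- 0
        }
        fw <- nn_forward(net, xc, keep_cache = TRUE)
        ## reconstruction CE summed over pixels, averaged over the batch
        lf <- bce_with_logits(fw$out, xb)
        M <- nrow(xb)
        lf$dz <- lf$dz * M
        list(loss = lf$loss * M + lam * weight_sq_norm(net),
             grads = nn_backward(net, fw$cache, lf$dz))
      },
      monitor = function(net) {
        nrow(val_images) *
          bce_with_logits(nn_forward(net, xv_cor)$out, val_images)$loss
      }
    )
  })
  model$net <- res$net
  model$history <- res$history
  model$best_epoch <- res$best_epoch
  model$trained <- TRUE
  model
}

#' Encode images into the CDAE latent space
#'
#' Runs the trained encoder only; no corruption is applied at encoding time.
#'
#' @param model a trained `cdae_model`.
#' @param images `M x n` matrix or `detection_dataset`.
#' @return `n x latent_units` feature matrix.
#' @export
encode <- function(model, images) {
  stopifnot(inherits(model, "cdae_model"))
  if (!isTRUE(model$trained)) stop_taskmo("model must be trained before encoding")
  if (inherits(images, "detection_dataset")) images <- images$images
  x <- images
  for (i in seq_len(model$n_enc)) {
    ly <- model$net$layers[[i]]
    x <- if (ly$type == "conv") {
      .conv3x3_forward(x, ly$W_, ly$b, ly$H, ly$W, ly$Cin,
                       act = if (ly$act == "lrelu") 1L else 0L,
                       slope = lrelu_slope)
    } else {
      act_forward(crossprod(ly$W_, x) + ly$b, ly$act)
    }
  }
  t(x)
}

#' Reconstruct images with a trained CDAE
#'
#' @param model a trained `cdae_model`.
#' @param images `M x n` matrix in [0, 1].
#' @return `M x n` matrix of reconstructions in (0, 1).
#' @export
reconstruct <- function(model, images) {
  stopifnot(inherits(model, "cdae_model"), isTRUE(model$trained))
  if (inherits(images, "detection_dataset")) images <- images$images
  stats::plogis(nn_forward(model$net, images)$out)
}

#' Principal component analysis feature extractor
#'
#' The linear baseline: a one-layer linear autoencoder trained with squared
#' error converges to the principal subspace, so PCA is the natural linear
#' counterpart of the CDAE features.
#'
#' @param images `M x n` matrix (columns are images).
#' @param k number of components, `k <= min(n - 1, M)`.
#' @return a `pca_features` object with orthonormal `components` (`M x k`),
#'   `center` and a `predict` method mapping images to `n x k` scores.
#' @export
fit_pca <- function(images, k) {
  if (inherits(images, "detection_dataset")) images <- images$images
  n <- ncol(images)
  M <- nrow(images)
  if (k > min(n - 1, M)) {
    stop_taskmo(sprintf("k = %d exceeds min(n - 1, M) = %d", k, min(n - 1, M)))
  }
  pc <- prcomp(t(images), center = TRUE, scale. = FALSE, rank. = k)
  structure(
    list(components = pc$rotation, center = pc$center,
         sdev = pc$sdev[seq_len(k)], k = k),
    class = "pca_features"
  )
}

#' @export
predict.pca_features <- function(object, images, ...) {
  if (inherits(images, "detection_dataset")) images <- images$images
  crossprod(images - object$center, object$components)
}

#' Train a one-hidden-layer linear autoencoder with squared-error loss
#'
#' Linear encoder/decoder trained by Adam on the mean squared reconstruction
#' error. At the optimum the decoder's column space equals the top-`k`
#' principal subspace of the data (the encoder may carry arbitrary
#' components along zero-variance directions, so the decoder range is the
#' meaningful subspace); the test suite verifies this against [fit_pca()]
#' through principal angles.
#'
#' @param images `M x n` matrix.
#' @param k bottleneck dimension.
#' @param epochs,lr,batch_size training parameters.
#' @param seed RNG seed.
#' @return list with `encoder` (`M x k` weights), `decoder` (`M x k`,
#'   columns span the learned reconstruction subspace), `net`, `history`.
#' @export
train_linear_ae <- function(images, k, epochs = 400, lr = 1e-2,
                            batch_size = 32, seed = 1) {
  M <- nrow(images)
  ctr <- rowMeans(images)
  x <- images - ctr
  net <- with_seed(derive_seed(seed, "lae-init"), {
    list(layers = list(
      nn_dense_layer(M, k, act = "linear"),
      nn_dense_layer(k, M, act = "linear")
    ))
  })
  res <- with_seed(derive_seed(seed, "lae-train"), {
    nn_train_loop(
      net, n_obs = ncol(x), batch_size = batch_size, epochs = epochs, lr = lr,
      loss_fn = function(net, b) {
        xb <- x[, b, drop = FALSE]
        fw <- nn_forward(net, xb, keep_cache = TRUE)
        lf <- mse_loss(fw$out, xb)
        list(loss = lf$loss, grads = nn_backward(net, fw$cache, lf$dz))
      }
    )
  })
  list(encoder = res$net$layers[[1]]$W_,
       decoder = t(res$net$layers[[2]]$W_),
       net = res$net, history = res$history, center = ctr)
}

#' Bayesian search over CDAE architectures
#'
#' Sequential model-based optimization of (depth, filters, latent_units)
#' minimizing validation reconstruction cross-entropy. A Gaussian-process
#' surrogate with an RBF kernel is fitted to the evaluated trials and the
#' next candidate maximizes expected improvement over the full discrete
#' space; the initial design is a Latin hypercube. Each trial re-splits the
#' provided images into training and validation sets by resampling.
#'
#' @param images unlabeled images (`M x n` matrix or `detection_dataset`).
#' @param grid the [pixel_grid()].
#' @param trials total number of architecture evaluations.
#' @param seed master seed.
#' @param depth_range,filters_set,latent_range search-space bounds.
#' @param train_cfg a [cdae_train_config()] applied to every trial.
#' @param val_fraction fraction of images held out per trial.
#' @param corruption_rate,lambda fixed non-architectural hyperparameters.
#' @return list with `best` (a [cdae_config()]) and `log` (one row per
#'   trial: architecture, validation loss).
#' @export
cdae_bayesian_search <- function(images, grid, trials = 20, seed = 1,
                                 depth_range = c(1, 8),
                                 filters_set = c(4, 8, 16),
                                 latent_range = c(2, 32),
                                 train_cfg = cdae_train_config(),
                                 val_fraction = 0.2,
                                 corruption_rate = 0.2, lambda = 0.001) {
  if (inherits(images, "detection_dataset")) images <- images$images
  if (trials < 1) stop_taskmo("trials must be >= 1")
  depths <- seq(depth_range[1], depth_range[2])
  latents <- seq(latent_range[1], latent_range[2])
  space <- expand.grid(depth = depths, filters = filters_set, latent = latents)
  if (nrow(space) == 0) stop_taskmo("empty architecture search space")
  ## normalized coordinates for the surrogate
  norm_x <- function(cfg_rows) {
    cbind(
      (cfg_rows$depth - min(depths)) / max(1, diff(range(depths))),
      (match(cfg_rows$filters, filters_set) - 1) / max(1, length(filters_set) - 1),
      (cfg_rows$latent - min(latents)) / max(1, diff(range(latents)))
    )
  }
  Xall <- norm_x(space)

  evaluate <- function(row, trial) {
    tr_seed <- derive_seed(seed, sprintf("bayes-trial-%d", trial))
    n <- ncol(images)
    idx <- with_seed(tr_seed, sample.int(n))
    n_val <- max(2, round(val_fraction * n))
    val <- images[, idx[seq_len(n_val)], drop = FALSE]
    trn <- images[, idx[-seq_len(n_val)], drop = FALSE]
    cfg <- cdae_config(row$depth, row$filters, row$latent,
                       corruption_rate = corruption_rate, lambda = lambda)
    model <- build_cdae(grid, cfg, seed = tr_seed)
    tc <- train_cfg
    tc$seed <- tr_seed
    model <- train_cdae(model, trn, val, tc)
    min(model$history$val_loss)
  }

  n_init <- min(max(3, min(5, trials)), trials)
  init_idx <- with_seed(derive_seed(seed, "bayes-init"), {
    u <- lhs::randomLHS(n_init, 3)
    apply(u, 1, function(p) {
      d <- depths[pmin(length(depths), 1 + floor(p[1] * length(depths)))]
      f <- filters_set[pmin(length(filters_set), 1 + floor(p[2] * length(filters_set)))]
      l <- latents[pmin(length(latents), 1 + floor(p[3] * length(latents)))]
      which(space$depth == d & space$filters == f & space$latent == l)[1]
    })
  })
  init_idx <- unique(init_idx)

  log_df <- data.frame()
  tried <- integer()
  for (t_i in seq_len(trials)) {
    cand <- if (t_i <= length(init_idx)) {
      init_idx[t_i]
    } else {
      ## GP-EI proposal over the untried configurations
      X <- norm_x(space[tried, , drop = FALSE])
      y <- log_df$val_loss
      mu_y <- mean(y)
      sd_y <- max(sd(y), 1e-9)
      ys <- (y - mu_y) / sd_y
      ell <- 0.3
      Kf <- exp(-0.5 * as.matrix(stats::dist(X))^2 / ell^2) + diag(1e-4, nrow(X))
      alpha <- solve(Kf, ys)
      free <- setdiff(seq_len(nrow(space)), tried)
      Xf <- Xall[free, , drop = FALSE]
      d2 <- outer(rowSums(Xf^2), rowSums(X^2), `+`) - 2 * Xf %*% t(X)
      Ks <- exp(-0.5 * pmax(d2, 0) / ell^2)
      mu <- as.numeric(Ks %*% alpha)
      v <- pmax(1 - rowSums((Ks %*% solve(Kf)) * Ks), 1e-9)
      s <- sqrt(v)
      imp <- min(ys) - mu
      zz <- imp / s
      ei <- imp * pnorm(zz) + s * dnorm(zz)
      free[which.max(ei)]
    }
    if (cand %in% tried) cand <- setdiff(seq_len(nrow(space)), tried)[1]
    if (is.na(cand)) break # space exhausted
    row <- space[cand, ]
    vl <- evaluate(row, t_i)
    tried <- c(tried, cand)
    log_df <- rbind(log_df, data.frame(
      trial = t_i, depth = row$depth, filters = row$filters,
      latent_units = row$latent, val_loss = vl
    ))
  }
  best_row <- log_df[which.min(log_df$val_loss), ]
  list(
    best = cdae_config(best_row$depth, best_row$filters, best_row$latent_units,
                       corruption_rate = corruption_rate, lambda = lambda),
    log = log_df
  )
}
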