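#' CNN architecture configuration for the supervised model observer
#'
#' The convolutional observer stacks `depth` 3x3 convolutional layers (all
#' with the same number of filters, LeakyReLU activations, zero padding and
#' no downscaling, so feature maps keep the input resolution and no
#' high-frequency content is discarded), followed by a fully connected layer
#' whose sigmoid output is read as the posterior probability of signal
#' presence. The search space is depth 2-10 and filters in {4, 8, 16}.
#'
#' @param depth number of convolutional layers (2-10).
#' @param filters filters per layer (4, 8 or 16).
#' @return a `cnn_config`.
#' @export
cnn_config <- function(depth = 2, filters = 8) {
  if (!(depth %in% 2:10)) stop_taskmo("CNN depth must be in 2..10")
  if (!(filters %in% c(4, 8, 16))) stop_taskmo("filters must be 4, 8 or 16")
  structure(list(depth = as.integer(depth), filters = as.integer(filters)),
            class = "cnn_config")
}

#' Training configuration for learned observers
#'
#' @param epochs training epochs (paper-style default: 50).
#' @param batch_size mini-batch size.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param seed seed controlling weight initialization and batch shuffling.
#' @param monitor_every record validation loss every this many epochs (the
#'   final epoch is always evaluated).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 64, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, seed = 1,
                         monitor_every = 1) {
  if (epochs < 0) stop_taskmo("epochs must be >= 0")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
         monitor_every = as.integer(monitor_every)),
    class = "train_config"
  )
}

#' Build an untrained supervised model observer
#'
#' @param kind `"cnn"` or `"slnn"` (single fully connected layer + sigmoid;
#'   deliberately nonlinear in its output even though its pre-activation is a
#'   linear template).
#' @param grid the [pixel_grid()] the observer will see.
#' @param config a [cnn_config()] (ignored for `"slnn"`).
#' @param seed weight-initialization seed.
#' @return a `supervised_observer` with untrained weights.
#' @export
build_supervised_observer <- function(kind = c("cnn", "slnn"), grid,
                                      config = cnn_config(), seed = 1) {
  kind <- match.arg(kind)
  H <- grid$n_rows
  W <- grid$n_cols
  net <- with_seed(derive_seed(seed, "init"), {
    layers <- list()
    if (kind == "cnn") {
      stopifnot(inherits(config, "cnn_config"))
      cin <- 1L
      for (i in seq_len(config$depth)) {
        layers[[length(layers) + 1]] <- nn_conv_layer(H, W, cin, config$filters, act = "lrelu")
        cin <- config$filters
      }
      layers[[length(layers) + 1]] <- nn_dense_layer(H * W * cin, 1L, act = "linear")
    } else {
      layers[[length(layers) + 1]] <- nn_dense_layer(H * W, 1L, act = "linear")
    }
    list(layers = layers)
  })
  structure(
    list(kind = kind, grid = grid, config = if (kind == "cnn") config else NULL,
         net = net, trained = FALSE, history = NULL, seed = as.integer(seed)),
    class = "supervised_observer"
  )
}

## Error if two datasets share images (guards the train/val/test protocol).
assert_disjoint <- function(a, b, what = c("training", "validation")) {
  ia <- attr(a, "split_indices")
  ib <- attr(b, "split_indices")
  overlap <- if (!is.null(ia) && !is.null(ib) &&
                 identical(attr(a, "split_parent"), attr(b, "split_parent"))) {
    length(intersect(ia, ib)) > 0
  } else {
    key <- function(m) apply(m[seq_len(min(32, nrow(m))), , drop = FALSE], 2,
                             paste, collapse = "\r")
    any(key(a$images) %in% key(b$images))
  }
  if (overlap) {
    stop_taskmo(sprintf("%s and %s sets overlap; splits must be disjoint",
                        what[1], what[2]))
  }
}

#' Train a supervised observer by mini-batch Adam on binary cross-entropy
#'
#' Minimizes the binary cross-entropy of the sigmoid output against the 0/1
#' labels for a fixed number of epochs, recording training and validation
#' loss per epoch. Deterministic for a fixed seed and thread configuration.
#'
#' @param observer a `supervised_observer` from [build_supervised_observer()].
#' @param train_ds,val_ds disjoint `detection_dataset`s.
#' @param cfg a [train_config()].
#' @return the observer with trained weights and a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_supervised <- function(observer, train_ds, val_ds, cfg = train_config()) {
  stopifnot(inherits(observer, "supervised_observer"))
  assert_disjoint(train_ds, val_ds)
  x <- train_ds$images
  y <- train_ds$labels
  xv <- val_ds$images
  yv <- val_ds$labels
  if (cfg$epochs == 0) {
    observer$trained <- TRUE
    observer$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                   val_loss = numeric())
    return(observer)
  }
  res <- with_seed(derive_seed(cfg$seed, "train"), {
    nn_train_loop(
      observer$net, n_obs = ncol(x), batch_size = cfg$batch_size,
      epochs = cfg$epochs, lr = cfg$lr,
      loss_fn = function(net, b) {
        fw <- nn_forward(net, x[, b, drop = FALSE], keep_cache = TRUE)
        lf <- bce_with_logits(fw$out, y[b])
        list(loss = lf$loss, grads = nn_backward(net, fw$cache, lf$dz))
      },
      monitor = function(net) {
        bce_with_logits(nn_forward(net, xv)$out, yv)$loss
      },
      patience = Inf,
      monitor_every = cfg$monitor_every %||% 1L
    )
  })
  observer$net <- res$net
  observer$history <- res$history
  observer$trained <- TRUE
  observer
}

#' Score images with a trained observer
#'
#' Returns the sigmoid output, interpretable as the posterior probability of
#' signal presence; strictly inside (0, 1).
#'
#' @param observer a trained `supervised_observer`.
#' @param images `M x n` matrix or `detection_dataset`.
#' @return numeric vector of scores in (0, 1).
#' @export
score_observer <- function(observer, images) {
  if (inherits(images, "detection_dataset")) images <- images$images
  if (nrow(images) != observer$grid$n_pixels) {
    stop_taskmo("image size does not match the observer's grid")
  }
  as.numeric(stats::plogis(nn_forward(observer$net, images)$out))
}

#' Extract the implied linear template of a trained SLNN
#'
#' The SLNN's pre-activation is `w' f + b`; its weight vector is directly
#' comparable with a Hotelling template.
#'
#' @param observer a trained `"slnn"` observer.
#' @return a `linear_observer`.
#' @export
slnn_template <- function(observer) {
  stopifnot(observer$kind == "slnn")
  linear_observer(as.numeric(observer$net$layers[[1]]$W_), source = "other")
}

#' Brute-force CNN structure search
#'
#' Trains every (depth, filters) architecture `repeats` times with fresh
#' initialization/batching seeds, scores each run by its final validation
#' cross-entropy and test AUC, and selects the architecture with the lowest
#' mean validation cross-entropy.
#'
#' @param train_ds,val_ds,test_ds disjoint datasets; the validation set
#'   drives selection and the test set is only used for reporting.
#' @param depths,filters search space (defaults: depths 2-10, filters
#'   {4, 8, 16}).
#' @param repeats training repetitions per architecture.
#' @param cfg a [train_config()]; its seed is the master seed for all runs.
#' @return list with `best` (a [cnn_config()]), `stats` (one row per
#'   (depth, filters, repeat): `val_ce`, `test_auc`), and `summary` (mean/sd
#'   per architecture).
#' @export
cnn_structure_search <- function(train_ds, val_ds, test_ds, depths = 2:10,
                                 filters = c(4, 8, 16), repeats = 20,
                                 cfg = train_config()) {
  if (length(depths) == 0 || length(filters) == 0) {
    stop_taskmo("empty architecture search space")
  }
  stats_df <- data.frame()
  for (d in depths) {
    for (f in filters) {
      for (r in seq_len(repeats)) {
        run_seed <- derive_seed(cfg$seed, sprintf("cnn-d%d-f%d-r%d", d, f, r))
        obs <- build_supervised_observer("cnn", train_ds$grid, cnn_config(d, f),
                                         seed = run_seed)
        run_cfg <- cfg
        run_cfg$seed <- run_seed
        obs <- train_supervised(obs, train_ds, val_ds, run_cfg)
        val_ce <- utils::tail(obs$history$val_loss, 1)
        sc <- score_observer(obs, test_ds)
        auc <- mann_whitney_auc(sc[test_ds$labels == 0], sc[test_ds$labels == 1])
        stats_df <- rbind(stats_df, data.frame(
          depth = d, filters = f, rep = r, val_ce = val_ce, test_auc = auc
        ))
      }
    }
  }
  agg <- do.call(rbind, lapply(split(stats_df, stats_df[c("depth", "filters")], drop = TRUE),
    function(g) data.frame(
      depth = g$depth[1], filters = g$filters[1],
      mean_val_ce = mean(g$val_ce), sd_val_ce = sd(g$val_ce),
      mean_test_auc = mean(g$test_auc), sd_test_auc = sd(g$test_auc)
    )))
  rownames(agg) <- NULL
  best_row <- agg[order(agg$mean_val_ce, agg$depth, agg$filters), ][1, ]
  list(
    best = cnn_config(best_row$depth, best_row$filters),
    stats = stats_df,
    summary = agg
  )
}
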