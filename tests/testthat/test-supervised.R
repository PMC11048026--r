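test_that("CNN parameter count matches the layer formula", {
  grid <- pixel_grid(64, 64, 0.7)
  obs <- build_supervised_observer("cnn", grid, cnn_config(2, 8), seed = 1)
  # conv1: 3*3*1*8 + 8 = 80; conv2: 3*3*8*8 + 8 = 584; head: 64*64*8 + 1
  expect_equal(taskmo:::n_parameters(obs$net), 33433)
  slnn <- build_supervised_observer("slnn", grid, seed = 1)
  expect_equal(taskmo:::n_parameters(slnn$net), 64 * 64 + 1)
  expect_error(cnn_config(depth = 11), "depth")
  expect_error(cnn_config(filters = 5), "filters")
})

test_that("feature maps preserve spatial size through every conv layer", {
  grid <- pixel_grid(16, 16, 0.7)
  obs <- build_supervised_observer("cnn", grid, cnn_config(3, 4), seed = 2)
  x <- matrix(runif(256 * 5), 256, 5)
  for (ly in obs$net$layers) {
    if (ly$type != "conv") break
    x <- taskmo:::act_forward(
      taskmo:::.conv3x3_forward(x, ly$W_, ly$b, ly$H, ly$W, ly$Cin), ly$act
    )
    expect_equal(nrow(x), 16 * 16 * ly$F) # same H x W, F channels
    expect_equal(ncol(x), 5)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  grid <- pixel_grid(5, 5, 1)
  obs <- build_supervised_observer("cnn", grid, cnn_config(2, 4), seed = 4)
  net <- obs$net
  x <- with_seed(5, matrix(runif(25 * 3), 25, 3))
  y <- c(0, 1, 1)
  fw <- taskmo:::nn_forward(net, x, keep_cache = TRUE)
  gr <- taskmo:::nn_backward(net, fw$cache,
                             taskmo:::bce_with_logits(fw$out, y)$dz)
  loss_at <- function(n) taskmo:::bce_with_logits(taskmo:::nn_forward(n, x)$out, y)$loss
  eps <- 1e-6
  worst <- 0
  for (li in seq_along(net$layers)) {
    for (item in c("W_", "b")) {
      k <- length(net$layers[[li]][[item]])
      for (idx in unique(round(seq(1, k, length.out = 5)))) {
        n2 <- net
        n2$layers[[li]][[item]][idx] <- n2$layers[[li]][[item]][idx] + eps
        lp <- loss_at(n2)
        n2$layers[[li]][[item]][idx] <- n2$layers[[li]][[item]][idx] - 2 * eps
        lm <- loss_at(n2)
        worst <- max(worst, abs((lp - lm) / (2 * eps) - gr[[li]][[item]][idx]))
      }
    }
  }
  expect_lt(worst, 1e-7)
})

test_that("zero epochs leave the initialized weights untouched", {
  grid <- pixel_grid(8, 8, 1)
  obs <- build_supervised_observer("slnn", grid, seed = 6)
  w0 <- obs$net$layers[[1]]$W_ + 0
  tr <- toy_separable_dataset()
  va <- toy_separable_dataset(seed = 8)
  obs2 <- train_supervised(obs, tr, va, train_config(epochs = 0, seed = 1))
  expect_identical(obs2$net$layers[[1]]$W_, w0)
})

test_that("a separable toy task is learned to AUC 1 and training is deterministic", {
  tr <- toy_separable_dataset(n_per_class = 30, seed = 7)
  va <- toy_separable_dataset(n_per_class = 10, seed = 8)
  cfg <- train_config(epochs = 50, batch_size = 16, seed = 2)
  obs <- build_supervised_observer("slnn", tr$grid, seed = 2)
  fit1 <- train_supervised(obs, tr, va, cfg)
  sc <- score_observer(fit1, tr)
  expect_equal(mann_whitney_auc(sc[tr$labels == 0], sc[tr$labels == 1]), 1)
  expect_true(all(sc > 0 & sc < 1))

  # identical seed -> identical validation loss trajectory
  fit2 <- train_supervised(build_supervised_observer("slnn", tr$grid, seed = 2),
                           tr, va, cfg)
  expect_identical(fit1$history$val_loss, fit2$history$val_loss)

  # the implied linear template is exportable
  expect_s3_class(slnn_template(fit1), "linear_observer")
})

test_that("training refuses overlapping train/validation sets", {
  tr <- toy_separable_dataset()
  obs <- build_supervised_observer("slnn", tr$grid, seed = 1)
  expect_error(train_supervised(obs, tr, tr, train_config(epochs = 1)),
               "disjoint")
})

test_that("label flip maps AUC to its complement", {
  tr <- toy_separable_dataset(n_per_class = 25, seed = 9)
  va <- toy_separable_dataset(n_per_class = 10, seed = 10)
  obs <- train_supervised(build_supervised_observer("slnn", tr$grid, seed = 3),
                          tr, va, train_config(epochs = 10, seed = 3))
  sc <- score_observer(obs, tr)
  a <- mann_whitney_auc(sc[tr$labels == 0], sc[tr$labels == 1])
  flipped <- mann_whitney_auc(sc[tr$labels == 1], sc[tr$labels == 0])
  expect_equal(a + flipped, 1)
})

test_that("structure search returns the single config of a one-point space", {
  task <- task16()
  ds <- make_task_dataset(task, 60, seed = 12)
  sp <- train_val_test_split(ds, c(train = 60, val = 30, test = 30), seed = 1)
  res <- cnn_structure_search(
    sp$train, sp$val, sp$test, depths = 2, filters = 4, repeats = 2,
    cfg = train_config(epochs = 2, seed = 5)
  )
  expect_equal(res$best$depth, 2L)
  expect_equal(res$best$filters, 4L)
  expect_equal(nrow(res$stats), 2) # one row per (depth, filters, repeat)
  expect_named(res$stats, c("depth", "filters", "rep", "val_ce", "test_auc"))
  expect_error(
    cnn_structure_search(sp$train, sp$val, sp$test, depths = integer(0)),
    "empty"
  )
})
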