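test_that("conv_activate evaluates the kernel formula with ReLU", {
  w <- rbind(c(1, -2), c(3, 0.5))
  x1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(conv_activate(x1, w, 0L), 1.5)
  x2 <- rbind(c(0, 1), c(0, 0))
  expect_equal(conv_activate(x2, w, 0L), 0) # ReLU clamps -2
  expect_error(conv_activate(x1, w, 1L), "out of range")
})

test_that("conv_activate matches the brute-force double loop", {
  withr::local_seed(51)
  for (i in 1:200) {
    M <- sample(2:8, 1)
    N <- sample(1:4, 1)
    L <- M + sample(0:20, 1)
    w <- matrix(rnorm(M * N), M, N)
    x <- matrix(rnorm(L * N), L, N)
    pos <- sample(0:(L - M), 1)
    bias <- rnorm(1)
    # summation order differs between the two routes, so agreement is
    # to double-precision accumulation error, not bit-exact
    expect_equal(conv_activate(x, w, pos, bias),
                 brute_conv(x, w, pos, bias), tolerance = 1e-12)
  }
})

test_that("softmax is exact, normalized and overflow-safe", {
  expect_equal(softmax_probability(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_probability(c(0, log(3))), c(0.25, 0.75))
  big <- softmax_probability(c(1000, 0))
  expect_equal(big[1], 1, tolerance = 1e-12)
  expect_false(any(is.nan(big)))
  withr::local_seed(5)
  for (i in 1:20) {
    z <- runif(2, -1e4, 1e4)
    expect_equal(sum(softmax_probability(z)), 1, tolerance = 1e-12)
  }
})

test_that("feature-module shapes follow the stack geometry", {
  cfg <- network_config()
  shp <- model_shapes(cfg)
  expect_equal(unname(shp[[1]]), c(300, 128)) # conv(128, 8), same padding
  expect_equal(unname(shp[[4]]), c(300, 128)) # NIN back to 128 channels
  expect_equal(unname(shp[[5]]), c(150, 128)) # first max-pool
  expect_equal(unname(shp[[8]]), c(75, 64))   # 300 / 2 / 2, 64 kernels
})

test_that("the full forward pass yields probabilities summing to 1", {
  cfg <- reduced_network_config(input_len = 40L)
  model <- build_model(cfg, seed = 2L)
  withr::local_seed(3)
  B <- 5L
  Xseq <- matrix(runif(B * 40 * 4), B * 40, 4)
  Xdna <- matrix(rnorm(B * 40), B * 40, 1)
  fwd <- nn_forward(model, Xseq, Xdna, B)
  P <- t(apply(fwd$logits, 1, softmax_probability))
  expect_equal(unname(rowSums(P)), rep(1, B))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("analytic gradients match numeric differentiation", {
  # biases are perturbed away from 0 so no pre-activation sits exactly
  # on the ReLU kink, where the loss is not differentiable
  cfg <- network_config(kernels_wide = 3L, kernels_narrow = 2L,
                        dense_sizes = 5L, dropout = 0,
                        merge_dropout = 0, input_len = 12L)
  model <- build_model(cfg, seed = 4L)
  withr::local_seed(8)
  model$params <- lapply(model$params, function(p) {
    p + stats::rnorm(length(p), sd = 0.05)
  })
  B <- 3L
  Xseq <- matrix(runif(B * 12 * 4), B * 12, 4)
  Xdna <- matrix(rnorm(B * 12), B * 12, 1)
  y <- c(0L, 1L, 1L)
  loss_of <- function(params) {
    m <- model
    m$params <- params
    fwd <- nn_forward(m, Xseq, Xdna, B, keep_cache = FALSE)
    softmax_xent(fwd$logits, y)$loss
  }
  fwd <- nn_forward(model, Xseq, Xdna, B, keep_cache = TRUE)
  sx <- softmax_xent(fwd$logits, y)
  grads <- nn_backward(model, fwd, sx$dlogits)
  eps <- 1e-6
  for (nm in names(grads)) {
    idx <- sample(length(model$params[[nm]]),
                  min(4, length(model$params[[nm]])))
    for (i in idx) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-5,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("the auto-encoder embeds any replicate count to one channel", {
  withr::local_seed(61)
  for (k in c(1L, 3L, 5L)) {
    acc <- array(rpois(k * 60 * 8, 2), c(k, 60L, 8L))
    enc <- train_autoencoder(acc, epochs = 10L, seed = 3L)
    z <- encode_windows(enc, acc)
    expect_equal(dim(z), c(8L, 60L))
  }
})

test_that("auto-encoder training reduces reconstruction error", {
  withr::local_seed(67)
  # correlated channels: a 1-channel embedding can reconstruct well
  base <- matrix(rpois(80 * 20, 3), 80, 20)
  acc <- array(0, c(3, 80, 20))
  for (r in 1:3) acc[r, , ] <- base * r + rnorm(80 * 20, sd = 0.1)
  enc <- train_autoencoder(acc, epochs = 300L, seed = 9L)
  losses <- enc$loss_history
  expect_lt(losses[length(losses)], losses[1])
  # on constant-structure data the first epochs improve monotonically
  diffs <- diff(losses[1:5])
  expect_true(all(diffs <= 1e-8))
  # proportional channels admit a near-perfect 1-channel embedding
  expect_lt(reconstruction_error(enc, acc), 0.01)
})

test_that("encoder rejects mismatched replicate counts", {
  acc3 <- array(rpois(3 * 30 * 4, 1), c(3, 30, 4))
  acc2 <- array(rpois(2 * 30 * 4, 1), c(2, 30, 4))
  enc <- train_autoencoder(acc3, epochs = 2L, seed = 1L)
  expect_error(encode_windows(enc, acc2), "k = 3")
})

test_that("aggregation over augmented windows is mean or max", {
  expect_equal(aggregate_origin(c(0.2, 0.4, 0.9), "mean"), 0.5)
  expect_equal(aggregate_origin(c(0.2, 0.4, 0.9), "max"), 0.9)
  expect_equal(aggregate_origin(0.7, "mean"), 0.7)
  expect_error(aggregate_origin(numeric(0)), "no window")
})

test_that("collective scoring is the unweighted mean over models", {
  expect_equal(average_model_probabilities(rbind(c(0.2, 0.4, 0.6))), 0.4)
  m <- rbind(c(0.1, 0.3), c(0.8, 0.6))
  expect_equal(average_model_probabilities(m), c(0.2, 0.7))
  expect_error(average_model_probabilities(matrix(0, 2, 0)), "no models")
})

test_that("two-stage training freezes the feature modules in stage 2", {
  sim <- small_sim()
  cfg <- reduced_network_config(kernels_wide = 8L, kernels_narrow = 4L,
                                dense_sizes = c(16L, 8L),
                                stage1_epochs = 4L, stage2_epochs = 4L,
                                min_epochs = 2L, ae_epochs = 5L)
  model <- train_two_stage(build_model(cfg, seed = 3L), sim$dataset,
                           test_fold = 0L, seed = 3L)
  log <- model$train_log
  expect_true(all(c("stage", "epoch", "loss", "val_loss",
                    "feature_checksum") %in% names(log)))
  s2 <- log$feature_checksum[log$stage == 2]
  expect_gte(length(s2), 1)
  # identical digest at every stage-2 epoch, equal to the final model's
  expect_equal(unique(s2), feature_checksum(model))
  # stage 1 used a class-balanced subset
  expect_equal(model$train_info$stage1_n_pos, model$train_info$stage1_n_neg)
})

test_that("training is deterministic given the seed", {
  sim <- small_sim()
  cfg <- reduced_network_config(kernels_wide = 4L, kernels_narrow = 2L,
                                dense_sizes = 8L, stage1_epochs = 2L,
                                stage2_epochs = 1L, min_epochs = 1L,
                                ae_epochs = 3L)
  m1 <- train_two_stage(build_model(cfg, seed = 5L), sim$dataset,
                        test_fold = 0L, seed = 5L)
  m2 <- train_two_stage(build_model(cfg, seed = 5L), sim$dataset,
                        test_fold = 0L, seed = 5L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$train_log, m2$train_log)
})

test_that("inference is deterministic and batch-size invariant", {
  sim <- small_sim()
  cfg <- reduced_network_config(kernels_wide = 4L, kernels_narrow = 2L,
                                dense_sizes = 8L, stage1_epochs = 1L,
                                stage2_epochs = 1L, min_epochs = 1L,
                                ae_epochs = 2L)
  model <- train_two_stage(build_model(cfg, seed = 6L), sim$dataset,
                           test_fold = 0L, seed = 6L)
  idx <- 1:20
  p1 <- predict_windows(model, sim$dataset, idx, batch = 512L)
  p2 <- predict_windows(model, sim$dataset, idx, batch = 3L)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # a duplicated window gets an identical probability
  expect_equal(p1[1], predict_windows(model, sim$dataset, c(1L, 1L))[2])

  # model round-trips through serialization
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  expect_equal(predict_windows(load_model(f), sim$dataset, idx), p1)
})

test_that("cross-cell-line prediction averages per-model scores", {
  sim <- small_sim()
  cfg <- reduced_network_config(kernels_wide = 4L, kernels_narrow = 2L,
                                dense_sizes = 8L, stage1_epochs = 1L,
                                stage2_epochs = 1L, min_epochs = 1L,
                                ae_epochs = 2L)
  model <- train_two_stage(build_model(cfg, seed = 8L), sim$dataset,
                           test_fold = 0L, seed = 8L)
  # identical models: collective prediction equals the single model's,
  # with the encoder refit on the target windows
  res <- cross_cell_line_predict(list(model, model, model), sim$dataset,
                                 seed = 4L)
  expect_equal(res$prob, res$prob_1)
  expect_equal(res$prob_1, res$prob_2)
  single <- cross_cell_line_predict(list(model), sim$dataset, seed = 4L)
  expect_equal(res$prob, single$prob)
  expect_error(cross_cell_line_predict(list(), sim$dataset), "at least one")
})
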