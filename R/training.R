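# Auto-encoder for replicate embedding, two-stage training, prediction.

#' Train the replicate auto-encoder
#'
#' Embeds the `k`-replicate accessibility signal of a window into a
#' single channel of the same length. The encoder standardizes each
#' replicate channel (batch normalization over the training windows) and
#' applies a position-shared linear map `k -> 1`; the decoder
#' standardizes the latent channel and maps it back `1 -> k`. Both maps
#' are trained jointly with Adam to minimize the mean squared
#' reconstruction error of the standardized input. Because the map is
#' shared across positions, the latent representation has length equal
#' to the window length for any number of replicates, which is what
#' makes models transferable between cell lines with different replicate
#' counts.
#'
#' @param acc `(k, L, n)` array of accessibility windows.
#' @param epochs training epochs (full-batch updates).
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return An object of class `encap_encoder` carrying the
#'   normalization statistics, encoder/decoder weights and the training
#'   loss history.
#' @export
train_autoencoder <- function(acc, epochs = 30L, lr = 0.01, seed = 1L) {
  stopifnot(is.array(acc), length(dim(acc)) == 3)
  k <- dim(acc)[1]
  if (k < 1) stop("need at least one replicate channel")
  L <- dim(acc)[2]
  n <- dim(acc)[3]
  X <- aperm(acc, c(2, 3, 1))
  dim(X) <- c(L * n, k)
  mu_in <- colMeans(X)
  sd_in <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xn <- sweep(sweep(X, 2, mu_in), 2, sd_in, `/`)
  with_seed(seed, {
    params <- list(u = matrix(stats::rnorm(k, sd = 1 / sqrt(k)), k, 1),
                   b_e = 0,
                   v = matrix(stats::rnorm(k, sd = 1), 1, k),
                   b_d = numeric(k))
    state <- adam_state_new(params)
    losses <- numeric(epochs + 1L)
    mu_z <- 0; sd_z <- 1
    for (ep in 0:epochs) {
      z <- drop(Xn %*% params$u) + params$b_e
      mu_z <- mean(z)
      sd_z <- max(stats::sd(z), 1e-8)
      zn <- (z - mu_z) / sd_z
      R <- zn %*% params$v + rep(params$b_d, each = length(zn))
      err <- R - Xn
      losses[ep + 1L] <- mean(err^2)
      if (ep == epochs) break
      m <- length(zn) * k
      dR <- 2 * err / m
      dzn <- drop(dR %*% t(params$v))
      # normalization statistics treated as constants in the gradient
      dz <- dzn / sd_z
      grads <- list(u = crossprod(Xn, dz), b_e = sum(dz),
                    v = crossprod(matrix(zn, ncol = 1), dR),
                    b_d = colSums(dR))
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
    structure(
      list(k = k, mu_in = mu_in, sd_in = sd_in,
           u = params$u, b_e = params$b_e,
           mu_z = mu_z, sd_z = sd_z,
           v = params$v, b_d = params$b_d,
           loss_history = losses),
      class = "encap_encoder"
    )
  })
}

#' Encode accessibility windows into the single latent channel
#'
#' @param encoder an [train_autoencoder()] result.
#' @param acc `(k, L, n)` array of accessibility windows.
#' @return An `n x L` matrix of latent accessibility profiles.
#' @export
encode_windows <- function(encoder, acc) {
  stopifnot(inherits(encoder, "encap_encoder"))
  if (dim(acc)[1] != encoder$k) {
    stop("encoder was fit for k = ", encoder$k, " replicates, got ",
         dim(acc)[1])
  }
  k <- dim(acc)[1]; L <- dim(acc)[2]; n <- dim(acc)[3]
  X <- aperm(acc, c(2, 3, 1))
  dim(X) <- c(L * n, k)
  Xn <- sweep(sweep(X, 2, encoder$mu_in), 2, encoder$sd_in, `/`)
  z <- (drop(Xn %*% encoder$u) + encoder$b_e - encoder$mu_z) / encoder$sd_z
  matrix(z, nrow = L) |> t()
}

#' Reconstruct windows through the auto-encoder (for diagnostics)
#'
#' @inheritParams encode_windows
#' @return Mean squared reconstruction error on the standardized scale.
#' @export
reconstruction_error <- function(encoder, acc) {
  k <- dim(acc)[1]; L <- dim(acc)[2]; n <- dim(acc)[3]
  X <- aperm(acc, c(2, 3, 1))
  dim(X) <- c(L * n, k)
  Xn <- sweep(sweep(X, 2, encoder$mu_in), 2, encoder$sd_in, `/`)
  z <- drop(Xn %*% encoder$u) + encoder$b_e
  zn <- (z - encoder$mu_z) / encoder$sd_z
  R <- zn %*% encoder$v + rep(encoder$b_d, each = length(zn))
  mean((R - Xn)^2)
}

# mean cross-entropy of the model on the given window indices (eval mode)
eval_loss <- function(model, dataset, z_all, idx, batch = 512L) {
  total <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch))) {
    B <- length(chunk)
    Xseq <- if (model$cfg$use_dna) seq_batch(dataset$seq, chunk) else NULL
    Xdna <- if (model$cfg$use_dnase) dnase_batch(z_all, chunk) else NULL
    fwd <- nn_forward(model, Xseq, Xdna, B, train = FALSE,
                      keep_cache = FALSE)
    sx <- softmax_xent(fwd$logits, dataset$manifest$label[chunk])
    total <- total + sx$loss * B
  }
  total / length(idx)
}

run_stage <- function(model, dataset, z_all, train_idx, val_idx, stage,
                      max_epochs, frozen, state, log_env) {
  cfg <- model$cfg
  best <- list(loss = Inf, params = model$params, state = state)
  wait <- 0L
  min_eff <- min(cfg$min_epochs, max_epochs)
  for (ep in seq_len(max_epochs)) {
    idx <- sample(train_idx)
    ep_loss <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      B <- length(chunk)
      Xseq <- if (cfg$use_dna) seq_batch(dataset$seq, chunk) else NULL
      Xdna <- if (cfg$use_dnase) dnase_batch(z_all, chunk) else NULL
      fwd <- nn_forward(model, Xseq, Xdna, B, train = TRUE)
      sx <- softmax_xent(fwd$logits, dataset$manifest$label[chunk])
      ep_loss <- ep_loss + sx$loss * B
      grads <- nn_backward(model, fwd, sx$dlogits)
      upd <- adam_step(model$params, grads, state, lr = cfg$lr,
                       frozen = frozen, weight_decay = cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    ep_loss <- ep_loss / length(idx)
    val_loss <- eval_loss(model, dataset, z_all, val_idx)
    log_env$log <- rbind(log_env$log, data.frame(
      stage = stage, epoch = ep, loss = ep_loss, val_loss = val_loss,
      feature_checksum = feature_checksum(model),
      stringsAsFactors = FALSE))
    if (ep >= min_eff && val_loss < best$loss - 1e-5) {
      best <- list(loss = val_loss, params = model$params, state = state)
      wait <- 0L
    } else if (ep >= min_eff) {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  list(model = model, state = best$state)
}

#' Two-stage training on an imbalanced dataset
#'
#' Stage 1 trains the whole network on all positive training windows
#' plus an equally sized random subset of negative training windows, so
#' the feature modules learn from balanced batches. Stage 2 continues on
#' the full imbalanced training set with the DNA and DNase feature
#' modules frozen (their learning rate is effectively zero; only the
#' joint module updates). The replicate auto-encoder is fit first on the
#' training windows and frozen as the input transform of the DNase
#' module. Both stages use cross-entropy loss, Adam, and early stopping
#' on a held-out slice of the training origins.
#'
#' @param model an untrained [build_model()] result.
#' @param dataset an [assemble_dataset()] result.
#' @param test_fold fold id held out entirely from training (use its
#'   windows only for evaluation).
#' @param seed integer seed driving batching, dropout, the stage-1
#'   negative subset and the validation split.
#' @return The trained model, with `train_log` (one row per epoch:
#'   stage, loss, validation loss, feature-module checksum),
#'   `train_info` (stage-1 subset composition, validation origins) and
#'   the fitted `encoder` attached.
#' @export
train_two_stage <- function(model, dataset, test_fold = 0L, seed = 1L) {
  stopifnot(inherits(model, "encap_model"),
            inherits(dataset, "encap_dataset"))
  man <- dataset$manifest
  train_mask <- man$fold != test_fold
  if (length(unique(man$label[train_mask])) < 2) {
    stop("training folds must contain both classes")
  }
  with_seed(seed, {
    # validation split at origin level, stratified by label
    train_origins <- unique(man$origin_id[train_mask])
    olab <- man$label[match(train_origins, man$origin_id)]
    val_origins <- unlist(lapply(c(0L, 1L), function(lb) {
      ids <- train_origins[olab == lb]
      n_val <- max(1L, round(model$cfg$val_fraction * length(ids)))
      sample(ids, n_val)
    }))
    is_val <- train_mask & man$origin_id %in% val_origins
    is_train <- train_mask & !is_val
    val_idx <- which(is_val)
    pos_idx <- which(is_train & man$label == 1L)
    neg_idx <- which(is_train & man$label == 0L)

    if (model$cfg$use_dnase) {
      model$encoder <- train_autoencoder(
        dataset$acc[, , train_mask, drop = FALSE],
        epochs = model$cfg$ae_epochs, lr = model$cfg$ae_lr,
        seed = sample.int(.Machine$integer.max, 1))
      z_all <- encode_windows(model$encoder, dataset$acc)
    } else {
      z_all <- NULL
    }

    # stage 1: balanced subset, everything trainable
    stage1_neg <- sample(neg_idx, min(length(pos_idx), length(neg_idx)))
    stage1_idx <- c(pos_idx, stage1_neg)
    state <- adam_state_new(model$params)
    log_env <- new.env()
    log_env$log <- NULL
    s1 <- run_stage(model, dataset, z_all, stage1_idx, val_idx,
                    stage = 1L, max_epochs = model$cfg$stage1_epochs,
                    frozen = character(0), state = state,
                    log_env = log_env)
    model <- s1$model

    # stage 2: full imbalanced training set, feature modules frozen
    s2 <- run_stage(model, dataset, z_all, c(pos_idx, neg_idx), val_idx,
                    stage = 2L, max_epochs = model$cfg$stage2_epochs,
                    frozen = feature_param_names(model), state = s1$state,
                    log_env = log_env)
    model <- s2$model
    model$train_log <- log_env$log
    model$train_info <- list(
      test_fold = test_fold,
      stage1_n_pos = length(pos_idx), stage1_n_neg = length(stage1_neg),
      val_origins = val_origins, seed = seed)
    model
  })
}

#' Per-window enhancer probabilities
#'
#' Deterministic forward pass (no dropout) over a set of windows.
#'
#' @param model a trained `encap_model` (its `encoder` is used to embed
#'   the accessibility channel when the DNase module is enabled).
#' @param dataset an `encap_dataset`.
#' @param idx window indices to score (default: all).
#' @param batch inference batch size.
#' @return Numeric vector of probabilities in `[0, 1]`, one per window.
#' @export
predict_windows <- function(model, dataset, idx = NULL, batch = 512L) {
  stopifnot(inherits(model, "encap_model"))
  if (is.null(idx)) idx <- seq_len(nrow(dataset$manifest))
  z_all <- NULL
  if (model$cfg$use_dnase) {
    if (is.null(model$encoder)) stop("model has no fitted encoder")
    z_all <- encode_windows(model$encoder, dataset$acc)
  }
  out <- numeric(length(idx))
  pos <- 1L
  for (chunk in split(idx, ceiling(seq_along(idx) / batch))) {
    B <- length(chunk)
    Xseq <- if (model$cfg$use_dna) seq_batch(dataset$seq, chunk) else NULL
    Xdna <- if (model$cfg$use_dnase) dnase_batch(z_all, chunk) else NULL
    fwd <- nn_forward(model, Xseq, Xdna, B, train = FALSE,
                      keep_cache = FALSE)
    P <- softmax_rows(fwd$logits)
    out[pos:(pos + B - 1L)] <- P[, 2L]
    pos <- pos + B
  }
  out
}

#' Aggregate window probabilities to an origin-level score
#'
#' A variable-length region is scored by aggregating the probabilities
#' of all fixed-length windows augmented from it, either by their mean
#' (the default) or their maximum.
#'
#' @param probs numeric vector of window probabilities.
#' @param aggregator `"mean"` or `"max"`.
#' @return A single probability.
#' @export
aggregate_origin <- function(probs, aggregator = c("mean", "max")) {
  if (length(probs) == 0) stop("no window probabilities to aggregate")
  aggregator <- match.arg(aggregator)
  if (aggregator == "mean") mean(probs) else max(probs)
}

#' Origin-level predictions for a dataset subset
#'
#' @param model a trained model.
#' @param dataset an `encap_dataset`.
#' @param fold fold id to score (default: all windows).
#' @param aggregator window aggregation rule, see [aggregate_origin()].
#' @return Data frame with one row per origin: `origin_id`, `label`,
#'   `prob`.
#' @export
predict_origins <- function(model, dataset, fold = NULL,
                            aggregator = "mean") {
  man <- dataset$manifest
  idx <- if (is.null(fold)) seq_len(nrow(man)) else which(man$fold == fold)
  if (length(idx) == 0) stop("no windows in the requested fold")
  probs <- predict_windows(model, dataset, idx)
  agg <- tapply(probs, man$origin_id[idx],
                function(p) aggregate_origin(p, aggregator))
  ids <- names(agg)
  data.frame(
    origin_id = ids,
    label = man$label[match(ids, man$origin_id)],
    prob = as.numeric(agg),
    stringsAsFactors = FALSE
  )
}

#' Average per-model probabilities into a collective score
#'
#' The cross-cell-line rule: the final probability of a region is the
#' unweighted mean of the probabilities assigned by the individual
#' models, with no weighting or other adjustment.
#'
#' @param prob_matrix numeric matrix, one row per region and one column
#'   per model (a vector is treated as one region).
#' @return Numeric vector of collective probabilities.
#' @export
average_model_probabilities <- function(prob_matrix) {
  if (is.null(dim(prob_matrix))) {
    prob_matrix <- matrix(prob_matrix, nrow = 1)
  }
  if (ncol(prob_matrix) == 0) stop("no models to average")
  rowMeans(prob_matrix)
}

#' Cross-cell-line collective prediction
#'
#' Scores the regions of a target cell line with models trained on other
#' cell lines. Because the target cell line may have a different number
#' of DNase-seq replicates, a fresh auto-encoder is first fit
#' (unsupervised) on the target windows and used as the accessibility
#' input transform for every source model; each model then scores all
#' windows, window scores are aggregated per origin, and the final
#' probability is the unweighted mean over models.
#'
#' @param models list of trained `encap_model`s.
#' @param dataset target cell line `encap_dataset`.
#' @param aggregator window aggregation rule.
#' @param seed seed for the target auto-encoder fit.
#' @return Data frame with `origin_id`, `label`, per-model columns
#'   `prob_1 .. prob_m`, and the collective `prob`.
#' @export
cross_cell_line_predict <- function(models, dataset, aggregator = "mean",
                                    seed = 1L) {
  if (length(models) == 0) stop("need at least one model")
  needs_enc <- any(vapply(models, function(m) m$cfg$use_dnase, logical(1)))
  target_enc <- if (needs_enc) {
    train_autoencoder(dataset$acc, seed = seed)
  } else NULL
  per_model <- lapply(models, function(m) {
    if (m$cfg$use_dnase) m$encoder <- target_enc
    predict_origins(m, dataset, fold = NULL, aggregator = aggregator)
  })
  out <- per_model[[1]][, c("origin_id", "label")]
  probs <- vapply(per_model, function(p) {
    p$prob[match(out$origin_id, p$origin_id)]
  }, numeric(nrow(out)))
  probs <- matrix(probs, nrow = nrow(out))
  colnames(probs) <- paste0("prob_", seq_along(models))
  out <- cbind(out, probs)
  out$prob <- average_model_probabilities(probs)
  out
}

#' Save / load a trained model
#'
#' Serializes the model (architecture config, parameters, encoder and
#' training log) with R's native serialization.
#'
#' @param model an `encap_model`.
#' @param path file path.
#' @return `path` invisibly for the writer; the model for the reader.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "encap_model"))
  m
}
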