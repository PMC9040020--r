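#' Network architecture configuration
#'
#' Describes the four-module architecture: a DNA feature module (input
#' `300 x 4` one-hot sequence), a DNase feature module (input `300 x 1`,
#' the auto-encoder embedding of the replicate accessibility signal),
#' and a joint module that concatenates skip-connection taps from both
#' feature modules and passes them through fully connected layers into a
#' 2-unit softmax.
#'
#' Each feature module is the stack
#' `conv(wide, 8) - conv(narrow, 1) - conv(narrow, 3) - conv(wide, 1) -
#' maxpool(2) - conv(narrow, 3) - conv(narrow, 3) - maxpool(2)`,
#' with ReLU activations, same-padding and stride 1; length-1
#' convolutions are Network-in-Network channel mixers. By default the
#' flattened outputs of both max-pooling layers of each module are the
#' skip-connection taps feeding the joint module.
#'
#' @param kernels_wide kernel count of the wide convolution layers
#'   (default 128; the first layer scans motifs of length 8).
#' @param kernels_narrow kernel count of the narrow (NIN / VGG-style)
#'   layers (default 64).
#' @param dense_sizes sizes of the joint module's hidden dense layers.
#' @param dropout dropout rate applied after each hidden dense layer
#'   during training.
#' @param merge_dropout dropout rate applied to the concatenated
#'   skip-connection taps (the merge layer) during training; this is
#'   where most parameters sit, so it is the main guard against
#'   memorization on small datasets. Defaults to `dropout`.
#' @param weight_decay L2 penalty on weight matrices (not biases).
#' @param input_len window length consumed by both feature modules.
#' @param use_dna,use_dnase enable/disable the two feature modules
#'   (disabling one gives the sequence-only / accessibility-only
#'   ablations).
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param stage1_epochs,stage2_epochs maximum epochs per training stage.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param min_epochs burn-in: early stopping is not considered before
#'   this many epochs of a stage have run (a small validation set can
#'   produce an accidentally low loss in the first epochs, before the
#'   feature modules have learned anything).
#' @param val_fraction fraction of training origins held out for early
#'   stopping.
#' @param ae_epochs,ae_lr auto-encoder training epochs and learning
#'   rate.
#' @return A `network_config` list.
#' @export
network_config <- function(kernels_wide = 128L, kernels_narrow = 64L,
                           dense_sizes = c(512L, 256L, 128L),
                           dropout = 0.5, merge_dropout = dropout,
                           weight_decay = 1e-4, input_len = 300L,
                           use_dna = TRUE, use_dnase = TRUE,
                           lr = 1e-3, batch_size = 128L,
                           stage1_epochs = 30L, stage2_epochs = 20L,
                           patience = 5L, min_epochs = 8L,
                           val_fraction = 0.1,
                           ae_epochs = 100L, ae_lr = 0.01) {
  stopifnot(kernels_wide >= 1, kernels_narrow >= 1, dropout >= 0,
            dropout < 1, input_len %% 4L == 0L, use_dna || use_dnase)
  structure(
    list(kernels_wide = as.integer(kernels_wide),
         kernels_narrow = as.integer(kernels_narrow),
         dense_sizes = as.integer(dense_sizes), dropout = dropout,
         merge_dropout = merge_dropout, weight_decay = weight_decay,
         input_len = as.integer(input_len), use_dna = use_dna,
         use_dnase = use_dnase, lr = lr,
         batch_size = as.integer(batch_size),
         stage1_epochs = as.integer(stage1_epochs),
         stage2_epochs = as.integer(stage2_epochs),
         patience = as.integer(patience),
         min_epochs = as.integer(min_epochs),
         val_fraction = val_fraction,
         ae_epochs = as.integer(ae_epochs), ae_lr = ae_lr),
    class = "network_config"
  )
}

#' Reduced configuration for CPU-scale experiments
#'
#' Same architecture shape as [network_config()] with 16/8 kernels and
#' dense layers `(32, 16)`, small enough to train in minutes on one CPU
#' while preserving every structural property of the full model.
#'
#' @param ... overrides passed to [network_config()].
#' @export
reduced_network_config <- function(...) {
  defaults <- list(kernels_wide = 16L, kernels_narrow = 8L,
                   dense_sizes = c(32L, 16L), dropout = 0.2,
                   merge_dropout = 0.3, weight_decay = 1e-4, lr = 3e-3,
                   stage1_epochs = 40L, stage2_epochs = 10L,
                   patience = 6L, min_epochs = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(network_config, args)
}

#' Single-kernel convolution activation
#'
#' The activation of a convolution kernel at position `i` of an input:
#' `ReLU(sum_m sum_n w[m, n] * x[i + m, n] + bias)`. Positions are
#' 0-based; valid positions satisfy `0 <= i <= L - M`.
#'
#' @param x `L x N` input matrix (e.g. a one-hot sequence, N = 4).
#' @param w `M x N` kernel weight matrix.
#' @param i 0-based position.
#' @param bias kernel bias (default 0).
#' @return Non-negative activation value.
#' @export
conv_activate <- function(x, w, i, bias = 0) {
  M <- nrow(w)
  if (i < 0 || i > nrow(x) - M) stop("position out of range")
  max(0, sum(w * x[(i + 1):(i + M), , drop = FALSE]) + bias)
}

#' Softmax probabilities
#'
#' `f_i = exp(z_i) / sum_j exp(z_j)`, computed with max-subtraction so
#' large logits do not overflow.
#'
#' @param z numeric vector of logits.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_probability(c(0, log(3))) # 0.25 0.75
#' @export
softmax_probability <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

# joint-module input dimension given the config
joint_input_dim <- function(cfg) {
  layers <- stack_layers(cfg$kernels_wide, cfg$kernels_narrow)
  tap_at <- which(vapply(layers, function(l) l$type == "pool", logical(1)))
  shp <- stack_shapes(layers, cfg$input_len, 4L)
  per_module <- sum(vapply(tap_at, function(j) prod(shp[[j]]), numeric(1)))
  per_module * (cfg$use_dna + cfg$use_dnase)
}

#' Build an untrained model
#'
#' Allocates and He-initializes all parameters of the configured
#' architecture.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `encap_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  layers <- stack_layers(cfg$kernels_wide, cfg$kernels_narrow)
  with_seed(seed, {
    params <- list()
    if (cfg$use_dna) {
      p <- stack_init(layers, 4L)
      names(p) <- paste0("dna_", names(p))
      params <- c(params, p)
    }
    if (cfg$use_dnase) {
      p <- stack_init(layers, 1L)
      names(p) <- paste0("dnase_", names(p))
      params <- c(params, p)
    }
    din <- joint_input_dim(cfg)
    sizes <- c(din, cfg$dense_sizes, 2L)
    for (h in seq_len(length(sizes) - 1L)) {
      params[[paste0("dense", h, "_W")]] <-
        he_init(sizes[h], sizes[h + 1L], sizes[h])
      params[[paste0("dense", h, "_b")]] <- numeric(sizes[h + 1L])
    }
    structure(
      list(cfg = cfg, layers = layers, params = params, encoder = NULL,
           train_log = NULL, train_info = NULL),
      class = "encap_model"
    )
  })
}

#' @export
print.encap_model <- function(x, ...) {
  cat("<encap_model> ",
      paste(c(if (x$cfg$use_dna) "DNA", if (x$cfg$use_dnase) "DNase"),
            collapse = " + "),
      " module(s), ", model_parameter_count(x), " parameters",
      if (!is.null(x$train_log)) ", trained" else ", untrained",
      "\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#' @param model an `encap_model`.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Per-layer output shapes of the feature modules
#'
#' @param cfg a [network_config()].
#' @return List with one `(length, channels)` row per layer.
#' @export
model_shapes <- function(cfg) {
  layers <- stack_layers(cfg$kernels_wide, cfg$kernels_narrow)
  stack_shapes(layers, cfg$input_len, 4L)
}

feature_param_names <- function(model) {
  nm <- names(model$params)
  nm[startsWith(nm, "dna_") | startsWith(nm, "dnase_")]
}

#' Digest of the feature-module parameters
#'
#' Hash of all DNA- and DNase-module weights, used to verify that the
#' feature extractors stay byte-identical while they are frozen during
#' the second training stage.
#'
#' @param model an `encap_model`.
#' @return Character hash.
#' @export
feature_checksum <- function(model) {
  rlang::hash(model$params[feature_param_names(model)])
}

# -- full forward / backward -------------------------------------------

# Xseq: (B*L) x 4 or NULL; Xdnase: (B*L) x 1 or NULL
nn_forward <- function(model, Xseq, Xdnase, B, train = FALSE,
                       keep_cache = train) {
  cfg <- model$cfg
  L <- cfg$input_len
  taps <- list()
  fwd_dna <- fwd_dnase <- NULL
  if (cfg$use_dna) {
    fwd_dna <- stack_forward(Xseq, model$params, "dna_", model$layers,
                             B, L, 4L, keep_cache = keep_cache)
    taps <- c(taps, fwd_dna$taps)
  }
  if (cfg$use_dnase) {
    fwd_dnase <- stack_forward(Xdnase, model$params, "dnase_",
                               model$layers, B, L, 1L,
                               keep_cache = keep_cache)
    taps <- c(taps, fwd_dnase$taps)
  }
  A <- do.call(cbind, taps)
  merged <- A
  merge_mask <- NULL
  if (train && cfg$merge_dropout > 0) {
    keep <- 1 - cfg$merge_dropout
    merge_mask <- matrix(stats::runif(length(A)) < keep,
                         nrow(A), ncol(A)) / keep
    A <- A * merge_mask
  }
  n_hidden <- length(cfg$dense_sizes)
  dense_caches <- vector("list", n_hidden + 1L)
  drop_masks <- vector("list", n_hidden)
  for (h in seq_len(n_hidden)) {
    f <- dense_forward(A, model$params[[paste0("dense", h, "_W")]],
                       model$params[[paste0("dense", h, "_b")]])
    A <- f$out
    dense_caches[[h]] <- f$cache
    if (train && cfg$dropout > 0) {
      keep <- 1 - cfg$dropout
      mask <- matrix(stats::runif(length(A)) < keep, nrow(A), ncol(A)) / keep
      A <- A * mask
      drop_masks[[h]] <- mask
    }
  }
  hout <- n_hidden + 1L
  f <- dense_forward(A, model$params[[paste0("dense", hout, "_W")]],
                     model$params[[paste0("dense", hout, "_b")]],
                     relu = FALSE)
  dense_caches[[hout]] <- f$cache
  list(logits = f$out, merged = merged,
       cache = list(fwd_dna = fwd_dna, fwd_dnase = fwd_dnase,
                    dense = dense_caches, drop = drop_masks,
                    merge_mask = merge_mask,
                    n_taps_dna = if (cfg$use_dna) length(fwd_dna$taps) else 0L))
}

nn_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  grads <- list()
  n_hidden <- length(cfg$dense_sizes)
  dA <- dlogits
  for (h in rev(seq_len(n_hidden + 1L))) {
    W <- model$params[[paste0("dense", h, "_W")]]
    bk <- dense_backward(dA, fwd$cache$dense[[h]], W)
    grads[[paste0("dense", h, "_W")]] <- bk$dW
    grads[[paste0("dense", h, "_b")]] <- bk$db
    dA <- bk$dX
    if (h > 1L && !is.null(fwd$cache$drop[[h - 1L]])) {
      dA <- dA * fwd$cache$drop[[h - 1L]]
    }
  }
  if (!is.null(fwd$cache$merge_mask)) {
    dA <- dA * fwd$cache$merge_mask
  }
  # split merged gradient back into the taps
  offset <- 0L
  split_tap <- function(fwd_mod) {
    lapply(fwd_mod$taps, function(tp) {
      cols <- (offset + 1L):(offset + ncol(tp))
      offset <<- offset + ncol(tp)
      dA[, cols, drop = FALSE]
    })
  }
  if (cfg$use_dna) {
    dtaps <- split_tap(fwd$cache$fwd_dna)
    grads <- c(grads, stack_backward(dtaps, fwd$cache$fwd_dna,
                                     model$params, "dna_", model$layers))
  }
  if (cfg$use_dnase) {
    dtaps <- split_tap(fwd$cache$fwd_dnase)
    grads <- c(grads, stack_backward(dtaps, fwd$cache$fwd_dnase,
                                     model$params, "dnase_", model$layers))
  }
  grads
}

# -- batch assembly -----------------------------------------------------

# seq array (L, 4, n) -> (B*L) x 4, rows sample-major
seq_batch <- function(seq_arr, idx) {
  L <- dim(seq_arr)[1]
  a <- aperm(seq_arr[, , idx, drop = FALSE], c(1, 3, 2))
  dim(a) <- c(L * length(idx), 4L)
  a
}

# encoded windows (n x L) -> (B*L) x 1
dnase_batch <- function(z_all, idx) {
  z <- t(z_all[idx, , drop = FALSE])
  matrix(as.vector(z), ncol = 1L)
}
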