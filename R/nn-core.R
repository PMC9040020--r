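# Internal neural-network primitives.
#
# Activations for a batch of B windows of length L with C channels are
# stored as a (B*L) x C matrix, rows grouped by sample (sample s occupies
# rows (s-1)*L + 1 .. s*L). Convolutions are computed by gathering the
# padded input into an im2col matrix and multiplying by the kernel
# matrix, so all heavy lifting happens in BLAS.

# -- convolution (same padding, stride 1) -------------------------------

conv_pad <- function(X, B, L, M, Cin) {
  pad_l <- (M - 1L) %/% 2L
  Lp <- L + M - 1L
  Xp <- matrix(0, B * Lp, Cin)
  prow <- rep((0:(B - 1L)) * Lp, each = L) + pad_l + seq_len(L)
  Xp[prow, ] <- X
  list(Xp = Xp, prow = prow, Lp = Lp)
}

conv_im2col <- function(Xp, base, M, Cin, nout) {
  Xc <- matrix(0, nout, M * Cin)
  for (m in seq_len(M)) {
    Xc[, ((m - 1L) * Cin + 1L):(m * Cin)] <- Xp[base + (m - 1L), ,
                                                drop = FALSE]
  }
  Xc
}

# W: (M*Cin) x K, b: length K
conv1d_forward <- function(X, W, b, B, L, M, Cin, relu = TRUE) {
  p <- conv_pad(X, B, L, M, Cin)
  base <- rep((0:(B - 1L)) * p$Lp, each = L) + seq_len(L)
  Xc <- conv_im2col(p$Xp, base, M, Cin, B * L)
  Z <- Xc %*% W
  Z <- Z + rep(b, each = nrow(Z))
  A <- if (relu) pmax(Z, 0) else Z
  list(out = A,
       cache = list(Xc = Xc, mask = if (relu) Z > 0 else NULL,
                    base = base, prow = p$prow, Lp = p$Lp,
                    B = B, L = L, M = M, Cin = Cin))
}

conv1d_backward <- function(dA, cache, W, need_dx = TRUE) {
  dZ <- if (is.null(cache$mask)) dA else dA * cache$mask
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dXc <- tcrossprod(dZ, W)
    M <- cache$M; Cin <- cache$Cin
    dXp <- matrix(0, cache$B * cache$Lp, Cin)
    for (m in seq_len(M)) {
      idx <- cache$base + (m - 1L)
      dXp[idx, ] <- dXp[idx, ] + dXc[, ((m - 1L) * Cin + 1L):(m * Cin),
                                     drop = FALSE]
    }
    dX <- dXp[cache$prow, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# -- max pooling, pool size 2, stride 2 ---------------------------------

pool2_forward <- function(X) {
  n <- nrow(X)
  stopifnot(n %% 2L == 0L)
  odd <- seq(1L, n, by = 2L)
  A1 <- X[odd, , drop = FALSE]
  A2 <- X[odd + 1L, , drop = FALSE]
  take1 <- A1 >= A2
  list(out = pmax(A1, A2), cache = list(take1 = take1, n = n))
}

pool2_backward <- function(dY, cache) {
  dX <- matrix(0, cache$n, ncol(dY))
  odd <- seq(1L, cache$n, by = 2L)
  dX[odd, ] <- dY * cache$take1
  dX[odd + 1L, ] <- dY * !cache$take1
  dX
}

# -- flatten (B*L) x C  <->  B x (L*C) ----------------------------------

flatten_rows <- function(A, B, L, C) {
  arr <- array(A, c(L, B, C))
  matrix(aperm(arr, c(1, 3, 2)), nrow = L * C, ncol = B) |> t()
}

unflatten_rows <- function(F, B, L, C) {
  arr <- array(t(F), c(L, C, B))
  matrix(aperm(arr, c(1, 3, 2)), nrow = L * B, ncol = C)
}

# -- dense layer --------------------------------------------------------

dense_forward <- function(A, W, b, relu = TRUE) {
  Z <- A %*% W
  Z <- Z + rep(b, each = nrow(Z))
  out <- if (relu) pmax(Z, 0) else Z
  list(out = out, cache = list(A = A, mask = if (relu) Z > 0 else NULL))
}

dense_backward <- function(dOut, cache, W) {
  dZ <- if (is.null(cache$mask)) dOut else dOut * cache$mask
  list(dX = tcrossprod(dZ, W), dW = crossprod(cache$A, dZ),
       db = colSums(dZ))
}

# -- softmax + cross-entropy -------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y: integer vector of 0/1 labels; column 2 is the positive class
softmax_xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  picked <- P[cbind(seq_len(n), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), y + 1L)] <- dZ[cbind(seq_len(n), y + 1L)] - 1
  list(loss = loss, probs = P, dlogits = dZ / n)
}

# -- parameter initialization and Adam ---------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

adam_state_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, frozen = character(0),
                      weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (weight_decay > 0 && endsWith(nm, "_W")) {
      g <- g + weight_decay * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# -- feature-module stack ----------------------------------------------

# layers: list of list(type = "conv", kernels =, len =) or list(type = "pool")
stack_layers <- function(k_wide, k_narrow) {
  list(
    list(type = "conv", kernels = k_wide, len = 8L),
    list(type = "conv", kernels = k_narrow, len = 1L),
    list(type = "conv", kernels = k_narrow, len = 3L),
    list(type = "conv", kernels = k_wide, len = 1L),
    list(type = "pool"),
    list(type = "conv", kernels = k_narrow, len = 3L),
    list(type = "conv", kernels = k_narrow, len = 3L),
    list(type = "pool")
  )
}

stack_init <- function(layers, cin) {
  params <- list()
  for (j in seq_along(layers)) {
    ly <- layers[[j]]
    if (ly$type != "conv") next
    fan_in <- ly$len * cin
    params[[paste0("conv", j, "_W")]] <- he_init(fan_in, ly$kernels, fan_in)
    params[[paste0("conv", j, "_b")]] <- numeric(ly$kernels)
    cin <- ly$kernels
  }
  params
}

# shapes of every layer output for input length L, channels cin
stack_shapes <- function(layers, L, cin) {
  out <- list()
  for (j in seq_along(layers)) {
    ly <- layers[[j]]
    if (ly$type == "conv") {
      cin <- ly$kernels
    } else {
      L <- L %/% 2L
    }
    out[[j]] <- c(length = L, channels = cin)
  }
  out
}

# forward through one feature module; taps are the flattened outputs of
# the layers listed in tap_at (default: every pooling layer)
stack_forward <- function(X, params, prefix, layers, B, L, cin,
                          tap_at = NULL, keep_cache = TRUE) {
  if (is.null(tap_at)) {
    tap_at <- which(vapply(layers, function(l) l$type == "pool", logical(1)))
  }
  caches <- vector("list", length(layers))
  taps <- list()
  tap_dims <- list()
  A <- X
  for (j in seq_along(layers)) {
    ly <- layers[[j]]
    if (ly$type == "conv") {
      W <- params[[paste0(prefix, "conv", j, "_W")]]
      b <- params[[paste0(prefix, "conv", j, "_b")]]
      f <- conv1d_forward(A, W, b, B, L, ly$len, cin)
      A <- f$out
      if (keep_cache) caches[[j]] <- f$cache
      cin <- ly$kernels
    } else {
      f <- pool2_forward(A)
      A <- f$out
      L <- L %/% 2L
      if (keep_cache) caches[[j]] <- f$cache
    }
    if (j %in% tap_at) {
      taps[[length(taps) + 1L]] <- flatten_rows(A, B, L, cin)
      tap_dims[[length(tap_dims) + 1L]] <- c(j = j, L = L, C = cin)
    }
  }
  list(taps = taps, tap_dims = tap_dims, caches = caches, B = B)
}

# backward through one feature module given gradients on the taps;
# returns parameter gradients (input gradient is not needed)
stack_backward <- function(dtaps, fwd, params, prefix, layers) {
  grads <- list()
  B <- fwd$B
  tap_j <- vapply(fwd$tap_dims, `[[`, numeric(1), "j")
  dA <- NULL
  for (j in rev(seq_along(layers))) {
    hit <- which(tap_j == j)
    if (length(hit) == 1) {
      d <- fwd$tap_dims[[hit]]
      dtap <- unflatten_rows(dtaps[[hit]], B, d[["L"]], d[["C"]])
      dA <- if (is.null(dA)) dtap else dA + dtap
    }
    if (is.null(dA)) next
    ly <- layers[[j]]
    if (ly$type == "conv") {
      W <- params[[paste0(prefix, "conv", j, "_W")]]
      bk <- conv1d_backward(dA, fwd$caches[[j]], W, need_dx = j > 1L)
      grads[[paste0(prefix, "conv", j, "_W")]] <- bk$dW
      grads[[paste0(prefix, "conv", j, "_b")]] <- bk$db
      dA <- bk$dX
    } else {
      dA <- pool2_backward(dA, fwd$caches[[j]])
    }
  }
  grads
}
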