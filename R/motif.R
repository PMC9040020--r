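# Conversion of first-layer convolution kernels into PWMs and MEME
# export.

#' Extreme activation value of a kernel
#'
#' The maximum pre-ReLU response the kernel can produce on any one-hot
#' input: the sum over kernel positions of the largest weight across
#' channels. The bias is not part of the definition.
#'
#' @param w `M x N` kernel weight matrix.
#' @return The extreme activation value.
#' @examples
#' extreme_activation_value(rbind(c(1, -2), c(3, 0.5))) # 4
#' @export
extreme_activation_value <- function(w) {
  stopifnot(is.matrix(w), all(is.finite(w)))
  sum(apply(w, 1, max))
}

#' Positions of a sequence that activate a kernel
#'
#' A position `i` (0-based) is activated when the pre-ReLU convolution
#' response exceeds `alpha` times the kernel's extreme activation value
#' (strict inequality, no bias).
#'
#' @param w `M x N` kernel weight matrix (first-layer kernels: `8 x 4`).
#' @param onehot `L x 4` one-hot sequence matrix.
#' @param alpha activation control coefficient in `(0, 1)`, default 0.9.
#' @return Integer vector of 0-based activated positions.
#' @export
activated_positions <- function(w, onehot, alpha = 0.9) {
  stopifnot(is.matrix(w), is.matrix(onehot), ncol(w) == ncol(onehot),
            alpha > 0, alpha < 1)
  M <- nrow(w)
  L <- nrow(onehot)
  if (L < M) stop("sequence shorter than the kernel")
  # valid (no padding) convolution via im2col
  n_out <- L - M + 1L
  Xc <- matrix(0, n_out, M * ncol(w))
  for (m in seq_len(M)) {
    cols <- ((m - 1L) * ncol(w) + 1L):(m * ncol(w))
    Xc[, cols] <- onehot[m:(m + n_out - 1L), , drop = FALSE]
  }
  act <- drop(Xc %*% as.vector(t(w)))
  which(act > alpha * extreme_activation_value(w)) - 1L
}

#' Convert a kernel into a position weight matrix
#'
#' Scans the given sequences for activated positions of the kernel,
#' collects the kernel-length subsequence at every activation, and
#' builds a PWM from per-column nucleotide counts plus a pseudocount.
#' Subsequences containing `N` are skipped.
#'
#' @param w `M x 4` kernel weight matrix.
#' @param sequences character vector of DNA sequences to scan (typically
#'   the positive training sequences).
#' @param alpha activation threshold coefficient.
#' @param pseudocount added to every count cell before normalization
#'   (default 0.1, so no PWM column is ever exactly zero).
#' @return A list with `probs` (`M x 4` row-stochastic matrix, columns
#'   `A,C,G,T`) and `n_sites` (number of activating subsequences), or
#'   `NULL` when no position activates the kernel.
#' @export
kernel_to_pwm <- function(w, sequences, alpha = 0.9, pseudocount = 0.1) {
  M <- nrow(w)
  if (extreme_activation_value(w) <= 0) return(NULL)
  sites <- character(0)
  for (s in sequences) {
    if (nchar(s) < M) next
    oh <- one_hot_encode(s)
    pos <- activated_positions(w, oh, alpha)
    if (length(pos) > 0) {
      sub <- substring(s, pos + 1L, pos + M)
      sites <- c(sites, sub[!grepl("N", sub, fixed = TRUE)])
    }
  }
  if (length(sites) == 0) return(NULL)
  counts <- matrix(pseudocount, M, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  chars <- matrix(unlist(strsplit(sites, "", fixed = TRUE)), nrow = M)
  for (b in 1:4) {
    counts[, b] <- counts[, b] +
      rowSums(chars == c("A", "C", "G", "T")[b])
  }
  list(probs = counts / rowSums(counts), n_sites = length(sites))
}

#' Extract PWMs from all first-layer kernels of a model
#'
#' @param model a trained `encap_model` with a DNA module.
#' @param sequences character vector of sequences to scan for
#'   activations.
#' @param alpha,pseudocount see [kernel_to_pwm()].
#' @return Named list of PWMs (`kernel_<k>`); kernels with no
#'   activations or non-positive extreme activation value are omitted.
#' @export
extract_motifs <- function(model, sequences, alpha = 0.9,
                           pseudocount = 0.1) {
  stopifnot(inherits(model, "encap_model"))
  if (!model$cfg$use_dna) stop("model has no DNA module")
  W <- model$params$dna_conv1_W # (8*4) x K, rows ordered pos-major
  K <- ncol(W)
  out <- list()
  for (k in seq_len(K)) {
    w <- matrix(W[, k], nrow = 8L, ncol = 4L, byrow = TRUE)
    pwm <- kernel_to_pwm(w, sequences, alpha, pseudocount)
    if (!is.null(pwm)) out[[paste0("kernel_", k)]] <- pwm
  }
  out
}

#' Write PWMs in MEME minimal format
#'
#' The output is a version-4 MEME minimal-format motif file (the input
#' format of TomTom and other MEME-suite tools).
#'
#' @param pwms named list of PWMs as returned by [kernel_to_pwm()].
#' @param path output path.
#' @param background length-4 background letter frequencies (default
#'   uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  if (length(pwms) == 0) stop("no PWMs to write")
  if (is.null(names(pwms))) names(pwms) <- paste0("motif_", seq_along(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3],
                       background[4]), ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(p$probs), p$n_sites), con)
    writeLines(apply(p$probs, 1, function(r) {
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal-format motif file
#'
#' @param path MEME file path.
#' @return Named list of PWMs (`probs`, `n_sites`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal-format file (missing version line)")
  }
  motif_at <- grep("^MOTIF ", lines)
  out <- list()
  for (i in motif_at) {
    nm <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- lines[i + 1L]
    if (!grepl("^letter-probability matrix:", hdr)) {
      stop("motif ", nm, ": missing letter-probability matrix header")
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else NA_integer_
    rows <- lines[(i + 2L):(i + 1L + w)]
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    colnames(probs) <- c("A", "C", "G", "T")
    out[[nm]] <- list(probs = probs, n_sites = nsites)
  }
  out
}

#' Validate a MEME minimal-format file
#'
#' Checks the structural requirements of the minimal format: a version
#' line, an alphabet line, and for every motif a letter-probability
#' header whose width matches the number of matrix rows, with
#' row-stochastic non-negative entries.
#'
#' @param path MEME file path.
#' @param tol tolerance for row sums.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_meme <- function(path, tol = 1e-4) {
  lines <- readLines(path)
  if (!grepl("^MEME version \\d", lines[1])) {
    stop("first line must be a MEME version line")
  }
  if (!any(grepl("^ALPHABET=", lines))) stop("missing ALPHABET= line")
  pwms <- read_meme(path)
  if (length(pwms) == 0) stop("no MOTIF blocks")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]$probs
    if (any(p < 0)) stop("motif ", nm, ": negative probability")
    if (any(abs(rowSums(p) - 1) > tol)) {
      stop("motif ", nm, ": rows do not sum to 1")
    }
  }
  invisible(TRUE)
}

#' Mean per-column Pearson correlation between two PWMs
#'
#' Compares a recovered motif with a reference (e.g. an implanted
#' synthetic motif): the mean over aligned positions of the correlation
#' between the two 4-vectors of base probabilities. A learned kernel has
#' no reason to center the motif exactly, so — as motif-comparison tools
#' like TomTom do — the two matrices may be aligned at a small offset:
#' with `max_shift > 0` the best mean correlation over offsets
#' `-max_shift .. max_shift` (restricted to the overlapping columns, at
#' least `min_overlap` of them) is returned.
#'
#' @param p,q `M x 4` probability matrices of equal width (or PWM lists
#'   with a `probs` field).
#' @param max_shift maximum alignment offset (default 0: positional
#'   comparison only).
#' @param min_overlap minimum overlapping columns for a shifted
#'   alignment to count.
#' @return Mean per-column correlation in `[-1, 1]`.
#' @export
pwm_correlation <- function(p, q, max_shift = 0L, min_overlap = 5L) {
  if (is.list(p)) p <- p$probs
  if (is.list(q)) q <- q$probs
  stopifnot(nrow(p) == nrow(q), ncol(p) == 4, ncol(q) == 4)
  M <- nrow(p)
  col_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  score_at <- function(shift) {
    ip <- seq_len(M)[seq_len(M) + shift >= 1 & seq_len(M) + shift <= M]
    iq <- ip + shift
    if (length(ip) < min_overlap) return(-Inf)
    mean(vapply(seq_along(ip), function(j) {
      col_cor(p[ip[j], ], q[iq[j], ])
    }, numeric(1)))
  }
  shifts <- seq(-max_shift, max_shift)
  max(vapply(shifts, score_at, numeric(1)))
}
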