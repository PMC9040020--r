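# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# a tiny two-chromosome genome with known sequence
tiny_genome <- function() {
  c(chr1 = "ACGTACGTACGTACGTACGT", chr2 = "GGGGCCCCAAAATTTTNNNN")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force accessibility scoring: explicit loop over every window
brute_accessibility <- function(counts, W) {
  if (W %% 2 == 0) W <- W + 1
  n <- length(counts)
  half <- (W - 1) %/% 2
  s <- numeric(n)
  for (p in seq_len(n)) {
    lo <- max(1, p - half)
    hi <- min(n, p + half)
    M <- sum(counts[lo:hi])
    if (M > 0) s[p] <- counts[p] * (hi - lo + 1) / M
  }
  s
}

# brute-force single-kernel convolution (double loop)
brute_conv <- function(x, w, i, bias = 0) {
  M <- nrow(w)
  acc <- bias
  for (m in seq_len(M)) {
    for (n in seq_len(ncol(w))) {
      acc <- acc + w[m, n] * x[i + m, n]
    }
  }
  max(0, acc)
}

# brute-force AUROC by pairwise comparison (O(n^2))
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force average precision by direct enumeration over ranks
brute_auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  n_pos <- sum(y)
  ap <- 0
  prev_recall <- 0
  k <- 0
  while (k < length(y)) {
    # advance over a whole tied block
    k2 <- k + 1
    while (k2 < length(y) && s[k2 + 1] == s[k + 1]) k2 <- k2 + 1
    tp <- sum(y[1:k2])
    precision <- tp / k2
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
    k <- k2
  }
  ap
}

# brute-force interval intersection oracle
brute_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# small synthetic dataset shared by several training tests (cached per
# test run; generation takes a few seconds)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(genome_length = 150000L, n_enhancers = 15L,
                              k_replicates = 2L, seed = 5L)
      cache <<- make_dataset(cfg, ratio = 3L, stride = 20L, n_folds = 3L)
    }
    cache
  }
})
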