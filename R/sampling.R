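# Dataset construction: background model, matched negatives, fixed-stride
# augmentation, leakage-safe folds.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Build the background model for negative sampling
#'
#' The background is the genome minus a set of exclusion intervals
#' (known enhancers, promoters, exons, ...). Negative samples are drawn
#' only from the remaining allowed intervals.
#'
#' @param chrom_sizes named integer vector of chromosome lengths, or
#'   `NULL` to derive them from `genome`.
#' @param exclusions interval data frame of regions negatives must avoid.
#' @param genome named character vector of chromosome sequences (needed
#'   for GC-matched sampling).
#' @return An object of class `background_model` with the sorted,
#'   disjoint `allowed` intervals.
#' @export
build_background <- function(chrom_sizes = NULL, exclusions, genome = NULL) {
  if (is.null(chrom_sizes)) {
    if (is.null(genome)) stop("need chrom_sizes or genome")
    chrom_sizes <- vapply(genome, nchar, integer(1))
  }
  if (nrow(exclusions) > 0) {
    validate_intervals(exclusions)
    bad <- !exclusions$chrom %in% names(chrom_sizes) |
      exclusions$end > chrom_sizes[exclusions$chrom]
    if (any(bad)) stop("exclusion outside chromosome bounds: line ",
                       which(bad)[1])
    excl <- merge_intervals(exclusions)
  } else {
    excl <- exclusions
  }
  allowed <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    ex <- excl[excl$chrom == ch, , drop = FALSE]
    if (nrow(ex) == 0) {
      return(data.frame(chrom = ch, start = 0L, end = size,
                        name = NA_character_, strand = NA_character_,
                        stringsAsFactors = FALSE))
    }
    gaps <- IRanges::setdiff(
      IRanges::IRanges(1L, size),
      IRanges::IRanges(ex$start + 1L, ex$end)
    )
    if (length(gaps) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), name = NA_character_,
               strand = NA_character_, stringsAsFactors = FALSE)
  }))
  if (is.null(allowed)) {
    allowed <- genomic_intervals(character(), integer(), integer())[0, ]
  }
  structure(
    list(allowed = allowed, chrom_sizes = chrom_sizes, genome = genome),
    class = "background_model"
  )
}

#' Sample length/GC-matched negative intervals
#'
#' For each positive interval, draws `ratio` negatives from the allowed
#' background by rejection sampling. Every negative has exactly the
#' length of its positive; with `match_gc = TRUE` its GC content must
#' additionally lie within `gc_tol` of the positive's. Negatives never
#' overlap an exclusion interval or one another.
#'
#' When `target_len` is supplied, the whole augmentation footprint of
#' each negative (the span its fixed-length windows will cover, see
#' [augment_region()]) is required to fit inside one allowed interval,
#' so that no augmented window of a negative can touch an exclusion.
#'
#' @param positives interval data frame of positive regions.
#' @param bg a [build_background()] model.
#' @param ratio negatives per positive (the study uses 1:10 and 1:20).
#' @param match_gc match GC content as well as length?
#' @param gc_tol maximum absolute GC difference when `match_gc`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param target_len augmentation window length, or `NULL` to constrain
#'   only the negative interval itself.
#' @param max_attempts rejection draws allowed per negative before
#'   giving up with an error.
#' @return Interval data frame of `ratio * nrow(positives)` negatives,
#'   with `name` set to `neg_<i>_<j>` for the j-th negative of the i-th
#'   positive.
#' @export
sample_negatives <- function(positives, bg, ratio = 10L, match_gc = TRUE,
                             gc_tol = 0.02, seed = 1L, target_len = NULL,
                             max_attempts = 10000L) {
  validate_intervals(positives)
  stopifnot(inherits(bg, "background_model"), ratio >= 1)
  if (nrow(bg$allowed) == 0) stop("background model has no allowed intervals")
  if (match_gc && is.null(bg$genome)) {
    stop("GC matching requires a genome in the background model")
  }
  allowed <- bg$allowed
  aw <- allowed$end - allowed$start
  with_seed(seed, {
    acc_chrom <- character(0)
    acc_start <- integer(0)
    acc_end <- integer(0)
    acc_name <- character(0)
    for (i in seq_len(nrow(positives))) {
      len <- positives$end[i] - positives$start[i]
      fp <- if (is.null(target_len)) len else max(len, 2L * target_len - len)
      pad <- (fp - len) %/% 2L
      ok <- aw >= fp
      if (!any(ok)) {
        stop("no allowed interval can host a footprint of length ", fp,
             " for positive ", i)
      }
      slots <- ifelse(ok, aw - fp + 1L, 0L)
      gc_target <- if (match_gc) {
        gc_content(extract_sequence(bg$genome, positives[i, ]))
      } else NA_real_
      for (j in seq_len(ratio)) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          a <- sample.int(nrow(allowed), 1L, prob = slots)
          fp_start <- allowed$start[a] +
            sample.int(slots[a], 1L) - 1L
          st <- fp_start + pad
          en <- st + len
          ch <- allowed$chrom[a]
          # reject overlap with an already-accepted negative
          same <- acc_chrom == ch
          if (any(same & acc_start < en & acc_end > st)) next
          if (match_gc) {
            gc <- gc_content(substr(bg$genome[[ch]], st + 1L, en))
            if (abs(gc - gc_target) > gc_tol) next
          }
          acc_chrom <- c(acc_chrom, ch)
          acc_start <- c(acc_start, st)
          acc_end <- c(acc_end, en)
          acc_name <- c(acc_name, sprintf("neg_%d_%d", i, j))
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place negative ", j, " for positive ", i,
               if (match_gc) sprintf(" (target GC %.3f)", gc_target) else "",
               " after ", max_attempts, " attempts")
        }
      }
    }
    genomic_intervals(acc_chrom, acc_start, acc_end, acc_name)
  })
}

#' Fixed-stride window augmentation of one region
#'
#' Converts a variable-length region into fixed-length windows. A region
#' at least as long as `target_len` yields every `target_len` window
#' fully inside it at the given stride; a shorter region yields every
#' `target_len` window fully containing it, clipped to chromosome
#' bounds. Without clipping the window count is
#' `floor(|len - target_len| / stride) + 1`.
#'
#' @param region single-row interval data frame.
#' @param target_len window length (default 300, matching the typical
#'   enhancer length).
#' @param stride step between consecutive window starts.
#' @param chrom_length length of the region's chromosome.
#' @return Interval data frame of windows, each of length `target_len`.
#' @export
augment_region <- function(region, target_len = 300L, stride = 1L,
                           chrom_length) {
  validate_intervals(region)
  stopifnot(nrow(region) == 1, target_len >= 1, stride >= 1,
            stride <= target_len)
  if (chrom_length < target_len) {
    stop("chromosome shorter than the window length")
  }
  len <- region$end[1] - region$start[1]
  if (len >= target_len) {
    starts <- region$start[1] + seq(0L, len - target_len, by = stride)
  } else {
    starts <- (region$end[1] - target_len) +
      seq(0L, target_len - len, by = stride)
    starts <- pmin(pmax(starts, 0L), chrom_length - target_len)
    starts <- unique(starts)
  }
  genomic_intervals(region$chrom[1], starts, starts + target_len,
                    name = region$name[1])
}

#' Stratified origin-level fold assignment
#'
#' Cross-validation folds are assigned to origin regions *before*
#' augmentation, so all windows derived from one region share a fold and
#' no information leaks between training and test sets. Assignment is
#' stratified by label; within each class, fold sizes differ by at most
#' one.
#'
#' @param positive_ids character vector of positive origin ids.
#' @param negative_ids character vector of negative origin ids.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return Data frame with columns `origin_id`, `label`, `fold` (folds
#'   numbered `0 .. n_folds - 1`).
#' @export
split_folds <- function(positive_ids, negative_ids, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2)
  if (length(positive_ids) < n_folds || length(negative_ids) < n_folds) {
    stop("each class needs at least n_folds origin regions")
  }
  if (anyDuplicated(c(positive_ids, negative_ids))) {
    stop("origin ids must be unique across classes")
  }
  with_seed(seed, {
    assign_class <- function(ids, label) {
      ids <- sample(ids)
      data.frame(origin_id = ids, label = label,
                 fold = (seq_along(ids) - 1L) %% n_folds,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(assign_class(positive_ids, 1L),
                 assign_class(negative_ids, 0L))
    rownames(out) <- NULL
    out
  })
}

# one-hot encode many equal-length sequences into an (L, 4, n) array
one_hot_batch <- function(seqs, L) {
  n <- length(seqs)
  bases <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  flat <- matrix(0, n * L, 4)
  known <- !is.na(idx)
  flat[cbind(which(known), idx[known])] <- 1
  flat[!known, ] <- 0.25
  # rows are (window-major, position within window); reorder to (L, 4, n)
  arr <- array(0, c(L, 4, n))
  for (b in 1:4) arr[, b, ] <- matrix(flat[, b], nrow = L)
  arr
}

#' Assemble a fixed-length training dataset
#'
#' Runs augmentation over all positive and negative origin regions,
#' extracts the one-hot sequence and the `k`-replicate accessibility
#' window for every augmented window, and attaches origin-level fold
#' assignments.
#'
#' @param positives,negatives interval data frames; their `name` columns
#'   are the origin ids (generated when missing).
#' @param genome named character vector of chromosome sequences.
#' @param tracks list of `accessibility_track` objects (one per
#'   replicate).
#' @param folds fold assignment from [split_folds()], or `NULL` to
#'   assign folds here with `seed`.
#' @param target_len,stride augmentation parameters, see
#'   [augment_region()].
#' @param n_folds,seed used only when `folds` is `NULL`.
#' @return An object of class `encap_dataset`: a `manifest` data frame
#'   (origin_id, label, fold, window coordinates), a sequence array of
#'   dimension `(target_len, 4, n_windows)` and an accessibility array
#'   of dimension `(k, target_len, n_windows)`.
#' @export
assemble_dataset <- function(positives, negatives, genome, tracks,
                             folds = NULL, target_len = 300L, stride = 1L,
                             n_folds = 5L, seed = 1L) {
  validate_intervals(positives)
  validate_intervals(negatives)
  if (all(is.na(positives$name))) {
    positives$name <- sprintf("pos_%d", seq_len(nrow(positives)))
  }
  if (all(is.na(negatives$name))) {
    negatives$name <- sprintf("neg_%d", seq_len(nrow(negatives)))
  }
  if (is.null(folds)) {
    folds <- split_folds(positives$name, negatives$name, n_folds, seed)
  }
  fold_of <- stats::setNames(folds$fold, folds$origin_id)
  chrom_len <- vapply(genome, nchar, integer(1))

  augment_all <- function(iv, label) {
    pieces <- lapply(seq_len(nrow(iv)), function(i) {
      w <- augment_region(iv[i, ], target_len, stride,
                          chrom_len[[iv$chrom[i]]])
      w$label <- label
      w
    })
    do.call(rbind, pieces)
  }
  manifest <- rbind(augment_all(positives, 1L), augment_all(negatives, 0L))
  names(manifest)[names(manifest) == "name"] <- "origin_id"
  if (any(!manifest$origin_id %in% names(fold_of))) {
    stop("fold assignment is missing some origin ids")
  }
  manifest$fold <- unname(fold_of[manifest$origin_id])
  manifest <- manifest[, c("origin_id", "label", "fold",
                           "chrom", "start", "end")]
  rownames(manifest) <- NULL

  n <- nrow(manifest)
  seqs <- substring(genome[manifest$chrom], manifest$start + 1L,
                    manifest$end)
  seq_arr <- one_hot_batch(seqs, target_len)
  k <- length(tracks)
  acc_arr <- array(0, c(k, target_len, n))
  idx <- outer(seq_len(target_len), manifest$start, `+`)
  for (r in seq_len(k)) {
    acc_arr[r, , ] <- tracks[[r]]$scores[idx]
  }
  structure(
    list(manifest = manifest, seq = seq_arr, acc = acc_arr,
         target_len = target_len, k = k),
    class = "encap_dataset"
  )
}

#' @export
print.encap_dataset <- function(x, ...) {
  m <- x$manifest
  cat("<encap_dataset> ", nrow(m), " windows (",
      sum(m$label == 1), " positive, ", sum(m$label == 0), " negative), ",
      length(unique(m$origin_id)), " origins, k = ", x$k,
      " replicates, window length ", x$target_len, "\n", sep = "")
  invisible(x)
}

#' Write / read a dataset manifest
#'
#' The manifest is the plain-text record of a dataset: one row per
#' augmented window with its origin id, label, fold and coordinates.
#'
#' @param dataset an `encap_dataset` (or a manifest data frame).
#' @param path TSV path.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_manifest <- function(dataset, path) {
  m <- if (inherits(dataset, "encap_dataset")) dataset$manifest else dataset
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
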