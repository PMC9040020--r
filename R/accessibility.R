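#' Read-start track
#'
#' Per-position counts of DNase-seq read 5' ends along one chromosome
#' for one replicate. Position `p` (0-based) is stored at `counts[p + 1]`.
#'
#' @param chrom chromosome name.
#' @param counts non-negative integer vector, one entry per position.
#' @param replicate_id identifier of the sequencing replicate.
#' @return An object of class `read_start_track`.
#' @export
read_start_track <- function(chrom, counts, replicate_id = "rep1") {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("read-start counts must be finite and non-negative")
  }
  structure(
    list(chrom = chrom, counts = counts, replicate_id = replicate_id),
    class = "read_start_track"
  )
}

#' Count read 5' ends per position
#'
#' DNase-seq reads mark nuclease cleavage at their 5' end: a plus-strand
#' read contributes at its `start`, a minus-strand read at `end - 1`
#' (half-open coordinates). Unstranded reads are treated as plus-strand.
#'
#' @param reads interval data frame of aligned reads (chrom, start, end,
#'   strand).
#' @param chrom chromosome to count on.
#' @param chrom_length chromosome length in bp.
#' @param replicate_id replicate identifier attached to the track.
#' @return A [read_start_track()] of length `chrom_length`.
#' @export
count_read_starts <- function(reads, chrom, chrom_length,
                              replicate_id = "rep1") {
  validate_intervals(reads)
  reads <- reads[reads$chrom == chrom, , drop = FALSE]
  if (nrow(reads) > 0 && (any(reads$start < 0) ||
                          any(reads$end > chrom_length))) {
    stop("read beyond chromosome bounds on ", chrom)
  }
  minus <- !is.na(reads$strand) & reads$strand == "-"
  pos5 <- ifelse(minus, reads$end - 1L, reads$start)
  counts <- tabulate(pos5 + 1L, nbins = chrom_length)
  read_start_track(chrom, counts, replicate_id)
}

#' Read a per-position count track from a TSV file
#'
#' Plain-text alternative to aligned reads: three tab-separated columns
#' `chrom`, `pos` (0-based) and `count`. Positions absent from the file
#' have count 0.
#'
#' @param path TSV path.
#' @param chrom chromosome to extract.
#' @param chrom_length chromosome length.
#' @param replicate_id replicate identifier.
#' @return A [read_start_track()].
#' @export
read_count_track <- function(path, chrom, chrom_length,
                             replicate_id = "rep1") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "count"),
                           colClasses = c("character", "integer", "numeric"))
  tab <- tab[tab$chrom == chrom, , drop = FALSE]
  if (nrow(tab) > 0 && (any(tab$pos < 0) || any(tab$pos >= chrom_length))) {
    stop("count-track position beyond chromosome bounds on ", chrom)
  }
  counts <- numeric(chrom_length)
  counts[tab$pos + 1L] <- tab$count
  read_start_track(chrom, counts, replicate_id)
}

#' Per-position chromatin accessibility score
#'
#' The accessibility score of a position is the number of read starts at
#' that position divided by the average per-position read-start rate in
#' a background window of size `W` centered there: `S = N / Ntilde` with
#' `Ntilde = M / W`, where `M` is the total read-start count in the
#' window. Windows are truncated at chromosome ends and the truncated
#' length replaces `W`, so `S` stays a ratio of rates. Positions whose
#' window contains no reads at all get `S = 0`.
#'
#' @param track a [read_start_track()].
#' @param W background window size in bp; if even it is incremented by 1
#'   so the window is symmetric around the scored position. Default 201.
#' @return An object of class `accessibility_track` with fields `chrom`,
#'   `scores`, `replicate_id`, `window_size`.
#' @export
accessibility_score <- function(track, W = 201L) {
  stopifnot(inherits(track, "read_start_track"))
  W <- as.integer(W)
  if (is.na(W) || W < 1) stop("window size W must be >= 1")
  if (W %% 2L == 0L) W <- W + 1L
  n <- length(track$counts)
  half <- (W - 1L) %/% 2L
  # window sums via cumulative sums, truncated at chromosome ends
  cs <- c(0, cumsum(track$counts))
  pos <- seq_len(n)
  lo <- pmax(pos - half, 1L)
  hi <- pmin(pos + half, n)
  M <- cs[hi + 1L] - cs[lo]
  eff_w <- hi - lo + 1L
  scores <- numeric(n)
  nz <- M > 0
  scores[nz] <- track$counts[nz] * eff_w[nz] / M[nz]
  structure(
    list(chrom = track$chrom, scores = scores,
         replicate_id = track$replicate_id, window_size = W),
    class = "accessibility_track"
  )
}

#' Accessibility window for one interval across replicates
#'
#' Slices the per-replicate accessibility scores over an interval,
#' producing the `k x L` matrix consumed by the replicate auto-encoder.
#'
#' @param tracks list of `accessibility_track` objects (the `k`
#'   replicates), all covering the interval's chromosome.
#' @param iv single-row interval data frame.
#' @return A `k x L` numeric matrix, rows in replicate order, columns in
#'   genomic order.
#' @export
window_accessibility <- function(tracks, iv) {
  validate_intervals(iv)
  stopifnot(nrow(iv) == 1, length(tracks) >= 1)
  L <- iv$end[1] - iv$start[1]
  out <- matrix(0, length(tracks), L)
  for (r in seq_along(tracks)) {
    tr <- tracks[[r]]
    stopifnot(inherits(tr, "accessibility_track"))
    if (tr$chrom != iv$chrom[1]) {
      stop("replicate ", tr$replicate_id, " has no track for ", iv$chrom[1])
    }
    if (iv$start[1] < 0 || iv$end[1] > length(tr$scores)) {
      stop("interval not covered by replicate ", tr$replicate_id)
    }
    out[r, ] <- tr$scores[(iv$start[1] + 1L):iv$end[1]]
  }
  rownames(out) <- vapply(tracks, `[[`, character(1), "replicate_id")
  out
}

#' Write an accessibility track as bedGraph
#'
#' @param track an `accessibility_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "accessibility_track"))
  s <- track$scores
  # run-length encode so flat stretches collapse to one line
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%.10g", track$chrom, starts[keep],
                   ends[keep], r$values[keep])
  writeLines(lines, path)
  invisible(path)
}
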