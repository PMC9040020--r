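#' Genomic intervals as a data frame
#'
#' `encap` represents genomic intervals as plain data frames in BED
#' convention: 0-based, half-open `[start, end)`. This is the coordinate
#' system used everywhere inside the package, including FASTA extraction,
#' so interval length is always `end - start`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, exclusive end; must satisfy `end > start`.
#' @param name optional character vector of feature names.
#' @param strand optional character vector over `+`, `-`, `.`.
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, one row per interval.
#' @examples
#' genomic_intervals("chr1", 10, 20)
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  iv <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    name = rep_len(as.character(name), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv),
            all(c("chrom", "start", "end") %in% names(iv)))
  if (any(is.na(iv$start)) || any(is.na(iv$end))) {
    stop("interval coordinates contain NA")
  }
  if (any(iv$start < 0)) {
    stop("negative interval start: line ", which(iv$start < 0)[1])
  }
  if (any(iv$start >= iv$end)) {
    stop("interval with start >= end: line ", which(iv$start >= iv$end)[1])
  }
  bad_strand <- !is.na(iv$strand) & !iv$strand %in% c("+", "-", ".")
  if (any(bad_strand)) stop("invalid strand value")
  invisible(iv)
}

#' Interval lengths
#'
#' @param iv interval data frame (see [genomic_intervals()]).
#' @return Integer vector of lengths `end - start`.
#' @export
interval_length <- function(iv) {
  iv$end - iv$start
}

# Convert 0-based half-open intervals to GRanges (1-based closed) and back.
# Used only internally where IRanges machinery (reduce, complement,
# overlap) does the heavy lifting.
iv_to_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
}

granges_to_iv <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = NA_character_,
    strand = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Sorted union of possibly-overlapping intervals, per chromosome.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  granges_to_iv(GenomicRanges::reduce(iv_to_granges(iv)))
}
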