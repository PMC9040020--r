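#' Read a FASTA file
#'
#' Sequences are uppercase-normalized on read; any letter outside the
#' `A`/`C`/`G`/`T` alphabet (including IUPAC ambiguity codes) is mapped
#' to `N`. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA
#'   record ids (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    stop("empty sequence for FASTA record '", names(seqs)[empty][1], "'")
  }
  # collapse everything outside the alphabet to N
  normalize_alphabet(seqs)
}

normalize_alphabet <- function(seqs) {
  gsub("[^ACGTN]", "N", seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3 and wider; columns beyond the sixth are ignored. BED is
#' 0-based half-open, which is also the package-internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path path to a tab-separated BED file.
#' @return An interval data frame (see [genomic_intervals()]) in file
#'   order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), integer(), integer())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- vapply(fields, length, integer(1))
  if (any(ncol_min < 3)) {
    stop("BED line ", which(ncol_min < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  if (any(start < 0)) {
    stop("BED line ", which(start < 0)[1], ": negative start")
  }
  if (any(start >= end)) {
    stop("BED line ", which(start >= end)[1], ": start >= end")
  }
  name <- vapply(fields, function(f) {
    if (length(f) >= 4) f[[4]] else NA_character_
  }, character(1))
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6) f[[6]] else NA_character_
  }, character(1))
  genomic_intervals(chrom, start, end, name, strand)
}

#' Write intervals to a BED file
#'
#' @param iv interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  has_name <- "name" %in% names(iv) && any(!is.na(iv$name))
  has_strand <- "strand" %in% names(iv) && any(!is.na(iv$strand))
  cols <- list(iv$chrom, iv$start, iv$end)
  if (has_name || has_strand) {
    cols <- c(cols, list(ifelse(is.na(iv$name), ".", iv$name)))
  }
  if (has_strand) {
    cols <- c(cols, list(0L, ifelse(is.na(iv$strand), ".", iv$strand)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Extract the sequence of an interval from a genome
#'
#' Always returns the forward-strand sequence; the interval's `strand`
#' field is ignored (enhancer annotations are unstranded and no
#' reverse-complement augmentation is performed).
#'
#' @param genome named character vector of chromosome sequences, as
#'   returned by [read_fasta()].
#' @param iv a single-row interval data frame.
#' @return The interval's sequence as a character scalar of length
#'   `end - start`.
#' @export
extract_sequence <- function(genome, iv) {
  validate_intervals(iv)
  stopifnot(nrow(iv) == 1)
  chrom <- iv$chrom[1]
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom)
  }
  clen <- nchar(genome[[chrom]])
  if (iv$end[1] > clen) {
    stop("interval [", iv$start[1], ",", iv$end[1], ") out of bounds for ",
         chrom, " (length ", clen, ")")
  }
  substr(genome[[chrom]], iv$start[1] + 1L, iv$end[1])
}

#' One-hot encode a DNA sequence
#'
#' Columns are ordered `A,C,G,T`. An `N` is encoded as the uniform row
#' `(0.25, 0.25, 0.25, 0.25)`, which keeps every row summing to 1.
#'
#' @param seq character scalar over `A,C,G,T,N`.
#' @return An `L x 4` numeric matrix with column names `A,C,G,T`.
#' @examples
#' one_hot_encode("ACGTN")
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  L <- length(bases)
  m <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  known <- !is.na(idx)
  m[cbind(which(known), idx[known])] <- 1
  if (any(!known)) {
    if (any(bases[!known] != "N")) {
      stop("sequence contains letters outside A,C,G,T,N")
    }
    m[!known, ] <- 0.25
  }
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()] on N-free sequences; uniform rows decode
#' to `N`.
#'
#' @param m `L x 4` one-hot matrix, columns `A,C,G,T`.
#' @return Character scalar.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4)
  letters4 <- c("A", "C", "G", "T")
  out <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (all(abs(r - 0.25) < 1e-9)) return("N")
    letters4[which.max(r)]
  }, character(1))
  paste(out, collapse = "")
}

#' GC content of a sequence
#'
#' `N` bases count in the denominator but never as G/C, so an all-`N`
#' sequence has GC content 0.
#'
#' @param seq character scalar, length >= 1.
#' @return Fraction of G/C bases in `[0, 1]`.
#' @examples
#' gc_content("ACGTN") # 2/5
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  L <- nchar(seq)
  if (L == 0) stop("empty sequence")
  gc <- L - nchar(gsub("[GCgc]", "", seq))
  gc / L
}
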