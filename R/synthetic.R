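# Synthetic fixture generator: a small genome with implanted enhancers,
# an implanted TF motif, and replicate DNase-seq read-start tracks with
# elevated Poisson rates inside enhancers.

#' Default implanted motif
#'
#' A sharp 8-bp E-box-like motif (consensus `GCACGTGA`) used as the
#' default implanted transcription factor binding signal.
#'
#' @param sharpness probability mass on the consensus base per position.
#' @return An `8 x 4` row-stochastic matrix, columns `A,C,G,T`.
#' @export
default_motif <- function(sharpness = 0.85) {
  consensus <- c("G", "C", "A", "C", "G", "T", "G", "A")
  p <- matrix((1 - sharpness) / 3, 8, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  p[cbind(1:8, match(consensus, colnames(p)))] <- sharpness
  p
}

#' Synthetic dataset configuration
#'
#' Describes the generative model of the fixture data: an i.i.d.
#' background genome at a given GC content, non-overlapping enhancer
#' intervals with lengths bracketing the typical enhancer length
#' statistics (median 275 bp, mean 288 bp), an implanted 8-bp motif in a
#' configurable fraction of enhancers, and `k` replicate read-start
#' tracks that are Poisson with rate `lambda_enh` per position inside
#' enhancers and `lambda_bg` outside.
#'
#' @param genome_length chromosome length in bp.
#' @param gc genome GC fraction (default 0.41, human-like).
#' @param n_enhancers number of enhancers to implant.
#' @param enhancer_length_range min/max enhancer length.
#' @param motif `8 x 4` PWM of the implanted motif.
#' @param motif_prob fraction of enhancers receiving implanted motif
#'   sites.
#' @param sites_per_enhancer number of PWM-sampled sites written into
#'   each motif-carrying enhancer (default 1; real enhancers often carry
#'   homotypic clusters of several sites).
#' @param k_replicates number of DNase-seq replicates.
#' @param lambda_bg,lambda_enh Poisson read-start rates per position.
#' @param seed integer seed; the whole dataset is deterministic given
#'   the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(genome_length = 600000L, gc = 0.41,
                             n_enhancers = 50L,
                             enhancer_length_range = c(200L, 400L),
                             motif = default_motif(), motif_prob = 1,
                             sites_per_enhancer = 1L,
                             k_replicates = 3L, lambda_bg = 0.2,
                             lambda_enh = 1.0, seed = 1L) {
  stopifnot(gc > 0, gc <= 1, motif_prob >= 0, motif_prob <= 1,
            lambda_bg >= 0, lambda_enh >= lambda_bg, k_replicates >= 1,
            genome_length >= 10L * max(enhancer_length_range))
  structure(
    list(genome_length = as.integer(genome_length), gc = gc,
         n_enhancers = as.integer(n_enhancers),
         enhancer_length_range = as.integer(enhancer_length_range),
         motif = motif, motif_prob = motif_prob,
         sites_per_enhancer = as.integer(sites_per_enhancer),
         k_replicates = as.integer(k_replicates),
         lambda_bg = lambda_bg, lambda_enh = lambda_enh,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the background genome
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`, split evenly within the
#' G/C and A/T pairs.
#'
#' @param cfg a [synthetic_config()].
#' @return Named character vector with one chromosome `chrS`.
#' @export
generate_genome <- function(cfg) {
  with_seed(cfg$seed, {
    p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
           T = (1 - cfg$gc) / 2)
    bases <- sample(names(p), cfg$genome_length, replace = TRUE, prob = p)
    stats::setNames(paste(bases, collapse = ""), "chrS")
  })
}

#' Implant enhancers (and motif sites) into a genome
#'
#' Places non-overlapping enhancer intervals with lengths uniform in the
#' configured range, keeping a margin of one window length from the
#' chromosome ends. A `motif_prob` fraction of enhancers receive one
#' motif site sampled from the PWM, written into the genome at a uniform
#' internal offset.
#'
#' @param genome named character vector from [generate_genome()].
#' @param cfg a [synthetic_config()].
#' @param margin distance kept free at both chromosome ends.
#' @return List with the modified `genome`, the `enhancers` interval
#'   data frame, and `truth` (interval data frame of implanted motif
#'   sites; zero rows when `motif_prob = 0`).
#' @export
plant_enhancers <- function(genome, cfg, margin = 300L) {
  chrom <- names(genome)[1]
  glen <- nchar(genome[[1]])
  with_seed(cfg$seed + 1L, {
    lens <- sample(seq(cfg$enhancer_length_range[1],
                       cfg$enhancer_length_range[2]),
                   cfg$n_enhancers, replace = TRUE)
    starts <- integer(0)
    ends <- integer(0)
    for (i in seq_len(cfg$n_enhancers)) {
      placed <- FALSE
      for (att in 1:10000) {
        st <- sample.int(glen - 2L * margin - lens[i], 1L) + margin
        en <- st + lens[i]
        if (!any(starts < en & ends > st)) {
          starts <- c(starts, st); ends <- c(ends, en)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place enhancer ", i,
                        " without overlap; genome too crowded")
    }
    enh <- genomic_intervals(chrom, starts, ends,
                             name = sprintf("pos_%d", seq_along(starts)))
    has_motif <- stats::runif(cfg$n_enhancers) < cfg$motif_prob
    site_start <- integer(0)
    site_enh <- character(0)
    seqchars <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
    n_sites <- max(1L, cfg$sites_per_enhancer)
    for (i in which(has_motif)) {
      # non-overlapping uniform internal offsets for the site cluster
      placed_off <- integer(0)
      for (s_i in seq_len(n_sites)) {
        for (att in 1:100) {
          off <- sample.int(lens[i] - 8L + 1L, 1L) - 1L
          if (!any(abs(off - placed_off) < 8L)) break
          off <- NA_integer_
        }
        if (is.na(off)) next
        placed_off <- c(placed_off, off)
        st <- starts[i] + off
        site <- vapply(1:8, function(m) {
          sample(colnames(cfg$motif), 1L, prob = cfg$motif[m, ])
        }, character(1))
        seqchars[(st + 1L):(st + 8L)] <- site
        site_start <- c(site_start, st)
        site_enh <- c(site_enh, enh$name[i])
      }
    }
    genome[[1]] <- paste(seqchars, collapse = "")
    truth <- if (length(site_start) > 0) {
      genomic_intervals(chrom, site_start, site_start + 8L,
                        name = site_enh)
    } else {
      genomic_intervals(character(), integer(), integer())[0, ]
    }
    list(genome = genome, enhancers = enh, truth = truth)
  })
}

#' Simulate replicate read-start tracks
#'
#' Per-position read-start counts are independent Poisson draws with
#' rate `lambda_enh` inside enhancers and `lambda_bg` elsewhere,
#' independently for each of the `k` replicates.
#'
#' @param enhancers enhancer interval data frame.
#' @param cfg a [synthetic_config()].
#' @param chrom_length chromosome length.
#' @return List of `k` [read_start_track()]s.
#' @export
simulate_read_starts <- function(enhancers, cfg, chrom_length) {
  chrom <- if (nrow(enhancers) > 0) enhancers$chrom[1] else "chrS"
  rate <- rep(cfg$lambda_bg, chrom_length)
  for (i in seq_len(nrow(enhancers))) {
    rate[(enhancers$start[i] + 1L):enhancers$end[i]] <- cfg$lambda_enh
  }
  with_seed(cfg$seed + 2L, {
    lapply(seq_len(cfg$k_replicates), function(r) {
      read_start_track(chrom, stats::rpois(chrom_length, rate),
                       sprintf("rep%d", r))
    })
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the full pipeline on generated data: genome and enhancer
#' generation, accessibility scoring of the simulated read-start tracks,
#' background construction (exclusions = the enhancers), length/GC-
#' matched negative sampling, origin-level fold splitting and
#' fixed-stride window augmentation. The result flows through training
#' and evaluation exactly like a dataset built from real annotation.
#'
#' @param cfg a [synthetic_config()].
#' @param ratio negatives per positive.
#' @param target_len,stride augmentation parameters.
#' @param n_folds cross-validation folds.
#' @param match_gc,gc_tol negative-sampling GC constraint.
#' @param W accessibility background window size.
#' @return List with `dataset` (an `encap_dataset`), `genome`,
#'   `enhancers`, `negatives`, `truth`, `tracks` (accessibility tracks)
#'   and `config`.
#' @export
make_dataset <- function(cfg, ratio = 10L, target_len = 300L, stride = 10L,
                         n_folds = 5L, match_gc = TRUE, gc_tol = 0.02,
                         W = 201L) {
  genome <- generate_genome(cfg)
  planted <- plant_enhancers(genome, cfg, margin = target_len)
  genome <- planted$genome
  enh <- planted$enhancers
  tracks <- simulate_read_starts(enh, cfg, cfg$genome_length)
  acc <- lapply(tracks, accessibility_score, W = W)
  bg <- build_background(exclusions = enh, genome = genome)
  neg <- sample_negatives(enh, bg, ratio = ratio, match_gc = match_gc,
                          gc_tol = gc_tol, seed = cfg$seed + 3L,
                          target_len = target_len)
  folds <- split_folds(enh$name, neg$name, n_folds = n_folds,
                       seed = cfg$seed + 4L)
  dataset <- assemble_dataset(enh, neg, genome, acc, folds = folds,
                              target_len = target_len, stride = stride)
  list(dataset = dataset, genome = genome, enhancers = enh,
       negatives = neg, truth = planted$truth, tracks = acc,
       config = cfg)
}
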