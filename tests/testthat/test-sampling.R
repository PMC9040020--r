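test_that("background complement is the genome minus exclusions", {
  excl <- genomic_intervals("chr1", 20L, 40L)
  bg <- build_background(c(chr1 = 100L), excl)
  expect_equal(bg$allowed$start, c(0L, 40L))
  expect_equal(bg$allowed$end, c(20L, 100L))

  none <- build_background(c(chr1 = 100L), excl[0, ])
  expect_equal(none$allowed$start, 0L)
  expect_equal(none$allowed$end, 100L)

  all_excl <- build_background(c(chr1 = 100L),
                               genomic_intervals("chr1", 0L, 100L))
  expect_equal(nrow(all_excl$allowed), 0L)

  expect_error(build_background(c(chr1 = 100L),
                                genomic_intervals("chr1", 90L, 110L)),
               "bounds")
})

test_that("overlapping exclusions are merged before complementing", {
  excl <- genomic_intervals(rep("chr1", 3), c(10L, 30L, 20L),
                            c(25L, 50L, 35L))
  bg <- build_background(c(chr1 = 60L), excl)
  expect_equal(bg$allowed$start, c(0L, 50L))
  expect_equal(bg$allowed$end, c(10L, 60L))
})

test_that("negatives match positive lengths exactly and avoid exclusions", {
  withr::local_seed(2)
  glen <- 60000L
  genome <- stats::setNames(random_dna(glen), "chr1")
  pos <- genomic_intervals("chr1", c(5000L, 20000L, 40000L),
                           c(5230L, 20400L, 40310L),
                           name = paste0("p", 1:3))
  bg <- build_background(exclusions = pos, genome = genome)
  neg <- sample_negatives(pos, bg, ratio = 10L, match_gc = TRUE,
                          gc_tol = 0.03, seed = 9L, target_len = 300L)
  expect_equal(nrow(neg), 30L)
  expect_equal(interval_length(neg),
               rep(interval_length(pos), each = 10L))
  # independent interval-intersection oracle: no overlap with exclusions
  expect_false(any(brute_overlaps(neg, pos)))
  # negatives are pairwise disjoint
  ov <- sapply(seq_len(nrow(neg)), function(i) {
    sum(neg$chrom == neg$chrom[i] & neg$start < neg$end[i] &
          neg$end > neg$start[i])
  })
  expect_equal(ov, rep(1L, nrow(neg)))
  # GC constraint holds
  gc_of <- function(iv) vapply(seq_len(nrow(iv)), function(i) {
    gc_content(extract_sequence(genome, iv[i, ]))
  }, numeric(1))
  dev <- abs(gc_of(neg) - rep(gc_of(pos), each = 10L))
  expect_true(max(dev) <= 0.03)
  # deterministic given the seed
  neg2 <- sample_negatives(pos, bg, ratio = 10L, match_gc = TRUE,
                           gc_tol = 0.03, seed = 9L, target_len = 300L)
  expect_identical(neg, neg2)
})

test_that("length-only sampling ignores GC", {
  withr::local_seed(4)
  genome <- stats::setNames(random_dna(30000L), "chr1")
  pos <- genomic_intervals("chr1", 1000L, 1250L, name = "p1")
  bg <- build_background(exclusions = pos, genome = genome)
  neg <- sample_negatives(pos, bg, ratio = 5L, match_gc = FALSE, seed = 1L)
  expect_equal(interval_length(neg), rep(250L, 5L))
})

test_that("augmented window footprints of negatives avoid exclusions", {
  withr::local_seed(6)
  genome <- stats::setNames(random_dna(80000L), "chr1")
  # short positives force containing windows that extend beyond them
  pos <- genomic_intervals("chr1", c(10000L, 30000L), c(10200L, 30220L),
                           name = c("p1", "p2"))
  bg <- build_background(exclusions = pos, genome = genome)
  neg <- sample_negatives(pos, bg, ratio = 8L, match_gc = FALSE,
                          seed = 3L, target_len = 300L)
  wins <- do.call(rbind, lapply(seq_len(nrow(neg)), function(i) {
    augment_region(neg[i, ], 300L, 1L, 80000L)
  }))
  expect_false(any(brute_overlaps(wins, pos)))
})

test_that("window counts follow floor(|len - target|/stride) + 1", {
  r <- function(len) genomic_intervals("chr1", 1000L, 1000L + len)
  w <- augment_region(r(310L), 300L, 5L, 5000L)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start - 1000L, c(0L, 5L, 10L))

  w <- augment_region(r(300L), 300L, 7L, 5000L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 1000L)

  w <- augment_region(r(290L), 300L, 1L, 5000L)
  expect_equal(nrow(w), 11L)
  # every window fully contains the region
  expect_true(all(w$start <= 1000L & w$end >= 1290L))

  expect_error(augment_region(r(100L), 300L, 1L, 200L), "shorter")
})

test_that("window enumeration matches brute force for random geometries", {
  withr::local_seed(13)
  for (i in 1:40) {
    target <- sample(50:400, 1)
    len <- sample(20:500, 1)
    stride <- sample(1:min(20, target), 1)
    start <- 1000L
    w <- augment_region(genomic_intervals("chr1", start, start + len),
                        target, stride, 1e6)
    # brute force: enumerate all candidate starts
    if (len >= target) {
      starts <- start + seq(0L, len - target, by = stride)
    } else {
      starts <- (start + len - target) + seq(0L, target - len, by = stride)
    }
    expect_equal(w$start, starts)
    expect_equal(nrow(w), floor(abs(len - target) / stride) + 1)
    expect_equal(unique(interval_length(w)), target)
  }
})

test_that("fold assignment is stratified, balanced, and deterministic", {
  pos <- paste0("p", 1:10)
  neg <- paste0("n", 1:103)
  f1 <- split_folds(pos, neg, n_folds = 5L, seed = 21L)
  f2 <- split_folds(pos, neg, n_folds = 5L, seed = 21L)
  expect_identical(f1, f2)
  expect_setequal(f1$origin_id, c(pos, neg))
  for (lb in 0:1) {
    sizes <- table(f1$fold[f1$label == lb])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(split_folds(paste0("p", 1:3), neg, n_folds = 5L),
               "at least")
})

test_that("all windows of an origin share one fold after augmentation", {
  sim <- small_sim()
  man <- sim$dataset$manifest
  per_origin <- tapply(man$fold, man$origin_id, function(f) {
    length(unique(f))
  })
  expect_true(all(per_origin == 1))
  # and labels are constant per origin
  per_lab <- tapply(man$label, man$origin_id, function(l) {
    length(unique(l))
  })
  expect_true(all(per_lab == 1))
})

test_that("assembled dataset aligns sequence and accessibility windows", {
  sim <- small_sim()
  ds <- sim$dataset
  man <- ds$manifest
  expect_equal(dim(ds$seq), c(300L, 4L, nrow(man)))
  expect_equal(dim(ds$acc), c(2L, 300L, nrow(man)))
  expect_true(all(man$end - man$start == 300L))
  # spot-check a window against direct extraction
  withr::local_seed(1)
  for (i in sample(nrow(man), 5)) {
    s <- extract_sequence(sim$genome, man[i, c("chrom", "start", "end")] |>
                            (\(x) genomic_intervals(x$chrom, x$start, x$end))())
    expect_equal(one_hot_decode(ds$seq[, , i]), s)
    acc_direct <- window_accessibility(
      sim$tracks, genomic_intervals(man$chrom[i], man$start[i], man$end[i]))
    expect_equal(ds$acc[, , i], acc_direct, ignore_attr = TRUE)
  }
  # manifest round-trips through TSV
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(ds, tsv)
  expect_equal(read_manifest(tsv), man)
})
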