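test_that("extreme activation value sums per-position maxima", {
  w <- rbind(c(1, -2), c(3, 0.5))
  expect_equal(extreme_activation_value(w), 4)
  expect_equal(extreme_activation_value(matrix(0, 3, 4)), 0)
})

test_that("a one-hot input built from the argmax attains the EAV", {
  withr::local_seed(71)
  for (i in 1:20) {
    w <- matrix(rnorm(8 * 4), 8, 4)
    x <- matrix(0, 8, 4)
    x[cbind(1:8, apply(w, 1, which.max))] <- 1
    pre_relu <- sum(w * x)
    expect_equal(pre_relu, extreme_activation_value(w))
  }
})

test_that("EAV bounds the pre-ReLU activation of any one-hot input", {
  withr::local_seed(73)
  for (i in 1:50) {
    w <- matrix(rnorm(8 * 4), 8, 4)
    s <- random_dna(8)
    pre_relu <- sum(w * one_hot_encode(s))
    expect_lte(pre_relu, extreme_activation_value(w) + 1e-12)
  }
})

test_that("activation threshold rule uses strict alpha * EAV", {
  # kernel with EAV 4; inputs selecting weights (1, 3) vs (1, 0.5)
  w <- rbind(c(1, -2, 0, 0), c(3, 0.5, 0, 0))
  stopifnot(extreme_activation_value(w) == 4)
  hit <- matrix(0, 2, 4); hit[1, 1] <- 1; hit[2, 1] <- 1   # 1 + 3 = 4
  miss <- matrix(0, 2, 4); miss[1, 1] <- 1; miss[2, 2] <- 1 # 1 + 0.5
  expect_equal(activated_positions(w, hit, alpha = 0.9), 0L)
  expect_length(activated_positions(w, miss, alpha = 0.9), 0)
  # the exact argmax input still activates as alpha approaches 1 ...
  expect_equal(activated_positions(w, hit, alpha = 1 - 1e-9), 0L)
  # ... but equality is not enough: activation 1.5 at alpha = 0.375
  # sits exactly on the strict threshold 0.375 * 4 and does not fire
  expect_length(activated_positions(w, miss, alpha = 0.375), 0)
})

test_that("activated positions match a brute-force scan", {
  withr::local_seed(79)
  for (i in 1:60) {
    M <- sample(c(4L, 8L), 1)
    w <- matrix(rnorm(M * 4), M, 4)
    s <- random_dna(sample(M:60, 1))
    oh <- one_hot_encode(s)
    alpha <- runif(1, 0.3, 0.95)
    eav <- extreme_activation_value(w)
    slow <- integer(0)
    for (p in 0:(nchar(s) - M)) {
      a <- sum(w * oh[(p + 1):(p + M), ])
      if (a > alpha * eav) slow <- c(slow, p)
    }
    expect_identical(activated_positions(w, oh, alpha), slow)
  }
})

test_that("kernel_to_pwm counts bases at activated sites", {
  # kernel that only fires on ACGTACGT
  w <- matrix(-10, 8, 4)
  w[cbind(1:8, rep(1:4, 2))] <- 1
  pwm <- kernel_to_pwm(w, "TTACGTACGTTT", alpha = 0.9, pseudocount = 0)
  expect_equal(pwm$n_sites, 1L)
  expect_equal(unname(pwm$probs[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pwm$probs[2, ]), c(0, 1, 0, 0))

  # two sites, mixed first column
  w2 <- matrix(0, 8, 4)
  w2[, 1] <- 1 # fires on A-rich 8-mers
  pwm2 <- kernel_to_pwm(w2, c("CAAAAAAAA"), alpha = 0.8, pseudocount = 0)
  # sites AAAAAAAA (pos 1) only; CAAAAAAA scores 7 < 0.8*8 = 6.4 -> fires
  expect_gte(pwm2$n_sites, 1L)
  expect_true(all(abs(rowSums(pwm2$probs) - 1) < 1e-9))

  # kernel with non-positive EAV is skipped
  expect_null(kernel_to_pwm(matrix(-1, 8, 4), "ACGTACGTACGT"))
  # no activations -> NULL
  expect_null(kernel_to_pwm(w, "TTTTTTTTTTTT", alpha = 0.9))
})

test_that("pwm rows stay stochastic with pseudocounts", {
  w <- matrix(0, 8, 4); w[, 2] <- 2
  pwm <- kernel_to_pwm(w, c("CCCCCCCC", "ACCCCCCC"), alpha = 0.5,
                       pseudocount = 0.1)
  expect_true(all(pwm$probs > 0))
  expect_equal(unname(rowSums(pwm$probs)), rep(1, 8))
})

test_that("MEME files round-trip and pass the format validator", {
  withr::local_seed(83)
  pwms <- lapply(1:3, function(i) {
    m <- matrix(runif(32), 8, 4)
    list(probs = m / rowSums(m), n_sites = sample(1:50, 1))
  })
  names(pwms) <- paste0("kernel_", 1:3)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, f)
  expect_true(validate_meme(f))
  back <- read_meme(f)
  expect_named(back, names(pwms))
  for (nm in names(pwms)) {
    expect_equal(back[[nm]]$probs, pwms[[nm]]$probs, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(back[[nm]]$n_sites, pwms[[nm]]$n_sites)
  }
  # uniform PWM stays uniform
  u <- list(u1 = list(probs = matrix(0.25, 8, 4), n_sites = 4L))
  f2 <- withr::local_tempfile(fileext = ".meme")
  write_meme(u, f2)
  expect_true(all(abs(read_meme(f2)$u1$probs - 0.25) < 1e-9))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a meme file", bad)
  expect_error(validate_meme(bad), "version")
})

test_that("pwm_correlation is 1 for identical and low for unrelated PWMs", {
  p <- default_motif(0.9)
  expect_equal(pwm_correlation(p, p), 1)
  q <- matrix(0.25, 8, 4)
  expect_lte(abs(pwm_correlation(p, q)), 0.01)
})
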