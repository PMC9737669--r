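test_that("FPKM follows the formula and its conservation identity", {
  counts <- matrix(c(100, 999900, 0, 10), 2L, 2L,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  lens <- c(a = 1000, b = 500)
  # count 100, length 1000 nt, sample total 1e6 -> FPKM 100
  fpkm <- computeFpkm(counts, lens)
  expect_equal(fpkm["a", "s1"], 100)
  expect_equal(fpkm["a", "s2"], 0)    # zero count, zero FPKM
  set.seed(2L)
  rc <- matrix(rpois(300L, 50) + 1, 50L, 6L,
               dimnames = list(paste0("t", 1:50), paste0("s", 1:6)))
  rl <- setNames(sample(200:3000, 50L), rownames(rc))
  rf <- computeFpkm(rc, rl)
  expect_equal(unname(colSums(rf * rl)), rep(1e9, 6L))
  bad <- rc; bad[, 3L] <- 0
  expect_error(computeFpkm(bad, rl), "s3")
})

test_that("size factors match the forced and brute-force references", {
  m <- matrix(rep(c(10, 20, 30), 2L), 3L, 2L,
              dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(unname(estimateSizeFactors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  expect_equal(unname(estimateSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(estimateSizeFactors(m2, method = "mode")),
               c(1 / sqrt(2), sqrt(2)))
  set.seed(4L)
  nb <- matrix(rnbinom(600L, mu = 200, size = 10) + 1, 100L, 6L,
               dimnames = list(paste0("t", 1:100), paste0("s", 1:6)))
  expect_equal(unname(estimateSizeFactors(nb)), bruteSizeFactors(nb))
  allZero <- matrix(c(0, 5, 3, 0), 2L, 2L,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(estimateSizeFactors(allZero), "total-count")
})

test_that("the NB test is silent on flat transcripts and strict on calls", {
  cnt <- matrix(7L, 3L, 6L,
                dimnames = list(paste0("t", 1:3), paste0("s", 1:6)))
  res <- nbTest(cnt, rep(c("S50", "S96"), each = 3L))
  expect_equal(res$log2fc, rep(0, 3L))
  expect_true(all(res$p >= 0.99))
  expect_true(all(res$call == "ns"))
  # boundary: log2fc exactly 1 is not significant (strict >)
  fake <- S4Vectors::DataFrame(transcript_id = c("a", "b", "c"),
                               log2fc = c(1, 1.0001, -1),
                               p = c(1e-6, 1e-6, 1e-6),
                               q = c(1e-5, 1e-5, 1e-5))
  del <- callDEL(fake)
  expect_identical(del$up, "b")
  expect_length(del$down, 0L)
})

test_that("calls are invariant to global count rescaling and row order", {
  set.seed(8L)
  n <- 300L
  mu <- exp(rnorm(n, log(300), 1))
  lfc <- c(rep(2, 20L), rep(-2, 20L), rep(0, n - 40L))
  muA <- mu * 2^lfc
  cnt <- cbind(matrix(rnbinom(n * 3L, mu = rep(muA, 3L), size = 10), n),
               matrix(rnbinom(n * 3L, mu = rep(mu, 3L), size = 10), n))
  dimnames(cnt) <- list(paste0("t", seq_len(n)), paste0("s", 1:6))
  cond <- rep(c("S50", "S96"), each = 3L)
  r1 <- nbTest(cnt, cond)
  r2 <- nbTest(cnt * 7L, cond)
  expect_identical(r1$call, r2$call)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 0.02)
  perm <- sample(n)
  r3 <- nbTest(cnt[perm, ], cond)
  expect_identical(r3$call, r1$call[perm])
})

test_that("null p-values are calibrated and roughly uniform", {
  p <- sharedNullP()
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("detection is monotone in the planted effect size at fixed mean", {
  set.seed(12L)
  effects <- c(0, 1, 2, 3)
  rate <- vapply(effects, function(e) {
    # 30 planted transcripts over a null majority (normalization needs a
    # non-differential backbone)
    n <- 230L
    mu <- c(rep(500, 30L), exp(rnorm(200L, log(400), 1)))
    lfc <- c(rep(e, 30L), rep(0, 200L))
    cnt <- cbind(matrix(rnbinom(n * 3L, mu = rep(mu * 2^lfc, 3L), size = 10), n),
                 matrix(rnbinom(n * 3L, mu = rep(mu, 3L), size = 10), n))
    dimnames(cnt) <- list(paste0("t", 1:n), paste0("s", 1:6))
    res <- nbTest(cnt, rep(c("S50", "S96"), each = 3L))
    mean(res$call[1:30] == "up")
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1L], 0.05)
  expect_gt(rate[4L], 0.95)
})

test_that("relative expression follows the ddCt identities", {
  expect_equal(deltaDeltaCt(20, 20, 20, 20), 1)
  expect_equal(deltaDeltaCt(25, 20, 24, 20), 0.5)
  set.seed(3L)
  ct <- matrix(runif(40L, 15, 35), 10L)
  res <- deltaDeltaCt(ct[, 1L], ct[, 2L], ct[, 3L], ct[, 4L])
  ddct <- (ct[, 1L] - ct[, 2L]) - (ct[, 3L] - ct[, 4L])
  expect_equal(log2(res), -ddct)
  expect_error(deltaDeltaCt(Inf, 20, 20, 20))
})
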