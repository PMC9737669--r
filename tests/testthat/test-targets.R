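test_that("pearson correlation matches references on fixed and random input", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearsonCor(x, x)$r, 1)
  expect_lt(pearsonCor(x, x + rnorm(6, sd = 1e-9))$p, 1e-10)
  expect_equal(pearsonCor(x, -x)$r, -1)
  y <- c(2, 1, 4, 3, 6, 5)
  pc <- pearsonCor(x, y)
  expect_equal(pc$r, naivePearson(x, y))
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value)
  cst <- pearsonCor(rep(2, 6L), x)
  expect_false(cst$ok)
  expect_equal(cst$p, 1)
})

test_that("pearson r is affine-invariant per vector", {
  set.seed(21L)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(pearsonCor(3.7 * x + 2, y)$r, pearsonCor(x, y)$r)
  expect_equal(pearsonCor(x, 0.2 * y - 5)$r, pearsonCor(x, y)$r)
})

test_that("cis co-localization respects chromosome, window and distance", {
  lnc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 11000),
                                strand = "+")
  S4Vectors::mcols(lnc)$transcript_id <- "lnc1"
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(10500, 111001, 111002, 10500),
                     c(12000, 111500, 111600, 12000)),
    strand = c("-", "+", "+", "+"))
  S4Vectors::mcols(genes)$gene_id <- c("gOverlap", "gAt100k", "gBeyond",
                                       "gOtherChrom")
  hits <- cisTargets(lnc, genes, window = 100000L)
  expect_setequal(hits$gene_id, c("gOverlap", "gAt100k"))
  expect_identical(hits$distance[hits$gene_id == "gOverlap"], 0L)
  expect_identical(hits$distance[hits$gene_id == "gAt100k"], 100000L)
})

test_that("cis pairs are preserved under genome translation", {
  inst <- randomCascadeInstance(n = 60L, seed = 14L)
  lnc <- txSpans(inst$candidates)
  genes <- txSpans(inst$annotation)
  S4Vectors::mcols(genes)$gene_id <- geneIds(inst$annotation)
  p1 <- cisTargets(lnc, genes)
  p2 <- cisTargets(GenomicRanges::shift(lnc, 12345L),
                   GenomicRanges::shift(genes, 12345L))
  expect_identical(p1[, c("lncrna_id", "gene_id", "distance")],
                   p2[, c("lncrna_id", "gene_id", "distance")])
})

test_that("trans filtering keeps planted co-expression and is strict at the bound", {
  set.seed(17L)
  n <- 6L
  latent <- matrix(rnorm(5L * n, sd = 3), 5L)
  lnc <- latent + rnorm(5L * n, sd = 0.1)
  mr <- latent + rnorm(5L * n, sd = 0.1)
  lnc <- rbind(lnc, matrix(rnorm(50L * n), 50L))
  mr <- rbind(mr, matrix(rnorm(50L * n), 50L))
  dimnames(lnc) <- list(paste0("l", 1:55), paste0("s", 1:6))
  dimnames(mr) <- list(paste0("m", 1:55), paste0("s", 1:6))
  out <- transTargets(lnc, mr)
  for (i in 1:5)
    expect_true(any(out$lncrna_id == paste0("l", i) &
                      out$gene_id == paste0("m", i)))
  # false positives among the 50x50 independent block stay near the p bound
  indep <- out[as.integer(sub("l", "", out$lncrna_id)) > 5L &
                 as.integer(sub("m", "", out$gene_id)) > 5L, ]
  expect_lte(nrow(indep), 5L)

  # strictness at the r boundary: a pair at exactly rMin is excluded
  x <- c(1, 2, 3, 4, 5, 6)
  z <- residuals(lm(c(2, 1, 4, 3, 6, 5) ~ x))
  y <- 0.95 * scale(x)[, 1L] + sqrt(1 - 0.95^2) * scale(z)[, 1L]
  one <- matrix(x, 1L, dimnames = list("lnc", paste0("s", 1:6)))
  two <- matrix(y, 1L, dimnames = list("mrna", paste0("s", 1:6)))
  rObs <- transTargets(one, two, rMin = -2, pMax = 2)$pcc[1L]
  expect_identical(nrow(transTargets(one, two, rMin = rObs, pMax = 2)), 0L)
  expect_identical(nrow(transTargets(one, two, rMin = rObs - 1e-9, pMax = 2)), 1L)
})

test_that("trans testing rejects mismatched samples and constant profiles", {
  a <- matrix(rnorm(12L), 2L, dimnames = list(c("l1", "l2"), paste0("s", 1:6)))
  b <- matrix(rnorm(12L), 2L, dimnames = list(c("m1", "m2"), paste0("x", 1:6)))
  expect_error(transTargets(a, b), "same samples")
  const <- matrix(rep(a[1L, ], 2L), 2L, byrow = TRUE,
                  dimnames = list(c("m1", "m2"), colnames(a)))
  const[2L, ] <- 4
  out <- transTargets(a, const)
  expect_false("m2" %in% out$gene_id)
})
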