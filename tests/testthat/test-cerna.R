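test_that("duplex pseudo-energy follows the pairing scheme exactly", {
  # 10 G + 11 A miRNA against its perfect complement: 10 G:C + 11 A:U
  m <- paste(c(rep("G", 10L), rep("A", 11L)), collapse = "")
  site <- paste(rev(c(rep("C", 10L), rep("U", 11L))), collapse = "")
  d <- duplexScore(m, site)
  expect_equal(d$energy, -(10 * 3 + 11 * 2))
  expect_identical(d$pairing, paste(rep("|", 21L), collapse = ""))
  # an all-mismatch site scores +L
  expect_equal(duplexScore(m, m)$energy, 21)
  expect_error(duplexScore("ACGX", "ACGU"), "non-RNA")
  expect_error(duplexScore("ACGU", "ACG"), "equal length")
})

test_that("duplex score equals an independent per-position recomputation", {
  set.seed(23L)
  for (i in 1:30) {
    m <- paste(sample(c("A", "C", "G", "U"), 21L, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "U"), 21L, TRUE), collapse = "")
    expect_equal(duplexScore(m, s)$energy, refDuplexEnergy(m, s))
  }
})

test_that("expectation penalties double in the seed region only", {
  m <- paste(rep("G", 21L), collapse = "")
  perfect <- paste(rep("C", 21L), collapse = "")
  expect_equal(expectationScore(m, perfect), 0)
  # mismatch opposite miRNA position 5 (inside 2-13): doubled to 2
  s <- strsplit(perfect, "")[[1L]]
  s[21L - 5L + 1L] <- "A"
  expect_equal(expectationScore(m, paste(s, collapse = "")), 2)
  # G:U wobble opposite position 15 (outside the seed region): 0.5
  s <- strsplit(perfect, "")[[1L]]
  s[21L - 15L + 1L] <- "U"
  expect_equal(expectationScore(m, paste(s, collapse = "")), 0.5)
  # position 1 is never doubled
  s <- strsplit(perfect, "")[[1L]]
  s[21L] <- "A"
  expect_equal(expectationScore(m, paste(s, collapse = "")), 1)
})

test_that("scanning finds planted sites exactly and stays quiet on noise", {
  set.seed(29L)
  m <- paste(sample(c("A", "C", "G", "U"), 21L, TRUE), collapse = "")
  mdna <- chartr("U", "T", m)
  comp <- chartr("ACGT", "TGCA", mdna)
  site <- paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
  backbone <- paste(sample(c("A", "C", "G", "T"), 400L, TRUE), collapse = "")
  target <- paste0(substr(backbone, 1L, 100L), site,
                   substr(backbone, 122L, 400L))
  hits <- scanTargets(m, target, mode = "lncRNA")
  expect_identical(hits$site_start, 101L)
  expect_equal(hits$score, duplexScore(m, chartr("T", "U", site))$energy)
  # translation invariance: prepending shifts the site, not the score
  shifted <- scanTargets(m, paste0(paste(rep("C", 100L), collapse = ""), target),
                         mode = "lncRNA")
  expect_identical(shifted$site_start, 201L)
  expect_equal(shifted$score, hits$score)
  # mRNA mode finds the same planted site with zero penalty
  mh <- scanTargets(m, target, mode = "mRNA")
  expect_identical(mh$site_start, 101L)
  expect_equal(mh$score, 0)
  # determinism
  expect_identical(scanTargets(m, target, mode = "lncRNA"), hits)
})

test_that("false-hit rate on shuffled sequence stays below 0.05 per kb", {
  set.seed(37L)
  totKb <- 0
  nHits <- 0L
  for (i in 1:40) {
    m <- paste(sample(c("A", "C", "G", "U"), 21L, TRUE), collapse = "")
    tg <- paste(sample(c("A", "C", "G", "T"), 5000L, TRUE), collapse = "")
    nHits <- nHits + nrow(scanTargets(m, tg, mode = "lncRNA"))
    nHits <- nHits + nrow(scanTargets(m, tg, mode = "mRNA"))
    totKb <- totKb + 5
  }
  expect_lt(nHits / totKb, 0.05)
})

test_that("network assembly is exactly the miRNA join", {
  lnc <- data.frame(mirna_id = "miR1", target_id = c("l1", "l2"))
  mr <- data.frame(mirna_id = "miR1", target_id = c("g1", "g2", "g3"))
  net <- buildCernaNetwork(lnc, mr)
  expect_identical(nrow(net$triplets), 6L)
  expect_identical(unlist(net$summary[, c("n_lncrna", "n_mirna", "n_mrna")],
                          use.names = FALSE), c(2L, 1L, 3L))
  # disjoint miRNA sets give an empty network
  empty <- buildCernaNetwork(
    data.frame(mirna_id = "miRa", target_id = "l1"),
    data.frame(mirna_id = "miRb", target_id = "g1"))
  expect_identical(nrow(empty$triplets), 0L)

  set.seed(41L)
  for (i in 1:5) {
    nl <- sample(100:500, 1L)
    nm <- sample(100:500, 1L)
    lncH <- data.frame(mirna_id = paste0("miR", sample(12L, nl, TRUE)),
                       target_id = paste0("l", sample(40L, nl, TRUE)))
    mrH <- data.frame(mirna_id = paste0("miR", sample(12L, nm, TRUE)),
                      target_id = paste0("g", sample(40L, nm, TRUE)))
    net <- buildCernaNetwork(lncH, mrH)
    ref <- bruteJoin(lncH, mrH)
    expect_setequal(tripletKey(net$triplets), tripletKey(ref))
  }
})

test_that("the DE filter restricts the network to admitted transcripts", {
  lnc <- data.frame(mirna_id = c("miR1", "miR1"), target_id = c("l1", "l2"))
  mr <- data.frame(mirna_id = "miR1", target_id = c("g1", "g2"))
  net <- buildCernaNetwork(lnc, mr, deFilter = list(lncrna = "l1",
                                                    mrna = c("g1", "g2")))
  expect_setequal(net$triplets$lncrna_id, "l1")
  expect_identical(nrow(net$triplets), 2L)
})
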