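test_that("identical seeds give byte-identical exported datasets", {
  cfg <- smallConfig(seed = 101L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  exportDataset(simulateCounts(generateDataset(cfg)), d1, overwrite = TRUE)
  exportDataset(simulateCounts(generateDataset(cfg)), d2, overwrite = TRUE)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("an empty configuration yields an empty but well-formed dataset", {
  cfg <- smallConfig(seed = 5L)
  cfg$n_mrna <- 0L; cfg$n_lncrna <- 0L; cfg$contaminants_per_class <- 0L
  cfg$n_planted_triplets <- 0L; cfg$n_terms <- 0L
  cfg$de_config <- list(n_up_lnc = 0L, n_down_lnc = 0L, n_up_mrna = 0L,
                        n_down_mrna = 0L, lfc_range = c(2, 4))
  ds <- generateDataset(cfg)
  expect_length(ds@annotation, 0L)
  expect_length(ds@candidates, 0L)
  expect_identical(nrow(truthTable(ds)), 0L)
  dir <- withr::local_tempdir()
  exportDataset(ds, dir, overwrite = TRUE)
  back <- readDatasetDir(dir)
  expect_length(back$candidates, 0L)
})

test_that("population structure matches the configuration", {
  ds <- sharedDataset()
  cfg <- ds@config
  tr <- truthTable(ds)
  expect_identical(sum(tr$biotype == "mRNA"), cfg$n_mrna)
  nLnc <- sum(tr$biotype %in% c("lincRNA", "lncNAT"))
  expect_identical(nLnc, cfg$n_lncrna)
  # lincRNA : lncNAT ratio about 2:1
  expect_equal(sum(tr$biotype == "lincRNA") / sum(tr$biotype == "lncNAT"),
               2, tolerance = 0.05)
  # planted up/down lncRNA counts equal the configuration exactly
  lnc <- tr[tr$biotype %in% c("lincRNA", "lncNAT"), ]
  expect_identical(sum(lnc$de == "up"), cfg$de_config$n_up_lnc)
  expect_identical(sum(lnc$de == "down"), cfg$de_config$n_down_lnc)
  expect_true(all(abs(lnc$true_lfc[lnc$de != "ns"]) > 1))
  # lncRNA length and exon-count ranges hold
  lncTs <- ds@candidates[lnc$transcript_id]
  expect_true(all(txLengths(lncTs) >= 200L & txLengths(lncTs) <= 1000L))
  nex <- S4Vectors::elementNROWS(txExons(lncTs))
  expect_true(all(nex %in% 2:3))
  # mRNA lengths in range
  mrnaTs <- ds@annotation[txBiotype(ds@annotation) == "protein_coding"]
  expect_true(all(txLengths(mrnaTs) >= 800L & txLengths(mrnaTs) <= 3000L))
})

test_that("planted lncRNA population audit: short ORFs, placement rules", {
  ds <- sharedDataset()
  tr <- truthTable(ds)
  lncIds <- tr$transcript_id[tr$biotype %in% c("lincRNA", "lncNAT")]
  orf <- vapply(lncIds, function(id)
    longestOrf(as.character(ds@txSeqs[[id]]))$length, integer(1))
  expect_gt(mean(orf <= 200L), 0.9)
  # lincRNAs are >= 1 kb from any protein-coding gene span
  lincIds <- tr$transcript_id[tr$biotype == "lincRNA"]
  coding <- ds@annotation[txBiotype(ds@annotation) == "protein_coding"]
  d <- GenomicRanges::distanceToNearest(
    txSpans(ds@candidates[lincIds]), txSpans(coding), ignore.strand = TRUE)
  expect_true(all(S4Vectors::mcols(d)$distance >= 1000L))
  # lncNATs overlap an mRNA exon on the opposite strand
  natIds <- tr$transcript_id[tr$biotype == "lncNAT"]
  codEx <- unlist(txExons(coding), use.names = FALSE)
  for (id in natIds) {
    ex <- txExons(ds@candidates[id])[[1L]]
    ov <- GenomicRanges::countOverlaps(GenomicRanges::invertStrand(ex), codEx)
    expect_gt(sum(ov), 0L)
  }
})

test_that("simulated counts recover planted effects and the Poisson limit", {
  # null transcripts: mean ratio between conditions within 3 SE of 1
  truthNull <- S4Vectors::DataFrame(
    transcript_id = paste0("n", 1:200), biotype = "lincRNA", fate = "pass",
    de = "ns", true_lfc = 0, base_mean = 500)
  cfg <- syntheticConfig(seed = 55L, library_size_range = c(1, 1))
  se <- simulateCounts(truthNull, cfg)
  m <- SummarizedExperiment::assay(se)
  ratio <- rowMeans(m[, 1:3]) / rowMeans(m[, 4:6])
  seRatio <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * seRatio)

  # planted log2FC +2 at base mean 500: median estimate within +/- 0.3
  truthDe <- S4Vectors::DataFrame(
    transcript_id = paste0("d", 1:100), biotype = "lincRNA", fate = "pass",
    de = "up", true_lfc = 2, base_mean = 500)
  se <- simulateCounts(rbind(truthDe, truthNull), cfg)
  res <- nbTest(se)
  expect_lt(abs(median(res[paste0("d", 1:100), "log2fc"]) - 2), 0.3)

  # dispersion -> 0 limit: variance approaches the mean
  cfgP <- syntheticConfig(seed = 66L, nb_dispersion = 1e-6,
                          library_size_range = c(1, 1))
  seP <- simulateCounts(truthNull, cfgP)
  mP <- SummarizedExperiment::assay(seP)
  vm <- apply(mP, 1L, var) / rowMeans(mP)
  expect_equal(mean(vm), 1, tolerance = 0.1)
  cfgBad <- cfgP; cfgBad$nb_dispersion <- 0
  expect_error(simulateCounts(truthNull, cfgBad), "positive")
})

test_that("library sizes vary by at most two-fold", {
  ds <- sharedDataset()
  tot <- colSums(SummarizedExperiment::assay(ds@counts))
  expect_lt(max(tot) / min(tot), 2)
})

test_that("site planting writes recoverable reverse-complement sites", {
  seqs <- c(t1 = paste(rep("C", 200L), collapse = ""))
  mir <- c(miR1 = paste(rep("G", 21L), collapse = ""))
  # no plan: sequences unchanged
  un <- plantMirnaSites(seqs, mir, data.frame())
  expect_identical(un$seqs, seqs)
  plan <- data.frame(mirna_id = "miR1", target_id = "t1",
                     target_kind = "lncRNA")
  set.seed(7L)
  out <- plantMirnaSites(seqs, mir, plan, wobbles = 0L)
  s <- out$sites
  window <- substr(out$seqs[["t1"]], s$site_start, s$site_start + 20L)
  expect_identical(window, paste(rep("C", 21L), collapse = ""))
  expect_equal(expectationScore(mir[["miR1"]], chartr("T", "U", window)), 0)
  expect_identical(s$site_type, "perfect")
})

test_that("all planted sites in the default dataset are recovered exactly", {
  ds <- sharedDataset()
  sites <- plantedSites(ds)
  expect_identical(nrow(sites), 2L * ds@config$n_planted_triplets)
  for (i in seq_len(nrow(sites))) {
    mode <- if (sites$target_kind[i] == "lncRNA") "lncRNA" else "mRNA"
    hits <- scanTargets(as.character(ds@mirnas[[sites$mirna_id[i]]]),
                        as.character(ds@txSeqs[[sites$target_id[i]]]),
                        mode = mode)
    expect_true(sites$site_start[i] %in% hits$site_start,
                label = paste("site", i, "recovered"))
  }
})

test_that("export and re-read reproduce the in-memory dataset", {
  ds <- sharedDataset()
  dir <- withr::local_tempdir()
  exportDataset(ds, dir, overwrite = TRUE)
  files <- c("annotation.gtf", "candidates.gtf", "genome.fa",
             "transcripts.fa", "counts.tsv", "design.tsv", "mirnas.fa",
             "terms.tsv", "truth.tsv")
  expect_setequal(list.files(dir), files)
  expect_error(exportDataset(ds, dir), "not empty")
  back <- readDatasetDir(dir)
  expect_identical(as.character(back$txSeqs[names(ds@txSeqs)]),
                   as.character(ds@txSeqs))
  expect_identical(as.character(back$mirnas), as.character(ds@mirnas))
  expect_identical(as.data.frame(txExons(back$candidates[names(ds@candidates)])),
                   as.data.frame(txExons(ds@candidates)))
  expect_identical(SummarizedExperiment::assay(back$counts),
                   SummarizedExperiment::assay(ds@counts))
  expect_identical(back$truth$fate, as.character(truthTable(ds)$fate))
  expect_identical(back$sites$site_start, plantedSites(ds)$site_start)
})
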