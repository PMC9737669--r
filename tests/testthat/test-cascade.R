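# helper to build a TranscriptSet from a compact exon spec
mkTS <- function(spec, biotype = "unknown") {
  grl <- lapply(spec, function(x)
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$starts, x$ends),
                           strand = x$strand))
  names(grl) <- names(spec)
  TranscriptSet(GenomicRanges::GRangesList(grl), biotype = biotype)
}

test_that("each cascade filter removes its designed failure case", {
  annotation <- mkTS(list(
    gene1 = list(chrom = "chr1", starts = c(10000, 11000),
                 ends = c(10400, 11400), strand = "+")),
    biotype = "protein_coding")
  cands <- mkTS(list(
    uncertain = list(chrom = "chr1", starts = c(1000, 1500),
                     ends = c(1200, 1800), strand = "*"),
    single = list(chrom = "chr1", starts = 3000, ends = 3500, strand = "+"),
    short = list(chrom = "chr1", starts = c(5000, 5200),
                 ends = c(5070, 5275), strand = "-"),
    overlap = list(chrom = "chr1", starts = c(10200, 11600),
                   ends = c(10500, 11800), strand = "+"),
    lowexpr = list(chrom = "chr1", starts = c(20000, 20500),
                   ends = c(20200, 20800), strand = "+"),
    coding = list(chrom = "chr1", starts = c(30000, 30700),
                  ends = c(30400, 31000), strand = "-"),
    clean = list(chrom = "chr1", starts = c(40000, 40500),
                 ends = c(40200, 40800), strand = "+")))
  fpkm <- matrix(5, nrow = 7L, ncol = 2L,
                 dimnames = list(names(cands), c("s1", "s2")))
  fpkm["lowexpr", ] <- c(0.2, 0.4)
  coding <- setNames(rep(FALSE, 7L), names(cands))
  coding["coding"] <- TRUE

  out <- filterCascade(cands, fpkm, annotation, coding)
  expect_identical(survivors(out$report), "clean")
  st <- filterSummary(out$report)
  expect_identical(st$removed, rep(1L, 6L))
  expect_identical(st$input - st$removed, st$surviving)
  expect_identical(st$surviving[-6L], st$input[-1L])
  expect_identical(unname(out$records$cls), "lincRNA")
  expect_identical(unname(out$records$status), "novel")
})

test_that("boundary values pass their inclusive thresholds", {
  annotation <- TranscriptSet(GenomicRanges::GRangesList())
  cands <- mkTS(list(
    exactly200 = list(chrom = "chr1", starts = c(1000, 1200),
                      ends = c(1099, 1299), strand = "+")))
  fpkm <- matrix(c(0.5, 0.1), nrow = 1L,
                 dimnames = list("exactly200", c("s1", "s2")))
  out <- filterCascade(cands, fpkm, annotation,
                       setNames(FALSE, "exactly200"))
  expect_identical(survivors(out$report), "exactly200")
})

test_that("missing expression or coding scores raise named errors", {
  cands <- mkTS(list(t1 = list(chrom = "chr1", starts = c(1, 300),
                               ends = c(200, 500), strand = "+")))
  ann <- TranscriptSet(GenomicRanges::GRangesList())
  fpkm <- matrix(1, 1L, 1L, dimnames = list("other", "s1"))
  expect_error(filterCascade(cands, fpkm, ann, setNames(FALSE, "t1")), "t1")
  fpkm2 <- matrix(1, 1L, 1L, dimnames = list("t1", "s1"))
  expect_error(filterCascade(cands, fpkm2, ann, setNames(FALSE, "other")),
               "coding")
})

test_that("the surviving set is invariant to candidate order", {
  inst <- randomCascadeInstance(n = 200L, seed = 9L)
  out1 <- filterCascade(inst$candidates, inst$fpkm, inst$annotation,
                        inst$isCoding)
  perm <- sample(length(inst$candidates))
  out2 <- filterCascade(inst$candidates[perm], inst$fpkm, inst$annotation,
                        inst$isCoding)
  expect_setequal(survivors(out1$report), survivors(out2$report))
})

test_that("positional classes follow their coordinate definitions", {
  coding <- mkTS(list(
    cod1 = list(chrom = "chr1", starts = c(10000, 15000),
                ends = c(10500, 15500), strand = "+")),
    biotype = "protein_coding")
  cands <- mkTS(list(
    far = list(chrom = "chr1", starts = c(40000, 40400),
               ends = c(40200, 40700), strand = "+"),
    nat = list(chrom = "chr1", starts = c(9800, 10400),
               ends = c(9900, 10600), strand = "-"),
    intr = list(chrom = "chr1", starts = c(11000, 12000),
                ends = c(11200, 12300), strand = "+"),
    intrMinus = list(chrom = "chr1", starts = c(11000, 12000),
                     ends = c(11200, 12300), strand = "-"),
    senseOv = list(chrom = "chr1", starts = c(9000, 11000),
                   ends = c(9200, 11300), strand = "+"),
    otherChrom = list(chrom = "chr2", starts = c(10000, 10400),
                      ends = c(10200, 10600), strand = "+")))
  cls <- classifyLncrna(cands, coding)
  expect_identical(unname(cls["far"]), "lincRNA")
  expect_identical(unname(cls["nat"]), "lncNAT")
  expect_identical(unname(cls["intr"]), "intronic")
  expect_identical(unname(cls["intrMinus"]), "intronic")
  expect_identical(unname(cls["senseOv"]), "sense_overlapping")
  expect_identical(unname(cls["otherChrom"]), "lincRNA")
})

test_that("exact intron-chain matches against annotated lncRNAs are flagged", {
  ann <- TranscriptSet(
    GenomicRanges::GRangesList(
      annl = GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1000, 2000),
                                                     c(1400, 2400)),
                                    strand = "+")),
    biotype = "lncRNA_annotated")
  cands <- mkTS(list(
    match = list(chrom = "chr1", starts = c(1000, 2000),
                 ends = c(1400, 2400), strand = "+"),
    nomatch = list(chrom = "chr1", starts = c(5000, 6000),
                   ends = c(5400, 6400), strand = "+")))
  fpkm <- matrix(5, 2L, 2L, dimnames = list(names(cands), c("s1", "s2")))
  out <- filterCascade(cands, fpkm, ann,
                       setNames(c(FALSE, FALSE), names(cands)))
  expect_identical(unname(out$records["match", "status"]), "annotated")
  expect_identical(unname(out$records["nomatch", "status"]), "novel")
})

test_that("cascade recovers exactly the planted truth on the default dataset", {
  ds <- sharedDataset()
  casc <- sharedCascade()
  truth <- truthTable(ds)
  truthPass <- truth$transcript_id[!is.na(truth$fate) & truth$fate == "pass"]
  expect_setequal(survivors(casc$report), truthPass)
  # every filter removed at least one planted contaminant
  expect_true(all(filterSummary(casc$report)$removed >= 1L))
  # classification agrees with the planted biotype for every survivor
  m <- merge(as.data.frame(casc$records), as.data.frame(truth),
             by = "transcript_id")
  expect_identical(m$cls, m$biotype)
  # annotated status agrees with the planted annotation subset
  expect_identical(m$status == "annotated", m$annotated)
  # emitted classes satisfy their invariants by direct coordinate re-check
  coding <- ds@annotation[txBiotype(ds@annotation) == "protein_coding"]
  recheck <- classifyLncrna(casc$lncrnas, coding)
  expect_identical(unname(recheck[casc$records$transcript_id]),
                   unname(casc$records$cls))
})

test_that("characterization histograms conserve mass and expose the planted shape", {
  ds <- sharedDataset()
  casc <- sharedCascade()
  mrna <- ds@annotation[txBiotype(ds@annotation) == "protein_coding"]
  ch <- characterize(casc$lncrnas, mrna, ds@txSeqs)
  for (pop in ch) {
    for (h in pop) {
      expect_equal(sum(h$proportion), 1)
    }
    expect_identical(sum(pop$exon_count$count), sum(pop$chromosome$count))
  }
  exonH <- ch$lncRNA$exon_count
  expect_gte(sum(exonH$proportion[exonH$bin %in% c("2", "3")]), 0.9)
  orfH <- ch$lncRNA$orf
  shortBins <- c("[0,100]", "(100,200]")
  expect_gt(sum(orfH$proportion[orfH$bin %in% shortBins]), 0.9)
  # single transcript puts all mass in one bin per axis
  single <- characterize(casc$lncrnas[1L], mrna[1L], ds@txSeqs)
  expect_identical(nrow(single$lncRNA$exon_count), 1L)
  expect_identical(single$lncRNA$length$proportion, 1)
  expect_warning(characterize(casc$lncrnas[0L], mrna[1L], ds@txSeqs), "empty")
})
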