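# Independent oracle implementations, kept deliberately naive and separate
# from the package's code paths.

# brute-force longest ORF: try every position as a start codon and walk
# codon by codon to the first stop
bruteLongestOrf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  if (n < 6L) return(best)
  for (i in seq_len(n - 5L)) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(s, j, j + 2L) %in% stops) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# straight-line application of the five identification rules, using plain
# data frames and explicit interval comparisons (no GenomicRanges machinery)
refCascadeSurvivors <- function(candidates, fpkm, annotation, isCoding,
                                minExons = 2L, minLength = 200L,
                                fpkmMin = 0.5) {
  annBio <- txBiotype(annotation)
  codingIds <- names(annotation)[annBio == "protein_coding"]
  codDf <- do.call(rbind, lapply(codingIds, function(id) {
    e <- as.data.frame(txExons(annotation)[[id]])
    e$seqnames <- as.character(e$seqnames)
    e$strand <- as.character(e$strand)
    e
  }))
  keep <- character()
  for (id in names(candidates)) {
    e <- as.data.frame(txExons(candidates)[[id]])
    e$seqnames <- as.character(e$seqnames)
    e$strand <- as.character(e$strand)
    if (!all(e$strand %in% c("+", "-"))) next              # (0) strand
    if (nrow(e) < minExons) next                           # (1) exon count
    if (sum(e$end - e$start + 1L) < minLength) next        # (2) length
    overlap <- FALSE                                       # (3) coding overlap
    if (!is.null(codDf)) {
      for (r in seq_len(nrow(e))) {
        hit <- codDf$seqnames == e$seqnames[r] &
          codDf$strand == e$strand[r] &
          codDf$start <= e$end[r] & codDf$end >= e$start[r]
        if (any(hit)) { overlap <- TRUE; break }
      }
    }
    if (overlap) next
    if (max(fpkm[id, ]) < fpkmMin) next                    # (4) expression
    if (isCoding[[id]]) next                               # (5) coding
    keep <- c(keep, id)
  }
  keep
}

# random transcript models plus random annotation / fpkm / coding labels,
# exercising every cascade failure mode
randomCascadeInstance <- function(n = 1000L, seed = 1L) {
  set.seed(seed)
  mkTx <- function(chrom, strand, starts, widths) {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts, width = widths),
                           strand = strand)
  }
  # annotation: coding genes scattered over two chromosomes
  nGene <- 60L
  annList <- list()
  for (g in seq_len(nGene)) {
    nEx <- sample(1:4, 1L)
    starts <- sort(sample.int(480000L, 1L)) + cumsum(c(0L, rep(600L, nEx - 1L)))
    annList[[sprintf("ANN_%03d", g)]] <-
      mkTx(sample(c("chr1", "chr2"), 1L), sample(c("+", "-"), 1L),
           starts, sample(100:400, nEx, replace = TRUE))
  }
  annotation <- TranscriptSet(GenomicRanges::GRangesList(annList),
                              geneId = sprintf("ANNG_%03d", seq_len(nGene)),
                              biotype = "protein_coding")
  candList <- list()
  for (i in seq_len(n)) {
    nEx <- sample(1:3, 1L)
    widths <- sample(40:400, nEx, replace = TRUE)
    start <- sample.int(480000L, 1L)
    starts <- start + cumsum(c(0L, head(widths, -1L) +
                                 sample(50:500, max(nEx - 1L, 1L),
                                        replace = TRUE)))[seq_len(nEx)]
    candList[[sprintf("C_%04d", i)]] <-
      mkTx(sample(c("chr1", "chr2"), 1L),
           sample(c("+", "-", "*"), 1L, prob = c(.45, .45, .1)),
           starts, widths)
  }
  candidates <- TranscriptSet(GenomicRanges::GRangesList(candList))
  fpkm <- matrix(round(exp(rnorm(n * 6L, log(2), 2)), 3), nrow = n,
                 dimnames = list(names(candidates), paste0("s", 1:6)))
  fpkm[sample.int(n, n %/% 5L), ] <- round(runif(n %/% 5L * 6L, 0, 0.49), 3)
  isCoding <- setNames(runif(n) < 0.15, names(candidates))
  list(candidates = candidates, annotation = annotation, fpkm = fpkm,
       isCoding = isCoding)
}

# brute-force median-of-ratios
bruteSizeFactors <- function(counts) {
  ok <- apply(counts, 1L, function(r) all(r > 0))
  sub <- counts[ok, , drop = FALSE]
  geo <- apply(sub, 1L, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(sub)), function(s) median(sub[, s] / geo), numeric(1))
}

# naive two-pass product-moment correlation
naivePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive hypergeometric upper tail by enumerating every draw
enumHypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d <= K) >= k))
}

# brute-force double-loop join of two hit relations on the miRNA id
bruteJoin <- function(lncHits, mrnaHits) {
  out <- list()
  ln <- unique(lncHits[, c("mirna_id", "target_id")])
  mr <- unique(mrnaHits[, c("mirna_id", "target_id")])
  for (i in seq_len(nrow(ln))) {
    for (j in seq_len(nrow(mr))) {
      if (ln$mirna_id[i] == mr$mirna_id[j])
        out[[length(out) + 1L]] <- data.frame(lncrna_id = ln$target_id[i],
                                              mirna_id = ln$mirna_id[i],
                                              mrna_id = mr$target_id[j])
    }
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character()))
  unique(do.call(rbind, out))
}

# per-position duplex rescoring with an explicit pairing table
refDuplexEnergy <- function(mirna, site) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1L]]
  s <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1L]])
  sum(vapply(seq_along(m), function(i) {
    pair <- paste0(m[i], s[i])
    if (pair %in% c("GC", "CG")) -3
    else if (pair %in% c("AU", "UA")) -2
    else if (pair %in% c("GU", "UG")) -1
    else 1
  }, numeric(1)))
}

tripletKey <- function(df)
  paste(df$lncrna_id, df$mirna_id, df$mrna_id)
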