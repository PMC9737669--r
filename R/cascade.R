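#' @include AllClasses.R
NULL

.CASCADE_STEPS <- c("strand_certain", "multi_exon", "min_length",
                    "annotation_overlap", "expression", "non_coding")

#' Five-round lncRNA identification cascade
#'
#' Applies, in fixed order, the filters used to call lncRNAs from an
#' assembled transcript set:
#'
#' 1. `strand_certain` — strand must be `+` or `-` (`.` marks transcripts of
#'    uncertain chain direction).
#' 2. `multi_exon` — exon count >= `minExons` (default 2, inclusive).
#' 3. `min_length` — spliced length >= `minLength` nt (default 200).
#' 4. `annotation_overlap` — candidates with >= 1 bp same-strand exonic
#'    overlap with an annotated protein-coding exon are removed; candidates
#'    whose intron chain exactly matches an annotated lncRNA are kept and
#'    flagged `status = "annotated"`, all other survivors are `"novel"`.
#' 5. `expression` — FPKM across samples (aggregated per `fpkmAggregate`)
#'    >= `fpkmMin` (default 0.5).
#' 6. `non_coding` — `is_coding` must be `FALSE` (see [codingPotential()]).
#'
#' Survivors are classified into lincRNA/lncNAT/sense_overlapping/intronic
#' by [classifyLncrna()]. The surviving set is independent of input order.
#'
#' @param candidates [TranscriptSet-class] of candidate transcripts.
#' @param fpkm FPKM values covering all candidates: a matrix/`DataFrame`
#'   with rownames, or a `SummarizedExperiment` (first assay used).
#' @param annotation [TranscriptSet-class] of reference models whose
#'   `biotype` column marks `protein_coding` and `lncRNA_annotated` entries.
#' @param coding per-candidate coding calls: the `DataFrame` from
#'   [codingPotential()], or a named logical vector of `is_coding`.
#' @param minExons,minLength,fpkmMin inclusive thresholds (defaults 2,
#'   200 nt, 0.5 FPKM).
#' @param fpkmAggregate how FPKM is aggregated across samples before the
#'   threshold: `"max"` (default), `"mean"`, or `"all"` (every sample must
#'   pass).
#' @return list with elements
#'   \describe{
#'     \item{records}{`DataFrame` of surviving lncRNAs: `transcript_id`,
#'       `gene_id`, `cls` (lincRNA/lncNAT/sense_overlapping/intronic),
#'       `status` (novel/annotated).}
#'     \item{report}{a [FilterReport-class] with telescoping counts.}
#'     \item{lncrnas}{the surviving [TranscriptSet-class].}
#'   }
#' @export
filterCascade <- function(candidates, fpkm, annotation, coding,
                          minExons = 2L, minLength = 200L, fpkmMin = 0.5,
                          fpkmAggregate = c("max", "mean", "all")) {
  stopifnot(is(candidates, "TranscriptSet"), is(annotation, "TranscriptSet"))
  fpkmAggregate <- match.arg(fpkmAggregate)
  if (is(fpkm, "SummarizedExperiment"))
    fpkm <- SummarizedExperiment::assay(fpkm, 1L)
  fpkm <- as.matrix(fpkm)
  ids <- names(candidates)
  missing <- setdiff(ids, rownames(fpkm))
  if (length(missing))
    stop("candidate(s) missing from fpkm: ", paste(head(missing, 5), collapse = ", "))
  if (is(coding, "DataFrame") || is.data.frame(coding)) {
    isCoding <- setNames(as.logical(coding$is_coding), rownames(coding))
    if (is.null(names(isCoding)) || all(names(isCoding) == as.character(seq_along(isCoding))))
      names(isCoding) <- coding$transcript_id
  } else {
    isCoding <- coding
  }
  missing <- setdiff(ids, names(isCoding))
  if (length(missing))
    stop("candidate(s) missing a coding score: ",
         paste(head(missing, 5), collapse = ", "))

  keep <- ids
  steps <- data.frame(step = .CASCADE_STEPS, input = NA_integer_,
                      removed = NA_integer_, surviving = NA_integer_)
  record <- function(i, surviving) {
    steps$input[i] <<- length(keep)
    steps$removed[i] <<- length(keep) - length(surviving)
    steps$surviving[i] <<- length(surviving)
    keep <<- surviving
  }

  spans <- txSpans(candidates)
  names(spans) <- names(candidates)

  # (0) certain chain direction
  strandOf <- setNames(as.character(GenomicRanges::strand(spans)), ids)
  record(1L, keep[strandOf[keep] %in% c("+", "-")])
  # (1) exon count
  nEx <- setNames(S4Vectors::elementNROWS(txExons(candidates)), ids)
  record(2L, keep[nEx[keep] >= minExons])
  # (2) spliced length
  lens <- txLengths(candidates)
  record(3L, keep[lens[keep] >= minLength])
  # (3) annotation overlap
  annBio <- txBiotype(annotation)
  codingAnn <- annotation[annBio == "protein_coding"]
  annLnc <- annotation[annBio == "lncRNA_annotated"]
  codingEx <- unlist(txExons(codingAnn), use.names = FALSE)
  overlapCoding <- character()
  if (length(codingEx) && length(keep)) {
    candEx <- unlist(txExons(candidates[keep]), use.names = FALSE)
    candTx <- rep(keep, S4Vectors::elementNROWS(txExons(candidates[keep])))
    hit <- GenomicRanges::findOverlaps(candEx, codingEx, ignore.strand = FALSE,
                                       minoverlap = 1L)
    overlapCoding <- unique(candTx[S4Vectors::queryHits(hit)])
  }
  record(4L, setdiff(keep, overlapCoding))
  annotatedIds <- .intronChainMatches(candidates, keep, annLnc)
  # (4) expression
  agg <- switch(fpkmAggregate,
                max = apply(fpkm, 1L, max),
                mean = rowMeans(fpkm),
                all = apply(fpkm, 1L, min))
  record(5L, keep[agg[keep] >= fpkmMin])
  # (5) coding potential
  record(6L, keep[!isCoding[keep]])

  surviving <- candidates[keep]
  cls <- classifyLncrna(surviving, codingAnn)
  records <- DataFrame(
    transcript_id = keep,
    gene_id = unname(geneIds(surviving)),
    cls = unname(cls),
    status = ifelse(keep %in% annotatedIds, "annotated", "novel"),
    row.names = keep)
  report <- new("FilterReport", steps = steps, survivorIds = keep)
  list(records = records, report = report, lncrnas = surviving)
}

# candidates (restricted to ids) whose intron chain exactly matches an
# annotated lncRNA: same chromosome, strand and identical intron boundaries
.intronChainMatches <- function(candidates, ids, annLnc) {
  if (!length(annLnc) || !length(ids)) return(character())
  chain <- function(ts) {
    vapply(seq_along(ts), function(i) {
      ex <- txExons(ts)[[i]]
      s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
      paste(as.character(GenomicRanges::seqnames(ex))[1L],
            as.character(GenomicRanges::strand(ex))[1L],
            paste(e[-length(e)] + 1L, s[-1L] - 1L, sep = "-", collapse = ","),
            sep = "|")
    }, character(1))
  }
  candChain <- chain(candidates[ids])
  ids[candChain %in% chain(annLnc)]
}

#' Positional classification of lncRNAs relative to coding genes
#'
#' Classifies each transcript by explicit coordinate rules:
#' \describe{
#'   \item{lncNAT}{>= 1 bp exonic overlap with a protein-coding exon on the
#'     opposite strand (long non-coding natural antisense transcript).}
#'   \item{intronic}{entirely inside an intron of a coding gene, either
#'     strand, with no exonic overlap.}
#'   \item{sense_overlapping}{same-strand overlap with a coding gene span
#'     without exonic overlap.}
#'   \item{lincRNA}{no overlap with any protein-coding gene span on either
#'     strand (long intergenic non-coding RNA).}
#' }
#' Precedence when several rules apply: lncNAT, then intronic, then
#' sense_overlapping.
#'
#' @param transcripts a [TranscriptSet-class] of transcripts that passed the
#'   cascade.
#' @param codingGenes a [TranscriptSet-class] of protein-coding models.
#' @return named character vector of classes, one per transcript.
#' @export
classifyLncrna <- function(transcripts, codingGenes) {
  ids <- names(transcripts)
  out <- setNames(rep("lincRNA", length(ids)), ids)
  if (!length(transcripts)) return(out)
  sp <- txSpans(transcripts)
  if (!length(codingGenes)) return(out)

  codingEx <- unlist(txExons(codingGenes), use.names = FALSE)
  geneSpans <- txSpans(codingGenes)
  # collapse transcript spans to gene spans
  gs <- unlist(range(GenomicRanges::split(geneSpans, mcols(geneSpans)$gene_id)),
               use.names = FALSE)

  candEx <- unlist(txExons(transcripts), use.names = FALSE)
  candTx <- rep(ids, S4Vectors::elementNROWS(txExons(transcripts)))

  antisense <- GenomicRanges::findOverlaps(
    GenomicRanges::invertStrand(candEx), codingEx, minoverlap = 1L)
  isNAT <- ids %in% candTx[S4Vectors::queryHits(antisense)]

  sense <- GenomicRanges::findOverlaps(candEx, codingEx, minoverlap = 1L)
  hasExonic <- ids %in% candTx[S4Vectors::queryHits(sense)]

  # introns of each coding transcript
  introns <- .codingIntrons(codingGenes)
  inIntron <- rep(FALSE, length(ids))
  if (length(introns)) {
    within <- GenomicRanges::findOverlaps(sp, introns, type = "within",
                                          ignore.strand = TRUE)
    inIntron <- seq_along(ids) %in% S4Vectors::queryHits(within)
  }

  spanHit <- GenomicRanges::findOverlaps(sp, gs, ignore.strand = FALSE)
  sameStrandSpan <- seq_along(ids) %in% S4Vectors::queryHits(spanHit)

  out[sameStrandSpan & !hasExonic] <- "sense_overlapping"
  out[inIntron & !hasExonic & !isNAT] <- "intronic"
  out[isNAT] <- "lncNAT"
  out
}

.codingIntrons <- function(codingGenes) {
  exl <- txExons(codingGenes)
  multi <- S4Vectors::elementNROWS(exl) > 1L
  if (!any(multi)) return(GRanges())
  exl <- exl[multi]
  res <- lapply(seq_along(exl), function(i) {
    ex <- exl[[i]]
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    GRanges(GenomicRanges::seqnames(ex)[1L],
            IRanges::IRanges(e[-length(e)] + 1L, s[-1L] - 1L),
            strand = GenomicRanges::strand(ex)[1L])
  })
  do.call(c, res)
}

#' Structural characterization histograms for lncRNA and mRNA populations
#'
#' Computes, for each population, four histograms: exon count,
#' per-chromosome transcript count, spliced transcript length (200 nt bins
#' up to 3000, then open-ended), and longest-ORF length (100 nt bins up to
#' 1000, then open-ended). Proportions sum to 1 within each histogram and
#' counts sum to the population size.
#'
#' @param lncrnas,mrnas [TranscriptSet-class] objects (either may be empty,
#'   with a warning).
#' @param sequences named character vector or `DNAStringSet` covering both
#'   populations (used for the ORF axis).
#' @return nested list `list(lncRNA = ..., mRNA = ...)`, each element a list
#'   of data.frames `exon_count`, `chromosome`, `length`, `orf` with columns
#'   `bin`, `count`, `proportion`.
#' @export
characterize <- function(lncrnas, mrnas, sequences) {
  seqs <- as.character(sequences)
  one <- function(ts, label) {
    if (!length(ts)) {
      warning("empty ", label, " population")
      empty <- data.frame(bin = character(), count = integer(),
                          proportion = numeric())
      return(list(exon_count = empty, chromosome = empty,
                  length = empty, orf = empty))
    }
    tab <- function(v) {
      t <- table(v)
      t <- t[t > 0L]  # observed bins only
      data.frame(bin = names(t), count = as.integer(t),
                 proportion = as.integer(t) / length(v))
    }
    exons <- S4Vectors::elementNROWS(txExons(ts))
    chrom <- as.character(GenomicRanges::seqnames(txSpans(ts)))
    lens <- txLengths(ts)
    lenBin <- cut(lens, c(seq(0, 3000, 200), Inf), right = TRUE)
    orf <- vapply(names(ts), function(id) {
      if (!id %in% names(seqs)) return(NA_integer_)
      as.integer(longestOrf(seqs[[id]])$length)
    }, integer(1))
    orfBin <- cut(orf, c(seq(0, 1000, 100), Inf), right = TRUE,
                  include.lowest = TRUE)
    list(exon_count = tab(exons), chromosome = tab(chrom),
         length = tab(lenBin), orf = tab(orfBin[!is.na(orfBin)]))
  }
  list(lncRNA = one(lncrnas, "lncRNA"), mRNA = one(mrnas, "mRNA"))
}
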