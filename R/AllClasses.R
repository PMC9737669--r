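#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom stats setNames median p.adjust pnorm pt rnbinom rnorm runif quantile var
#' @importFrom utils read.delim write.table head modifyList
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
#' @importClassesFrom Biostrings DNAStringSet RNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
NULL

setClassUnion("SummarizedExperimentOrNULL",
              c("SummarizedExperiment", "NULL"))

#' Set of exon-structured transcript models
#'
#' A `TranscriptSet` holds stranded, exon-structured transcript models on a
#' genome: the unit that flows through the lncRNA identification cascade.
#' Exons are stored as a [GenomicRanges::GRangesList] named by transcript id;
#' per-transcript metadata (gene id, biotype) live in a parallel `DataFrame`.
#' Coordinates are 1-based inclusive throughout (GTF native), so an interval
#' `start..end` has length `end - start + 1`.
#'
#' Validity requires, per transcript: all exons on one chromosome and one
#' strand, sorted by start, non-overlapping.
#'
#' @slot exons `GRangesList` of exons, one element per transcript.
#' @slot txData `DataFrame` with columns `gene_id` and `biotype`
#'   (one of `protein_coding`, `lncRNA_annotated`, `unknown`), rownames the
#'   transcript ids.
#'
#' @seealso [TranscriptSet()] constructor, [readGtf()], [filterCascade()]
#' @aliases TranscriptSet
#' @export
setClass("TranscriptSet",
         slots = c(exons = "CompressedGRangesList", txData = "DataFrame"))

.validTranscriptSet <- function(object) {
  msg <- character()
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    msg <- c(msg, "exons and txData must have the same length")
  if (!identical(names(ex), rownames(td)))
    msg <- c(msg, "names(exons) must equal rownames(txData)")
  if (!all(c("gene_id", "biotype") %in% colnames(td)))
    msg <- c(msg, "txData must have columns gene_id and biotype")
  if (length(ex)) {
    nchr <- lengths(unique(GenomicRanges::seqnames(ex)))
    nstr <- lengths(unique(GenomicRanges::strand(ex)))
    if (any(nchr != 1L) || any(nstr != 1L))
      msg <- c(msg, "each transcript's exons must share one chromosome and one strand")
    starts <- GenomicRanges::start(ex)
    ends <- GenomicRanges::end(ex)
    unsorted <- any(S4Vectors::elementNROWS(starts) > 1L &
                      vapply(starts, is.unsorted, logical(1)))
    if (unsorted)
      msg <- c(msg, "exons must be sorted by start within each transcript")
    ov <- mapply(function(s, e) {
      length(s) > 1L && any(s[-1L] <= e[-length(e)])
    }, as.list(starts), as.list(ends))
    if (any(ov))
      msg <- c(msg, "exons must be non-overlapping within each transcript")
  }
  if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param exons a named [GenomicRanges::GRangesList] of exons (names are
#'   transcript ids), or a `GRanges` of exons carrying a `transcript_id`
#'   metadata column to be split on.
#' @param geneId character vector of gene ids, one per transcript (recycled
#'   if length 1). Defaults to the transcript ids.
#' @param biotype character vector of biotypes, one per transcript
#'   (recycled). Default `"unknown"`.
#' @return a [TranscriptSet-class].
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 400)),
#'                              strand = "+")
#' ts <- TranscriptSet(GenomicRanges::GRangesList(t1 = ex), geneId = "g1")
#' txLengths(ts)
#' @export
TranscriptSet <- function(exons, geneId = NULL, biotype = "unknown") {
  if (is(exons, "GRanges")) {
    stopifnot("transcript_id" %in% colnames(mcols(exons)))
    exons <- GenomicRanges::split(exons, mcols(exons)$transcript_id)
  }
  exons <- as(exons, "CompressedGRangesList")
  exons <- endoapply_sort(exons)
  n <- length(exons)
  if (is.null(geneId)) geneId <- names(exons)
  td <- DataFrame(gene_id = rep_len(as.character(geneId), n),
                  biotype = rep_len(as.character(biotype), n),
                  row.names = names(exons))
  new("TranscriptSet", exons = exons, txData = td)
}

# sort exons by start within each transcript without losing mcols
endoapply_sort <- function(grl) {
  gr <- unlist(grl, use.names = FALSE)
  if (!length(gr)) return(grl)
  f <- rep(names(grl), S4Vectors::elementNROWS(grl))
  o <- order(factor(f, levels = names(grl)), GenomicRanges::start(gr))
  GenomicRanges::split(gr[o], factor(f[o], levels = names(grl)))
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x,object a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet-class transcript ids
#' @export
setMethod("names", "TranscriptSet", function(x) {
  n <- names(x@exons)
  if (is.null(n)) character(0) else n
})

#' @describeIn TranscriptSet-class subset by index, id or logical
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x))
  initialize(x, exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' @rdname txIds
#' @export
setMethod("txIds", "TranscriptSet", function(x) names(x@exons))

#' @rdname txIds
#' @export
setMethod("geneIds", "TranscriptSet",
          function(x) setNames(x@txData$gene_id, names(x@exons)))

#' @rdname txIds
#' @export
setMethod("txBiotype", "TranscriptSet",
          function(x) setNames(x@txData$biotype, names(x@exons)))

#' @rdname txIds
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname txIds
#' @export
setMethod("txSpans", "TranscriptSet", function(x) {
  sp <- unlist(range(x@exons), use.names = TRUE)
  mcols(sp)$transcript_id <- names(x@exons)
  mcols(sp)$gene_id <- x@txData$gene_id
  mcols(sp)$biotype <- x@txData$biotype
  sp
})

#' @rdname txIds
#' @export
setMethod("txLengths", "TranscriptSet",
          function(x) setNames(sum(GenomicRanges::width(x@exons)), names(x@exons)))

#' @describeIn TranscriptSet-class compact display
#' @export
setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
  bt <- table(object@txData$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
  if (length(object)) {
    ln <- txLengths(object)
    cat(sprintf("  spliced length: %d-%d nt (median %d)\n",
                min(ln), max(ln), as.integer(stats::median(ln))))
  }
  invisible(NULL)
})

#' Per-step report of the lncRNA identification cascade
#'
#' Records, for each of the six cascade steps, the number of input
#' transcripts, the number removed, and the number surviving. Counts
#' telescope: `input[k] - removed[k] == input[k+1]`, and the survivors of the
#' final step are exactly the emitted lncRNA set.
#'
#' @slot steps data.frame with columns `step`, `input`, `removed`,
#'   `surviving`, in fixed cascade order.
#' @slot survivorIds character vector of transcript ids passing all steps.
#' @aliases FilterReport
#' @seealso [filterCascade()]
#' @export
setClass("FilterReport",
         slots = c(steps = "data.frame", survivorIds = "character"))

setValidity("FilterReport", function(object) {
  st <- object@steps
  if (!all(c("step", "input", "removed", "surviving") %in% colnames(st)))
    return("steps must have columns step, input, removed, surviving")
  if (nrow(st)) {
    if (any(st$input - st$removed != st$surviving))
      return("per-step counts must satisfy input - removed = surviving")
    if (nrow(st) > 1L && any(st$surviving[-nrow(st)] != st$input[-1L]))
      return("counts must telescope between consecutive steps")
    if (st$surviving[nrow(st)] != length(object@survivorIds))
      return("final surviving count must equal length(survivorIds)")
  }
  TRUE
})

#' @rdname filterSummary
#' @export
setMethod("filterSummary", "FilterReport", function(x) x@steps)

#' @rdname filterSummary
#' @export
setMethod("survivors", "FilterReport", function(x) x@survivorIds)

#' @describeIn FilterReport-class print the telescoping step table
#' @param object a `FilterReport`
#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", nrow(object@steps), "steps,",
      length(object@survivorIds), "survivors\n")
  print(object@steps, row.names = FALSE)
  invisible(NULL)
})

#' Synthetic seed-aging dataset with planted ground truth
#'
#' Container for one generated dataset: reference annotation (protein-coding
#' genes plus annotated lncRNAs), candidate transcript models entering the
#' identification cascade, genome and spliced transcript sequences, mature
#' miRNAs, the negative-binomial count matrix, and the planted truth tables
#' against which each pipeline stage is evaluated.
#'
#' @slot annotation [TranscriptSet-class] of reference models.
#' @slot candidates [TranscriptSet-class] of assembled candidate transcripts.
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot txSeqs [Biostrings::DNAStringSet] of spliced transcript sequences
#'   (candidates and mRNAs), oriented 5'->3'.
#' @slot mirnas [Biostrings::RNAStringSet] of mature miRNA sequences.
#' @slot counts `SummarizedExperiment` of counts with `colData(.)$condition`,
#'   or `NULL` before [simulateCounts()] has run.
#' @slot truth `DataFrame`, one row per transcript: `transcript_id`,
#'   `biotype` (truth class), `fate` (cascade step that removes it, or
#'   `"pass"`), `annotated`, `de` (`up`/`down`/`ns`), `true_lfc`,
#'   `base_mean`.
#' @slot sites `DataFrame` of planted miRNA binding sites: `mirna_id`,
#'   `target_id`, `target_kind`, `site_start` (1-based on the transcript),
#'   `site_type` (`perfect`/`wobble`).
#' @slot terms `DataFrame` mapping `gene_id` to `term_id`/`term_name`.
#' @slot config list, the [syntheticConfig()] that generated the dataset.
#' @aliases SeedAgingDataset
#' @seealso [generateDataset()], [exportDataset()]
#' @export
setClass("SeedAgingDataset",
         slots = c(annotation = "TranscriptSet",
                   candidates = "TranscriptSet",
                   genome = "DNAStringSet",
                   txSeqs = "DNAStringSet",
                   mirnas = "RNAStringSet",
                   counts = "SummarizedExperimentOrNULL",
                   truth = "DataFrame",
                   sites = "DataFrame",
                   terms = "DataFrame",
                   config = "list"))

setValidity("SeedAgingDataset", function(object) {
  msg <- character()
  tr <- object@truth
  if (nrow(tr) && !all(c("transcript_id", "biotype", "fate", "de") %in% colnames(tr)))
    msg <- c(msg, "truth must have transcript_id, biotype, fate and de columns")
  if (nrow(object@sites)) {
    bad <- !object@sites$target_id %in% names(object@txSeqs)
    if (any(bad)) msg <- c(msg, "planted sites must point at known transcripts")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SeedAgingDataset-class compact display
#' @param object a `SeedAgingDataset`
#' @export
setMethod("show", "SeedAgingDataset", function(object) {
  cat("SeedAgingDataset\n")
  cat("  annotation:", length(object@annotation), "transcripts;",
      "candidates:", length(object@candidates), "\n")
  cat("  genome:", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp\n")
  cat("  miRNAs:", length(object@mirnas),
      "| planted sites:", nrow(object@sites), "\n")
  if (is.null(object@counts)) {
    cat("  counts: <not simulated>\n")
  } else {
    cat("  counts:", nrow(object@counts), "x", ncol(object@counts),
        "(conditions:",
        paste(unique(object@counts$condition), collapse = ", "), ")\n")
  }
  invisible(NULL)
})

#' @describeIn SeedAgingDataset-class planted truth table
#' @param x a `SeedAgingDataset`
#' @export
truthTable <- function(x) x@truth

#' @describeIn SeedAgingDataset-class planted miRNA site table
#' @export
plantedSites <- function(x) x@sites
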