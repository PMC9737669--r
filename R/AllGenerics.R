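#' Transcript identifiers
#'
#' @param x a [TranscriptSet-class] (or object containing one).
#' @return `txIds`: character vector of transcript ids.
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname txIds
#' @return `geneIds`: character vector of gene ids, parallel to `txIds(x)`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname txIds
#' @return `txBiotype`: character vector of biotypes
#'   (`protein_coding`, `lncRNA_annotated` or `unknown`).
#' @export
setGeneric("txBiotype", function(x) standardGeneric("txBiotype"))

#' @rdname txIds
#' @return `txExons`: a [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, exons sorted by start.
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname txIds
#' @return `txSpans`: a [GenomicRanges::GRanges] with one range per transcript
#'   spanning min(exon start)..max(exon end), with `transcript_id`, `gene_id`
#'   and `biotype` metadata columns.
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))

#' @rdname txIds
#' @return `txLengths`: named integer vector of spliced transcript lengths
#'   (sum of exon widths, 1-based inclusive coordinates so a single-base exon
#'   has length 1).
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' Filter report accessors
#'
#' @param x a [FilterReport-class].
#' @return `filterSummary`: data.frame with one row per cascade step
#'   (columns `step`, `input`, `removed`, `surviving`).
#' @export
setGeneric("filterSummary", function(x) standardGeneric("filterSummary"))

#' @rdname filterSummary
#' @return `survivors`: character vector of transcript ids emitted by the
#'   final step.
#' @export
setGeneric("survivors", function(x) standardGeneric("survivors"))

#' Simulate sequencing counts for a synthetic dataset
#'
#' @param x a [SeedAgingDataset-class] or a truth `DataFrame` as produced by
#'   [generateDataset()].
#' @param config a synthetic configuration (defaults to the dataset's own).
#' @param ... passed to methods.
#' @return for a dataset input, the dataset with the `counts` slot filled;
#'   for a truth table input, a [SummarizedExperiment::SummarizedExperiment]
#'   of negative-binomial counts.
#' @export
setGeneric("simulateCounts", function(x, config, ...) standardGeneric("simulateCounts"))
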