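#' @include AllClasses.R
NULL

#' Read transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `transcript_id`, `gene_id` and
#' optionally `transcript_biotype`) into a [TranscriptSet-class]. Exon
#' records are grouped by transcript and sorted by start. A transcript whose
#' exon lines appear without a `transcript` feature line is synthesized from
#' its exon span (logged via `message`); feature types other than
#' `transcript`/`exon` are ignored, logged once per type.
#'
#' @param path path to a GTF file.
#' @return a [TranscriptSet-class]; empty file gives an empty set.
#' @seealso [writeGtf()] for the inverse; round-trips are lossless for all
#'   fields the pipeline reads (coordinates, strand, ids, biotype).
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  firstLines <- readLines(path, warn = FALSE)
  if (!length(firstLines) || all(grepl("^#|^\\s*$", firstLines)))
    return(TranscriptSet(GRangesList()))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!length(gr)) {
    return(TranscriptSet(GRangesList()))
  }
  if (!"transcript_id" %in% colnames(mcols(gr)))
    stop("GTF has no transcript_id attribute: ", path)
  type <- as.character(gr$type)
  other <- setdiff(unique(type), c("transcript", "exon"))
  for (ty in other) message("readGtf: ignoring feature type '", ty, "'")
  exons <- gr[type == "exon"]
  txrows <- gr[type == "transcript"]
  noExon <- setdiff(txrows$transcript_id, exons$transcript_id)
  if (length(noExon)) {
    message("readGtf: ", length(noExon),
            " transcript(s) without exon lines; using span as single exon")
    syn <- txrows[txrows$transcript_id %in% noExon]
    exons <- c(exons, syn)
  }
  orphan <- setdiff(exons$transcript_id, txrows$transcript_id)
  if (length(orphan))
    message("readGtf: ", length(orphan),
            " transcript(s) synthesized from exon lines only")
  biotype <- rep("unknown", length(exons))
  for (col in c("transcript_biotype", "gene_biotype")) {
    if (col %in% colnames(mcols(exons))) {
      v <- mcols(exons)[[col]]
      biotype[!is.na(v)] <- v[!is.na(v)]
      break
    }
  }
  gene <- exons$gene_id
  if (is.null(gene)) gene <- exons$transcript_id
  gene[is.na(gene)] <- exons$transcript_id[is.na(gene)]
  key <- !duplicated(exons$transcript_id)
  grl <- GenomicRanges::split(granges(exons),
                              factor(exons$transcript_id,
                                     levels = exons$transcript_id[key]))
  TranscriptSet(grl,
                geneId = gene[key],
                biotype = biotype[key])
}

#' @importFrom GenomicRanges granges
NULL

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` line plus one `exon` line per exon, with
#' Ensembl-style `gene_id`/`transcript_id`/`transcript_biotype` attributes.
#' `readGtf(writeGtf(x))` reproduces `x` up to attribute ordering.
#'
#' @param transcripts a [TranscriptSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(transcripts, path) {
  stopifnot(is(transcripts, "TranscriptSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#!genome-version synthetic", con)
  if (!length(transcripts)) return(invisible(path))
  sp <- txSpans(transcripts)
  ex <- unlist(txExons(transcripts), use.names = FALSE)
  extx <- rep(names(transcripts), S4Vectors::elementNROWS(txExons(transcripts)))
  gid <- geneIds(transcripts)
  bt <- txBiotype(transcripts)
  attrs <- function(tx) sprintf(
    'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    gid[[tx]], tx, bt[[tx]])
  fmt <- function(gr, feature, tx) {
    sprintf("%s\tseedLncRNA\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomicRanges::seqnames(gr)), feature,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            chartr("*", ".", as.character(GenomicRanges::strand(gr))),
            vapply(tx, attrs, ""))
  }
  lines <- character()
  for (i in seq_along(transcripts)) {
    tx <- names(transcripts)[i]
    lines <- c(lines, fmt(sp[i], "transcript", tx),
               fmt(ex[extx == tx], "exon", rep(tx, sum(extx == tx))))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTA file into a StringSet
#'
#' Sequences are uppercased. DNA inputs are stored in the DNA alphabet;
#' `alphabet = "RNA"` reads RNA (U) sequences, converting any T to U, for the
#' miRNA module.
#'
#' @param path FASTA file path.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::RNAStringSet], named
#'   by the first whitespace-delimited token of each header.
#' @export
readFasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate FASTA id(s): ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0L))
    stop("empty FASTA record(s): ",
         paste(names(raw)[Biostrings::width(raw) == 0L], collapse = ", "))
  chr <- toupper(as.character(raw))
  if (alphabet == "RNA") {
    Biostrings::RNAStringSet(chartr("T", "U", chr))
  } else {
    Biostrings::DNAStringSet(chartr("U", "T", chr))
  }
}

#' Read a transcripts-by-samples expression table with its design
#'
#' The table is a TSV whose header row names the samples and whose first
#' column holds transcript ids; the design is a two-column TSV
#' (`sample_id`, `condition`). Every sample in the table must appear in the
#' design.
#'
#' @param path expression TSV path.
#' @param designPath design TSV path.
#' @param assayName name for the assay (`"counts"` or `"fpkm"`); default
#'   `"counts"`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one assay and
#'   `colData(.)$condition`.
#' @export
readExpressionTable <- function(path, designPath, assayName = "counts") {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- tab[[1L]]
  num <- tab[, -1L, drop = FALSE]
  mat <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  mat <- matrix(mat, nrow = nrow(num),
                dimnames = list(ids, colnames(num)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at transcript '", ids[bad[1L]],
         "', sample '", colnames(mat)[bad[2L]], "'")
  }
  if (any(mat < 0)) stop("expression values must be non-negative")
  design <- read.delim(designPath, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% colnames(design)))
    stop("design must have columns sample_id and condition")
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  cond <- design$condition[match(colnames(mat), design$sample_id)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(mat), assayName),
    colData = DataFrame(condition = cond, row.names = colnames(mat)))
  se
}

#' Write an expression assay and design back to TSV
#'
#' Inverse of [readExpressionTable()]: writes the first assay as a TSV with
#' a `transcript_id` first column, and the design as `sample_id`/`condition`.
#'
#' @param se a `SummarizedExperiment` with `colData(.)$condition`.
#' @param path expression TSV path.
#' @param designPath design TSV path (skipped if `NULL`).
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(se, path, designPath = NULL) {
  mat <- SummarizedExperiment::assay(se, 1L)
  df <- data.frame(transcript_id = rownames(mat), mat,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(designPath)) {
    write.table(data.frame(sample_id = colnames(se),
                           condition = se$condition),
                designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a network edge list as a three-column TSV
#'
#' The dialect (source, interaction, target; tab-separated; header row) is
#' directly importable by common network viewers such as Cytoscape. Edges
#' are written in deterministic order: lexicographic by source, then target.
#'
#' @param edges data.frame with columns `source`, `interaction`, `target`
#'   (extra columns are preserved after the first three).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path) {
  if (is.null(edges) || !nrow(edges)) {
    writeLines("source\tinteraction\ttarget", path)
    return(invisible(path))
  }
  stopifnot(all(c("source", "interaction", "target") %in% colnames(edges)))
  edges <- edges[, c("source", "interaction", "target",
                     setdiff(colnames(edges), c("source", "interaction", "target")))]
  o <- order(edges$source, edges$target, edges$interaction, method = "radix")
  write.table(edges[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
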