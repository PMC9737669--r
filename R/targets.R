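#' @include AllClasses.R
NULL

#' Pearson correlation with a t-reference p-value
#'
#' Standard product-moment correlation, clamped to `[-1, 1]`, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Constant vectors give `r = NA`, `p = 1` and
#' `ok = FALSE` (such pairs are excluded by [transTargets()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `p`, `n`, `ok`.
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need n >= 3 samples")
  sx <- x - mean(x)
  sy <- y - mean(y)
  denom <- sqrt(sum(sx^2) * sum(sy^2))
  if (denom == 0)
    return(list(r = NA_real_, p = 1, n = n, ok = FALSE))
  r <- min(1, max(-1, sum(sx * sy) / denom))
  p <- .pearsonP(r, n)
  list(r = r, p = p, n = n, ok = TRUE)
}

.pearsonP <- function(r, n) {
  if (is.na(r)) return(1)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Cis target prediction by genomic co-localization
#'
#' A protein-coding gene is a cis (co-localized) candidate target of a
#' lncRNA when its span lies within `window` bases of the lncRNA span on the
#' same chromosome, either strand. The boundary is inclusive: a gap of
#' exactly `window` bases is included, `window + 1` is not. Distance is the
#' span gap in bases (0 when the spans overlap or are adjacent).
#'
#' @param lncrnas [TranscriptSet-class] (or `GRanges` of spans with a
#'   `transcript_id` column).
#' @param codingGenes [TranscriptSet-class] of protein-coding models (gene
#'   spans are the union over a gene's transcripts), or `GRanges` with a
#'   `gene_id` column.
#' @param window co-localization window in bases; default 100000 (100 kb
#'   upstream or downstream).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `mode`
#'   (`"cis"`), `distance`, sorted by `lncrna_id` then `gene_id`.
#' @export
cisTargets <- function(lncrnas, codingGenes, window = 100000L) {
  stopifnot(window > 0)
  lsp <- if (is(lncrnas, "TranscriptSet")) txSpans(lncrnas) else lncrnas
  if (is(codingGenes, "TranscriptSet")) {
    sp <- txSpans(codingGenes)
    gsp <- unlist(range(GenomicRanges::split(sp, mcols(sp)$gene_id)),
                  use.names = TRUE)
    gid <- names(gsp)
  } else {
    gsp <- codingGenes
    gid <- mcols(gsp)$gene_id
  }
  lid <- if (!is.null(mcols(lsp)$transcript_id)) mcols(lsp)$transcript_id
         else names(lsp)
  hits <- GenomicRanges::findOverlaps(lsp, gsp, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), distance = integer()))
  d <- GenomicRanges::distance(lsp[S4Vectors::queryHits(hits)],
                               gsp[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  out <- data.frame(lncrna_id = lid[S4Vectors::queryHits(hits)],
                    gene_id = gid[S4Vectors::subjectHits(hits)],
                    mode = "cis", distance = as.integer(d))
  out <- out[out$lncrna_id != out$gene_id, , drop = FALSE]
  out <- unique(out)
  out[order(out$lncrna_id, out$gene_id, method = "radix"), , drop = FALSE]
}

#' Trans target prediction by expression correlation
#'
#' Tests every lncRNA x mRNA pair on their expression profiles (FPKM in the
#' seed study design, all `n = 6` samples from both conditions) and keeps
#' pairs with `r > rMin` (strict) and `p < pMax` (strict). Constant
#' profiles are excluded. At n = 6, r > 0.95 already implies p ~ 0.004, so
#' the correlation criterion dominates the default p criterion.
#'
#' @param lncExpr,mrnaExpr expression matrices (transcripts x samples) or
#'   `SummarizedExperiment`s over identical samples in identical order.
#' @param rMin,pMax strict thresholds; defaults 0.95 and 0.01.
#' @return data.frame with columns `lncrna_id`, `gene_id`, `mode`
#'   (`"trans"`), `pcc`, `p`, sorted by `lncrna_id` then `gene_id`.
#' @export
transTargets <- function(lncExpr, mrnaExpr, rMin = 0.95, pMax = 0.01) {
  if (is(lncExpr, "SummarizedExperiment"))
    lncExpr <- SummarizedExperiment::assay(lncExpr, 1L)
  if (is(mrnaExpr, "SummarizedExperiment"))
    mrnaExpr <- SummarizedExperiment::assay(mrnaExpr, 1L)
  lncExpr <- as.matrix(lncExpr)
  mrnaExpr <- as.matrix(mrnaExpr)
  if (ncol(lncExpr) != ncol(mrnaExpr) ||
      !identical(colnames(lncExpr), colnames(mrnaExpr)))
    stop("lncRNA and mRNA matrices must cover the same samples in the same order")
  n <- ncol(lncExpr)
  if (n < 3L) stop("need >= 3 samples")
  constL <- apply(lncExpr, 1L, function(v) var(v) == 0)
  constM <- apply(mrnaExpr, 1L, function(v) var(v) == 0)
  r <- suppressWarnings(stats::cor(t(lncExpr), t(mrnaExpr)))
  r[constL, ] <- NA
  r[, constM] <- NA
  r <- pmax(pmin(r, 1), -1)
  keep <- which(!is.na(r) & r > rMin, arr.ind = TRUE)
  if (!nrow(keep))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), pcc = numeric(), p = numeric()))
  rv <- r[keep]
  pv <- vapply(rv, .pearsonP, numeric(1), n = n)
  out <- data.frame(lncrna_id = rownames(lncExpr)[keep[, 1L]],
                    gene_id = rownames(mrnaExpr)[keep[, 2L]],
                    mode = "trans", pcc = rv, p = pv)
  out <- out[out$p < pMax, , drop = FALSE]
  out[order(out$lncrna_id, out$gene_id, method = "radix"), , drop = FALSE]
}
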