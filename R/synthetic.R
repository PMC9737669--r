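#' @include AllClasses.R AllGenerics.R
NULL

#' Configuration for the synthetic seed-aging dataset generator
#'
#' Defaults encode the statistical structure the generator emulates: two
#' conditions (aged `S50`, fresh `S96`) with 3 replicates; a lncRNA
#' population of 2-3 exon transcripts of 200-1000 nt with short ORFs; an
#' mRNA population of 800-3000 nt with broad exon counts; twice as many
#' lincRNAs as lncNATs; negative-binomial counts with shared dispersion
#' 0.1; differential expression heavily skewed toward lncRNA
#' downregulation (90 down, exactly 4 up at this toy scale) with effect
#' sizes of 2-4 log2 units; planted miRNA binding sites in strongly
#' differential lncRNAs and mRNAs; and one genuinely enriched annotation
#' term (`TERM01`) among the cis targets of downregulated lncRNAs.
#'
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param n_mrna,n_lncrna population sizes.
#' @param lincRNA_fraction fraction of lncRNAs that are intergenic
#'   (remainder are antisense lncNATs); default 2/3.
#' @param mrna_exon_range,mrna_length_range exon-count and spliced-length
#'   ranges for mRNAs.
#' @param lncrna_exon_range,lncrna_length_range same for lncRNAs.
#' @param nb_dispersion shared NB dispersion alpha (> 0).
#' @param n_replicates replicates per condition.
#' @param de_config list: `n_up_lnc`, `n_down_lnc`, `n_up_mrna`,
#'   `n_down_mrna`, `lfc_range` (absolute log2 fold changes, all > 1).
#' @param n_mirna,mirna_length mature miRNA count and length (nt).
#' @param n_planted_triplets planted (lncRNA, miRNA, mRNA) triplets.
#' @param site_wobbles G:U wobbles planted per site, outside the
#'   seed-critical region; default 1.
#' @param contaminants_per_class planted contaminants per cascade filter
#'   (strand-uncertain, single-exon, short-fragment, sense-overlap,
#'   low-expression, coding).
#' @param annotated_fraction fraction of lncRNAs that also exist in the
#'   reference annotation (recovered as `status = "annotated"`).
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of
#'   per-transcript base means (count scale).
#' @param low_expr_mean base mean of low-expression artifacts.
#' @param library_size_range per-sample library-size factor range (ratio
#'   across samples stays below 2).
#' @param n_terms,term_size,enriched_overlap annotation-term map shape;
#'   `TERM01` receives `enriched_overlap` genes from the cis-target pool
#'   of downregulated lncRNAs.
#' @param conditions named character vector `c(aged = , new = )`.
#' @param seed root RNG seed; all sub-generators derive child seeds from
#'   it deterministically.
#' @return a validated config list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(n_chrom = 3L, chrom_length = 2e6,
                            n_mrna = 200L, n_lncrna = 100L,
                            lincRNA_fraction = 2 / 3,
                            mrna_exon_range = c(1L, 12L),
                            mrna_length_range = c(800L, 3000L),
                            lncrna_exon_range = c(2L, 3L),
                            lncrna_length_range = c(200L, 1000L),
                            nb_dispersion = 0.1, n_replicates = 3L,
                            de_config = list(n_up_lnc = 4L, n_down_lnc = 90L,
                                             n_up_mrna = 5L, n_down_mrna = 40L,
                                             lfc_range = c(2, 4)),
                            n_mirna = 12L, mirna_length = 21L,
                            n_planted_triplets = 10L, site_wobbles = 1L,
                            contaminants_per_class = 4L,
                            annotated_fraction = 0.2,
                            base_mean_meanlog = log(5e4),
                            base_mean_sdlog = 1,
                            low_expr_mean = 0.2,
                            library_size_range = c(0.75, 1.4),
                            n_terms = 20L, term_size = 30L,
                            enriched_overlap = 20L,
                            conditions = c(aged = "S50", new = "S96"),
                            seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              lincRNA_fraction = lincRNA_fraction,
              mrna_exon_range = mrna_exon_range,
              mrna_length_range = mrna_length_range,
              lncrna_exon_range = lncrna_exon_range,
              lncrna_length_range = lncrna_length_range,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              de_config = de_config,
              n_mirna = as.integer(n_mirna),
              mirna_length = as.integer(mirna_length),
              n_planted_triplets = as.integer(n_planted_triplets),
              site_wobbles = as.integer(site_wobbles),
              contaminants_per_class = as.integer(contaminants_per_class),
              annotated_fraction = annotated_fraction,
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              low_expr_mean = low_expr_mean,
              library_size_range = library_size_range,
              n_terms = as.integer(n_terms),
              term_size = as.integer(term_size),
              enriched_overlap = as.integer(enriched_overlap),
              conditions = conditions, seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  .validateSyntheticConfig(cfg)
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  stopifnot(cfg$n_chrom >= 1L, cfg$chrom_length > 0,
            cfg$n_mrna >= 0L, cfg$n_lncrna >= 0L,
            cfg$lincRNA_fraction >= 0, cfg$lincRNA_fraction <= 1,
            cfg$nb_dispersion > 0, cfg$n_replicates >= 2L,
            cfg$contaminants_per_class >= 0L,
            cfg$n_planted_triplets >= 0L, cfg$n_mirna >= 0L)
  de <- cfg$de_config
  stopifnot(de$n_up_lnc >= 0, de$n_down_lnc >= 0,
            de$n_up_mrna >= 0, de$n_down_mrna >= 0,
            all(de$lfc_range > 1))
  if (de$n_up_lnc + de$n_down_lnc > cfg$n_lncrna)
    stop("more differential lncRNAs requested than lncRNAs")
  if (de$n_up_mrna + de$n_down_mrna > cfg$n_mrna)
    stop("more differential mRNAs requested than mRNAs")
  if (cfg$n_planted_triplets > 0L && cfg$n_mirna < 1L)
    stop("planted triplets need at least one miRNA")
  invisible(cfg)
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcompChars <- function(v) unname(.COMP[rev(v)])

.randBases <- function(n) sample(.BASES, n, replace = TRUE)

# random sequence whose longest ORF is < 200 nt (hence non-coding under the
# cascade's ORF rule)
.drawNoncodingSeq <- function(len, maxTries = 200L) {
  for (i in seq_len(maxTries)) {
    s <- paste(.randBases(len), collapse = "")
    if (longestOrf(s)$length < 200L) return(s)
  }
  stop("could not draw a non-coding sequence of length ", len)
}

# sequence with a planted ATG..stop ORF covering covFrac of the length
.drawCodingSeq <- function(len, covFrac = runif(1, 0.5, 0.75)) {
  orfLen <- 3L * floor(covFrac * len / 3)
  orfLen <- max(orfLen, 300L)
  utr5 <- max(3L, floor(0.1 * len))
  utr3 <- len - utr5 - orfLen
  if (utr3 < 0) { utr5 <- len - orfLen; utr3 <- 0L }
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(orfLen / 3L - 2L)
  for (i in seq_along(codons)) {
    repeat {
      cd <- paste(.randBases(3L), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0(paste(.randBases(utr5), collapse = ""),
         "ATG", paste(codons, collapse = ""), sample(stops, 1L),
         paste(.randBases(utr3), collapse = ""))
}

.splitWidths <- function(total, n, minw = 30L) {
  total <- as.integer(total)
  if (n == 1L) return(total)
  extra <- total - minw * n
  if (extra < 0L) stop("length ", total, " too small for ", n, " exons")
  u <- runif(n)
  w <- floor(u / sum(u) * extra)
  w[1L] <- w[1L] + (extra - sum(w))
  as.integer(minw + w)
}

# transcript-coordinate interval of each exon, in transcript (5'->3') order
.txExonIntervals <- function(widths, strand) {
  u <- if (strand == "-") rev(widths) else widths
  hi <- cumsum(u)
  lo <- hi - u + 1L
  cbind(lo = lo, hi = hi)
}

#' Generate a synthetic seed-aging dataset with planted truth
#'
#' Builds, deterministically for a fixed seed, a complete toy study:
#' reference annotation (protein-coding genes and a fraction of annotated
#' lncRNA models), candidate transcripts (lincRNAs, lncNATs, and one
#' planted contaminant class per cascade filter), a random genome carrying
#' every planted sequence, mature miRNAs with binding sites planted in
#' strongly differential transcripts, an annotation-term map with one
#' genuinely enriched term, and a truth table recording each transcript's
#' class, expected cascade fate, DE direction and effect size.
#'
#' LncNATs are placed antisense-overlapping an mRNA exon; lincRNAs at
#' least 1 kb from any protein-coding gene. All lincRNA and lncNAT
#' sequences are drawn (by rejection) with longest ORF < 200 nt.
#'
#' Counts are not simulated here; see [simulateCounts()].
#'
#' @param config a [syntheticConfig()].
#' @return a [SeedAgingDataset-class] (with empty `counts`).
#' @export
generateDataset <- function(config = syntheticConfig()) {
  .validateSyntheticConfig(config)
  set.seed(config$seed)
  de <- config$de_config

  nLinc <- round(config$n_lncrna * config$lincRNA_fraction)
  nNat <- config$n_lncrna - nLinc
  cpc <- config$contaminants_per_class
  artClasses <- c("strand_uncertain_artifact", "single_exon_artifact",
                  "short_fragment", "sense_overlap_artifact",
                  "low_expression_artifact", "coding_contaminant")
  artFate <- c(strand_uncertain_artifact = "strand_certain",
               single_exon_artifact = "multi_exon",
               short_fragment = "min_length",
               sense_overlap_artifact = "annotation_overlap",
               low_expression_artifact = "expression",
               coding_contaminant = "non_coding")
  nAttached <- nNat + cpc  # lncNATs + sense-overlap artifacts need hosts
  if (nAttached > config$n_mrna && (nNat > 0L || cpc > 0L))
    stop("not enough mRNA hosts for lncNATs and sense-overlap artifacts; ",
         "increase n_mrna")

  ## ---- structure planning -------------------------------------------------
  tx <- list()
  addTx <- function(id, class, nEx, exonic, strand = sample(c("+", "-"), 1L),
                    host = NA_character_) {
    tx[[id]] <<- list(id = id, class = class, n_exons = nEx,
                      exonic = exonic, strand = strand, host = host,
                      widths = NULL, introns = NULL, chrom = NA, start = NA,
                      seq = NULL)
  }
  rint <- function(rng) if (rng[1L] >= rng[2L]) as.integer(rng[1L]) else
    sample(seq.int(rng[1L], rng[2L]), 1L)

  for (i in seq_len(config$n_mrna))
    addTx(sprintf("MRNA_%04d", i), "mRNA",
          rint(config$mrna_exon_range), rint(config$mrna_length_range))
  for (i in seq_len(nLinc))
    addTx(sprintf("TCONS_%05d", i), "lincRNA",
          rint(config$lncrna_exon_range), rint(config$lncrna_length_range))
  natIds <- sprintf("TCONS_%05d", nLinc + seq_len(nNat))
  for (id in natIds) addTx(id, "lncNAT", 2L, NA_integer_)
  nextIdx <- nLinc + nNat
  artIds <- list()
  for (cl in artClasses) {
    ids <- sprintf("TCONS_%05d", nextIdx + seq_len(cpc))
    nextIdx <- nextIdx + cpc
    artIds[[cl]] <- ids
    for (id in ids) {
      if (cl == "strand_uncertain_artifact")
        addTx(id, cl, 2L, rint(c(300L, 800L)), strand = "*")
      else if (cl == "single_exon_artifact")
        addTx(id, cl, 1L, rint(c(300L, 800L)))
      else if (cl == "short_fragment")
        addTx(id, cl, 2L, rint(c(100L, 180L)))
      else if (cl == "sense_overlap_artifact")
        addTx(id, cl, 2L, NA_integer_)
      else if (cl == "low_expression_artifact")
        addTx(id, cl, 2L, rint(c(300L, 800L)))
      else  # coding_contaminant
        addTx(id, cl, 2L, rint(c(600L, 1000L)))
    }
  }

  # exon widths and introns for independently placed transcripts
  attached <- c(natIds, artIds[["sense_overlap_artifact"]])
  for (id in names(tx)) {
    if (id %in% attached) next
    t <- tx[[id]]
    minw <- if (t$exonic < 60L * t$n_exons) 20L else
            if (t$class == "mRNA") 50L else 30L
    t$widths <- .splitWidths(t$exonic, t$n_exons, minw = minw)
    t$introns <- if (t$n_exons > 1L) {
      if (t$class == "mRNA") sample(100:1500, t$n_exons - 1L, replace = TRUE)
      else sample(100:400, t$n_exons - 1L, replace = TRUE)
    } else integer()
    tx[[id]] <- t
  }

  ## ---- placement ----------------------------------------------------------
  independent <- setdiff(names(tx), attached)
  if (length(independent)) {
    ord <- sample(independent)
    chromOf <- rep_len(seq_len(config$n_chrom), length(ord))
    cursor <- rep(1L, config$n_chrom)
    for (k in seq_along(ord)) {
      id <- ord[k]; ch <- chromOf[k]
      t <- tx[[id]]
      gap <- sample(2000:8000, 1L)
      start <- cursor[ch] + gap
      span <- sum(t$widths) + sum(t$introns)
      if (start + span - 1L > config$chrom_length - 2000L)
        stop("chromosome ", ch, " too short to place the requested ",
             "transcripts; increase chrom_length")
      t$chrom <- paste0("chr", ch)
      t$start <- start
      cursor[ch] <- start + span - 1L
      tx[[id]] <- t
    }
  }

  # attach lncNATs and sense-overlap artifacts to distinct mRNA hosts
  mrnaIds <- grep("^MRNA_", names(tx), value = TRUE)
  hosts <- if (length(attached)) sample(mrnaIds, length(attached)) else character()
  for (k in seq_along(attached)) {
    id <- attached[k]
    t <- tx[[id]]
    h <- tx[[hosts[k]]]
    t$host <- h$id
    w1 <- h$widths[1L]
    ov <- rint(c(30L, min(150L, w1)))
    extra <- rint(c(80L, 200L))
    intron <- rint(c(100L, 400L))
    e2w <- rint(c(100L, 400L))
    t$widths <- c(e2w, extra + ov)      # genomic order, left to right
    t$introns <- intron
    t$exonic <- e2w + extra + ov
    t$chrom <- h$chrom
    t$start <- h$start - extra - intron - e2w
    t$strand <- if (t$class == "lncNAT") {
      if (h$strand == "+") "-" else "+"
    } else h$strand
    tx[[id]] <- t
  }

  ## ---- base means and differential expression -----------------------------
  allIds <- names(tx)
  baseMean <- exp(rnorm(length(allIds), config$base_mean_meanlog,
                        config$base_mean_sdlog))
  names(baseMean) <- allIds
  baseMean[unlist(artIds["low_expression_artifact"])] <- config$low_expr_mean

  lncIds <- c(sprintf("TCONS_%05d", seq_len(nLinc)), natIds)
  deDir <- setNames(rep("ns", length(allIds)), allIds)
  trueLfc <- setNames(rep(0, length(allIds)), allIds)
  pickDe <- function(pool, nUp, nDown) {
    sel <- sample(pool, nUp + nDown)
    list(up = sel[seq_len(nUp)], down = sel[nUp + seq_len(nDown)])
  }
  lncDe <- pickDe(lncIds, de$n_up_lnc, de$n_down_lnc)
  mrnaDe <- pickDe(mrnaIds, de$n_up_mrna, de$n_down_mrna)
  for (s in c("up", "down")) {
    ids <- c(lncDe[[s]], mrnaDe[[s]])
    deDir[ids] <- s
    mag <- runif(length(ids), de$lfc_range[1L], de$lfc_range[2L])
    trueLfc[ids] <- if (s == "up") mag else -mag
  }

  ## ---- miRNAs and planted-site plan ---------------------------------------
  mirnas <- character(0)
  if (config$n_mirna > 0L) {
    mirnas <- vapply(seq_len(config$n_mirna), function(i)
      paste(sample(c("A", "C", "G", "U"), config$mirna_length, TRUE),
            collapse = ""), character(1))
    names(mirnas) <- sprintf("miR%03d", seq_len(config$n_mirna))
  }
  sitePlan <- data.frame(mirna_id = character(), target_id = character(),
                         target_kind = character())
  if (config$n_planted_triplets > 0L) {
    # strongly differential transcripts carry the planted network, so that
    # every planted triplet survives the DE filter
    lincDe <- intersect(c(lncDe$up, lncDe$down),
                        sprintf("TCONS_%05d", seq_len(nLinc)))
    lincDe <- lincDe[order(-abs(trueLfc[lincDe]))]
    mrnaFree <- setdiff(c(mrnaDe$up, mrnaDe$down), hosts)
    mrnaFree <- mrnaFree[order(-abs(trueLfc[mrnaFree]))]
    nt <- config$n_planted_triplets
    if (length(lincDe) < nt || length(mrnaFree) < nt)
      stop("not enough differential lincRNAs/mRNAs to host ",
           nt, " planted triplets")
    mi <- names(mirnas)[rep_len(seq_len(config$n_mirna), nt)]
    sitePlan <- data.frame(
      mirna_id = rep(mi, each = 2L),
      target_id = as.vector(rbind(lincDe[seq_len(nt)], mrnaFree[seq_len(nt)])),
      target_kind = rep(c("lncRNA", "mRNA"), nt))
  }

  ## ---- sequence generation and site planting ------------------------------
  plantedIds <- setdiff(allIds, attached)  # all but genome-derived NAT-likes
  drawSeq <- function(t) {
    if (t$class %in% c("mRNA", "coding_contaminant"))
      .drawCodingSeq(t$exonic)
    else .drawNoncodingSeq(t$exonic)
  }
  seqs <- vapply(plantedIds, function(id) drawSeq(tx[[id]]), character(1))

  siteRecords <- data.frame(mirna_id = character(), target_id = character(),
                            target_kind = character(), site_start = integer(),
                            site_type = character())
  if (nrow(sitePlan)) {
    regions <- lapply(sitePlan$target_id, function(id) {
      t <- tx[[id]]
      iv <- .txExonIntervals(t$widths, t$strand)
      big <- which.max(iv[, "hi"] - iv[, "lo"])
      c(iv[big, "lo"], iv[big, "hi"])
    })
    names(regions) <- sitePlan$target_id
    planted <- NULL
    for (attempt in 1:50) {
      planted <- plantMirnaSites(seqs[unique(sitePlan$target_id)], mirnas,
                                 sitePlan, wobbles = config$site_wobbles,
                                 regions = regions)
      bad <- vapply(unique(sitePlan$target_id), function(id) {
        tx[[id]]$class == "lincRNA" &&
          longestOrf(planted$seqs[[id]])$length >= 200L
      }, logical(1))
      if (!any(bad)) break
      if (attempt == 50L)
        stop("could not plant miRNA sites without creating long ORFs")
      # redraw the offending lincRNA backbones and replant
      for (id in names(bad)[bad])
        seqs[[id]] <- .drawNoncodingSeq(tx[[id]]$exonic)
    }
    seqs[names(planted$seqs)] <- planted$seqs
    siteRecords <- planted$sites
  }

  ## ---- genome assembly ----------------------------------------------------
  chromNames <- paste0("chr", seq_len(config$n_chrom))
  genomeChars <- lapply(chromNames, function(ch) .randBases(config$chrom_length))
  names(genomeChars) <- chromNames

  writeTx <- function(t, s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (t$strand == "-") chars <- .revcompChars(chars)
    # chars now in genomic orientation; split across exons left to right
    stops <- cumsum(t$widths)
    starts0 <- stops - t$widths + 1L
    gstarts <- t$start + c(0L, cumsum(t$widths[-t$n_exons] +
                                        t$introns))[seq_len(t$n_exons)]
    for (e in seq_len(t$n_exons)) {
      idx <- gstarts[e]:(gstarts[e] + t$widths[e] - 1L)
      genomeChars[[t$chrom]][idx] <<- chars[starts0[e]:stops[e]]
    }
  }
  for (id in plantedIds) writeTx(tx[[id]], seqs[[id]])

  extractTx <- function(t) {
    gstarts <- t$start + c(0L, cumsum(t$widths[-t$n_exons] +
                                        t$introns))[seq_len(t$n_exons)]
    chars <- unlist(lapply(seq_len(t$n_exons), function(e)
      genomeChars[[t$chrom]][gstarts[e]:(gstarts[e] + t$widths[e] - 1L)]))
    if (t$strand == "-") chars <- .revcompChars(chars)
    paste(chars, collapse = "")
  }

  # genome-derived sequences (lncNATs, sense-overlap artifacts); re-randomize
  # their private (non-host) region until the spliced ORF stays short
  for (id in attached) {
    t <- tx[[id]]
    priv <- t$start:(tx[[t$host]]$start - 1L)
    for (i in 1:50) {
      s <- extractTx(t)
      if (longestOrf(s)$length < 200L) break
      genomeChars[[t$chrom]][priv] <- .randBases(length(priv))
      if (i == 50L) stop("could not draw a short-ORF antisense transcript")
    }
    seqs[[id]] <- extractTx(t)
  }

  ## ---- assemble S4 objects ------------------------------------------------
  mkExons <- function(ids) {
    if (!length(ids)) return(GRangesList())
    grl <- lapply(ids, function(id) {
      t <- tx[[id]]
      gstarts <- t$start + c(0L, cumsum(t$widths[-t$n_exons] +
                                          t$introns))[seq_len(t$n_exons)]
      GRanges(t$chrom, IRanges::IRanges(gstarts, width = t$widths),
              strand = t$strand)
    })
    names(grl) <- ids
    as(GRangesList(grl), "CompressedGRangesList")
  }

  candIds <- setdiff(allIds, mrnaIds)
  candidates <- if (length(candIds))
    TranscriptSet(mkExons(candIds),
                  geneId = sprintf("XLOC_%05d", seq_along(candIds)),
                  biotype = "unknown")
  else TranscriptSet(GRangesList())

  annotated <- character(0)
  if (config$annotated_fraction > 0 && length(lncIds))
    annotated <- sample(lncIds, round(config$annotated_fraction * length(lncIds)))
  annIds <- c(mrnaIds, annotated)
  annotation <- if (length(annIds))
    TranscriptSet(setNames(mkExons(annIds),
                           c(mrnaIds, sprintf("ANNLNC_%03d", seq_along(annotated)))),
                  geneId = c(sub("MRNA", "GENE", mrnaIds),
                             sprintf("ANNLNCG_%03d", seq_along(annotated))),
                  biotype = c(rep("protein_coding", length(mrnaIds)),
                              rep("lncRNA_annotated", length(annotated))))
  else TranscriptSet(GRangesList())

  fate <- setNames(rep(NA_character_, length(allIds)), allIds)
  fate[candIds] <- "pass"
  for (cl in artClasses) fate[artIds[[cl]]] <- artFate[[cl]]
  classOf <- vapply(allIds, function(id) tx[[id]]$class, "")

  truth <- DataFrame(transcript_id = allIds,
                     biotype = classOf,
                     fate = fate,
                     annotated = allIds %in% annotated,
                     de = unname(deDir),
                     true_lfc = unname(trueLfc),
                     base_mean = unname(baseMean),
                     row.names = allIds)

  ## ---- annotation-term map with one planted enriched term -----------------
  terms <- DataFrame(gene_id = character(), term_id = character(),
                     term_name = character())
  geneOf <- setNames(sub("MRNA", "GENE", mrnaIds), mrnaIds)
  if (config$n_terms > 0L && length(mrnaIds)) {
    # the genes recovered downstream as (trans) targets of downregulated
    # lncRNAs are the downregulated mRNAs; seed the enriched term there
    pool <- geneOf[mrnaDe$down]
    k <- min(config$enriched_overlap, length(pool))
    enrichedGenes <- if (k) sample(pool, k) else character()
    fill <- sample(setdiff(geneOf, enrichedGenes),
                   min(config$term_size - k, length(geneOf) - k))
    rows <- list(DataFrame(gene_id = c(enrichedGenes, fill),
                           term_id = "TERM01",
                           term_name = "synthetic_pathway_01"))
    for (i in seq_len(config$n_terms - 1L)) {
      g <- sample(geneOf, min(config$term_size, length(geneOf)))
      rows[[i + 1L]] <- DataFrame(gene_id = g,
                                  term_id = sprintf("TERM%02d", i + 1L),
                                  term_name = sprintf("synthetic_pathway_%02d", i + 1L))
    }
    terms <- do.call(rbind, rows)
    rownames(terms) <- NULL
  }

  txSeqs <- Biostrings::DNAStringSet(unlist(seqs)[allIds])
  genome <- Biostrings::DNAStringSet(vapply(genomeChars, paste,
                                            character(1), collapse = ""))

  new("SeedAgingDataset",
      annotation = annotation, candidates = candidates,
      genome = genome, txSeqs = txSeqs,
      mirnas = Biostrings::RNAStringSet(mirnas),
      counts = NULL,
      truth = truth,
      sites = DataFrame(siteRecords),
      terms = terms,
      config = unclass(config))
}

#' Plant miRNA binding sites into transcript sequences
#'
#' Each planned site is the reverse complement of its miRNA with
#' `wobbles` G:U wobble pairs introduced outside the seed-critical region
#' (miRNA positions 2-13; position 1 is also left untouched), written into
#' the target sequence at a position drawn uniformly from the allowed
#' region. A position overlapping a previously planted site in the same
#' target is redrawn, with an error after `maxTries` attempts.
#'
#' @param seqs named character vector (or `DNAStringSet`) of target
#'   transcript sequences (DNA alphabet).
#' @param mirnas named character vector (or `RNAStringSet`) of miRNAs.
#' @param plan data.frame with columns `mirna_id`, `target_id`,
#'   `target_kind`; zero rows leave `seqs` unchanged.
#' @param wobbles G:U wobbles per site (applied where the miRNA has a G or
#'   U available outside the seed region); default 1.
#' @param regions optional named list (by target id) of `c(lo, hi)`
#'   transcript-coordinate intervals the site must lie within; default the
#'   whole transcript.
#' @param maxTries redraw budget per site; default 100.
#' @return list with `seqs` (modified named character vector) and `sites`
#'   (data.frame `mirna_id`, `target_id`, `target_kind`, `site_start`,
#'   `site_type`).
#' @export
plantMirnaSites <- function(seqs, mirnas, plan, wobbles = 1L, regions = NULL,
                            maxTries = 100L) {
  seqs <- setNames(as.character(seqs), names(seqs))
  mirnas <- setNames(as.character(mirnas), names(mirnas))
  records <- data.frame(mirna_id = character(), target_id = character(),
                        target_kind = character(), site_start = integer(),
                        site_type = character())
  if (!nrow(plan)) return(list(seqs = seqs, sites = records))
  occupied <- lapply(seqs, function(x) integer())
  for (row in seq_len(nrow(plan))) {
    mid <- plan$mirna_id[row]
    tid <- plan$target_id[row]
    m <- mirnas[[mid]]
    L <- nchar(m)
    target <- seqs[[tid]]
    if (nchar(target) <= L)
      stop("target ", tid, " shorter than the miRNA site")
    # site = DNA reverse complement of the miRNA
    mChars <- strsplit(chartr("U", "T", m), "", fixed = TRUE)[[1L]]
    site <- .revcompChars(mChars)
    siteType <- "perfect"
    if (wobbles > 0L) {
      cand <- which(seq_len(L) > 13L & mChars %in% c("G", "T"))
      cand <- cand[cand > 1L]
      if (length(cand)) {
        wob <- sample(cand, min(wobbles, length(cand)))
        for (k in wob) {
          j <- L - k + 1L  # position in the site (5'->3')
          site[j] <- if (mChars[k] == "G") "T" else "G"
        }
        siteType <- "wobble"
      }
    }
    lo <- 1L
    hi <- nchar(target) - L + 1L
    if (!is.null(regions) && tid %in% names(regions)) {
      lo <- max(lo, regions[[tid]][1L])
      hi <- min(hi, regions[[tid]][2L] - L + 1L)
    }
    if (hi < lo) stop("allowed region of ", tid, " shorter than the site")
    start <- NA_integer_
    for (i in seq_len(maxTries)) {
      s <- if (hi == lo) lo else sample(lo:hi, 1L)
      if (!any(abs(occupied[[tid]] - s) < L)) { start <- s; break }
    }
    if (is.na(start))
      stop("could not place a non-overlapping site in ", tid,
           " after ", maxTries, " attempts")
    occupied[[tid]] <- c(occupied[[tid]], start)
    substr(target, start, start + L - 1L) <- paste(site, collapse = "")
    seqs[[tid]] <- target
    records <- rbind(records,
                     data.frame(mirna_id = mid, target_id = tid,
                                target_kind = plan$target_kind[row],
                                site_start = start, site_type = siteType))
  }
  list(seqs = seqs, sites = records)
}

#' @rdname simulateCounts
#' @export
setMethod("simulateCounts", "SeedAgingDataset", function(x, config, ...) {
  if (missing(config)) config <- x@config
  se <- .simulateCountsFromTruth(x@truth, config)
  x@counts <- se
  x
})

#' @rdname simulateCounts
#' @export
setMethod("simulateCounts", "DataFrame", function(x, config, ...) {
  .simulateCountsFromTruth(x, config)
})

#' @rdname simulateCounts
#' @export
setMethod("simulateCounts", "data.frame", function(x, config, ...) {
  .simulateCountsFromTruth(DataFrame(x), config)
})

.simulateCountsFromTruth <- function(truth, config) {
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(config$seed + 1L)  # child seed of the root seed
  nrep <- config$n_replicates
  conds <- config$conditions
  condition <- rep(c(conds[["aged"]], conds[["new"]]), each = nrep)
  sampleIds <- paste0(condition, "_", rep(seq_len(nrep), 2L))
  lib <- runif(2L * nrep, config$library_size_range[1L],
               config$library_size_range[2L])
  ids <- truth$transcript_id
  n <- length(ids)
  mu <- matrix(truth$base_mean, n, 2L * nrep)
  aged <- condition == conds[["aged"]]
  mu[, aged] <- mu[, aged] * 2^truth$true_lfc
  mu <- sweep(mu, 2L, lib, "*")
  counts <- matrix(rnbinom(n * 2L * nrep, mu = as.vector(mu),
                           size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = list(ids, sampleIds))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = condition, row.names = sampleIds))
}

#' Export a synthetic dataset to plain-text files
#'
#' Writes `annotation.gtf`, `candidates.gtf`, `genome.fa`,
#' `transcripts.fa`, `counts.tsv`, `design.tsv`, `mirnas.fa`, `terms.tsv`
#' and `truth.tsv` into `dir`. Re-reading the files (e.g. with
#' [readDatasetDir()]) reproduces the in-memory objects.
#'
#' @param dataset a [SeedAgingDataset-class] with simulated counts.
#' @param dir output directory; must not already contain files unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
exportDataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is not empty (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGtf(dataset@annotation, file.path(dir, "annotation.gtf"))
  writeGtf(dataset@candidates, file.path(dir, "candidates.gtf"))
  Biostrings::writeXStringSet(dataset@genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(dataset@txSeqs, file.path(dir, "transcripts.fa"))
  Biostrings::writeXStringSet(dataset@mirnas, file.path(dir, "mirnas.fa"))
  if (!is.null(dataset@counts))
    writeExpressionTable(dataset@counts, file.path(dir, "counts.tsv"),
                         file.path(dir, "design.tsv"))
  else {
    writeLines("transcript_id", file.path(dir, "counts.tsv"))
    writeLines("sample_id\tcondition", file.path(dir, "design.tsv"))
  }
  write.table(as.data.frame(dataset@terms), file.path(dir, "terms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- as.data.frame(dataset@truth)
  tr <- cbind(record_type = rep("transcript", nrow(tr)), tr)
  si <- as.data.frame(dataset@sites)
  if (nrow(si)) {
    si <- cbind(record_type = "site", si)
    cols <- union(colnames(tr), colnames(si))
    for (cl in setdiff(cols, colnames(tr))) tr[[cl]] <- NA
    for (cl in setdiff(cols, colnames(si))) si[[cl]] <- NA
    all <- rbind(tr[, cols], si[, cols])
  } else all <- tr
  rownames(all) <- NULL
  write.table(all, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(dir)
}

#' Read an exported dataset directory back into memory
#'
#' @param dir directory written by [exportDataset()].
#' @return list with elements `annotation`, `candidates`
#'   ([TranscriptSet-class]), `genome`, `txSeqs` (`DNAStringSet`),
#'   `mirnas` (`RNAStringSet`), `counts` (`SummarizedExperiment`), `terms`,
#'   `truth`, `sites` (data.frames).
#' @export
readDatasetDir <- function(dir) {
  truthAll <- read.delim(file.path(dir, "truth.tsv"),
                         colClasses = "character", na.strings = "")
  isSite <- truthAll$record_type == "site"
  truth <- truthAll[!isSite, intersect(c("transcript_id", "biotype", "fate",
                                         "annotated", "de", "true_lfc",
                                         "base_mean"), colnames(truthAll))]
  truth$annotated <- truth$annotated == "TRUE"
  truth$true_lfc <- as.numeric(truth$true_lfc)
  truth$base_mean <- as.numeric(truth$base_mean)
  rownames(truth) <- truth$transcript_id
  sites <- truthAll[isSite, intersect(c("mirna_id", "target_id", "target_kind",
                                        "site_start", "site_type"),
                                      colnames(truthAll))]
  if (nrow(sites)) sites$site_start <- as.integer(sites$site_start)
  rownames(sites) <- NULL
  countsPath <- file.path(dir, "counts.tsv")
  counts <- NULL
  if (length(readLines(countsPath, n = 2L)) > 1L)
    counts <- readExpressionTable(countsPath, file.path(dir, "design.tsv"))
  list(annotation = readGtf(file.path(dir, "annotation.gtf")),
       candidates = readGtf(file.path(dir, "candidates.gtf")),
       genome = readFasta(file.path(dir, "genome.fa")),
       txSeqs = readFasta(file.path(dir, "transcripts.fa")),
       mirnas = readFasta(file.path(dir, "mirnas.fa"), alphabet = "RNA"),
       counts = counts,
       terms = read.delim(file.path(dir, "terms.tsv"),
                          colClasses = "character"),
       truth = truth, sites = sites)
}
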