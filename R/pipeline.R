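#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Collects every stage threshold of the seed-aging lncRNA pipeline, with
#' defaults equal to the study's published criteria: exon count >= 2,
#' length >= 200 nt, FPKM >= 0.5, |log2FC| > 1 with p < 0.05, a 100 kb cis
#' window, trans co-expression at PCC > 0.95 with p < 0.01, and enrichment
#' significance at p < 0.05.
#'
#' @param seed root seed for the run (drives the synthetic stage).
#' @param input_dir optional directory of an exported dataset
#'   ([exportDataset()] layout); when `NULL` a synthetic dataset is
#'   generated into the run directory.
#' @param synthetic list of [syntheticConfig()] overrides for the synth
#'   stage (its `seed` is always set to `seed`).
#' @param exon_min,len_min,fpkm_min,fpkm_aggregate identification-cascade
#'   thresholds (see [filterCascade()]).
#' @param lfc_threshold,p_threshold,use_adjusted differential-expression
#'   call thresholds (see [callDEL()]).
#' @param cis_window cis co-localization window, bases.
#' @param pcc_r,pcc_p trans co-expression thresholds.
#' @param energy_cutoff,expectation_cutoff miRNA scanning cutoffs
#'   (see [scanTargets()]).
#' @param enrich_p enrichment significance threshold.
#' @param conditions named vector `c(aged = , new = )` of condition labels.
#' @return config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, input_dir = NULL, synthetic = list(),
                           exon_min = 2L, len_min = 200L, fpkm_min = 0.5,
                           fpkm_aggregate = "max",
                           lfc_threshold = 1, p_threshold = 0.05,
                           use_adjusted = FALSE,
                           cis_window = 100000L, pcc_r = 0.95, pcc_p = 0.01,
                           energy_cutoff = -34, expectation_cutoff = 5,
                           enrich_p = 0.05,
                           conditions = c(aged = "S50", new = "S96")) {
  cfg <- list(seed = as.integer(seed), input_dir = input_dir,
              synthetic = synthetic, exon_min = exon_min, len_min = len_min,
              fpkm_min = fpkm_min, fpkm_aggregate = fpkm_aggregate,
              lfc_threshold = lfc_threshold, p_threshold = p_threshold,
              use_adjusted = use_adjusted, cis_window = cis_window,
              pcc_r = pcc_r, pcc_p = pcc_p, energy_cutoff = energy_cutoff,
              expectation_cutoff = expectation_cutoff, enrich_p = enrich_p,
              conditions = conditions)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipelineConfig()] arguments; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return config list of class `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$conditions)) vals$conditions <- unlist(vals$conditions)
  do.call(pipelineConfig, vals)
}

#' Run the full seed-aging lncRNA pipeline
#'
#' Executes, in fixed order: synthetic data generation (unless an input
#' directory is supplied), lncRNA identification, differential expression,
#' cis/trans target prediction, ceRNA network assembly, and term
#' enrichment. Every stage writes its outputs into `outDir`; a failing
#' stage aborts with its name and cause, renaming that stage's partial
#' outputs to `*.partial`. The final `report.tsv` summarizes per-stage
#' counts and, when planted truth is available, recovery metrics
#' (precision/recall of the identified lncRNA set, recovered DE direction
#' counts, planted site and triplet recall). Runs are deterministic for a
#' fixed seed and configuration.
#'
#' @param config a [pipelineConfig()], or the path to a YAML file for
#'   [readPipelineConfig()].
#' @param outDir run directory (created; existing files are overwritten).
#' @return invisibly, a list with `report` (data.frame) and the stage
#'   result objects (`cascade`, `de`, `cis`, `trans`, `network`,
#'   `enrichment`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "config_resolved.yaml"))

  runStage <- function(name, expr) {
    before <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      created <- setdiff(list.files(outDir, recursive = TRUE,
                                    full.names = TRUE), before)
      for (f in created) file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  ## synth ------------------------------------------------------------------
  dataDir <- config$input_dir
  if (is.null(dataDir)) {
    dataDir <- file.path(outDir, "data")
    runStage("synth", {
      scfg <- do.call(syntheticConfig,
                      modifyList(config$synthetic,
                                 list(seed = config$seed,
                                      conditions = config$conditions)))
      ds <- simulateCounts(generateDataset(scfg))
      exportDataset(ds, dataDir, overwrite = TRUE)
    })
  }
  d <- runStage("load", readDatasetDir(dataDir))
  candidates <- d$candidates
  annotation <- d$annotation
  counts <- d$counts
  if (is.null(counts)) stop("stage 'load' failed: no counts in ", dataDir)

  ## identify ---------------------------------------------------------------
  lengths <- c(txLengths(candidates), txLengths(annotation))
  lengths <- lengths[!duplicated(names(lengths))]
  fpkmSe <- computeFpkm(counts, lengths)
  fpkm <- SummarizedExperiment::assay(fpkmSe, "fpkm")
  casc <- runStage("identify", {
    coding <- codingPotential(d$txSeqs[names(candidates)])
    out <- filterCascade(candidates, fpkm[names(candidates), , drop = FALSE],
                         annotation, coding,
                         minExons = config$exon_min,
                         minLength = config$len_min,
                         fpkmMin = config$fpkm_min,
                         fpkmAggregate = config$fpkm_aggregate)
    write.table(as.data.frame(out$records),
                file.path(outDir, "lncrna_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(filterSummary(out$report),
                file.path(outDir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })
  lncIds <- survivors(casc$report)

  ## differential expression ------------------------------------------------
  mrnaIds <- intersect(names(annotation)[txBiotype(annotation) == "protein_coding"],
                       rownames(fpkm))
  de <- runStage("de", {
    res <- nbTest(counts, case = config$conditions[["aged"]],
                  ref = config$conditions[["new"]],
                  lfcThreshold = config$lfc_threshold,
                  pThreshold = config$p_threshold,
                  useAdjusted = config$use_adjusted)
    write.table(as.data.frame(res), file.path(outDir, "de_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  del <- callDEL(de[lncIds, , drop = FALSE], config$lfc_threshold,
                 config$p_threshold, config$use_adjusted)
  deg <- callDEL(de[mrnaIds, , drop = FALSE], config$lfc_threshold,
                 config$p_threshold, config$use_adjusted)

  ## targets ----------------------------------------------------------------
  codingAnn <- annotation[txBiotype(annotation) == "protein_coding"]
  cis <- runStage("targets", {
    cis <- cisTargets(candidates[lncIds], codingAnn, window = config$cis_window)
    write.table(cis, file.path(outDir, "cis_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cis
  })
  trans <- runStage("targets_trans", {
    tr <- transTargets(fpkm[lncIds, , drop = FALSE],
                       fpkm[mrnaIds, , drop = FALSE],
                       rMin = config$pcc_r, pMax = config$pcc_p)
    write.table(tr, file.path(outDir, "trans_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tr
  })

  ## ceRNA network ----------------------------------------------------------
  deLnc <- c(del$up, del$down)
  deMrna <- c(deg$up, deg$down)
  net <- runStage("cerna", {
    lncHits <- scanTargetSet(d$mirnas, d$txSeqs[deLnc], mode = "lncRNA",
                             energyCutoff = config$energy_cutoff)
    mrnaHits <- scanTargetSet(d$mirnas, d$txSeqs[deMrna], mode = "mRNA",
                              expectationCutoff = config$expectation_cutoff)
    hits <- rbind(lncHits, mrnaHits)
    write.table(hits, file.path(outDir, "mirna_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    net <- buildCernaNetwork(lncHits, mrnaHits,
                             deFilter = list(lncrna = deLnc, mrna = deMrna))
    write.table(net$triplets, file.path(outDir, "cerna_triplets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeEdgeList(net$edges, file.path(outDir, "cerna_edges.tsv"))
    c(net, list(hits = hits))
  })

  ## enrichment ---------------------------------------------------------------
  geneOfMrna <- setNames(unname(geneIds(annotation)[mrnaIds]), mrnaIds)
  enr <- runStage("enrich", {
    population <- unique(geneOfMrna)
    runOne <- function(study, tag) {
      study <- intersect(unique(study[!is.na(study)]), population)
      res <- if (length(study) && nrow(d$terms))
        enrich(study, population, d$terms, pThreshold = config$enrich_p)
      else data.frame()
      write.table(res, file.path(outDir, paste0("enrichment_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(res)) {
        dot <- res[, c("term_id", "rich_factor", "p", "k")]
        colnames(dot) <- c("term", "rich_factor", "p", "count")
        write.table(dot,
                    file.path(outDir, paste0("enrichment_", tag, "_dotplot.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      res
    }
    list(cis = runOne(cis$gene_id[cis$lncrna_id %in% del$down], "cis"),
         trans = runOne(geneOfMrna[trans$gene_id[trans$lncrna_id %in% del$down]],
                        "trans"))
  })

  ## report -------------------------------------------------------------------
  report <- data.frame(metric = character(), value = numeric())
  addMetric <- function(metric, value)
    report <<- rbind(report, data.frame(metric = metric,
                                        value = as.numeric(value)))
  addMetric("candidates_in", length(candidates))
  addMetric("lncrnas_identified", length(lncIds))
  addMetric("lncrna_lincRNA", sum(casc$records$cls == "lincRNA"))
  addMetric("lncrna_lncNAT", sum(casc$records$cls == "lncNAT"))
  addMetric("del_up", length(del$up))
  addMetric("del_down", length(del$down))
  addMetric("deg_up", length(deg$up))
  addMetric("deg_down", length(deg$down))
  addMetric("cis_pairs", nrow(cis))
  addMetric("trans_pairs", nrow(trans))
  addMetric("cerna_lncrnas", net$summary$n_lncrna)
  addMetric("cerna_mirnas", net$summary$n_mirna)
  addMetric("cerna_mrnas", net$summary$n_mrna)
  addMetric("cerna_triplets", net$summary$n_triplets)
  addMetric("enriched_terms_cis",
            if (nrow(enr$cis)) sum(enr$cis$significant) else 0)
  addMetric("enriched_terms_trans",
            if (nrow(enr$trans)) sum(enr$trans$significant) else 0)

  truth <- d$truth
  if (!is.null(truth) && nrow(truth)) {
    truthPass <- truth$transcript_id[!is.na(truth$fate) & truth$fate == "pass"]
    tp <- length(intersect(lncIds, truthPass))
    addMetric("identify_precision", if (length(lncIds)) tp / length(lncIds) else NA)
    addMetric("identify_recall", if (length(truthPass)) tp / length(truthPass) else NA)
    lncTruth <- truth[truth$transcript_id %in% truthPass, ]
    addMetric("del_up_recall",
              if (sum(lncTruth$de == "up"))
                length(intersect(del$up, lncTruth$transcript_id[lncTruth$de == "up"])) /
                  sum(lncTruth$de == "up") else NA)
    addMetric("del_down_recall",
              if (sum(lncTruth$de == "down"))
                length(intersect(del$down, lncTruth$transcript_id[lncTruth$de == "down"])) /
                  sum(lncTruth$de == "down") else NA)
    if (nrow(d$sites)) {
      hitKey <- paste(net$hits$mirna_id, net$hits$target_id, net$hits$site_start)
      siteKey <- paste(d$sites$mirna_id, d$sites$target_id, d$sites$site_start)
      addMetric("site_recall", mean(siteKey %in% hitKey))
      planted <- .plannedTriplets(d$sites)
      if (nrow(planted)) {
        netKey <- paste(net$triplets$lncrna_id, net$triplets$mirna_id,
                        net$triplets$mrna_id)
        plantedKey <- paste(planted$lncrna_id, planted$mirna_id, planted$mrna_id)
        addMetric("triplet_recall", mean(plantedKey %in% netKey))
      }
    }
  }
  write.table(report, file.path(outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(report = report, cascade = casc, de = de, del = del,
                 deg = deg, cis = cis, trans = trans, network = net,
                 enrichment = enr, dataDir = dataDir))
}

# planted (lncRNA, miRNA, mRNA) triplets implied by the planted site table
.plannedTriplets <- function(sites) {
  ln <- sites[sites$target_kind == "lncRNA", ]
  mr <- sites[sites$target_kind == "mRNA", ]
  out <- merge(data.frame(mirna_id = ln$mirna_id, lncrna_id = ln$target_id),
               data.frame(mirna_id = mr$mirna_id, mrna_id = mr$target_id),
               by = "mirna_id")
  unique(out[, c("lncrna_id", "mirna_id", "mrna_id")])
}
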