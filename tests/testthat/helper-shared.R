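# Shared fixtures, memoized so the expensive default-scale dataset and
# pipeline run are built once per test session.
.shared <- new.env(parent = emptyenv())

sharedDataset <- function() {
  if (is.null(.shared$ds))
    .shared$ds <- simulateCounts(generateDataset(syntheticConfig()))
  .shared$ds
}

sharedFpkm <- function() {
  if (is.null(.shared$fpkm)) {
    ds <- sharedDataset()
    lens <- c(txLengths(ds@candidates), txLengths(ds@annotation))
    lens <- lens[!duplicated(names(lens))]
    .shared$fpkm <- computeFpkm(SummarizedExperiment::assay(ds@counts), lens)
  }
  .shared$fpkm
}

sharedCascade <- function() {
  if (is.null(.shared$cascade)) {
    ds <- sharedDataset()
    coding <- codingPotential(ds@txSeqs[names(ds@candidates)])
    .shared$cascade <- filterCascade(
      ds@candidates, sharedFpkm()[names(ds@candidates), ], ds@annotation,
      coding)
  }
  .shared$cascade
}

sharedPipeline <- function() {
  if (is.null(.shared$pipe)) {
    dir <- file.path(tempdir(), "shared_pipeline_run")
    .shared$pipe <- suppressMessages(
      runPipeline(pipelineConfig(seed = 1L), dir))
    .shared$pipeDir <- dir
  }
  .shared$pipe
}

sharedPipelineDir <- function() {
  sharedPipeline()
  .shared$pipeDir
}

# null-simulation results (5000 transcripts, 3+3, NB alpha = 0.1), shared
# between the calibration tests
sharedNullP <- function() {
  if (is.null(.shared$nullP)) {
    set.seed(20260925L)
    n <- 5000L
    mu <- exp(rnorm(n, log(500), 1))
    cnt <- matrix(rnbinom(n * 6L, mu = rep(mu, 6L), size = 10),
                  nrow = n, dimnames = list(paste0("t", seq_len(n)), NULL))
    colnames(cnt) <- paste0("s", 1:6)
    .shared$nullP <- nbTest(cnt, rep(c("A", "B"), each = 3L))$p
  }
  .shared$nullP
}

# small, fast generator configuration for structural tests
smallConfig <- function(seed = 11L, ...) {
  syntheticConfig(n_chrom = 2L, chrom_length = 6e5, n_mrna = 40L,
                  n_lncrna = 30L, contaminants_per_class = 2L,
                  de_config = list(n_up_lnc = 2L, n_down_lnc = 20L,
                                   n_up_mrna = 2L, n_down_mrna = 10L,
                                   lfc_range = c(2, 4)),
                  n_mirna = 6L, n_planted_triplets = 4L,
                  n_terms = 8L, term_size = 10L, enriched_overlap = 8L,
                  seed = seed, ...)
}
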