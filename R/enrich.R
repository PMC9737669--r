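#' @include AllClasses.R
NULL

#' Hypergeometric upper-tail probability, computed in log space
#'
#' `P(X >= k)` for the number of annotated genes drawn when `n` study genes
#' are sampled without replacement from a population of `N` genes of which
#' `K` carry the annotation:
#' `sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`, accumulated via
#' log-binomials and log-sum-exp for numerical stability.
#'
#' @param k observed study genes in the term (>= 0).
#' @param K population genes in the term.
#' @param n study size.
#' @param N population size.
#' @return upper-tail probability in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeomP(4, 5, 4, 10)  # 5/210
#' @export
hypergeomP <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, k >= 0, K >= 0, n >= 0, N >= 0)
  if (K > N || n > N || k > min(n, K))
    stop("inconsistent hypergeometric arguments")
  if (k == 0) return(1)  # the upper tail covers every outcome
  i <- seq.int(k, min(n, K))
  i <- i[n - i <= N - K]          # terms with impossible complements vanish
  if (!length(i)) return(0)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Term enrichment of a study gene set with rich factors
#'
#' One hypergeometric upper-tail test per annotation term containing at
#' least one study gene, Benjamini-Hochberg adjustment across tested terms,
#' and the rich factor `k / K` (study genes in the term over all annotated
#' genes in the term). Terms with raw `p < pThreshold` are flagged
#' significant, mirroring the usual GO/KEGG reporting; `q` is reported
#' alongside.
#'
#' @param studyGenes character vector of study gene ids (must be a subset
#'   of `populationGenes`).
#' @param populationGenes character vector: the background population
#'   (e.g. all annotated genes).
#' @param termMap data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param pThreshold significance threshold on raw p; default 0.05.
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p`, `q`, `rich_factor`, `significant`; zero rows (with a
#'   warning) for an empty study set.
#' @export
enrich <- function(studyGenes, populationGenes, termMap, pThreshold = 0.05) {
  studyGenes <- unique(as.character(studyGenes))
  populationGenes <- unique(as.character(populationGenes))
  offenders <- setdiff(studyGenes, populationGenes)
  if (length(offenders))
    stop("study gene(s) outside the population: ",
         paste(head(offenders, 5), collapse = ", "))
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      rich_factor = numeric(), significant = logical())
  if (!length(studyGenes)) {
    warning("empty study set")
    return(empty)
  }
  termMap <- termMap[termMap$gene_id %in% populationGenes, , drop = FALSE]
  if (is.null(termMap$term_name)) termMap$term_name <- termMap$term_id
  n <- length(studyGenes)
  N <- length(populationGenes)
  byTerm <- split(termMap, termMap$term_id)
  rows <- lapply(byTerm, function(tm) {
    genes <- unique(tm$gene_id)
    k <- sum(studyGenes %in% genes)
    if (k == 0L) return(NULL)
    K <- length(genes)
    data.frame(term_id = tm$term_id[1L], term_name = tm$term_name[1L],
               k = k, n = n, K = K, N = N,
               p = hypergeomP(k, K, n, N), rich_factor = k / K)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < pThreshold
  out <- out[order(out$p, out$term_id, method = "radix"),
             c("term_id", "term_name", "k", "n", "K", "N", "p", "q",
               "rich_factor", "significant")]
  rownames(out) <- NULL
  out
}
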