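# GO-term enrichment of a gene subset (secretome) against the genome:
# one-sided (over-representation) Fisher exact test computed as an exact
# upper-tail hypergeometric sum in log space, Bonferroni-corrected over the
# number of terms actually tested.  The genome column includes the subset
# (a + c is the genome-wide term count), matching tables where the
# genome-wide count is always >= the subset count.

#' Build a 2x2 contingency table for one term
#'
#' `a` = subset genes with the term, `b` = subset genes without it,
#' `c` = non-subset genes with it, `d` = the rest.
#'
#' @param term term id.
#' @param gene2go data.frame with columns `gene_id`, `term`.
#' @param subset character vector of subset gene ids.
#' @param genes optional full genome gene universe; defaults to the genes
#'   seen in `gene2go` united with `subset`.
#' @return list of class `rb_contingency` with `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(term, gene2go, subset, genes = NULL) {
  if (is.null(genes)) genes <- union(unique(gene2go$gene_id), subset)
  if (!all(subset %in% genes))
    rb_stop("subset gene absent from the genome gene set", "rb_value_error")
  with_term <- unique(gene2go$gene_id[gene2go$term == term])
  a <- length(intersect(with_term, subset))
  b <- length(subset) - a
  c_ <- length(with_term) - a
  d <- length(genes) - length(subset) - c_
  structure(list(a = a, b = b, c = c_, d = d), class = "rb_contingency")
}

#' One-sided Fisher exact test (enrichment)
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for a population of
#' `a+b+c+d` genes with `a+c` successes and `a+b` draws, summed exactly in
#' log space.  A zero margin gives `p = 1` by convention.
#'
#' @param ct `rb_contingency` or list/vector with `a`, `b`, `c`, `d`.
#' @return raw p-value.
#' @export
#' @examples
#' fisher_one_sided(list(a = 6, b = 464, c = 3, d = 14455))
fisher_one_sided <- function(ct) {
  a <- ct$a; b <- ct$b; c_ <- ct$c; d <- ct$d
  if (min(a, b, c_, d) < 0) rb_stop("negative cell count", "rb_value_error")
  N <- a + b + c_ + d
  K <- a + c_      # successes in population
  n <- a + b       # draws
  if (K == 0L || n == 0L || K == N || n == N) return(1)
  hi <- min(K, n)
  if (a == 0L) return(1)
  x <- a:hi
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, exp(logsumexp(lp)))
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values.
#' @param m number of tests (default `length(p)`).
#' @return `pmin(1, m * p)`, order preserved.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1L) rb_stop("m must be >= 1", "rb_value_error")
  pmin(1, m * p)
}

#' Per-term enrichment report
#'
#' Tests every term with at least `min_genome_count` genome-wide genes;
#' rows are sorted by raw p then term id, Bonferroni-corrected over the
#' number of tested terms, and flagged significant at `alpha`.
#'
#' @param gene2go data.frame with columns `gene_id`, `term`.
#' @param subset character vector of subset gene ids.
#' @param alpha family-wise significance level.
#' @param min_genome_count minimum genome-wide gene count for a term to be
#'   tested.
#' @param genes optional gene universe (see [build_contingency()]).
#' @return data.frame: `term`, `a`, `subset_size`, `genome_count`,
#'   `genome_size`, `p_raw`, `p_corrected`, `significant`, `m_tested`.
#' @export
enrich_report <- function(gene2go, subset, alpha = 0.05, min_genome_count = 1L,
                          genes = NULL) {
  if (is.null(genes)) genes <- union(unique(gene2go$gene_id), subset)
  terms <- sort(unique(gene2go$term))
  counts <- table(gene2go$term[!duplicated(paste(gene2go$term, gene2go$gene_id))])
  terms <- terms[counts[terms] >= min_genome_count]
  if (!length(terms))
    return(data.frame(term = character(0), a = integer(0), subset_size = integer(0),
                      genome_count = integer(0), genome_size = integer(0),
                      p_raw = numeric(0), p_corrected = numeric(0),
                      significant = logical(0), m_tested = integer(0)))
  rows <- lapply(terms, function(tm) {
    ct <- build_contingency(tm, gene2go, subset, genes)
    data.frame(term = tm, a = ct$a, subset_size = ct$a + ct$b,
               genome_count = ct$a + ct$c, genome_size = ct$a + ct$b + ct$c + ct$d,
               p_raw = fisher_one_sided(ct), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_corrected <- bonferroni(res$p_raw, m)
  res$significant <- res$p_corrected <= alpha
  res$m_tested <- m
  res <- res[order(res$p_raw, res$term), ]
  rownames(res) <- NULL
  res
}
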