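#' Upper-tail cumulative hypergeometric probability
#'
#' Probability of observing `k` or more annotated genes in a draw of `n`
#' genes from a universe of `N` genes of which `K` are annotated, i.e.
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed through the
#' survival function, which is numerically stable for extreme tails.
#'
#' @param k Observed overlap (non-negative integer).
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N) {
    stop("invalid hypergeometric parameters: k=", k, " K=", K, " n=", n, " N=", N)
  }
  if (k <= 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Bonferroni correction for a single p-value
#'
#' @param p Raw p-value in \[0, 1\].
#' @param m Number of tests in the family (>= 1).
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0), all(p <= 1), m >= 1)
  pmin(1, p * m)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' the result is returned in the input order.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues >= 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

enrichment_table <- function(query, gs, min_set_size = 2L) {
  # one hypergeometric upper-tail test per term; query restricted to universe
  query <- intersect(query, gs$universe)
  N <- length(gs$universe)
  n <- length(query)
  terms <- names(gs$sets)
  keep <- vapply(gs$sets, length, 0L) >= min_set_size
  terms <- terms[keep]
  if (length(terms) == 0L || n == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric()))
  }
  K <- vapply(gs$sets[terms], length, 0L)
  k <- vapply(gs$sets[terms], function(s) length(intersect(s, query)), 0L)
  p <- mapply(hypergeom_upper_tail, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  data.frame(term_id = terms,
             term_name = unname(gs$term_names[terms]),
             k = unname(k), K = unname(K), n = n, N = N,
             p_raw = unname(p), row.names = NULL)
}

#' Identify disease-associated gene-set terms
#'
#' Tests every term of the collection for enrichment of the disease gene
#' list (restricted to the universe) with the cumulative hypergeometric
#' test, applies Bonferroni correction over the number of terms tested, and
#' returns terms significant at `alpha`, sorted by ascending adjusted p
#' (ties broken by term id). Terms with fewer than two universe genes are
#' skipped as untestable.
#'
#' @param go A `gene_sets` collection.
#' @param disease Character vector of disease-associated gene ids.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_adj`, `method`.
#' @export
disease_go_terms <- function(go, disease, alpha = 0.05) {
  query <- intersect(disease, go$universe)
  if (length(query) == 0L) {
    stop("no disease gene is present in the universe")
  }
  tab <- enrichment_table(query, go)
  if (nrow(tab) == 0L) return(cbind(tab, p_adj = numeric(0), method = character(0)))
  tab$p_adj <- bonferroni(tab$p_raw, nrow(tab))
  tab$method <- "bonferroni"
  tab <- tab[tab$p_adj < alpha, , drop = FALSE]
  tab <- tab[order(tab$p_adj, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Test a gene set for functional homogeneity
#'
#' A gene set is functionally homogeneous when it is significantly enriched
#' in at least one term of the collection after Benjamini-Hochberg
#' correction across all terms (q < `q_cutoff`). Genes outside the universe
#' are ignored.
#'
#' @param genes Character vector of gene ids.
#' @param go A `gene_sets` collection.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @return List with `homogeneous` (logical) and `best` (one-row data frame
#'   for the best term with `p_adj` = its q-value, or `NULL` when no gene
#'   overlaps the universe or the collection is empty).
#' @export
functional_homogeneity <- function(genes, go, q_cutoff = 0.05) {
  query <- intersect(genes, go$universe)
  if (length(query) == 0L) return(list(homogeneous = FALSE, best = NULL))
  tab <- enrichment_table(query, go)
  if (nrow(tab) == 0L) return(list(homogeneous = FALSE, best = NULL))
  tab$p_adj <- bh_fdr(tab$p_raw)
  tab$method <- "bh_fdr"
  best <- tab[order(tab$p_adj, tab$p_raw, tab$term_id), , drop = FALSE][1L, ]
  rownames(best) <- NULL
  list(homogeneous = best$p_adj < q_cutoff, best = best)
}
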