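#' Rank modules within one category by aggregated objective ranks
#'
#' Each module receives three ranks: `R1` ascending in FP, `R2` ascending
#' in FC, `R3` ascending in FF (all objectives are minimized, so rank 1 is
#' best on each). Ties receive the mean (fractional) rank. The final score
#' is the weighted sum `S = alpha*R1 + beta*R2 + gamma*R3` with equal
#' default weights 1/3; the output is sorted best-first (ascending S), ties
#' broken by comodule id then bit string.
#'
#' @param mfrms List of `mfrm` objects, all of one category.
#' @param weights Numeric length-3 vector `(alpha, beta, gamma)`,
#'   non-negative with positive sum.
#' @return Data frame: `category`, `comodule_id`, `mfrm` (list column),
#'   `R1`, `R2`, `R3`, `S`, `FP`, `FC`, `FF`, `m_sel`, `n_sel`.
#' @export
rank_mfrms <- function(mfrms, weights = c(1, 1, 1) / 3) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  if (length(mfrms) == 0L) {
    return(data.frame(category = character(), comodule_id = character(),
                      R1 = numeric(), R2 = numeric(), R3 = numeric(),
                      S = numeric(), FP = numeric(), FC = numeric(),
                      FF = numeric(), m_sel = integer(), n_sel = integer()))
  }
  FP <- vapply(mfrms, function(x) x$objectives$FP, 0)
  FC <- vapply(mfrms, function(x) x$objectives$FC, 0)
  FF <- vapply(mfrms, function(x) x$objectives$FF, 0)
  R1 <- rank(FP, ties.method = "average")
  R2 <- rank(FC, ties.method = "average")
  R3 <- rank(FF, ties.method = "average")
  S <- weights[1L] * R1 + weights[2L] * R2 + weights[3L] * R3
  bits <- vapply(mfrms, function(x) paste(x$selection, collapse = ""), "")
  cid <- vapply(mfrms, function(x) as.character(x$comodule_id), "")
  ord <- order(S, cid, bits)
  out <- data.frame(
    category = vapply(mfrms, function(x) as.character(x$category), ""),
    comodule_id = cid, R1 = R1, R2 = R2, R3 = R3, S = S,
    FP = FP, FC = FC, FF = FF,
    m_sel = vapply(mfrms, function(x) as.integer(x$objectives$m_sel), 0L),
    n_sel = vapply(mfrms, function(x) as.integer(x$objectives$n_sel), 0L))
  out$mfrm <- mfrms
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition modules by category and rank each category independently
#'
#' @param all_mfrms List of `mfrm` objects (any mix of categories).
#' @param weights Passed to [rank_mfrms()].
#' @return Named list: one ranked data frame per category present.
#' @export
categorize_and_rank <- function(all_mfrms, weights = c(1, 1, 1) / 3) {
  if (length(all_mfrms) == 0L) return(list())
  cats <- vapply(all_mfrms, function(x) as.character(x$category), "")
  lapply(split(all_mfrms, cats), rank_mfrms, weights = weights)
}

#' Build the bipartite miRNA-mRNA regulatory network of a module
#'
#' A miRNA-gene pair of the module is connected by an edge when it
#' concurrently shows (i) a significant negative expression correlation
#' across the comodule's samples (`c < 0`, `p < 0.05`) and (ii) a predicted
#' targeting relationship in at least one prediction source (`t > 0`).
#' Members incident to no edge are omitted from the node sets.
#'
#' @param mfrm An `mfrm`.
#' @param ctx The `comodule_context` of the module's parent comodule.
#' @param alpha_edge Significance level on the correlation p-value.
#' @return A list of class `regulatory_network` with `mirna_nodes`,
#'   `gene_nodes`, `edges` (data frame `mirna`, `gene`, `c`, `p`, `t`) and
#'   `parent_mfrm`.
#' @export
build_network <- function(mfrm, ctx, alpha_edge = 0.05) {
  mi <- mfrm$mirna_ids
  mr <- mfrm$gene_ids
  edges <- data.frame(mirna = character(), gene = character(),
                      c = numeric(), p = numeric(), t = numeric())
  if (length(mi) > 0L && length(mr) > 0L) {
    C <- ctx$corr[mi, mr, drop = FALSE]
    P <- ctx$corr_p[mi, mr, drop = FALSE]
    T_ <- ctx$targets[mi, mr, drop = FALSE]
    hit <- which(C < 0 & P < alpha_edge & T_ > 0, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      edges <- data.frame(mirna = mi[hit[, 1L]], gene = mr[hit[, 2L]],
                          c = C[hit], p = P[hit], t = T_[hit])
      edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(mirna_nodes = sort(unique(edges$mirna)),
                 gene_nodes = sort(unique(edges$gene)),
                 edges = edges,
                 parent_mfrm = paste0(as.character(mfrm$comodule_id), "-",
                                      paste(mfrm$selection, collapse = ""))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", length(x$mirna_nodes), "miRNAs,",
      length(x$gene_nodes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

regulatory_igraph <- function(net) {
  verts <- data.frame(name = c(net$mirna_nodes, net$gene_nodes),
                      type = c(rep("mirna", length(net$mirna_nodes)),
                               rep("gene", length(net$gene_nodes))))
  igraph::graph_from_data_frame(net$edges, directed = TRUE, vertices = verts)
}

#' Write a regulatory network to disk
#'
#' Formats: `"sif"` (lines `mirna<TAB>targets<TAB>gene`), `"graphml"`
#' (node-type attribute plus edge attributes `c`, `p`, `t`, via igraph) and
#' `"tsv"` (edge list with all attributes). Node and edge ordering is
#' deterministic (lexicographically sorted).
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- net$edges[order(net$edges$mirna, net$edges$gene), , drop = FALSE]
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$mirna, "targets", e$gene, sep = "\t")
               else character(0), path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(regulatory_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML regulatory network back
#'
#' Inverse of [write_network()] with `format = "graphml"`.
#'
#' @param path GraphML file path.
#' @return A `regulatory_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vattr <- igraph::vertex_attr(g)
  edf <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(mirna = edf$from, gene = edf$to,
                      c = edf$c, p = edf$p, t = edf$t)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(mirna_nodes = sort(vattr$name[vattr$type == "mirna"]),
                 gene_nodes = sort(vattr$name[vattr$type == "gene"]),
                 edges = edges, parent_mfrm = NA_character_),
            class = "regulatory_network")
}

#' Most frequently active miRNAs and genes per category
#'
#' Counts, within each category, how often each miRNA and each gene appears
#' across that category's modules, and returns the tables sorted by
#' descending count (ties by id), truncated to the requested top sizes.
#'
#' @param ranked Named list of ranked data frames from
#'   [categorize_and_rank()] (the `mfrm` list column is used).
#' @param top_k_mi,top_k_mr Truncation sizes (defaults 15 and 50).
#' @return Named list per category: list with `mirnas` and `genes` data
#'   frames (`id`, `count`).
#' @export
active_members <- function(ranked, top_k_mi = 15L, top_k_mr = 50L) {
  count_table <- function(ids, top_k) {
    if (length(ids) == 0L) {
      return(data.frame(id = character(), count = integer()))
    }
    tab <- table(ids)
    out <- data.frame(id = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$id), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, top_k)
  }
  lapply(ranked, function(df) {
    mfrms <- df$mfrm
    list(mirnas = count_table(unlist(lapply(mfrms, `[[`, "mirna_ids")), top_k_mi),
         genes = count_table(unlist(lapply(mfrms, `[[`, "gene_ids")), top_k_mr))
  })
}
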