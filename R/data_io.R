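#' Read an expression matrix half with sample annotations
#'
#' Reads one side of a paired expression data set (either the mRNA or the
#' miRNA matrix) from a tab-separated file whose first column holds feature
#' identifiers and whose header row holds sample identifiers, together with a
#' two-column annotation table assigning each sample a subtype label.
#'
#' Samples are matched to annotations by identifier, not by position, so the
#' two files may list samples in different orders. Rows containing missing
#' values are dropped with a message (the downstream module discovery assumes
#' complete matrices). Files may be gzip-compressed.
#'
#' @param path Path to the expression TSV (features x samples, header row).
#' @param annotation_path Path to a two-column TSV `sample_id<TAB>subtype`
#'   (no header).
#' @return A list of class `expression_half` with elements `mat` (numeric
#'   matrix, features x samples, dimnames set) and `subtype_of` (named
#'   character vector mapping sample id to subtype label).
#' @export
read_expression <- function(path, annotation_path) {
  check_readable(path)
  check_readable(annotation_path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file must have at least one sample column: ", path)
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate feature id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in header of ", path)
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !(trimws(col) %in% c("", "NA", "NaN")))
    if (length(bad) > 0L) {
      stop("non-numeric value ", dQuote(col[bad[1L]]), " in ", path,
           " at row ", bad[1L], " (feature ", ids[bad[1L]], "), column ",
           sample_ids[j])
    }
    mat[, j] <- num
  }
  incomplete <- !stats::complete.cases(mat)
  if (any(incomplete)) {
    message(sum(incomplete), " feature row(s) with missing values dropped from ", path)
    mat <- mat[!incomplete, , drop = FALSE]
  }

  ann <- utils::read.delim(annotation_path, header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(ann) < 2L) stop("annotation file must have two columns: ", annotation_path)
  subtype_of <- stats::setNames(ann[[2L]], ann[[1L]])
  missing_ann <- setdiff(sample_ids, names(subtype_of))
  if (length(missing_ann) > 0L) {
    stop("sample(s) without subtype annotation: ", paste(missing_ann, collapse = ", "))
  }
  structure(list(mat = mat, subtype_of = subtype_of[sample_ids]),
            class = "expression_half")
}

#' Pair a gene half and a miRNA half on their common samples
#'
#' Matched-sample analyses require the mRNA and miRNA matrices to share one
#' sample axis. The paired object keeps the intersection of the two sample
#' sets; when the two halves hold identical sample sets the gene half's
#' column order is kept, otherwise the common samples are sorted. Samples
#' present in only one half are dropped with a message.
#'
#' @param genes_half `expression_half` from [read_expression()] (mRNA side).
#' @param mirnas_half `expression_half` (miRNA side).
#' @return An object of class `paired_expression`: list with `gene_ids`,
#'   `mirna_ids`, `sample_ids`, matrices `E` (genes x samples) and `R`
#'   (miRNAs x samples), and `subtype_of` (named character over samples).
#' @export
pair_expression <- function(genes_half, mirnas_half) {
  sg <- colnames(genes_half$mat)
  sd_ <- colnames(mirnas_half$mat)
  common <- intersect(sg, sd_)
  if (length(common) == 0L) stop("expression halves share no samples")
  if (setequal(sg, sd_)) {
    samples <- sg
  } else {
    samples <- sort(common)
  }
  dropped <- c(setdiff(sg, common), setdiff(sd_, common))
  if (length(dropped) > 0L) {
    message(length(dropped), " unmatched sample(s) dropped: ",
            paste(dropped, collapse = ", "))
  }
  subtype_of <- genes_half$subtype_of[samples]
  # the miRNA half may carry annotations for samples the gene half lacks
  take <- is.na(subtype_of)
  if (any(take)) subtype_of[take] <- mirnas_half$subtype_of[samples[take]]
  pe <- list(gene_ids = rownames(genes_half$mat),
             mirna_ids = rownames(mirnas_half$mat),
             sample_ids = samples,
             E = genes_half$mat[, samples, drop = FALSE],
             R = mirnas_half$mat[, samples, drop = FALSE],
             subtype_of = subtype_of)
  class(pe) <- "paired_expression"
  pe
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("paired_expression:", length(x$gene_ids), "genes x",
      length(x$mirna_ids), "miRNAs x", length(x$sample_ids), "samples\n")
  cat("subtypes:", paste(sort(unique(x$subtype_of)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a paired expression object to a directory
#'
#' Writes `E.tsv`, `R.tsv` and `annotations.tsv` in the exact formats
#' [read_expression()] reads, so that reading them back reproduces the
#' object (matrices, orderings and labels).
#'
#' @param pe A `paired_expression` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_paired_expression <- function(pe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("E.tsv", "R.tsv", "annotations.tsv"))
  write_expression_matrix(pe$E, paths[1L])
  write_expression_matrix(pe$R, paths[2L])
  ann <- data.frame(sample = pe$sample_ids,
                    subtype = unname(pe$subtype_of[pe$sample_ids]))
  utils::write.table(ann, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

write_expression_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Aggregate miRNA target predictions from several sources
#'
#' Each source file is a two-column TSV (`mirna_id<TAB>gene_id`), one
#' predicted pair per row, no header. The target coefficient of a pair is
#' the fraction of the supplied sources that predict it; a source counts at
#' most once per pair regardless of duplicated rows. Pairs referencing
#' identifiers absent from `all_mirnas`/`all_genes` are dropped with a
#' message.
#'
#' @param paths Character vector of source file paths (at least one).
#' @param all_mirnas Character vector of known miRNA identifiers.
#' @param all_genes Character vector of known gene identifiers.
#' @return An object of class `target_scores`: list with `pairs` (data frame
#'   `mirna`, `gene`, `t`) and `n_sources`.
#' @export
read_target_sources <- function(paths, all_mirnas, all_genes) {
  if (length(paths) == 0L) stop("at least one target prediction source is required")
  for (p in paths) check_readable(p)
  counts <- new.env(parent = emptyenv())
  n_dropped <- 0L
  for (p in paths) {
    tab <- tryCatch(
      utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character"),
      error = function(e) data.frame(V1 = character(), V2 = character()))
    if (nrow(tab) == 0L) next
    if (ncol(tab) < 2L) stop("target source must have two columns: ", p)
    keep <- tab[[1L]] %in% all_mirnas & tab[[2L]] %in% all_genes
    n_dropped <- n_dropped + sum(!keep)
    keys <- unique(paste(tab[[1L]][keep], tab[[2L]][keep], sep = "\t"))
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  if (n_dropped > 0L) {
    message(n_dropped, " target pair(s) with unknown identifiers dropped")
  }
  keys <- ls(counts)
  if (length(keys) > 0L) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    pairs <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                        gene = vapply(parts, `[`, "", 2L),
                        t = vapply(keys, function(k) counts[[k]], 0L) / length(paths),
                        row.names = NULL)
    pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(mirna = character(), gene = character(), t = numeric())
  }
  structure(list(pairs = pairs, n_sources = length(paths)),
            class = "target_scores")
}

#' Look up target coefficients for a block of miRNA-gene pairs
#'
#' @param ts A `target_scores` object.
#' @param mirnas,genes Identifier vectors; the result is the
#'   `length(mirnas)` x `length(genes)` matrix of coefficients (0 for pairs
#'   predicted by no source).
#' @return Numeric matrix with dimnames `mirnas` x `genes`.
#' @export
target_score_matrix <- function(ts, mirnas, genes) {
  out <- matrix(0, nrow = length(mirnas), ncol = length(genes),
                dimnames = list(mirnas, genes))
  hit <- ts$pairs$mirna %in% mirnas & ts$pairs$gene %in% genes
  if (any(hit)) {
    sub <- ts$pairs[hit, , drop = FALSE]
    out[cbind(match(sub$mirna, mirnas), match(sub$gene, genes))] <- sub$t
  }
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Each set
#' is intersected with the background `universe`; sets that become empty are
#' dropped and counted in a message. Duplicate genes within a set are
#' collapsed.
#'
#' @param path Path to the GMT file (may be gzip-compressed).
#' @param universe Character vector: the enrichment background (typically
#'   the genes present in the expression matrix).
#' @return An object of class `gene_sets`: list with `sets` (named list of
#'   character vectors), `term_names` (named character) and `universe`.
#' @export
read_gmt <- function(path, universe) {
  check_readable(path)
  con <- file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); term_names <- character(0)
  n_empty <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path, ": fewer than 3 fields")
    }
    genes <- intersect(unique(fields[-(1:2)]), universe)
    if (length(genes) == 0L) { n_empty <- n_empty + 1L; next }
    sets[[fields[1L]]] <- genes
    term_names[fields[1L]] <- fields[2L]
  }
  if (n_empty > 0L) {
    message(n_empty, " gene set(s) with no gene in the universe dropped")
  }
  structure(list(sets = sets, term_names = term_names,
                 universe = unique(universe)),
            class = "gene_sets")
}

check_readable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  invisible(path)
}

#' Read a disease-associated gene list
#'
#' One identifier per line; blank lines are ignored.
#'
#' @param path Path to the list (may be gzip-compressed).
#' @return Character vector of unique gene identifiers.
#' @export
read_disease_genes <- function(path) {
  check_readable(path)
  con <- file(path, "r")
  on.exit(close(con))
  genes <- unique(trimws(readLines(con, warn = FALSE)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("disease gene list is empty: ", path)
  genes
}
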