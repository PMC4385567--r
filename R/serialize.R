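#' Write comodules as JSON lines
#'
#' One JSON object per line with id arrays, weight arrays, `seed_id`,
#' `n_iterations` and `category`.
#'
#' @param comodules List of `comodule` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_comodules <- function(comodules, path) {
  lines <- vapply(comodules, function(cm) {
    jsonlite::toJSON(list(
      seed_id = cm$seed_id,
      n_iterations = cm$n_iterations,
      category = cm$category,
      gene_ids = names(cm$genes), gene_weights = unname(cm$genes),
      mirna_ids = names(cm$mirnas), mirna_weights = unname(cm$mirnas),
      sample_ids = names(cm$samples), sample_weights = unname(cm$samples)),
      auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read comodules from JSON lines
#'
#' @param path File written by [write_comodules()].
#' @return List of `comodule` objects.
#' @export
read_comodules <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    o <- jsonlite::fromJSON(line)
    structure(list(genes = stats::setNames(o$gene_weights, o$gene_ids),
                   mirnas = stats::setNames(o$mirna_weights, o$mirna_ids),
                   samples = stats::setNames(o$sample_weights, o$sample_ids),
                   seed_id = as.integer(o$seed_id),
                   n_iterations = as.integer(o$n_iterations),
                   category = as.character(o$category)),
              class = "comodule")
  })
}

#' Write functional regulatory modules as JSON lines
#'
#' @param mfrms List of `mfrm` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mfrms <- function(mfrms, path) {
  lines <- vapply(mfrms, function(x) {
    jsonlite::toJSON(list(
      comodule_id = x$comodule_id,
      selection = paste(x$selection, collapse = ""),
      category = x$category,
      mirna_ids = x$mirna_ids, gene_ids = x$gene_ids,
      objectives = x$objectives),
      auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read functional regulatory modules from JSON lines
#'
#' @param path File written by [write_mfrms()].
#' @return List of `mfrm` objects.
#' @export
read_mfrms <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    o <- jsonlite::fromJSON(line)
    structure(list(comodule_id = o$comodule_id,
                   selection = as.integer(strsplit(o$selection, "")[[1L]]),
                   objectives = o$objectives,
                   mirna_ids = as.character(o$mirna_ids),
                   gene_ids = as.character(o$gene_ids),
                   category = as.character(o$category)),
              class = "mfrm")
  })
}

#' Write a ranked module table as TSV
#'
#' Flattens the per-category ranked data frames of
#' [categorize_and_rank()] into one TSV with id lists joined by commas.
#'
#' @param ranked Named list of ranked data frames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ranked <- function(ranked, path) {
  rows <- lapply(names(ranked), function(cat) {
    df <- ranked[[cat]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(category = df$category, comodule_id = df$comodule_id,
               S = df$S, R1 = df$R1, R2 = df$R2, R3 = df$R3,
               FP = df$FP, FC = df$FC, FF = df$FF,
               m_sel = df$m_sel, n_sel = df$n_sel,
               mirna_ids = vapply(df$mfrm, function(x)
                 paste(x$mirna_ids, collapse = ","), ""),
               gene_ids = vapply(df$mfrm, function(x)
                 paste(x$gene_ids, collapse = ","), ""))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(category = character(), comodule_id = character(),
                      S = numeric(), R1 = numeric(), R2 = numeric(),
                      R3 = numeric(), FP = numeric(), FC = numeric(),
                      FF = numeric(), m_sel = integer(), n_sel = integer(),
                      mirna_ids = character(), gene_ids = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
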