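# Shared fixtures, all built in code.

.fixture_env <- new.env(parent = emptyenv())

# Default-condition synthetic data set, memoised per seed.
default_synth <- function(seed = 1L) {
  key <- paste0("synth_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_synthetic(synth_config(rng_seed = seed))
  }
  .fixture_env[[key]]
}

# Small paired expression object built by hand (4 genes x 2 miRNAs x 6
# samples, two subtypes).
tiny_pe <- function() {
  E <- matrix(c(1, 2, 3, 4, 5, 6,
                6, 5, 4, 3, 2, 1,
                1, 1, 2, 2, 3, 3,
                0, 1, 0, 1, 0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  R <- matrix(c(6, 5, 4, 3, 2, 1,
                1, 2, 1, 2, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(paste0("d", 1:2), paste0("s", 1:6)))
  structure(list(gene_ids = rownames(E), mirna_ids = rownames(R),
                 sample_ids = colnames(E), E = E, R = R,
                 subtype_of = stats::setNames(rep(c("A", "B"), each = 3),
                                              colnames(E))),
            class = "paired_expression")
}

# Comodule object assembled directly from a planted truth entry.
comodule_from_truth <- function(sd_, k) {
  pl <- sd_$truth$planted_comodules[[k]]
  cm <- structure(list(
    genes = stats::setNames(rep(1, length(pl$genes)), pl$genes),
    mirnas = stats::setNames(rep(-1, length(pl$mirnas)), pl$mirnas),
    samples = stats::setNames(rep(1, length(pl$samples)), pl$samples),
    seed_id = k, n_iterations = 0L, category = NA_character_),
    class = "comodule")
  cm$category <- classify_comodule(cm, sd_$pe$subtype_of)
  cm
}

# Context for the k-th planted comodule of a synthetic data set.
planted_context <- function(sd_, k) {
  terms <- disease_go_terms(sd_$go, sd_$disease)
  comodule_context(comodule_from_truth(sd_, k), sd_$pe, sd_$targets,
                   sd_$go$sets[terms$term_id])
}

# Random small comodule context for GA-vs-oracle comparisons: correlations,
# p-values, target coefficients and variances drawn directly, with 3
# moderate-size disease terms over a 60-gene universe.
random_context <- function(m, n, seed) {
  set.seed(seed)
  mirnas <- paste0("d", seq_len(m))
  genes <- paste0("g", seq_len(n))
  C <- matrix(stats::runif(m * n, -1, 1), m, n,
              dimnames = list(mirnas, genes))
  P <- matrix(stats::runif(m * n), m, n, dimnames = list(mirnas, genes))
  Tm <- matrix(sample(0:7, m * n, TRUE, prob = c(0.5, rep(0.5 / 7, 7))) / 7,
               m, n, dimnames = list(mirnas, genes))
  terms <- lapply(1:3, function(i) sample(c(genes, paste0("x", 1:40)), 8))
  names(terms) <- paste0("T", 1:3)
  structure(list(comodule = NULL, comodule_id = seed, category = "cat1",
                 mirna_ids = mirnas, gene_ids = genes,
                 corr = C, corr_p = P, corr_gated = C * (P < 0.05),
                 targets = Tm,
                 variance_mi = stats::setNames(stats::runif(m), mirnas),
                 variance_mr = stats::setNames(stats::runif(n), genes),
                 disease_terms = terms, universe_size = 60L),
            class = "comodule_context")
}

# Minimal mfrm for postprocess tests.
make_mfrm <- function(FP, FC, FF, comodule_id = 1L, category = "cat1",
                      mirna_ids = c("d1"), gene_ids = c("g1"),
                      selection = NULL) {
  if (is.null(selection)) {
    selection <- rep(1L, length(mirna_ids) + length(gene_ids))
  }
  structure(list(comodule_id = comodule_id, selection = selection,
                 objectives = list(FP = FP, FC = FC, FF = FF, cc = FC,
                                   tc = 0, m_sel = length(mirna_ids),
                                   n_sel = length(gene_ids)),
                 mirna_ids = mirna_ids, gene_ids = gene_ids,
                 category = category),
            class = "mfrm")
}

# Objective-vector set signature of a front (distinct bit strings may
# share one objective vector, so fronts are compared as sets of vectors).
front_signature <- function(front) {
  if (length(front) == 0L) return(character(0))
  unique(sort(vapply(front, function(x)
    paste(signif(c(x$objectives$FP, x$objectives$FC, x$objectives$FF), 12),
          collapse = "|"), "")))
}

# Write the tiny expression/annotation files used by the reader tests.
write_expr_file <- function(lines, path) {
  writeLines(lines, path)
  path
}
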