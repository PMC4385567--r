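#' Configuration for comodule discovery
#'
#' Thresholds are in standard-deviation units applied to the z-scores of the
#' propagated score vectors (two-sided, so anticorrelated members are kept
#' with negative weights). Defaults are sized for arrays of a few thousand
#' genes, a few hundred miRNAs and tens of samples. A coherent block
#' occupying a fraction p of an axis can reach a z-score of at most about
#' sqrt((1-p)/p) on that axis, so feature axes (p ~ 0.01-0.03) support
#' strict thresholds (3-3.5) that keep the expected number of false
#' selections below one, while the sample axis (p ~ 0.1) caps near 3 and
#' needs a looser threshold (1.8).
#'
#' @param t_G,t_D,t_C Selection thresholds for genes, miRNAs and samples.
#' @param n_seeds Number of random gene seeds to launch.
#' @param seed_size Genes per random seed.
#' @param max_iterations Iteration cap per seed before flagging
#'   non-convergence.
#' @param convergence_tol Maximum absolute weight change regarded as
#'   stationary.
#' @param dedup_threshold Jaccard index (on the union of the three id sets)
#'   above which two comodules are duplicates.
#' @param rng_seed Integer seed for the seed-sampling RNG.
#' @return A list of class `ppa_config`.
#' @export
ppa_config <- function(t_G = 3.5, t_D = 3, t_C = 1.8,
                       n_seeds = 5000L, seed_size = 10L,
                       max_iterations = 100L, convergence_tol = 1e-6,
                       dedup_threshold = 0.9, rng_seed = 1L) {
  stopifnot(t_G >= 0, t_D >= 0, t_C >= 0, n_seeds >= 0, seed_size >= 1,
            max_iterations >= 1, convergence_tol > 0,
            dedup_threshold > 0, dedup_threshold <= 1)
  structure(list(t_G = t_G, t_D = t_D, t_C = t_C,
                 n_seeds = as.integer(n_seeds),
                 seed_size = as.integer(seed_size),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 dedup_threshold = dedup_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "ppa_config")
}

standardize <- function(mat, margin) {
  # margin 1: each row to mean 0 / sd 1; margin 2: each column.
  # sample (n-1) sd; constant vectors map to all zeros.
  if (margin == 2L) return(t(standardize(t(mat), 1L)))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  out <- (mat - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

#' Standardize a paired expression object along both axes
#'
#' Produces the four standardized matrices the ping-pong iteration projects
#' through: `E_G`/`R_D` standardized within each feature (row mean 0, sd 1)
#' and `E_C`/`R_C` standardized within each sample (column mean 0, sd 1).
#' The sample (n-1) standard deviation is used; constant vectors map to all
#' zeros.
#'
#' @param pe A `paired_expression` object.
#' @return A list of class `normalized_pair` with matrices `E_G`, `E_C`,
#'   `R_D`, `R_C` and the source `pe`.
#' @export
normalize_pair <- function(pe) {
  if (ncol(pe$E) < 2L || nrow(pe$E) < 2L || nrow(pe$R) < 2L) {
    stop("standardization needs at least 2 rows and 2 columns per matrix")
  }
  structure(list(E_G = standardize(pe$E, 1L), E_C = standardize(pe$E, 2L),
                 R_D = standardize(pe$R, 1L), R_C = standardize(pe$R, 2L),
                 pe = pe),
            class = "normalized_pair")
}

unit_norm <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm > 0) x / nrm else x
}

#' Threshold a score vector into a weighted selection
#'
#' Scores are z-scored against their own mean and standard deviation; items
#' with `|z| > t` are retained with their original signed score and the
#' retained weights are rescaled to unit Euclidean norm. A constant score
#' vector (sd zero) signals a degenerate direction and yields an empty
#' selection.
#'
#' @param scores Named numeric vector.
#' @param t Non-negative threshold in sd units.
#' @return Named numeric vector of unit norm (possibly empty).
#' @export
threshold_select <- function(scores, t) {
  stopifnot(all(is.finite(scores)))
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) return(stats::setNames(numeric(0), character(0)))
  z <- (scores - mean(scores)) / s
  keep <- abs(z) > t
  unit_norm(scores[keep])
}

#' One ping-pong run from a gene seed to a comodule
#'
#' Runs the alternating projection-and-threshold cycle: samples are scored
#' from the gene set through the sample-standardized mRNA matrix, miRNAs
#' from those samples through the miRNA-standardized matrix, samples are
#' refined through the sample-standardized miRNA matrix, and genes rescored
#' through the gene-standardized mRNA matrix. Each stage z-scores and
#' thresholds its score vector ([threshold_select()]), keeping signed
#' weights so anticorrelated members survive. The cycle repeats until the
#' three index sets stop changing (with stationary weights), and the fixed
#' point is verified by one additional full cycle; runs that hit the
#' iteration cap, lose a set entirely, or fail verification return `NULL`.
#'
#' @param seed_genes Character vector of gene ids, or a named numeric vector
#'   of initial signed gene weights.
#' @param np A `normalized_pair`.
#' @param cfg A `ppa_config`.
#' @param seed_id Integer identifier recorded on the result.
#' @return A list of class `comodule` with weighted sets `genes`, `mirnas`,
#'   `samples`, plus `seed_id`, `n_iterations` and `category` (initially
#'   `NA`), or `NULL` if the run diverged.
#' @export
ppa_iterate <- function(seed_genes, np, cfg, seed_id = NA_integer_) {
  if (is.character(seed_genes)) {
    seed_genes <- stats::setNames(rep(1, length(seed_genes)), seed_genes)
  }
  if (length(seed_genes) == 0L) stop("empty gene seed")
  g <- unit_norm(seed_genes)

  cycle <- function(g) {
    gvec <- stats::setNames(numeric(nrow(np$E_C)), rownames(np$E_C))
    gvec[names(g)] <- g
    c1 <- threshold_select(drop(crossprod(np$E_C, gvec)), cfg$t_C)
    if (length(c1) == 0L) return(NULL)
    cvec <- stats::setNames(numeric(ncol(np$R_D)), colnames(np$R_D))
    cvec[names(c1)] <- c1
    d <- threshold_select(drop(np$R_D %*% cvec), cfg$t_D)
    if (length(d) == 0L) return(NULL)
    dvec <- stats::setNames(numeric(nrow(np$R_C)), rownames(np$R_C))
    dvec[names(d)] <- d
    c2 <- threshold_select(drop(crossprod(np$R_C, dvec)), cfg$t_C)
    if (length(c2) == 0L) return(NULL)
    c2vec <- stats::setNames(numeric(ncol(np$E_G)), colnames(np$E_G))
    c2vec[names(c2)] <- c2
    g_new <- threshold_select(drop(np$E_G %*% c2vec), cfg$t_G)
    if (length(g_new) == 0L) return(NULL)
    list(genes = g_new, mirnas = d, samples = c2)
  }

  same_sets <- function(a, b) {
    setequal(names(a$genes), names(b$genes)) &&
      setequal(names(a$mirnas), names(b$mirnas)) &&
      setequal(names(a$samples), names(b$samples))
  }
  max_delta <- function(a, b) {
    if (!same_sets(a, b)) return(Inf)
    max(abs(a$genes - b$genes[names(a$genes)]),
        abs(a$mirnas - b$mirnas[names(a$mirnas)]),
        abs(a$samples - b$samples[names(a$samples)]))
  }

  prev <- NULL
  stationary <- 0L
  for (iter in seq_len(cfg$max_iterations)) {
    state <- cycle(g)
    if (is.null(state)) return(NULL)
    if (!is.null(prev)) {
      d <- max_delta(prev, state)
      stationary <- if (d < cfg$convergence_tol) stationary + 1L else 0L
      if (stationary >= 1L && same_sets(prev, state)) {
        # verify the fixed point with one more full cycle
        verify <- cycle(state$genes)
        if (!is.null(verify) && same_sets(state, verify) &&
            max_delta(state, verify) < cfg$convergence_tol) {
          return(structure(list(genes = state$genes, mirnas = state$mirnas,
                                samples = state$samples,
                                seed_id = as.integer(seed_id),
                                n_iterations = iter,
                                category = NA_character_),
                           class = "comodule"))
        }
      }
    }
    prev <- state
    g <- state$genes
  }
  NULL
}

#' @export
print.comodule <- function(x, ...) {
  cat("comodule (seed ", x$seed_id, "): ", length(x$genes), " genes, ",
      length(x$mirnas), " miRNAs, ", length(x$samples), " samples",
      if (!is.na(x$category)) paste0(" [", x$category, "]"), "\n", sep = "")
  invisible(x)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

comodule_id_union <- function(cm) {
  c(paste0("g:", names(cm$genes)), paste0("d:", names(cm$mirnas)),
    paste0("c:", names(cm$samples)))
}

#' Discover comodules from many random gene seeds
#'
#' Launches `cfg$n_seeds` random gene seeds (each `cfg$seed_size` genes
#' drawn without replacement), runs [ppa_iterate()] on each, and
#' deduplicates the converged comodules: two comodules are duplicates when
#' the Jaccard index of their combined gene/miRNA/sample id sets exceeds
#' `cfg$dedup_threshold`; the earlier-seeded one is kept. The result is
#' sorted by decreasing gene-set size, ties broken by seed id. Each
#' comodule is labelled with its sample category via [classify_comodule()].
#'
#' @param pe A `paired_expression` object.
#' @param cfg A `ppa_config`.
#' @return List of `comodule` objects (possibly empty).
#' @export
run_ppa <- function(pe, cfg = ppa_config()) {
  np <- normalize_pair(pe)
  found <- list()
  with_seed(cfg$rng_seed, {
    for (s in seq_len(cfg$n_seeds)) {
      seed <- sample(pe$gene_ids, cfg$seed_size)
      cm <- ppa_iterate(seed, np, cfg, seed_id = s)
      if (is.null(cm)) next
      dup <- FALSE
      ids <- comodule_id_union(cm)
      for (old in found) {
        if (jaccard(ids, comodule_id_union(old)) > cfg$dedup_threshold) {
          dup <- TRUE
          break
        }
      }
      if (!dup) found[[length(found) + 1L]] <- cm
    }
  })
  if (length(found) == 0L) {
    message("no converged comodules from ", cfg$n_seeds, " seeds")
    return(list())
  }
  ord <- order(-vapply(found, function(cm) length(cm$genes), 0L),
               vapply(found, function(cm) cm$seed_id, 0L))
  found <- found[ord]
  lapply(found, function(cm) {
    cm$category <- classify_comodule(cm, pe$subtype_of)
    cm
  })
}

#' Assign a comodule to a subtype category
#'
#' A comodule whose samples all carry one subtype label is specific to that
#' subtype; comodules spanning several subtypes are `"heterogeneous"`.
#'
#' @param cm A `comodule`.
#' @param subtype_of Named character vector mapping sample id to subtype.
#' @return Single category string.
#' @export
classify_comodule <- function(cm, subtype_of) {
  ids <- names(cm$samples)
  labs <- subtype_of[ids]
  if (anyNA(labs)) {
    stop("unlabeled sample(s): ", paste(ids[is.na(labs)], collapse = ", "))
  }
  u <- unique(labs)
  if (length(u) == 1L) u else "heterogeneous"
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
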