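#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the t transform `t = r * sqrt(df) / sqrt(1 - r^2)`
#' with `df = length(x) - 2` degrees of freedom. Degenerate inputs (fewer
#' than 3 points, or a constant vector) return `(0, 1)` with a degenerate
#' flag so callers can treat them as non-significant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `degenerate` (logical).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = 0, p = 1, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, degenerate = FALSE))
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), degenerate = FALSE)
}

#' Between-class variance of a vector under class labels
#'
#' The variance of the class means about the grand mean, weighted by class
#' size: `sum_c (n_c / N) * (mu_c - mu)^2`. With a single class (or a
#' constant vector) the result is 0. Translation-invariant.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Class (subtype) label per sample.
#' @return Non-negative scalar.
#' @export
between_class_variance <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  mu <- mean(values)
  cls <- split(values, labels)
  sum(vapply(cls, function(v) length(v) / length(values) * (mean(v) - mu)^2, 0))
}

#' Precompute everything the objective functions need for one comodule
#'
#' For every (miRNA, gene) pair of the comodule, the Pearson correlation and
#' its p-value across the comodule's samples are cached (comodules with
#' fewer than 3 samples get `r = 0, p = 1`: all pairs non-significant).
#' Target coefficients are restricted to the comodule's members.
#' Between-class variances of each member's expression across all samples
#' and all subtypes are min-max normalized to \[0, 1\] separately over the
#' comodule's miRNAs and over its genes (a degenerate spread maps to all
#' zeros).
#'
#' @param cm A `comodule`.
#' @param pe The `paired_expression` the comodule came from.
#' @param targets A `target_scores` object.
#' @param disease_terms Named list of disease-associated term gene sets
#'   (e.g. `sets` from the terms returned by [disease_go_terms()]),
#'   identifiers restricted to the expression universe.
#' @return A list of class `comodule_context`.
#' @export
comodule_context <- function(cm, pe, targets, disease_terms) {
  mirnas <- names(cm$mirnas)
  genes <- names(cm$genes)
  samples <- names(cm$samples)
  m <- length(mirnas); n <- length(genes)

  C <- matrix(0, m, n, dimnames = list(mirnas, genes))
  P <- matrix(1, m, n, dimnames = list(mirnas, genes))
  if (length(samples) >= 3L && m > 0L && n > 0L) {
    X <- pe$R[mirnas, samples, drop = FALSE]
    Y <- pe$E[genes, samples, drop = FALSE]
    ok_x <- apply(X, 1L, stats::sd) > 0
    ok_y <- apply(Y, 1L, stats::sd) > 0
    if (any(ok_x) && any(ok_y)) {
      r <- stats::cor(t(X[ok_x, , drop = FALSE]), t(Y[ok_y, , drop = FALSE]))
      df <- length(samples) - 2L
      tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
      p <- 2 * stats::pt(-abs(tval), df = df)
      p[abs(r) >= 1] <- 0
      C[ok_x, ok_y] <- r
      P[ok_x, ok_y] <- p
    }
  }

  labels <- pe$subtype_of[pe$sample_ids]
  var_mi <- vapply(mirnas, function(i)
    between_class_variance(pe$R[i, pe$sample_ids], labels), 0)
  var_mr <- vapply(genes, function(j)
    between_class_variance(pe$E[j, pe$sample_ids], labels), 0)

  minmax <- function(v) {
    if (length(v) == 0L) return(v)
    rng <- range(v)
    if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L]) else v * 0
  }

  disease_terms <- lapply(disease_terms, intersect, y = pe$gene_ids)

  structure(list(
    comodule = cm,
    comodule_id = cm$seed_id,
    category = cm$category,
    mirna_ids = mirnas,
    gene_ids = genes,
    sample_ids = samples,
    corr = C,
    corr_p = P,
    corr_gated = C * (P < 0.05),
    targets = target_score_matrix(targets, mirnas, genes),
    variance_mi = minmax(var_mi),
    variance_mr = minmax(var_mr),
    disease_terms = disease_terms,
    universe_size = length(pe$gene_ids)
  ), class = "comodule_context")
}

#' Module correlation coefficient over a selection
#'
#' Mean Pearson coefficient over all selected (miRNA, gene) pairs, where a
#' coefficient contributes its value only when its p-value is below 0.05
#' and 0 otherwise; 0 when either side of the selection is empty.
#'
#' @param selected_mi,selected_mr Character vectors of selected ids.
#' @param ctx A `comodule_context`.
#' @return Scalar in \[-1, 1\].
#' @export
compute_cc <- function(selected_mi, selected_mr, ctx) {
  if (length(selected_mi) == 0L || length(selected_mr) == 0L) return(0)
  mean(ctx$corr_gated[selected_mi, selected_mr, drop = FALSE])
}

#' Module target coefficient over a selection
#'
#' Negated mean target coefficient over all selected (miRNA, gene) pairs;
#' 0 when either side is empty.
#'
#' @inheritParams compute_cc
#' @return Scalar in \[-1, 0\].
#' @export
compute_tc <- function(selected_mi, selected_mr, ctx) {
  if (length(selected_mi) == 0L || length(selected_mr) == 0L) return(0)
  -mean(ctx$targets[selected_mi, selected_mr, drop = FALSE])
}

#' Disease gene-set objective FP for a gene selection
#'
#' For each disease-associated term, the hypergeometric upper-tail p of the
#' selected gene set's overlap, Bonferroni-corrected by the number of
#' disease terms; the objective is the minimum corrected p. An empty
#' selection (or no overlap anywhere) scores 1.
#'
#' @param selected_mr Character vector of selected gene ids.
#' @param ctx A `comodule_context`.
#' @return Scalar in \[0, 1\].
#' @export
compute_fp <- function(selected_mr, ctx) {
  n_terms <- length(ctx$disease_terms)
  if (n_terms == 0L || length(selected_mr) == 0L) return(1)
  p <- vapply(ctx$disease_terms, function(term) {
    hypergeom_upper_tail(length(intersect(selected_mr, term)),
                         K = length(term), n = length(selected_mr),
                         N = ctx$universe_size)
  }, 0)
  min(bonferroni(p, n_terms))
}

#' Subtype-variability objective FF for a selection
#'
#' Negated mean of the normalized between-class variances of the selected
#' miRNAs and genes; 0 when both selections are empty.
#'
#' @inheritParams compute_cc
#' @return Scalar in \[-1, 0\].
#' @export
compute_ff <- function(selected_mi, selected_mr, ctx) {
  k <- length(selected_mi) + length(selected_mr)
  if (k == 0L) return(0)
  -(sum(ctx$variance_mi[selected_mi]) + sum(ctx$variance_mr[selected_mr])) / k
}

decode_selection <- function(selection, ctx) {
  m <- length(ctx$mirna_ids); n <- length(ctx$gene_ids)
  if (length(selection) != m + n) {
    stop("selection length ", length(selection), " != m + n = ", m + n)
  }
  sel <- as.logical(selection)
  list(mirnas = ctx$mirna_ids[sel[seq_len(m)]],
       genes = ctx$gene_ids[sel[m + seq_len(n)]])
}

#' Evaluate the three objectives of a candidate module selection
#'
#' Decodes a bit string of length `m + n` over the comodule's miRNAs (first
#' `m` bits) and genes (remaining `n` bits; 1 = selected) and returns the
#' objective vector to be minimized.
#'
#' @param selection Integer/logical vector of length `m + n`.
#' @param ctx A `comodule_context`.
#' @return List of class `objective_vector` with `FP`, `FC`, `FF`, `cc`,
#'   `tc`, `m_sel`, `n_sel`.
#' @export
evaluate_selection <- function(selection, ctx) {
  dec <- decode_selection(selection, ctx)
  cc <- compute_cc(dec$mirnas, dec$genes, ctx)
  tc <- compute_tc(dec$mirnas, dec$genes, ctx)
  structure(list(FP = compute_fp(dec$genes, ctx),
                 FC = cc + tc,
                 FF = compute_ff(dec$mirnas, dec$genes, ctx),
                 cc = cc, tc = tc,
                 m_sel = length(dec$mirnas), n_sel = length(dec$genes)),
            class = "objective_vector")
}

# Batch evaluation of a population of selections (rows of a 0/1 matrix).
# Returns a data frame with one row per selection; used by the GA and the
# exhaustive oracle, and contract-tested for bit-exact agreement with
# evaluate_selection().
evaluate_population <- function(pop, ctx) {
  m <- length(ctx$mirna_ids); n <- length(ctx$gene_ids)
  stopifnot(ncol(pop) == m + n)
  U <- pop[, seq_len(m), drop = FALSE]
  V <- pop[, m + seq_len(n), drop = FALSE]
  m_sel <- rowSums(U)
  n_sel <- rowSums(V)
  npairs <- m_sel * n_sel

  cc_sum <- rowSums((U %*% ctx$corr_gated) * V)
  tc_sum <- rowSums((U %*% ctx$targets) * V)
  cc <- ifelse(npairs > 0, cc_sum / npairs, 0)
  tc <- ifelse(npairs > 0, -tc_sum / npairs, 0)

  n_terms <- length(ctx$disease_terms)
  FP <- rep(1, nrow(pop))
  if (n_terms > 0L) {
    term_ind <- vapply(ctx$disease_terms,
                       function(term) as.numeric(ctx$gene_ids %in% term),
                       numeric(n))
    if (n == 1L) term_ind <- matrix(term_ind, nrow = 1L)
    K <- vapply(ctx$disease_terms, length, 0L)
    kmat <- V %*% term_ind                       # overlaps, rows x terms
    for (t_i in seq_len(n_terms)) {
      p <- stats::phyper(kmat[, t_i] - 1, m = K[t_i],
                         n = ctx$universe_size - K[t_i], k = n_sel,
                         lower.tail = FALSE)
      p[kmat[, t_i] <= 0] <- 1
      FP <- pmin(FP, pmin(1, p * n_terms))
    }
    FP[n_sel == 0] <- 1
  }

  var_sum <- drop(U %*% ctx$variance_mi) + drop(V %*% ctx$variance_mr)
  k_tot <- m_sel + n_sel
  FF <- ifelse(k_tot > 0, -var_sum / k_tot, 0)

  data.frame(FP = FP, FC = cc + tc, FF = FF, cc = cc, tc = tc,
             m_sel = m_sel, n_sel = n_sel)
}
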