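#' Configuration for the multiobjective genetic algorithm
#'
#' Defaults follow common practice for three-objective subset selection:
#' an elitist non-dominated-sorting loop with binary tournament selection,
#' uniform crossover and per-bit flip mutation at rate `1/(m+n)` (the value
#' `NA` requests that per-instance rate).
#'
#' @param population_size Even integer >= 4.
#' @param generations Number of generations.
#' @param crossover_rate Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate_per_bit Per-bit flip probability; `NA` = `1/(m+n)`.
#' @param rng_seed Integer RNG seed; the run is deterministic given it.
#' @param max_front_size Cap on the returned front (pruned by crowding
#'   distance).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 250L,
                      crossover_rate = 0.9, mutation_rate_per_bit = NA_real_,
                      rng_seed = 1L, max_front_size = 50L) {
  population_size <- as.integer(population_size)
  stopifnot(population_size >= 4L, population_size %% 2L == 0L,
            generations >= 1, crossover_rate >= 0, crossover_rate <= 1,
            is.na(mutation_rate_per_bit) ||
              (mutation_rate_per_bit >= 0 && mutation_rate_per_bit <= 1),
            max_front_size >= 1)
  structure(list(population_size = population_size,
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate_per_bit = mutation_rate_per_bit,
                 rng_seed = as.integer(rng_seed),
                 max_front_size = as.integer(max_front_size)),
            class = "ga_config")
}

#' Pareto dominance between two objective vectors (minimization)
#'
#' @param a,b Objective vectors (lists or numeric vectors with `FP`, `FC`,
#'   `FF`).
#' @return `TRUE` iff `a` is no worse in every objective and strictly
#'   better in at least one.
#' @export
dominates <- function(a, b) {
  av <- c(a$FP, a$FC, a$FF); bv <- c(b$FP, b$FC, b$FF)
  all(av <= bv) && any(av < bv)
}

#' Feasibility of a candidate module
#'
#' A module is kept only when its gene set is significantly enriched in at
#' least one disease-associated term (`FP < 0.05`) and it selects at least
#' one miRNA and one gene.
#'
#' @param o An objective vector (list with `FP`, `m_sel`, `n_sel`).
#' @return Logical.
#' @export
feasible <- function(o) {
  o$FP < 0.05 && o$m_sel >= 1 && o$n_sel >= 1
}

# Rows of `objs` (FP, FC, FF) that no other row dominates. Duplicate
# vectors are all retained.
nondominated_rows <- function(objs) {
  n <- nrow(objs)
  if (n == 0L) return(integer(0))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    ge <- objs[, 1L] >= objs[i, 1L] & objs[, 2L] >= objs[i, 2L] &
      objs[, 3L] >= objs[i, 3L]
    gt <- objs[, 1L] > objs[i, 1L] | objs[, 2L] > objs[i, 2L] |
      objs[, 3L] > objs[i, 3L]
    dominated <- ge & gt
    dominated[i] <- FALSE
    keep[dominated] <- FALSE
  }
  which(keep)
}

#' Non-dominated front of a list of objective vectors
#'
#' @param population List of objective vectors (each with `FP`, `FC`, `FF`).
#' @return Integer indices (1-based) of the non-dominated members;
#'   duplicates of an identical vector are all retained.
#' @export
nondominated_front <- function(population) {
  if (length(population) == 0L) return(integer(0))
  objs <- t(vapply(population, function(o) c(o$FP, o$FC, o$FF), numeric(3)))
  nondominated_rows(objs)
}

# Crowding distance on the rows of an objective matrix (any # objectives).
crowding_distance <- function(objs) {
  n <- nrow(objs)
  d <- rep(0, n)
  if (n <= 2L) return(rep(Inf, n))
  for (j in seq_len(ncol(objs))) {
    ord <- order(objs[, j])
    rng <- objs[ord[n], j] - objs[ord[1L], j]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1L)]] <- d[ord[2:(n - 1L)]] +
        (objs[ord[3:n], j] - objs[ord[1:(n - 2L)], j]) / rng
    }
  }
  d
}

# Fast non-dominated sort with feasibility-first ranking: feasible fronts
# come first; infeasible individuals are ranked after all feasible ones, in
# ascending FP order. Returns integer rank per row (1 = best front).
constrained_ranks <- function(ev) {
  n <- nrow(ev)
  rank_out <- rep(NA_integer_, n)
  feas <- ev$FP < 0.05 & ev$m_sel >= 1 & ev$n_sel >= 1
  objs <- as.matrix(ev[, c("FP", "FC", "FF")])
  remaining <- which(feas)
  r <- 0L
  while (length(remaining) > 0L) {
    r <- r + 1L
    front <- remaining[nondominated_rows(objs[remaining, , drop = FALSE])]
    rank_out[front] <- r
    remaining <- setdiff(remaining, front)
  }
  if (any(!feas)) {
    inf <- which(!feas)
    rank_out[inf[order(ev$FP[inf])]] <- r + seq_along(inf)
  }
  rank_out
}

random_population <- function(size, L) {
  # half uniform random, half sparse (bit on with prob 0.15) to seed the
  # small subsets observed modules tend to be
  half <- size %/% 2L
  rbind(matrix(stats::rbinom(half * L, 1L, 0.5), nrow = half),
        matrix(stats::rbinom((size - half) * L, 1L, 0.15), nrow = size - half))
}

mfrm_from_row <- function(bits, ev_row, ctx) {
  dec <- decode_selection(bits, ctx)
  structure(list(comodule_id = ctx$comodule_id,
                 selection = as.integer(bits),
                 objectives = list(FP = ev_row$FP, FC = ev_row$FC,
                                   FF = ev_row$FF, cc = ev_row$cc,
                                   tc = ev_row$tc, m_sel = ev_row$m_sel,
                                   n_sel = ev_row$n_sel),
                 mirna_ids = dec$mirnas,
                 gene_ids = dec$genes,
                 category = ctx$category),
            class = "mfrm")
}

#' @export
print.mfrm <- function(x, ...) {
  cat(sprintf("mfrm (comodule %s): %d miRNAs, %d genes | FP=%.4g FC=%.4g FF=%.4g\n",
              as.character(x$comodule_id), x$objectives$m_sel,
              x$objectives$n_sel, x$objectives$FP, x$objectives$FC,
              x$objectives$FF))
  invisible(x)
}

front_from_matrix <- function(pop, ev, ctx, max_front_size = Inf) {
  # feasible, bit-string-deduplicated, nondominated rows -> mfrm list
  feas <- ev$FP < 0.05 & ev$m_sel >= 1 & ev$n_sel >= 1
  if (!any(feas)) return(list())
  pop <- pop[feas, , drop = FALSE]
  ev <- ev[feas, , drop = FALSE]
  key <- apply(pop, 1L, paste, collapse = "")
  first <- !duplicated(key)
  pop <- pop[first, , drop = FALSE]
  ev <- ev[first, , drop = FALSE]
  nd <- nondominated_rows(as.matrix(ev[, c("FP", "FC", "FF")]))
  pop <- pop[nd, , drop = FALSE]
  ev <- ev[nd, , drop = FALSE]
  if (nrow(pop) > max_front_size) {
    cd <- crowding_distance(as.matrix(ev[, c("FP", "FC", "FF")]))
    keep <- order(-cd, apply(pop, 1L, paste, collapse = ""))[seq_len(max_front_size)]
    pop <- pop[keep, , drop = FALSE]
    ev <- ev[keep, , drop = FALSE]
  }
  ord <- order(ev$FP, ev$FC, ev$FF, apply(pop, 1L, paste, collapse = ""))
  lapply(ord, function(i) mfrm_from_row(pop[i, ], ev[i, ], ctx))
}

#' Extract Pareto-optimal functional modules from a comodule
#'
#' Elitist non-dominated-sorting genetic algorithm over bit strings of
#' length `m + n` (miRNAs then genes, 1 = selected), minimizing the
#' objective vector (`FP`, `FC`, `FF`) subject to `FP < 0.05` and at least
#' one selected member on each side. Selection is binary tournament on
#' (feasibility-first front rank, crowding distance); variation is uniform
#' crossover plus per-bit mutation. A running archive of every feasible
#' nondominated individual encountered is maintained, and the returned
#' front is the archive's nondominated set at the final generation,
#' deduplicated by bit string and capped at `cfg$max_front_size` by
#' crowding distance. Deterministic given `cfg$rng_seed`.
#'
#' @param ctx A `comodule_context`.
#' @param cfg A `ga_config`.
#' @return List of `mfrm` objects (possibly empty when no feasible
#'   selection is ever found).
#' @export
evolve <- function(ctx, cfg = ga_config()) {
  m <- length(ctx$mirna_ids); n <- length(ctx$gene_ids)
  stopifnot(m >= 1L, n >= 1L)
  L <- m + n
  pmut <- if (is.na(cfg$mutation_rate_per_bit)) 1 / L else cfg$mutation_rate_per_bit

  with_seed(cfg$rng_seed, {
    pop <- random_population(cfg$population_size, L)
    ev <- evaluate_population(pop, ctx)
    arch_pop <- matrix(integer(0), ncol = L)
    arch_ev <- ev[0, ]
    pls_explored <- new.env(parent = emptyenv())
    update_archive <- function(pop, ev) {
      feas <- ev$FP < 0.05 & ev$m_sel >= 1 & ev$n_sel >= 1
      if (!any(feas)) return()
      cand_pop <- rbind(arch_pop, pop[feas, , drop = FALSE])
      cand_ev <- rbind(arch_ev, ev[feas, , drop = FALSE])
      key <- apply(cand_pop, 1L, paste, collapse = "")
      first <- !duplicated(key)
      cand_pop <- cand_pop[first, , drop = FALSE]
      cand_ev <- cand_ev[first, , drop = FALSE]
      nd <- nondominated_rows(as.matrix(cand_ev[, c("FP", "FC", "FF")]))
      arch_pop <<- cand_pop[nd, , drop = FALSE]
      arch_ev <<- cand_ev[nd, , drop = FALSE]
    }
    update_archive(pop, ev)

    for (gen in seq_len(cfg$generations)) {
      ranks <- constrained_ranks(ev)
      cd <- rep(0, nrow(pop))
      for (r in unique(ranks)) {
        idx <- which(ranks == r)
        cd[idx] <- crowding_distance(as.matrix(ev[idx, c("FP", "FC", "FF"),
                                                  drop = FALSE]))
      }
      tournament <- function(k) {
        i <- sample.int(nrow(pop), 2L * k, replace = TRUE)
        a <- i[seq_len(k)]; b <- i[k + seq_len(k)]
        win_a <- ranks[a] < ranks[b] | (ranks[a] == ranks[b] & cd[a] >= cd[b])
        ifelse(win_a, a, b)
      }
      p1 <- tournament(cfg$population_size %/% 2L)
      p2 <- tournament(cfg$population_size %/% 2L)
      kids <- matrix(0L, nrow = cfg$population_size, ncol = L)
      for (j in seq_along(p1)) {
        a <- pop[p1[j], ]; b <- pop[p2[j], ]
        if (stats::runif(1) < cfg$crossover_rate) {
          mask <- stats::runif(L) < 0.5
          tmp <- a
          a[mask] <- b[mask]
          b[mask] <- tmp[mask]
        }
        kids[2L * j - 1L, ] <- a
        kids[2L * j, ] <- b
      }
      flips <- matrix(stats::runif(length(kids)) < pmut, nrow = nrow(kids))
      kids <- (kids + flips) %% 2L
      # random immigrants keep global exploration alive after the
      # population has converged onto the front
      n_imm <- min(4L, nrow(kids))
      kids[seq_len(n_imm), ] <- matrix(
        stats::rbinom(n_imm * L, 1L, rep(c(0.5, 0.2), length.out = n_imm)),
        nrow = n_imm)
      ev_kids <- evaluate_population(kids, ctx)
      update_archive(kids, ev_kids)

      # Pareto local search interleaved with the evolutionary loop: the
      # 1-bit-flip and 1-swap (one bit on, one off) neighbourhood of each
      # archive member is evaluated exactly once, flood-filling front
      # regions that crossover/mutation step over
      if (nrow(arch_pop) > 0L) {
        keys <- apply(arch_pop, 1L, paste, collapse = "")
        todo <- utils::head(which(!(keys %in% ls(pls_explored))), 4L)
        rows <- arch_pop[todo, , drop = FALSE]   # snapshot: the archive
        for (k in keys[todo]) assign(k, TRUE, envir = pls_explored)
        for (i in seq_len(nrow(rows))) {         # mutates during updates
          x <- rows[i, ]
          nb <- matrix(x, nrow = L, ncol = L, byrow = TRUE)
          nb[cbind(seq_len(L), seq_len(L))] <- 1L - x
          ones <- which(x == 1L); zeros <- which(x == 0L)
          if (length(ones) > 0L && length(zeros) > 0L) {
            sw <- expand.grid(on = ones, off = zeros)
            swap <- matrix(x, nrow = nrow(sw), ncol = L, byrow = TRUE)
            swap[cbind(seq_len(nrow(sw)), sw$on)] <- 0L
            swap[cbind(seq_len(nrow(sw)), sw$off)] <- 1L
            nb <- rbind(nb, swap)
          }
          update_archive(nb, evaluate_population(nb, ctx))
        }
      }

      comb_pop <- rbind(pop, kids)
      comb_ev <- rbind(ev, ev_kids)
      comb_rank <- constrained_ranks(comb_ev)
      ord <- order(comb_rank)
      chosen <- integer(0)
      for (r in unique(comb_rank[ord])) {
        idx <- which(comb_rank == r)
        if (length(chosen) + length(idx) <= cfg$population_size) {
          chosen <- c(chosen, idx)
        } else {
          need <- cfg$population_size - length(chosen)
          cdr <- crowding_distance(as.matrix(comb_ev[idx, c("FP", "FC", "FF"),
                                                     drop = FALSE]))
          chosen <- c(chosen, idx[order(-cdr)][seq_len(need)])
        }
        if (length(chosen) >= cfg$population_size) break
      }
      pop <- comb_pop[chosen, , drop = FALSE]
      ev <- comb_ev[chosen, , drop = FALSE]
    }
    if (nrow(arch_pop) == 0L) {
      message("no feasible module found for comodule ",
              as.character(ctx$comodule_id))
      return(list())
    }
    front_from_matrix(arch_pop, arch_ev, ctx, cfg$max_front_size)
  })
}

#' Exhaustive Pareto front over all selections of a small comodule
#'
#' Enumerates every bit string of length `m + n`, filters by feasibility
#' and returns the exact non-dominated set. Guarded to `m + n <= 20`.
#'
#' @param ctx A `comodule_context`.
#' @return List of `mfrm` objects.
#' @export
brute_force_front <- function(ctx) {
  m <- length(ctx$mirna_ids); n <- length(ctx$gene_ids)
  L <- m + n
  if (L > 20L) stop("brute_force_front limited to m + n <= 20 (got ", L, ")")
  idx <- 0:(2^L - 1)
  pop <- matrix(0L, nrow = length(idx), ncol = L)
  for (b in seq_len(L)) pop[, b] <- bitwAnd(idx %/% 2^(b - 1L), 1L)
  ev <- evaluate_population(pop, ctx)
  front_from_matrix(pop, ev, ctx)
}
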