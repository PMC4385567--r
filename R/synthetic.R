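#' Configuration for the synthetic paired-data generator
#'
#' Defaults emulate a desk-scale version of a matched miRNA/mRNA disease
#' cohort: 2000 genes x 200 miRNAs x 60 samples split into 5 subtypes, with
#' 3 planted comodules of 20 genes x 5 miRNAs x 6 samples each, an effect
#' of 3 sd against noise of sd 0.5, and within each comodule a functional
#' core (3 miRNAs x 3 genes) whose pairs are predicted by all target
#' sources and whose genes form a disease-associated gene-set term (and a
#' small non-disease "tight" term that makes the core's gene set
#' functionally homogeneous on its own). The
#' block's mean shift is modulated per sample by an amplitude drawn
#' uniformly from `1 +/- amplitude_spread`, shared by all block members, so
#' miRNA-gene pairs of a block are negatively correlated within the block's
#' own samples (module activity varies between samples), not only across
#' the full sample axis. Term sizes are chosen so that, under the default
#' universe, the enrichment-feasibility constraint of the module search is
#' crossed exactly at the full core gene set: the planted core is the
#' unique feasible gene selection, hence the intended optimum.
#'
#' @param n_genes,n_mirnas,n_samples Matrix dimensions.
#' @param n_subtypes Number of subtype labels (samples split evenly).
#' @param n_comodules Number of planted comodules.
#' @param block_genes,block_mirnas,block_samples Planted block sizes.
#' @param core_genes,core_mirnas Functional-core sizes (subsets of the
#'   block).
#' @param effect_size Mean shift of block cells, in sd units; genes shift
#'   up, miRNAs down, producing negative core-pair correlation.
#' @param noise_sd Standard deviation of the iid Gaussian noise added to
#'   every cell.
#' @param n_sources Number of target-prediction source tables emitted.
#' @param core_target_sources How many sources predict every core pair.
#' @param background_target_rate Per-source probability that a random
#'   (miRNA, gene) pair is predicted.
#' @param n_go_terms Total gene-set terms (one per planted core plus random
#'   decoys).
#' @param go_term_size Genes per disease-associated (and decoy) term.
#' @param tight_term_size Genes per planted tight term.
#' @param amplitude_spread Half-width of the per-sample block amplitude
#'   (amplitudes are uniform on `1 +/- amplitude_spread`).
#' @param subtype_specific_prob Probability a planted comodule's samples
#'   are drawn within a single subtype (otherwise they span two).
#' @param rng_seed Integer seed; generation is deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L, n_mirnas = 200L, n_samples = 60L,
                         n_subtypes = 5L, n_comodules = 3L,
                         block_genes = 20L, block_mirnas = 5L,
                         block_samples = 6L, core_genes = 3L,
                         core_mirnas = 3L, effect_size = 3,
                         noise_sd = 0.5, n_sources = 7L,
                         core_target_sources = 7L,
                         background_target_rate = 0.01,
                         n_go_terms = 50L, go_term_size = 350L,
                         tight_term_size = 20L,
                         amplitude_spread = 0.3,
                         subtype_specific_prob = 1,
                         rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_samples = as.integer(n_samples),
              n_subtypes = as.integer(n_subtypes),
              n_comodules = as.integer(n_comodules),
              block_genes = as.integer(block_genes),
              block_mirnas = as.integer(block_mirnas),
              block_samples = as.integer(block_samples),
              core_genes = as.integer(core_genes),
              core_mirnas = as.integer(core_mirnas),
              effect_size = effect_size, noise_sd = noise_sd,
              n_sources = as.integer(n_sources),
              core_target_sources = as.integer(core_target_sources),
              background_target_rate = background_target_rate,
              n_go_terms = as.integer(n_go_terms),
              go_term_size = as.integer(go_term_size),
              tight_term_size = as.integer(tight_term_size),
              amplitude_spread = amplitude_spread,
              subtype_specific_prob = subtype_specific_prob,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_comodules * block_genes > n_genes ||
        n_comodules * block_mirnas > n_mirnas ||
        n_comodules * block_samples > n_samples) {
      stop("planted blocks do not fit in the requested matrix dimensions")
    }
    if (core_genes > block_genes || core_mirnas > block_mirnas) {
      stop("functional core must fit inside the planted block")
    }
    if (core_target_sources > n_sources) {
      stop("core_target_sources cannot exceed n_sources")
    }
    stopifnot(background_target_rate >= 0, background_target_rate <= 1,
              subtype_specific_prob >= 0, subtype_specific_prob <= 1,
              amplitude_spread >= 0, amplitude_spread < 1,
              tight_term_size >= core_genes,
              n_go_terms >= 2L * n_comodules)
  })
  structure(cfg, class = "synth_config")
}

# Aggregate in-memory per-source pair tables into a target_scores object
# (same arithmetic as read_target_sources, without touching disk).
aggregate_sources <- function(source_pairs, all_mirnas, all_genes) {
  n_src <- length(source_pairs)
  keys <- unlist(lapply(source_pairs, function(df) {
    keep <- df$mirna %in% all_mirnas & df$gene %in% all_genes
    unique(paste(df$mirna[keep], df$gene[keep], sep = "\t"))
  }))
  if (length(keys) == 0L) {
    pairs <- data.frame(mirna = character(), gene = character(), t = numeric())
  } else {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    pairs <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                        gene = vapply(parts, `[`, "", 2L),
                        t = as.integer(tab) / n_src)
    pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, n_sources = n_src), class = "target_scores")
}

#' Generate a synthetic paired data set with planted modules
#'
#' Builds every input the pipeline consumes: a paired expression object
#' with planted anticorrelated comodule blocks (block genes shifted up by
#' `effect_size`, block miRNAs down, on the block's samples; iid Gaussian
#' noise of sd `noise_sd` on every cell), per-source target prediction
#' tables in which every functional-core pair appears in
#' `core_target_sources` sources and background pairs appear at
#' `background_target_rate` per source, a gene-set collection holding one
#' term per planted core (the core's genes plus padding) among random decoy
#' terms, and a disease gene list containing exactly the planted terms'
#' genes. Planted gene/miRNA/sample sets are disjoint across comodules.
#'
#' @param cfg A `synth_config`.
#' @param dir Optional output directory; when given, `E.tsv`, `R.tsv`,
#'   `annotations.tsv`, `targets/source_<i>.tsv`, `go_bp.gmt`,
#'   `disease_genes.txt` and `truth.json` are written in the formats the
#'   readers accept.
#' @return A list of class `synth_data`: `pe` (`paired_expression`),
#'   `targets` (`target_scores`), `source_pairs` (list of per-source data
#'   frames), `go` (`gene_sets`), `disease` (character), and `truth` (list
#'   of class `synthetic_truth` with `planted_comodules`,
#'   `planted_cores`, `disease_term_map`, `subtype_assignment`).
#' @export
generate_synthetic <- function(cfg = synth_config(), dir = NULL) {
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  sample_ids <- sprintf("s%03d", seq_len(cfg$n_samples))
  subtype_labels <- sprintf("subtype%d", seq_len(cfg$n_subtypes))
  # contiguous, near-equal subtype blocks
  subtype_of <- stats::setNames(
    subtype_labels[rep(seq_len(cfg$n_subtypes),
                       each = ceiling(cfg$n_samples / cfg$n_subtypes))[
                         seq_len(cfg$n_samples)]], sample_ids)

  with_seed(cfg$rng_seed, {
    free_genes <- gene_ids
    free_mirnas <- mirna_ids
    free_samples <- sample_ids

    planted <- vector("list", cfg$n_comodules)
    cores <- vector("list", cfg$n_comodules)
    E_mu <- matrix(0, cfg$n_genes, cfg$n_samples,
                   dimnames = list(gene_ids, sample_ids))
    R_mu <- matrix(0, cfg$n_mirnas, cfg$n_samples,
                   dimnames = list(mirna_ids, sample_ids))

    for (k in seq_len(cfg$n_comodules)) {
      bg <- sort(sample(free_genes, cfg$block_genes))
      bd <- sort(sample(free_mirnas, cfg$block_mirnas))
      specific <- stats::runif(1) < cfg$subtype_specific_prob
      pick_samples <- function(subtypes) {
        pool <- free_samples[subtype_of[free_samples] %in% subtypes]
        if (length(pool) < cfg$block_samples) {
          stop("not enough unused samples in subtype(s) ",
               paste(subtypes, collapse = "/"), " for planted comodule ", k)
        }
        sort(sample(pool, cfg$block_samples))
      }
      if (specific) {
        # cycle through subtypes so distinct comodules land in distinct ones
        st <- subtype_labels[1L + (k - 1L) %% cfg$n_subtypes]
        bs <- pick_samples(st)
      } else {
        st2 <- subtype_labels[1L + (c(k - 1L, k) %% cfg$n_subtypes)]
        pool1 <- free_samples[subtype_of[free_samples] == st2[1L]]
        pool2 <- free_samples[subtype_of[free_samples] == st2[2L]]
        n1 <- ceiling(cfg$block_samples / 2)
        if (length(pool1) < n1 || length(pool2) < cfg$block_samples - n1) {
          stop("not enough unused samples for heterogeneous comodule ", k)
        }
        bs <- sort(c(sample(pool1, n1), sample(pool2, cfg$block_samples - n1)))
      }
      free_genes <- setdiff(free_genes, bg)
      free_mirnas <- setdiff(free_mirnas, bd)
      free_samples <- setdiff(free_samples, bs)

      amp <- stats::runif(cfg$block_samples, 1 - cfg$amplitude_spread,
                          1 + cfg$amplitude_spread)
      E_mu[bg, bs] <- E_mu[bg, bs] +
        cfg$effect_size * matrix(amp, cfg$block_genes, cfg$block_samples,
                                 byrow = TRUE)
      R_mu[bd, bs] <- R_mu[bd, bs] -
        cfg$effect_size * matrix(amp, cfg$block_mirnas, cfg$block_samples,
                                 byrow = TRUE)

      core_g <- sort(sample(bg, cfg$core_genes))
      core_d <- sort(sample(bd, cfg$core_mirnas))
      planted[[k]] <- list(genes = bg, mirnas = bd, samples = bs,
                           sign = list(genes = "+", mirnas = "-"),
                           subtype_specific = specific)
      cores[[k]] <- list(mirnas = core_d, genes = core_g)
    }

    E <- E_mu + matrix(stats::rnorm(length(E_mu), sd = cfg$noise_sd),
                       nrow = nrow(E_mu))
    R <- R_mu + matrix(stats::rnorm(length(R_mu), sd = cfg$noise_sd),
                       nrow = nrow(R_mu))

    pe <- structure(list(gene_ids = gene_ids, mirna_ids = mirna_ids,
                         sample_ids = sample_ids, E = E, R = R,
                         subtype_of = subtype_of),
                    class = "paired_expression")

    # target prediction sources: core pairs into the first
    # core_target_sources files, background pairs independently per source
    core_pairs <- do.call(rbind, lapply(cores, function(co)
      expand.grid(mirna = co$mirnas, gene = co$genes,
                  stringsAsFactors = FALSE)))
    n_all_pairs <- cfg$n_mirnas * cfg$n_genes
    source_pairs <- lapply(seq_len(cfg$n_sources), function(s) {
      n_bg <- stats::rbinom(1L, n_all_pairs, cfg$background_target_rate)
      idx <- sample.int(n_all_pairs, n_bg)
      bg_pairs <- data.frame(
        mirna = mirna_ids[1L + (idx - 1L) %% cfg$n_mirnas],
        gene = gene_ids[1L + (idx - 1L) %/% cfg$n_mirnas])
      df <- if (s <= cfg$core_target_sources) rbind(core_pairs, bg_pairs)
            else bg_pairs
      df <- unique(df[order(df$mirna, df$gene), , drop = FALSE])
      rownames(df) <- NULL
      df
    })
    targets <- aggregate_sources(source_pairs, mirna_ids, gene_ids)

    # gene sets: one term per planted core (core genes + padding drawn from
    # genes in no planted block), plus random decoy terms
    block_genes_all <- unlist(lapply(planted, `[[`, "genes"))
    off_block <- setdiff(gene_ids, block_genes_all)
    sets <- list(); term_names <- character(0)
    disease_term_map <- character(0)
    pad_pool <- off_block
    for (k in seq_len(cfg$n_comodules)) {
      id <- sprintf("TERM%04d", k)
      n_pad <- max(0L, cfg$go_term_size - cfg$core_genes)
      pad <- sample(pad_pool, min(n_pad, length(pad_pool)))
      pad_pool <- setdiff(pad_pool, pad)
      sets[[id]] <- sort(c(cores[[k]]$genes, pad))
      term_names[id] <- sprintf("planted core process %d", k)
      disease_term_map[id] <- id
    }
    disease <- sort(unique(unlist(sets[names(disease_term_map)])))
    # tight and decoy terms are kept disjoint from the disease list (apart
    # from the cores themselves) so that exactly the planted disease terms
    # come out disease-associated and the feasibility boundary of the
    # module search is untouched
    decoy_pool <- setdiff(gene_ids, disease)
    core_term_map <- character(0)
    for (k in seq_len(cfg$n_comodules)) {
      id <- sprintf("TIGHT%04d", k)
      n_pad <- min(cfg$tight_term_size - cfg$core_genes, length(decoy_pool))
      pad <- sample(decoy_pool, n_pad)
      sets[[id]] <- sort(c(cores[[k]]$genes, pad))
      term_names[id] <- sprintf("planted tight process %d", k)
      core_term_map[id] <- id
    }
    for (k in seq_len(cfg$n_go_terms - 2L * cfg$n_comodules)) {
      id <- sprintf("TERM%04d", cfg$n_comodules + k)
      sets[[id]] <- sort(sample(decoy_pool, min(cfg$go_term_size,
                                                length(decoy_pool))))
      term_names[id] <- sprintf("decoy process %d", k)
    }
    go <- structure(list(sets = sets, term_names = term_names,
                         universe = gene_ids), class = "gene_sets")

    truth <- structure(list(planted_comodules = planted,
                            planted_cores = cores,
                            disease_term_map = unname(disease_term_map),
                            core_term_map = unname(core_term_map),
                            subtype_assignment = subtype_of),
                       class = "synthetic_truth")
    out <- structure(list(pe = pe, targets = targets,
                          source_pairs = source_pairs, go = go,
                          disease = disease, truth = truth, cfg = cfg),
                     class = "synth_data")
    if (!is.null(dir)) write_synth_data(out, dir)
    out
  })
}

#' Write a synthetic data set to disk in the pipeline's input formats
#'
#' @param sd_ A `synth_data` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_synth_data <- function(sd_, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_paired_expression(sd_$pe, dir)
  tdir <- file.path(dir, "targets")
  if (!dir.exists(tdir)) dir.create(tdir)
  for (s in seq_along(sd_$source_pairs)) {
    utils::write.table(sd_$source_pairs[[s]],
                       file.path(tdir, sprintf("source_%d.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  gmt <- vapply(names(sd_$go$sets), function(id) {
    paste(c(id, sd_$go$term_names[[id]], sd_$go$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(unname(gmt), file.path(dir, "go_bp.gmt"))
  writeLines(sd_$disease, file.path(dir, "disease_genes.txt"))
  jsonlite::write_json(
    list(planted_comodules = sd_$truth$planted_comodules,
         planted_cores = sd_$truth$planted_cores,
         disease_term_map = sd_$truth$disease_term_map,
         subtype_assignment = as.list(sd_$truth$subtype_assignment)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Score recovered modules against the planted truth
#'
#' Matches found objects to planted objects greedily by descending mean
#' component-wise Jaccard index, then reports the per-component Jaccard of
#' each planted object's best match and the recall at a Jaccard threshold
#' applied to every component.
#'
#' @param truth A `synthetic_truth`.
#' @param found List of `comodule` objects (components genes / miRNAs /
#'   samples) or `mfrm` objects (components genes / miRNAs), compared to
#'   `planted_comodules` or `planted_cores` respectively.
#' @param what `"comodules"` or `"cores"`.
#' @param threshold Jaccard threshold for counting a planted object as
#'   recovered (default 0.9 for comodules, 0.8 for cores).
#' @return List with `table` (data frame, one row per planted object) and
#'   `recall`.
#' @export
evaluate_recovery <- function(truth, found,
                              what = c("comodules", "cores"),
                              threshold = NULL) {
  what <- match.arg(what)
  if (is.null(threshold)) threshold <- if (what == "comodules") 0.9 else 0.8
  if (what == "comodules") {
    planted <- lapply(truth$planted_comodules, function(p)
      list(genes = p$genes, mirnas = p$mirnas, samples = p$samples))
    extract <- function(f) list(genes = names(f$genes),
                                mirnas = names(f$mirnas),
                                samples = names(f$samples))
  } else {
    planted <- lapply(truth$planted_cores, function(p)
      list(genes = p$genes, mirnas = p$mirnas))
    extract <- function(f) list(genes = f$gene_ids, mirnas = f$mirna_ids)
  }
  comp <- names(planted[[1L]])
  found_sets <- lapply(found, extract)

  n_p <- length(planted); n_f <- length(found_sets)
  jac <- matrix(0, n_p, max(n_f, 1L))
  if (n_f > 0L) {
    for (i in seq_len(n_p)) {
      for (j in seq_len(n_f)) {
        jac[i, j] <- mean(vapply(comp, function(cc)
          jaccard(planted[[i]][[cc]], found_sets[[j]][[cc]]), 0))
      }
    }
  }
  match_of <- rep(NA_integer_, n_p)
  if (n_f > 0L) {
    free_f <- seq_len(n_f)
    repeat {
      open <- which(is.na(match_of))
      if (length(open) == 0L || length(free_f) == 0L) break
      sub <- jac[open, free_f, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      if (max(sub) <= 0) break
      match_of[open[best[1L]]] <- free_f[best[2L]]
      free_f <- free_f[-best[2L]]
    }
  }
  rows <- lapply(seq_len(n_p), function(i) {
    j <- match_of[i]
    jc <- if (is.na(j)) stats::setNames(rep(0, length(comp)), comp)
          else vapply(comp, function(cc)
            jaccard(planted[[i]][[cc]], found_sets[[j]][[cc]]), 0)
    c(list(planted = i, matched = j), as.list(jc),
      list(recovered = all(jc >= threshold)))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(table = tab, recall = mean(tab$recovered))
}
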