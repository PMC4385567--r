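#' Configuration for a full pipeline run
#'
#' Bundles the stage configurations and thresholds. All randomness flows
#' from `seed`: the comodule-discovery RNG uses `seed + 1000` and the
#' genetic algorithm on the i-th comodule uses `seed + 2000 + i`, so each
#' stage is independently reproducible.
#'
#' @param ppa A `ppa_config`.
#' @param ga A `ga_config`.
#' @param alpha_disease Significance level for disease-associated term
#'   identification.
#' @param alpha_edge Significance level for network edge correlations.
#' @param weights Rank-aggregation weights `(alpha, beta, gamma)`.
#' @param seed Top-level integer seed.
#' @param max_comodule_genes Comodules with more genes than this are
#'   skipped by the module-extraction stage (guards against degenerate,
#'   near-global comodules).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ppa = ppa_config(), ga = ga_config(),
                            alpha_disease = 0.05, alpha_edge = 0.05,
                            weights = c(1, 1, 1) / 3, seed = 1L,
                            max_comodule_genes = 1000L) {
  stopifnot(inherits(ppa, "ppa_config"), inherits(ga, "ga_config"),
            length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  structure(list(ppa = ppa, ga = ga, alpha_disease = alpha_disease,
                 alpha_edge = alpha_edge, weights = weights,
                 seed = as.integer(seed),
                 max_comodule_genes = as.integer(max_comodule_genes)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `ppa`, `ga`, `alpha_disease`, `alpha_edge`, `weights`,
#' `seed`, `max_comodule_genes`; the `ppa`/`ga` blocks hold the arguments
#' of [ppa_config()] / [ga_config()]. Missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(ppa = do.call(ppa_config, as.list(y$ppa)),
               ga = do.call(ga_config, as.list(y$ga)))
  for (k in c("alpha_disease", "alpha_edge", "weights", "seed",
              "max_comodule_genes")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

#' Run the full module-discovery pipeline on input files
#'
#' Executes, in order: input loading, comodule discovery, disease-term
#' identification, module extraction by the genetic algorithm, per-category
#' rank aggregation, regulatory-network construction for each category's
#' top-ranked module, and active-member tabulation. Every stage writes its
#' artifact under `out_dir`, and `manifest.json` records the configuration,
#' derived seeds and stage row counts. Rerunning with an identical
#' configuration and inputs reproduces identical artifacts.
#'
#' @param genes_path,mirnas_path Expression TSVs (features x samples).
#' @param annot_path Two-column sample annotation TSV.
#' @param target_paths Character vector of target-source TSVs.
#' @param gmt_path Gene-set GMT file.
#' @param disease_path Disease gene list (one id per line).
#' @param out_dir Output directory (created if absent).
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`pe`, `comodules`, `disease_terms`, `mfrms`, `ranked`, `networks`,
#'   `active`, `manifest`).
#' @export
run_pipeline <- function(genes_path, mirnas_path, annot_path, target_paths,
                         gmt_path, disease_path, out_dir,
                         cfg = pipeline_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("load", {
    genes_half <- read_expression(genes_path, annot_path)
    mirnas_half <- read_expression(mirnas_path, annot_path)
    pe <- pair_expression(genes_half, mirnas_half)
    targets <- read_target_sources(target_paths, pe$mirna_ids, pe$gene_ids)
    go <- read_gmt(gmt_path, universe = pe$gene_ids)
    disease <- read_disease_genes(disease_path)
    list(pe = pe, targets = targets, go = go, disease = disease)
  })
  pe <- inputs$pe

  ppa_cfg <- inputs_ppa_cfg <- cfg$ppa
  ppa_cfg$rng_seed <- cfg$seed + 1000L
  comodules <- stage("ppa", run_ppa(pe, ppa_cfg))
  write_comodules(comodules, file.path(out_dir, "comodules.jsonl"))

  disease_terms <- stage("disease-go",
                         disease_go_terms(inputs$go, inputs$disease,
                                          alpha = cfg$alpha_disease))
  utils::write.table(disease_terms, file.path(out_dir, "disease_terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  disease_sets <- inputs$go$sets[disease_terms$term_id]

  mfrm_out <- stage("moga", {
    all_mfrms <- list()
    contexts <- list()
    for (i in seq_along(comodules)) {
      cm <- comodules[[i]]
      if (length(cm$genes) > cfg$max_comodule_genes) next
      ctx <- comodule_context(cm, pe, inputs$targets, disease_sets)
      ga_cfg <- cfg$ga
      ga_cfg$rng_seed <- cfg$seed + 2000L + i
      front <- evolve(ctx, ga_cfg)
      contexts[[as.character(cm$seed_id)]] <- ctx
      all_mfrms <- c(all_mfrms, front)
    }
    list(mfrms = all_mfrms, contexts = contexts)
  })
  mfrms <- mfrm_out$mfrms
  write_mfrms(mfrms, file.path(out_dir, "mfrms.jsonl"))

  ranked <- stage("rank", categorize_and_rank(mfrms, cfg$weights))
  write_ranked(ranked, file.path(out_dir, "ranked_mfrms.tsv"))

  networks <- stage("network", {
    nets <- list()
    for (cat in names(ranked)) {
      df <- ranked[[cat]]
      if (nrow(df) == 0L) next
      top <- df$mfrm[[1L]]
      ctx <- mfrm_out$contexts[[as.character(top$comodule_id)]]
      if (is.null(ctx)) next
      net <- build_network(top, ctx, alpha_edge = cfg$alpha_edge)
      safe <- gsub("[^A-Za-z0-9._-]", "_", cat)
      write_network(net, file.path(out_dir, paste0("network_", safe, ".tsv")),
                    format = "tsv")
      write_network(net, file.path(out_dir, paste0("network_", safe, ".sif")),
                    format = "sif")
      nets[[cat]] <- net
    }
    nets
  })

  active <- stage("active", active_members(ranked))
  active_df <- do.call(rbind, c(lapply(names(active), function(cat) {
    rbind(
      if (nrow(active[[cat]]$mirnas)) cbind(category = cat, kind = "mirna",
                                            active[[cat]]$mirnas),
      if (nrow(active[[cat]]$genes)) cbind(category = cat, kind = "gene",
                                           active[[cat]]$genes))
  }), list(make.row.names = FALSE)))
  if (is.null(active_df)) {
    active_df <- data.frame(category = character(), kind = character(),
                            id = character(), count = integer())
  }
  utils::write.table(active_df, file.path(out_dir, "active_members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = list(
      ppa = unclass(inputs_ppa_cfg), ga = unclass(cfg$ga),
      alpha_disease = cfg$alpha_disease, alpha_edge = cfg$alpha_edge,
      weights = cfg$weights, seed = cfg$seed,
      max_comodule_genes = cfg$max_comodule_genes),
    seeds = list(ppa = cfg$seed + 1000L,
                 ga_base = cfg$seed + 2000L),
    counts = list(genes = length(pe$gene_ids),
                  mirnas = length(pe$mirna_ids),
                  samples = length(pe$sample_ids),
                  comodules = length(comodules),
                  disease_terms = nrow(disease_terms),
                  mfrms = length(mfrms),
                  categories = length(ranked)),
    versions = list(mirmodule = as.character(utils::packageVersion("mirmodule")),
                    r = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(pe = pe, comodules = comodules,
                 disease_terms = disease_terms, mfrms = mfrms,
                 ranked = ranked, networks = networks, active = active,
                 manifest = manifest))
}
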