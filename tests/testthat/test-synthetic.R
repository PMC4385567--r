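test_that("planted structures are disjoint and recorded in the truth", {
  sd_ <- default_synth(1)
  tr <- sd_$truth
  expect_length(tr$planted_comodules, 3)
  for (comp in c("genes", "mirnas", "samples")) {
    all_ids <- unlist(lapply(tr$planted_comodules, `[[`, comp))
    expect_identical(anyDuplicated(all_ids), 0L)
  }
  for (k in 1:3) {
    expect_true(all(tr$planted_cores[[k]]$genes %in%
                      tr$planted_comodules[[k]]$genes))
    expect_true(all(tr$planted_cores[[k]]$mirnas %in%
                      tr$planted_comodules[[k]]$mirnas))
    # every core's genes lie inside exactly one planted disease term
    hits <- vapply(sd_$go$sets[tr$disease_term_map], function(s)
      all(tr$planted_cores[[k]]$genes %in% s), TRUE)
    expect_identical(sum(hits), 1L)
  }
  expect_true(all(sd_$disease %in% sd_$go$universe))
})

test_that("generation is deterministic and validates its configuration", {
  a <- generate_synthetic(synth_config(n_genes = 300L, n_mirnas = 40L,
                                       n_samples = 30L, go_term_size = 50L,
                                       rng_seed = 3L))
  b <- generate_synthetic(synth_config(n_genes = 300L, n_mirnas = 40L,
                                       n_samples = 30L, go_term_size = 50L,
                                       rng_seed = 3L))
  expect_identical(a$pe$E, b$pe$E)
  expect_identical(a$targets$pairs, b$targets$pairs)
  expect_identical(a$truth$planted_comodules, b$truth$planted_comodules)
  expect_error(synth_config(n_genes = 10L, block_genes = 20L),
               "do not fit")
  expect_error(synth_config(core_genes = 30L, block_genes = 20L),
               "core must fit")
  expect_error(synth_config(core_target_sources = 9L, n_sources = 7L),
               "cannot exceed")
})

test_that("noise-free blocks give perfectly anticorrelated core pairs", {
  sd_ <- generate_synthetic(synth_config(n_genes = 200L, n_mirnas = 30L,
                                         n_samples = 30L, noise_sd = 0,
                                         amplitude_spread = 0.3,
                                         go_term_size = 30L, rng_seed = 5L))
  for (k in 1:3) {
    co <- sd_$truth$planted_cores[[k]]
    for (i in co$mirnas) {
      for (j in co$genes) {
        expect_equal(cor(sd_$pe$R[i, ], sd_$pe$E[j, ]), -1)
      }
    }
  }
})

test_that("core pairs are strongly anticorrelated and background is not", {
  rs_core <- c(); rs_bg <- c()
  for (seed in 1:5) {
    sd_ <- default_synth(seed)
    set.seed(seed)
    for (k in 1:3) {
      co <- sd_$truth$planted_cores[[k]]
      rs_core <- c(rs_core, cor(sd_$pe$R[co$mirnas[1], ],
                                sd_$pe$E[co$genes[1], ]))
    }
    block_g <- unlist(lapply(sd_$truth$planted_comodules, `[[`, "genes"))
    block_d <- unlist(lapply(sd_$truth$planted_comodules, `[[`, "mirnas"))
    bg_g <- sample(setdiff(sd_$pe$gene_ids, block_g), 5)
    bg_d <- sample(setdiff(sd_$pe$mirna_ids, block_d), 5)
    rs_bg <- c(rs_bg, vapply(1:5, function(i)
      cor(sd_$pe$R[bg_d[i], ], sd_$pe$E[bg_g[i], ]), 0))
  }
  expect_lte(mean(rs_core), -0.7)
  expect_lt(abs(mean(rs_bg)), 0.2)
})

test_that("written files reload through the standard readers unchanged", {
  d <- withr::local_tempdir()
  sd_ <- generate_synthetic(synth_config(n_genes = 300L, n_mirnas = 40L,
                                         n_samples = 30L, go_term_size = 50L,
                                         rng_seed = 7L), dir = d)
  g <- read_expression(file.path(d, "E.tsv"), file.path(d, "annotations.tsv"))
  r <- read_expression(file.path(d, "R.tsv"), file.path(d, "annotations.tsv"))
  pe <- pair_expression(g, r)
  expect_equal(pe$E, sd_$pe$E)
  expect_equal(pe$R, sd_$pe$R)
  expect_identical(pe$subtype_of, sd_$pe$subtype_of)
  ts <- suppressMessages(read_target_sources(
    list.files(file.path(d, "targets"), full.names = TRUE),
    pe$mirna_ids, pe$gene_ids))
  expect_equal(ts$pairs, sd_$targets$pairs)
  go <- read_gmt(file.path(d, "go_bp.gmt"), universe = pe$gene_ids)
  expect_setequal(names(go$sets), names(sd_$go$sets))
  expect_setequal(go$sets[[1]], sd_$go$sets[[1]])
  expect_setequal(read_disease_genes(file.path(d, "disease_genes.txt")),
                  sd_$disease)
  # byte-identical regeneration
  d2 <- withr::local_tempdir()
  generate_synthetic(synth_config(n_genes = 300L, n_mirnas = 40L,
                                  n_samples = 30L, go_term_size = 50L,
                                  rng_seed = 7L), dir = d2)
  for (f in c("E.tsv", "R.tsv", "annotations.tsv", "go_bp.gmt",
              "disease_genes.txt", "truth.json")) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d, f)))
  }
})

test_that("planted core gene sets are functionally homogeneous by construction", {
  sd_ <- default_synth(1)
  for (k in 1:3) {
    fh <- functional_homogeneity(sd_$truth$planted_cores[[k]]$genes, sd_$go)
    expect_true(fh$homogeneous)
  }
})

test_that("recovery scoring uses greedy best-match Jaccard", {
  sd_ <- default_synth(1)
  exact <- lapply(seq_along(sd_$truth$planted_comodules),
                  function(k) comodule_from_truth(sd_, k))
  rec <- evaluate_recovery(sd_$truth, exact, what = "comodules")
  expect_equal(rec$recall, 1)
  expect_true(all(rec$table$genes == 1 & rec$table$mirnas == 1 &
                    rec$table$samples == 1))
  expect_equal(evaluate_recovery(sd_$truth, list(),
                                 what = "comodules")$recall, 0)
  # hand-computed partial overlap: 18 of 20 genes plus 2 extras
  partial <- exact
  pl <- sd_$truth$planted_comodules[[1]]
  extras <- setdiff(sd_$pe$gene_ids,
                    unlist(lapply(sd_$truth$planted_comodules, `[[`, "genes")))
  genes <- c(pl$genes[1:18], extras[1:2])
  partial[[1]]$genes <- stats::setNames(rep(1, 20), genes)
  rec2 <- evaluate_recovery(sd_$truth, partial, what = "comodules")
  expect_equal(rec2$table$genes[1], 18 / 22)
  expect_false(rec2$table$recovered[1])
})
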