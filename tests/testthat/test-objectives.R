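test_that("pearson_with_p matches the t-transform closed form", {
  perfect <- pearson_with_p(c(1, 2, 3, 4), c(-1, -2, -3, -4))
  expect_equal(perfect$r, -1)
  expect_equal(perfect$p, 0)
  const <- pearson_with_p(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(const[c("r", "p")], list(r = 0, p = 1))
  expect_true(const$degenerate)
  short <- pearson_with_p(c(1, 2), c(3, 1))
  expect_true(short$degenerate)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  got <- pearson_with_p(x, y)
  expect_equal(got$r, 0.8)
  expect_equal(got$p, 2 * pt(-0.8 * sqrt(3) / sqrt(1 - 0.64), df = 3))
})

test_that("between-class variance is the size-weighted spread of class means", {
  expect_equal(between_class_variance(rep(2, 6), rep(c("a", "b"), 3)), 0)
  expect_equal(between_class_variance(c(0, 0, 1, 1), c("a", "a", "b", "b")),
               0.25)
  v <- rnorm(9); l <- rep(c("a", "b", "c"), 3)
  expect_equal(between_class_variance(v + 7, l), between_class_variance(v, l))
  expect_equal(between_class_variance(c(1, 2, 3), rep("a", 3)), 0)
})

test_that("module coherence objectives follow the significance-gated means", {
  ctx <- random_context(3, 4, seed = 1)
  # overwrite with known values
  ctx$corr <- matrix(c(-0.9, 0.5), 1, 2, dimnames = list("d1", c("g1", "g2")))
  ctx$corr_p <- matrix(c(0.01, 0.3), 1, 2,
                       dimnames = list("d1", c("g1", "g2")))
  ctx$corr_gated <- ctx$corr * (ctx$corr_p < 0.05)
  ctx$targets <- matrix(c(1, 0), 1, 2, dimnames = list("d1", c("g1", "g2")))
  ctx$mirna_ids <- "d1"; ctx$gene_ids <- c("g1", "g2")
  expect_equal(compute_cc(character(0), character(0), ctx), 0)
  expect_equal(compute_cc("d1", "g1", ctx), -0.9)
  expect_equal(compute_cc("d1", c("g1", "g2"), ctx), (-0.9 + 0) / 2)
  expect_equal(compute_tc(character(0), "g1", ctx), 0)
  expect_equal(compute_tc("d1", "g1", ctx), -1)
  expect_equal(compute_tc("d1", c("g1", "g2"), ctx), -0.5)
})

test_that("FP is the minimum Bonferroni-corrected disease-term enrichment", {
  universe <- 5000L
  term <- paste0("g", 1:20)
  ctx <- structure(list(mirna_ids = "d1", gene_ids = paste0("g", 1:30),
                        disease_terms = c(list(T1 = term),
                                          lapply(1:62, function(i)
                                            paste0("z", i, "_", 1:20))),
                        universe_size = universe),
                   class = "comodule_context")
  expect_equal(compute_fp(character(0), ctx), 1)
  expect_equal(compute_fp(paste0("g", 25:30), ctx), 1)   # disjoint from terms
  fp <- compute_fp(term, ctx)
  expect_equal(fp, min(1, 63 * hypergeom_upper_tail(20, 20, 20, 5000)))
  expect_lt(fp, 0.05)
})

test_that("FF averages normalized between-class variances of the selection", {
  ctx <- random_context(2, 2, seed = 2)
  ctx$variance_mi <- c(d1 = 1, d2 = 0.5)
  ctx$variance_mr <- c(g1 = 0, g2 = 1)
  expect_equal(compute_ff(character(0), character(0), ctx), 0)
  expect_equal(compute_ff(c("d1", "d2"), "g1", ctx), -0.5)
  expect_equal(compute_ff(c("d1", "d2"), c("g1", "g2"), ctx), -(2.5 / 4))
})

test_that("evaluate_selection decodes bit strings and satisfies identities", {
  ctx <- random_context(4, 6, seed = 3)
  expect_error(evaluate_selection(rep(1L, 9), ctx), "length")
  zero <- evaluate_selection(rep(0L, 10), ctx)
  expect_equal(zero[c("FP", "FC", "FF", "m_sel", "n_sel")],
               list(FP = 1, FC = 0, FF = 0, m_sel = 0L, n_sel = 0L),
               ignore_attr = TRUE)
  set.seed(4)
  for (i in 1:25) {
    bits <- rbinom(10, 1, 0.5)
    o <- evaluate_selection(bits, ctx)
    expect_equal(o$FC, o$cc + o$tc)
    sel_mi <- ctx$mirna_ids[as.logical(bits[1:4])]
    sel_mr <- ctx$gene_ids[as.logical(bits[5:10])]
    expect_equal(o$cc, compute_cc(sel_mi, sel_mr, ctx))
    expect_equal(o$tc, compute_tc(sel_mi, sel_mr, ctx))
    expect_equal(o$FP, compute_fp(sel_mr, ctx))
    expect_equal(o$FF, compute_ff(sel_mi, sel_mr, ctx))
    expect_true(o$cc >= -1 && o$cc <= 1)
    expect_true(o$tc >= -1 && o$tc <= 0)
    expect_true(o$FF >= -1 && o$FF <= 0)
  }
})

test_that("batch evaluation agrees with per-selection evaluation", {
  ctx <- random_context(5, 7, seed = 5)
  set.seed(6)
  pop <- matrix(rbinom(40 * 12, 1, 0.4), nrow = 40)
  ev <- mirmodule:::evaluate_population(pop, ctx)
  for (i in seq_len(nrow(pop))) {
    o <- evaluate_selection(pop[i, ], ctx)
    expect_equal(ev$FP[i], o$FP)
    expect_equal(ev$FC[i], o$FC)
    expect_equal(ev$FF[i], o$FF)
    expect_equal(ev$m_sel[i], o$m_sel)
    expect_equal(ev$n_sel[i], o$n_sel)
  }
})

test_that("a comodule context matches direct recomputation from raw data", {
  sd_ <- default_synth(1)
  ctx <- planted_context(sd_, 1)
  pe <- sd_$pe
  cm_samples <- ctx$sample_ids
  # correlations and p-values: independent recomputation with cor.test
  set.seed(8)
  for (i in sample(ctx$mirna_ids, 2)) {
    for (j in sample(ctx$gene_ids, 4)) {
      ct <- cor.test(pe$R[i, cm_samples], pe$E[j, cm_samples])
      expect_equal(ctx$corr[i, j], unname(ct$estimate))
      expect_equal(ctx$corr_p[i, j], ct$p.value)
    }
  }
  # target coefficients: recount from the raw source tables
  for (i in sample(ctx$mirna_ids, 2)) {
    for (j in sample(ctx$gene_ids, 4)) {
      hits <- vapply(sd_$source_pairs, function(df)
        any(df$mirna == i & df$gene == j), TRUE)
      expect_equal(ctx$targets[i, j], sum(hits) / length(sd_$source_pairs))
    }
  }
  # normalized variances span [0, 1] with the extremes attained
  expect_equal(max(ctx$variance_mi), 1)
  expect_gte(min(ctx$variance_mi), 0)
  expect_equal(max(ctx$variance_mr), 1)
  # comodules with fewer than 3 samples treat every pair as non-significant
  cm_small <- comodule_from_truth(sd_, 1)
  cm_small$samples <- cm_small$samples[1:2]
  ctx_small <- comodule_context(cm_small, pe, sd_$targets, ctx$disease_terms)
  expect_true(all(ctx_small$corr_p == 1))
  expect_true(all(ctx_small$corr_gated == 0))
})
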