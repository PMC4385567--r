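test_that("read_expression echoes the matrix and joins annotations by id", {
  d <- withr::local_tempdir()
  ep <- write_expr_file(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"),
                        file.path(d, "E.tsv"))
  # annotation order is a permutation of the header order
  ap <- write_expr_file(c("s2\tB", "s1\tA"), file.path(d, "ann.tsv"))
  half <- read_expression(ep, ap)
  expect_identical(half$mat,
                   matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                          dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
  expect_identical(half$subtype_of, c(s1 = "A", s2 = "B"))
})

test_that("read_expression rejects bad input with informative errors", {
  d <- withr::local_tempdir()
  ap <- write_expr_file(c("s1\tA", "s2\tA"), file.path(d, "ann.tsv"))
  dup <- write_expr_file(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"),
                         file.path(d, "dup.tsv"))
  expect_error(read_expression(dup, ap), "duplicate feature id.*g1")
  bad <- write_expr_file(c("gene\ts1\ts2", "g1\t1\tx2"),
                         file.path(d, "bad.tsv"))
  expect_error(read_expression(bad, ap), "non-numeric.*row 1.*s2")
  noann <- write_expr_file(c("gene\ts1\ts3", "g1\t1\t2"),
                           file.path(d, "noann.tsv"))
  expect_error(read_expression(noann, ap), "without subtype annotation: s3")
})

test_that("rows with missing values are dropped at load", {
  d <- withr::local_tempdir()
  ep <- write_expr_file(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t4"),
                        file.path(d, "E.tsv"))
  ap <- write_expr_file(c("s1\tA", "s2\tA"), file.path(d, "ann.tsv"))
  expect_message(half <- read_expression(ep, ap), "1 feature row")
  expect_identical(rownames(half$mat), "g1")
})

test_that("readers accept gzip-compressed files", {
  d <- withr::local_tempdir()
  gz <- gzfile(file.path(d, "E.tsv.gz"), "w")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2"), gz)
  close(gz)
  ap <- write_expr_file(c("s1\tA", "s2\tB"), file.path(d, "ann.tsv"))
  half <- read_expression(file.path(d, "E.tsv.gz"), ap)
  expect_identical(unname(half$mat[1, ]), c(1, 2))
})

test_that("pair_expression keeps the sample intersection regardless of order", {
  mk <- function(samples, ids = c("f1", "f2")) {
    m <- matrix(seq_len(2 * length(samples)), nrow = 2,
                dimnames = list(ids, samples))
    structure(list(mat = m,
                   subtype_of = stats::setNames(rep("A", length(samples)),
                                                samples)),
              class = "expression_half")
  }
  g <- mk(c("s1", "s2", "s3")); r <- mk(c("s2", "s3", "s4"), c("d1", "d2"))
  expect_message(pe <- pair_expression(g, r), "2 unmatched")
  expect_identical(pe$sample_ids, c("s2", "s3"))
  pe_rev <- suppressMessages(pair_expression(mk(c("s2", "s3", "s4")),
                                             mk(c("s1", "s2", "s3"),
                                                c("d1", "d2"))))
  expect_setequal(pe$sample_ids, pe_rev$sample_ids)
  # identical sample sets: no drops, gene-half order kept
  g2 <- mk(c("s3", "s1", "s2")); r2 <- mk(c("s1", "s2", "s3"), c("d1", "d2"))
  expect_silent(pe2 <- pair_expression(g2, r2))
  expect_identical(pe2$sample_ids, c("s3", "s1", "s2"))
  expect_error(pair_expression(mk("s1"), mk("s9", c("d1", "d2"))),
               "share no samples")
})

test_that("target sources aggregate to per-pair prediction frequencies", {
  d <- withr::local_tempdir()
  # pair (m1, g1) in sources 1-3, duplicated twice inside source 1
  for (i in 1:7) {
    rows <- if (i <= 3) c("m1\tg1", "m1\tg1")[seq_len(ifelse(i == 1, 2, 1))]
            else character(0)
    writeLines(c(rows, "m2\tg2"), file.path(d, paste0("src", i, ".tsv")))
  }
  paths <- file.path(d, paste0("src", 1:7, ".tsv"))
  ts <- read_target_sources(paths, c("m1", "m2"), c("g1", "g2"))
  expect_equal(ts$n_sources, 7L)
  tm <- target_score_matrix(ts, c("m1", "m2"), c("g1", "g2"))
  expect_equal(tm["m1", "g1"], 3 / 7)
  expect_equal(tm["m2", "g2"], 1)       # in all 7 files
  expect_equal(tm["m1", "g2"], 0)       # in none
  # order-invariance over the file list
  ts2 <- read_target_sources(rev(paths), c("m1", "m2"), c("g1", "g2"))
  expect_identical(ts$pairs, ts2$pairs)
  expect_error(read_target_sources(character(0), "m1", "g1"),
               "at least one")
  # unknown identifiers dropped with a message
  expect_message(
    ts3 <- read_target_sources(paths[1], "m1", "g1"),
    "unknown identifiers")
  expect_equal(target_score_matrix(ts3, "m1", "g1")[1, 1], 1)
})

test_that("read_gmt restricts to the universe and validates lines", {
  d <- withr::local_tempdir()
  p <- write_expr_file(c("T1\tdesc one\ta\tb\tc",
                         "T2\tdesc two\tz1\tz2",
                         "T3\tdesc three\tb\tc"),
                       file.path(d, "sets.gmt"))
  expect_message(gs <- read_gmt(p, universe = c("a", "b")),
                 "1 gene set")
  expect_named(gs$sets, c("T1", "T3"))
  expect_setequal(gs$sets$T1, c("a", "b"))
  expect_setequal(gs$sets$T3, "b")
  bad <- write_expr_file(c("T1\tonly-two-fields"), file.path(d, "bad.gmt"))
  expect_error(read_gmt(bad, universe = "a"), "line 1")
})

test_that("a paired expression object round-trips through disk", {
  pe <- tiny_pe()
  d <- withr::local_tempdir()
  write_paired_expression(pe, d)
  g <- read_expression(file.path(d, "E.tsv"), file.path(d, "annotations.tsv"))
  r <- read_expression(file.path(d, "R.tsv"), file.path(d, "annotations.tsv"))
  pe2 <- pair_expression(g, r)
  expect_identical(pe2$E, pe$E)
  expect_identical(pe2$R, pe$R)
  expect_identical(pe2$sample_ids, pe$sample_ids)
  expect_identical(pe2$subtype_of, pe$subtype_of)
})

test_that("disease gene lists load as unique non-empty identifiers", {
  d <- withr::local_tempdir()
  p <- write_expr_file(c("g1", "", "g2", "g1"), file.path(d, "dis.txt"))
  expect_setequal(read_disease_genes(p), c("g1", "g2"))
  empty <- write_expr_file("", file.path(d, "empty.txt"))
  expect_error(read_disease_genes(empty), "empty")
})
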