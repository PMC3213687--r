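test_that("GMT files read back in file order, de-duplicated, with errors on malformed lines", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("A\tfirst\tg1\tg2", "B\tsecond\tg2"), gmt)
  coll <- read_gmt(gmt)
  expect_s3_class(coll, "gene_set_tbl")
  expect_equal(unique(coll$set), c("A", "B"))
  expect_equal(nrow(coll), 3)

  writeLines("S\tdesc\tg1\tg1\tg2", gmt)
  expect_warning(coll2 <- read_gmt(gmt), "duplicate")
  expect_equal(coll2$gene, c("g1", "g2"))

  writeLines("S\tdesc", gmt)
  expect_error(read_gmt(gmt), "line 1")

  writeLines(c("S\td\tg1", "S\td\tg2"), gmt)
  expect_error(read_gmt(gmt), "Duplicate set name")
})

test_that("GMT write/read round trip is lossless", {
  coll <- toy_collection()
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, gmt)
  back <- read_gmt(gmt)
  expect_equal(back$set, coll$set)
  expect_equal(back$gene, coll$gene)
})

test_that("appearance frequency counts distinct sets per gene and sums to total membership", {
  f <- appearance_frequency(toy_collection())
  expect_equal(tibble::deframe(f), c(g1 = 1L, g2 = 2L, g3 = 1L))
  expect_equal(sum(f$f), nrow(toy_collection()))

  single <- gene_set_tbl(tibble::tibble(set = "S", gene = "g1"))
  expect_equal(appearance_frequency(single)$f, 1L)

  # brute-force oracle on a generated collection, incl. a gene in every set
  set.seed(7)
  n_sets <- 195
  sets <- sprintf("P%03d", seq_len(n_sets))
  rows <- purrr::map(sets, function(s) {
    tibble::tibble(set = s, gene = c("ubiq", sample(sprintf("g%02d", 1:50), 5)))
  })
  coll <- gene_set_tbl(dplyr::bind_rows(rows))
  f <- appearance_frequency(coll)
  oracle <- table(unique(as.data.frame(coll[c("set", "gene")]))$gene)
  expect_equal(f$f, as.integer(oracle[f$gene]))
  expect_equal(f$f[f$gene == "ubiq"], 195L)
})

test_that("IDF follows log(n_pathways / f) and validates its inputs", {
  f <- tibble::tibble(gene = c("a", "b", "c"), f = c(195L, 1L, 39L))
  out <- add_idf(f, n_pathways = 195)
  expect_equal(out$idf, c(0, log(195), log(5)), tolerance = 1e-12)
  expect_equal(out$idf[2], 5.2730, tolerance = 1e-4)
  expect_equal(out$idf[3], 1.6094, tolerance = 1e-4)
  expect_equal(attr(out, "mean_idf"), mean(out$idf))

  expect_error(add_idf(tibble::tibble(gene = "a", f = 196L), n_pathways = 195),
               "exceeds")
  expect_error(add_idf(tibble::tibble(gene = "a", f = 0L), n_pathways = 195),
               ">= 1")
})

test_that("exponents reproduce hand-computed values and the neutral point", {
  f <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"), f = c(1L, 1L, 4L, 16L))
  out <- add_exponents(add_idf(f, n_pathways = 195))
  expect_equal(attr(out, "mean_idf"), 4.2333, tolerance = 1e-4)
  expect_equal(out$exponent_gsea, c(0.8028, 0.8028, 1.0892, 1.6930),
               tolerance = 1e-4)
  # reciprocal form for the regression branch
  expect_equal(out$exponent_lrpath, pmin(pmax(out$idf / 4.233279, 0.5), 2),
               tolerance = 1e-4)

  # idf == mean_idf => both exponents exactly 1 (equal frequencies)
  eq <- add_exponents(add_idf(
    tibble::tibble(gene = c("a", "b"), f = c(3L, 3L)), n_pathways = 195))
  expect_identical(eq$exponent_gsea, c(1, 1))
  expect_identical(eq$exponent_lrpath, c(1, 1))

  # high-frequency gene hits the cap; zero-idf gene maps to the cap
  hi <- add_exponents(add_idf(
    tibble::tibble(gene = c("a", "b", "c"), f = c(1L, 150L, 195L)),
    n_pathways = 195))
  expect_equal(hi$exponent_gsea[2], 2)
  expect_equal(hi$exponent_gsea[3], 2)

  # all genes in every set: mean_idf = 0 is an error
  allin <- add_idf(tibble::tibble(gene = c("a", "b"), f = c(5L, 5L)),
                   n_pathways = 5)
  expect_error(add_exponents(allin), "mean IDF")
})

test_that("exponent mapping is invariant to the logarithm base", {
  set.seed(11)
  f <- tibble::tibble(gene = sprintf("g%02d", 1:30),
                      f = sample(1:120, 30, replace = TRUE))
  e_nat <- add_exponents(add_idf(f, n_pathways = 195, log_base = exp(1)))
  e_10 <- add_exponents(add_idf(f, n_pathways = 195, log_base = 10))
  expect_equal(e_nat$exponent_gsea, e_10$exponent_gsea, tolerance = 1e-12)
  expect_equal(e_nat$exponent_lrpath, e_10$exponent_lrpath, tolerance = 1e-12)
})

test_that("idf decreases and exponent_gsea increases with frequency until the cap", {
  f <- tibble::tibble(gene = sprintf("g%03d", 1:194), f = 1:194)
  out <- add_exponents(add_idf(f, n_pathways = 195))
  expect_true(all(diff(out$idf) < 0))
  expect_true(all(diff(out$exponent_gsea) >= 0))
  uncapped <- out$exponent_gsea < 2
  expect_true(all(diff(out$exponent_gsea[uncapped]) > 0))
  expect_true(all(diff(out$exponent_lrpath) <= 0))
  expect_true(all(out$exponent_gsea <= 2 & out$exponent_gsea > 0))
  expect_true(all(out$exponent_lrpath <= 2 & out$exponent_lrpath >= 0.5))
})

test_that("random_frequency permutes the multiset reproducibly", {
  f <- tibble::tibble(gene = c("g1", "g2", "g3"), f = c(1L, 1L, 5L))
  out <- random_frequency(f, seed = 3, n_pathways = 10)
  expect_equal(sort(out$f), c(1L, 1L, 5L))

  one <- random_frequency(tibble::tibble(gene = "g", f = 2L), seed = 1,
                          n_pathways = 10)
  expect_equal(one$f, 2L)

  big <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                        f = rep(1:10, each = 10))
  a <- random_frequency(big, seed = 5, n_pathways = 10)
  b <- random_frequency(big, seed = 5, n_pathways = 10)
  d <- random_frequency(big, seed = 6, n_pathways = 10)
  expect_identical(a$f, b$f)
  expect_false(identical(a$f, d$f))
  # histogram preserved exactly
  expect_identical(table(a$f), table(big$f))
  # exponents recomputed for the permuted frequencies
  expect_equal(a$exponent_gsea,
               add_exponents(add_idf(a[c("gene", "f")], n_pathways = 10))$exponent_gsea)
})

test_that("inverse_frequency honours the endpoint rules and is antitone", {
  f <- tibble::tibble(gene = sprintf("g%02d", 1:23), f = c(1L, 25L, 2L, 20L, 3:21))
  out <- inverse_frequency(f, seed = 9, n_pathways = 195)
  expect_true(out$f[1] %in% 20:30)         # f = 1 -> random 20..30
  expect_equal(out$f[2], 1L)               # f = 25 (> 20) -> 1
  expect_equal(out$f[3], 19L)              # f = 2 -> 21 - f
  expect_equal(out$f[4], 1L)               # f = 20 -> 21 - 20
  expect_true(all(out$f >= 1))

  # antitone on the deterministic part; the random f=1 band sits above it
  det <- tibble::tibble(gene = sprintf("g%02d", 2:30), f = 2:30)
  inv <- inverse_frequency(det, seed = 1, n_pathways = 195)
  expect_true(all(diff(inv$f) <= 0))
  expect_true(min(20:30) >= max(inv$f[det$f == 2]))

  # reproducible given the seed
  expect_identical(inverse_frequency(f, seed = 9, n_pathways = 195)$f, out$f)

  # small collections: inverse values truncated at n_pathways
  small <- inverse_frequency(
    tibble::tibble(gene = c("g1", "g2"), f = c(1L, 2L)), seed = 2,
    n_pathways = 25)
  expect_lte(small$f[1], 25L)
  expect_gte(small$f[1], 20L)
  expect_equal(small$f[2], 19L)
})

test_that("frequency tables round-trip through TSV", {
  tab <- frequency_table(toy_collection())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_tsv(tab, tsv)
  back <- read_frequency_tsv(tsv)
  expect_equal(back$gene, tab$gene)
  expect_equal(back$exponent_gsea, tab$exponent_gsea, tolerance = 1e-12)
})
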