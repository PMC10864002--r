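test_that("expression matrix validation rejects malformed input", {
  vals <- matrix(0:5, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_s3_class(expression_matrix(vals, layer = "counts"), "ExpressionMatrix")
  expect_error(expression_matrix(vals, gene_ids = c("A", "A", "B"),
                                 sample_ids = c("s1", "s2"), layer = "counts"),
               "duplicate gene id")
  expect_error(expression_matrix(-vals, layer = "counts"), "non-negative")
  expect_error(expression_matrix(vals + 0.5, layer = "counts"), "integral")
  expect_error(expression_matrix(vals, gene_ids = c("A", "B"),
                                 sample_ids = c("s1", "s2"), layer = "counts"),
               "dimensions")
})

test_that("csv and mtx reads agree and round-trip, layer is inferred", {
  m <- toy_counts()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_expression(m, csv, format = "csv")
  m_csv <- read_expression(csv)
  expect_equal(m_csv$values, m$values)
  expect_identical(m_csv$layer, "counts")

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_expression(m, mtx, format = "mtx")
  m_mtx <- read_expression(mtx)
  expect_equal(m_mtx$values, m$values)
  expect_identical(m_mtx$gene_ids, m$gene_ids)

  # non-integral entries infer cpm
  m2 <- expression_matrix(m$values + 0.5, m$gene_ids, m$sample_ids,
                          layer = "cpm")
  write_expression(m2, csv, format = "csv")
  expect_identical(read_expression(csv)$layer, "cpm")

  # duplicate gene row in the file is a format error
  writeLines(c("gene_id,s1", "A,1", "A,2"), csv)
  expect_error(read_expression(csv), "duplicate gene id")
})

test_that("gmt parsing de-duplicates and validates", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tA\tB", "S2\tdesc\tX"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$S1$genes, c("A", "B"))
  expect_identical(sets$S2$genes, "X")

  writeLines("S1\tdesc_only", gmt)
  expect_error(read_gmt(gmt), "format error")

  # round-trip
  writeLines(c("S1\tna\tA\tB", "S2\tna\tX"), gmt)
  sets <- read_gmt(gmt)
  gmt2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt2)
  expect_identical(lapply(read_gmt(gmt2), `[[`, "genes"),
                   lapply(sets, `[[`, "genes"))
})

test_that("normalization matches direct arithmetic and preserves ranks", {
  m <- expression_matrix(matrix(c(1, 3), nrow = 2,
                                dimnames = list(c("A", "B"), "s1")),
                         layer = "counts")
  expect_equal(normalize_expression(m, "cpm")$values[, 1],
               c(A = 250000, B = 750000))

  m2 <- expression_matrix(matrix(c(0, 0, 4), nrow = 3,
                                 dimnames = list(c("A", "B", "C"), "s1")),
                          layer = "counts")
  expect_equal(normalize_expression(m2, "logcpm")$values[, 1],
               c(A = 0, B = 0, C = log2(1e6 + 1)))

  expect_error(normalize_expression(normalize_expression(m, "cpm"), "cpm"),
               "layer must be counts")
  zero <- expression_matrix(matrix(c(1, 0), nrow = 1,
                                   dimnames = list("A", c("s1", "s2"))),
                            layer = "counts")
  expect_error(normalize_expression(zero, "cpm"), "s2")

  # rank preservation within columns
  set.seed(42)
  vals <- matrix(rpois(200, 5), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  mm <- expression_matrix(vals, layer = "counts")
  cpm <- normalize_expression(mm, "cpm")
  for (j in 1:10) {
    expect_identical(rank(cpm$values[, j]), rank(vals[, j]))
  }
})

test_that("filter_cells applies gene-count and mito thresholds, idempotently", {
  vals <- cbind(c1 = c(5, 3, 2, 0, 0, 1),  # 4 genes detected
                c2 = c(9, 0, 0, 0, 0, 0),  # 1 gene detected
                c3 = c(1, 1, 1, 1, 0, 0),  # 4 genes
                c4 = c(2, 2, 0, 2, 2, 0))  # 4 genes
  rownames(vals) <- c("mt-Nd1", "GA", "GB", "GC", "GD", "GE")
  m <- expression_matrix(vals, layer = "counts")
  # min_genes = 3 removes c2; mito fraction: c1 5/11, c2 9/9, c3 1/4, c4 2/8
  f <- filter_cells(m, min_genes = 3, max_genes = 10, max_mito_frac = 0.5)
  expect_identical(f$sample_ids, c("c1", "c3", "c4"))
  # cells above the mito threshold are removed (c1: 5/11, c2: 9/9)
  f2 <- filter_cells(m, min_genes = 0, max_genes = 10, max_mito_frac = 0.30)
  expect_identical(f2$sample_ids, c("c3", "c4"))
  # vacuous thresholds return input unchanged
  f3 <- filter_cells(m, min_genes = 0, max_genes = Inf, max_mito_frac = 1)
  expect_equal(f3$values, m$values)
  # idempotence
  f4 <- filter_cells(f, min_genes = 3, max_genes = 10, max_mito_frac = 0.5)
  expect_equal(f4$values, f$values)
  expect_error(filter_cells(m, min_genes = 100), "all cells removed")
})

test_that("gene matching is case-insensitive (mouse vs human symbols)", {
  m <- expression_matrix(matrix(1:4, 2, dimnames = list(c("Ly6e", "Actb"),
                                                        c("s1", "s2"))),
                         layer = "counts")
  set <- gene_set("s", c("LY6E", "ACTB"))
  expect_silent(ifnsig:::match_set_genes(set, m$gene_ids))
  expect_identical(ifnsig:::match_set_genes(set, m$gene_ids), c(1L, 2L))
})

test_that("sample metadata validates enumerations", {
  meta <- sample_metadata(c("a", "b"), c("NR", "R"))
  expect_identical(meta$timing, c("PRE", "PRE"))
  expect_error(sample_metadata(c("a", "a"), "NR"), "duplicate")
  expect_error(sample_metadata("a", "responder"), "NR, R")
  expect_error(sample_metadata("a", "R", timing = "DURING"), "PRE, POST")
})
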