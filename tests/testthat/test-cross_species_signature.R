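test_that("functional signature is the ordered union of exactly three sets", {
  s1 <- gene_set("a", c("A", "B"))
  s2 <- gene_set("b", c("B", "C"))
  s3 <- gene_set("c", "D")
  u <- build_functional_signature(list(s1, s2, s3))
  expect_identical(u$genes, c("A", "B", "C", "D"))
  expect_identical(u$name, "functional_ifn_tnfa")
  same <- build_functional_signature(list(s1, s1, s1))
  expect_identical(same$genes, s1$genes)
  expect_error(build_functional_signature(list(s1, s2)), "exactly three")

  # packaged-style fixtures: size equals an independently computed union
  sets <- synthetic_hallmark_sets(packaged_signature("neut_ifn15"),
                                  n_genes = 300, seed = 1)
  u2 <- build_functional_signature(sets)
  oracle <- unique(toupper(c(sets[[1]]$genes, sets[[2]]$genes,
                             sets[[3]]$genes)))
  expect_identical(length(u2$genes), length(oracle))
})

test_that("find_enriched_cluster returns the top-median cluster with exact p", {
  s <- signature_scores(sprintf("u%d", 1:6), "sig", "gsva",
                        c(10, 11, 12, 1, 2, 3))
  cl <- stats::setNames(rep(c("hot", "cold"), each = 3), sprintf("u%d", 1:6))
  res <- find_enriched_cluster(s, cl)
  expect_identical(res$cluster, "hot")
  # exact enumeration: all 3 top ranks in one cluster, p = 1/C(6,3)
  expect_equal(res$p_value, 1 / 20)

  # small clusters are excluded with a warning
  cl2 <- cl
  cl2["u6"] <- "tiny"
  expect_warning(res2 <- find_enriched_cluster(s, cl2), "excluding")
  expect_identical(res2$cluster, "hot")

  expect_error(find_enriched_cluster(s, stats::setNames(rep("one", 6),
                                                        names(cl))),
               "at least 2 clusters")
})

test_that("planted cluster is recovered from synthetic data", {
  sig <- gene_set("planted", paste0("PLANT", 1:10))
  sim <- simulate_single_cell(n_cells = 800, n_genes = 250, signature = sig,
                              shift_log2 = 2, seed = 31)
  logcpm <- normalize_expression(sim$matrix, "logcpm")
  scores <- module_score(logcpm, sig, seed = 1)
  res <- find_enriched_cluster(scores, sim$labels)
  expect_identical(res$cluster, "neutrophil_ifnhi")
  expect_lt(res$p_value, 1e-6)
})

test_that("derive_markers recovers planted genes and only them", {
  sig <- gene_set("planted", paste0("PLANT", 1:10))
  sim <- simulate_single_cell(n_cells = 1500, n_genes = 300, signature = sig,
                              shift_log2 = 2, seed = 41)
  logcpm <- normalize_expression(sim$matrix, "logcpm")
  target <- names(sim$labels)[sim$labels == "neutrophil_ifnhi"]
  mk <- derive_markers(logcpm, target)
  expect_setequal(mk$gene, sig$genes)
  expect_true(all(mk$p_adj < 0.001 & mk$log2_fc > 1.5))

  # vacuous threshold
  expect_identical(nrow(derive_markers(logcpm, target, fc_min = Inf)), 0L)
  expect_error(derive_markers(logcpm, logcpm$sample_ids), "proper subset")
  expect_error(derive_markers(logcpm, character(0)), "empty")
})

test_that("derive_markers is invariant to unit and gene ordering and monotone", {
  sig <- gene_set("planted", paste0("PLANT", 1:5))
  sim <- simulate_single_cell(n_cells = 400, n_genes = 120, signature = sig,
                              shift_log2 = 2, seed = 51)
  logcpm <- normalize_expression(sim$matrix, "logcpm")
  target <- names(sim$labels)[sim$labels == "neutrophil_ifnhi"]
  base <- derive_markers(logcpm, target, all_genes = TRUE)

  gp <- sample(nrow(logcpm$values))
  up <- sample(ncol(logcpm$values))
  perm <- expression_matrix(logcpm$values[gp, up], layer = "logcpm")
  permed <- derive_markers(perm, target, all_genes = TRUE)
  ord <- match(base$gene, permed$gene)
  expect_equal(permed$p_value[ord], base$p_value)
  expect_equal(permed$log2_fc[ord], base$log2_fc)

  # thresholding monotonicity: stricter settings never add genes
  loose <- derive_markers(logcpm, target, fc_min = 0.5, alpha = 0.01)
  strict <- derive_markers(logcpm, target, fc_min = 1.5, alpha = 0.001)
  expect_true(all(strict$gene %in% loose$gene))
})

test_that("null data yields no markers at the stringent thresholds", {
  sig <- gene_set("planted", paste0("PLANT", 1:5))
  hits <- vapply(1:5, function(s) {
    sim <- simulate_single_cell(n_cells = 400, n_genes = 150,
                                signature = sig, shift_log2 = 0, seed = s)
    logcpm <- normalize_expression(sim$matrix, "logcpm")
    target <- names(sim$labels)[sim$labels == "neutrophil_ifnhi"]
    nrow(derive_markers(logcpm, target))
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("exclusive signature filters on expressing fractions and ranks", {
  mk <- data.frame(
    gene = c("A", "B", "C", "D"),
    log2_fc = c(3, 2.5, 4, 2),
    p_value = c(1e-10, 1e-8, 1e-6, 1e-4),
    p_adj = c(1e-8, 1e-6, 1e-4, 1e-2),
    frac_in = c(0.8, 0.9, 0.4, 0.7),
    frac_out = c(0.02, 0.05, 0.01, 0.3))
  class(mk) <- c("MarkerResult", "data.frame")
  # C fails frac_in, D fails frac_out
  expect_warning(s <- derive_exclusive_signature(mk, k = 15), "only 2")
  expect_identical(s$genes, c("A", "B"))
  s1 <- derive_exclusive_signature(mk, k = 1)
  expect_identical(s1$genes, "A")
  expect_warning(s0 <- derive_exclusive_signature(mk, frac_out_max = 0),
                 "no markers pass")
  expect_length(s0$genes, 0)
  expect_error(derive_exclusive_signature(mk[0, ]), "non-empty")
})

test_that("planted near-exclusive genes are recovered exactly", {
  sig <- gene_set("planted", paste0("PLANT", 1:8))
  sim <- simulate_single_cell(n_cells = 1500, n_genes = 300, signature = sig,
                              shift_log2 = 2, seed = 61)
  logcpm <- normalize_expression(sim$matrix, "logcpm")
  target <- names(sim$labels)[sim$labels == "neutrophil_ifnhi"]
  mk <- derive_markers(logcpm, target)
  s <- derive_exclusive_signature(mk, k = 8)
  expect_setequal(s$genes, sig$genes)
})
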