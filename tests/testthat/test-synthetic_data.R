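sig5 <- gene_set("planted5", paste0("PLANT", 1:5))

test_that("single-cell generator is deterministic and validates inputs", {
  a <- simulate_single_cell(n_cells = 200, n_genes = 60, signature = sig5,
                            shift_log2 = 1, seed = 11)
  b <- simulate_single_cell(n_cells = 200, n_genes = 60, signature = sig5,
                            shift_log2 = 1, seed = 11)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$labels, b$labels)
  c <- simulate_single_cell(n_cells = 200, n_genes = 60, signature = sig5,
                            shift_log2 = 1, seed = 12)
  expect_false(identical(a$matrix$values, c$matrix$values))
  expect_error(simulate_single_cell(n_genes = 3, signature = sig5),
               "exceed n_genes")
  expect_error(simulate_single_cell(cell_type_props = c(neutrophil = 0.5),
                                    signature = sig5), "sum to 1")
})

test_that("planted shift yields the stated fold-change; no shift yields none", {
  sim <- simulate_single_cell(n_cells = 2000, n_genes = 300,
                              signature = sig5, shift_log2 = 2, seed = 5)
  ifnhi <- sim$labels == "neutrophil_ifnhi"
  neut <- sim$labels == "neutrophil"
  sig_idx <- match(sig5$genes, sim$matrix$gene_ids)
  m_in <- rowMeans(sim$matrix$values[sig_idx, ifnhi, drop = FALSE])
  m_out <- rowMeans(sim$matrix$values[sig_idx, neut, drop = FALSE])
  lfc <- log2(m_in / m_out)
  # NB sampling tolerance: se of the mean ratio at these cell counts
  expect_true(all(abs(lfc - 2) < 0.5))
  expect_equal(mean(lfc), 2, tolerance = 0.1)

  null <- simulate_single_cell(n_cells = 2000, n_genes = 300,
                               signature = sig5, shift_log2 = 0, seed = 5)
  ifnhi <- null$labels == "neutrophil_ifnhi"
  neut <- null$labels == "neutrophil"
  x <- colMeans(null$matrix$values[sig_idx, ifnhi, drop = FALSE])
  y <- colMeans(null$matrix$values[sig_idx, neut, drop = FALSE])
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  expect_lt(abs(mean(x) - mean(y)), 3 * se)
})

test_that("generated counts satisfy the NB mean-variance relation", {
  # one gene per (mu, alpha) cell, 5000 draws each via a single-type sim
  sim <- simulate_single_cell(n_cells = 5000, n_genes = 50,
                              cell_type_props = c(neutrophil = 1),
                              ifnhi_share_of_neutrophils = 0,
                              signature = sig5, shift_log2 = 0, seed = 9)
  mu_true <- sim$truth$gene_means[, "neutrophil"]
  alpha_true <- sim$truth$alpha
  keep <- mu_true > 5
  v_obs <- apply(sim$matrix$values[keep, ], 1, stats::var)
  v_exp <- mu_true[keep] + alpha_true[keep] * mu_true[keep]^2
  expect_true(all(abs(v_obs / v_exp - 1) < 0.35))
  expect_lt(abs(mean(v_obs / v_exp) - 1), 0.1)
})

test_that("bulk cohort: expectation mode is exact and truth records effects", {
  ref <- lm10_synthetic()
  sim <- simulate_bulk_cohort(n_per_group = c(NR = 5, R = 5), sigmatrix = ref,
                              effect = list(ifnhi_frac = c(NR = 0.05, R = 0.20)),
                              noise_alpha = 0, seed = 2)
  expect_identical(sim$bulk$layer, "cpm")
  fr <- sim$truth$fractions$fractions
  prof <- ref$profiles
  for (j in seq_along(sim$bulk$sample_ids)) {
    mu <- as.numeric(prof %*% fr[j, ]) * sim$truth$scale
    expect_equal(sim$bulk$values[, j], mu, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_equal(sim$truth$group_mean_target_fraction,
               c(NR = 0.05, R = 0.20))
  expect_error(simulate_bulk_cohort(n_per_group = c(NR = 2, R = 5),
                                    sigmatrix = ref), "at least 3")
  expect_error(simulate_bulk_cohort(
    n_per_group = c(NR = 5, R = 5), sigmatrix = ref,
    effect = list(ifnhi_frac = c(NR = -0.1, R = 0.2))), "\\[0, 1\\]")
})

test_that("flow table generator: Beta structure, determinism, errors", {
  ft <- simulate_flow_table(seed = 4)
  expect_s3_class(ft, "FlowTable")
  expect_true(all(ft$ly6e_hi_freq >= 0 & ft$ly6e_hi_freq <= 1))
  expect_identical(ft, simulate_flow_table(seed = 4))
  expect_error(simulate_flow_table(concentration = 0), "> 0")
  expect_error(simulate_flow_table(n_per_group = c(NR = 0, R = 5)),
               "at least 1")

  # equal group means give chance-level separation on average
  aucs <- vapply(1:40, function(s) {
    f <- simulate_flow_table(mean_freqs = c(NR = 0.2, R = 0.2), seed = s)
    auc(f$ly6e_hi_freq[f$group == "R"], f$ly6e_hi_freq[f$group == "NR"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("default flow effect separates groups in most seeds", {
  # Monte-Carlo reference: means 0.05 vs 0.30, concentration 50, n = 25/25
  hits <- vapply(1:100, function(s) {
    f <- simulate_flow_table(seed = s)
    auc(f$ly6e_hi_freq[f$group == "R"], f$ly6e_hi_freq[f$group == "NR"]) > 0.85
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_flow_table(seed = 99))
  invisible(simulate_single_cell(n_cells = 50, n_genes = 30,
                                 signature = sig5, seed = 99))
  expect_identical(.Random.seed, before)
})
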