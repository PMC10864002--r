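test_that("dispersion formula matches the direct arithmetic oracles", {
  # values {2,4,6}: mu = 4, CV^2 = 4/16 = 0.25 = 1/mu  ->  alpha = 0
  expect_equal(estimate_dispersion(group_profile_from_values(c(2, 4, 6)))$alpha,
               0)
  # values {10,20,30,40}: mu = 25, CV^2 = (500/3)/625, 1/mu = 0.04
  a <- estimate_dispersion(group_profile_from_values(c(10, 20, 30, 40)))$alpha
  expect_equal(a, (500 / 3) / 625 - 0.04, tolerance = 1e-12)
  expect_equal(a, 0.2266667, tolerance = 1e-6)
  # constant values: CV = 0, raw alpha = -1/mu clamped to 0
  expect_equal(estimate_dispersion(group_profile_from_values(c(7, 7, 7)))$alpha,
               0)
  # mu = 0 genes carry alpha 0 and are flagged
  d0 <- estimate_dispersion(group_profile("NR", "t", "g", 0, 0))
  expect_equal(d0$alpha, 0)
  expect_true(d0$flagged_zero_mu)
  expect_error(group_profile("NR", "t", "g", -1, 0), ">= 0")
})

test_that("simulated replicates match NB moments (Poisson limit included)", {
  d <- structure(data.frame(gene = c("gP", "gNB", "gZ"), group = "NR",
                            cell_type = "t", mu = c(50, 50, 0), cv = 0,
                            alpha = c(0, 0.3, 0),
                            flagged_zero_mu = c(FALSE, FALSE, TRUE)),
                 class = c("DispersionTable", "data.frame"))
  reps <- simulate_replicates(list(NR = d), n_reps = 10000, seed = 5)$NR
  v <- apply(reps$values, 1, stats::var)
  expect_equal(v[["gP"]], 50, tolerance = 0.1)                 # Poisson
  expect_equal(v[["gNB"]], 50 + 0.3 * 2500, tolerance = 0.1)   # mu + a mu^2
  expect_true(all(reps$values["gZ", ] == 0))                   # mu = 0
  expect_error(simulate_replicates(list(NR = d), n_reps = 2), ">= 3")
  # determinism
  reps2 <- simulate_replicates(list(NR = d), n_reps = 100, seed = 5)$NR
  reps3 <- simulate_replicates(list(NR = d), n_reps = 100, seed = 5)$NR
  expect_identical(reps2$values, reps3$values)
})

test_that("dispersion -> simulation -> moment re-estimation recovers alpha", {
  grid <- expand.grid(mu = c(20, 100), alpha = c(0.1, 0.5))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; alpha <- grid$alpha[i]
    cv <- sqrt(1 / mu + alpha)
    prof <- group_profile("NR", "t", "g1", mu, cv)
    d <- estimate_dispersion(prof)
    expect_equal(d$alpha, alpha, tolerance = 1e-12)
    reps <- simulate_replicates(list(NR = d), n_reps = 5000,
                                seed = 100 + i)$NR
    alpha_hat <- estimate_dispersion(
      group_profile_from_values(reps$values))$alpha
    expect_equal(alpha_hat, alpha, tolerance = 0.15)
  }
})

make_null_disp <- function(n_genes = 60, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "ifnsig")
  with_seed(seed, {
    mu <- stats::rlnorm(n_genes, log(50), 1)
    alpha <- stats::runif(n_genes, 0.1, 0.5)
    d <- data.frame(gene = sprintf("g%03d", seq_len(n_genes)), group = "NR",
                    cell_type = "t", mu = mu, cv = sqrt(1 / mu + alpha),
                    alpha = alpha, flagged_zero_mu = FALSE)
    class(d) <- c("DispersionTable", "data.frame")
    d
  })
}

test_that("score_and_compare detects a planted shift and is antisymmetric", {
  dnr <- make_null_disp(seed = 7)
  sig_genes <- dnr$gene[1:10]
  dr <- dnr; dr$group <- "R"
  dr$mu[1:10] <- dr$mu[1:10] * 2
  dr$cv <- sqrt(1 / dr$mu + dr$alpha)
  reps <- simulate_replicates(list(NR = dnr, R = dr), n_reps = 50, seed = 3)
  set <- gene_set("planted", sig_genes)
  res <- score_and_compare(reps, set)
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$median_R, res$median_NR)
  expect_identical(res$direction, "R>NR")

  # swapping the group labels maps U to n1 n2 - U
  swapped <- list(NR = reps$R, R = reps$NR)
  swapped$NR$sample_ids <- sub("^R", "NR", swapped$NR$sample_ids)
  colnames(swapped$NR$values) <- swapped$NR$sample_ids
  swapped$R$sample_ids <- sub("^NR", "R", swapped$R$sample_ids)
  colnames(swapped$R$values) <- swapped$R$sample_ids
  res2 <- score_and_compare(swapped, set)
  expect_equal(res2$U, 50 * 50 - res$U)
  expect_identical(res2$direction, "NR>R")

  expect_error(score_and_compare(reps, gene_set("absent", c("NOPE1", "NOPE2"))),
               "fewer than 1|absent|NOPE")
})

test_that("run_dataset_panel isolates failures and is deterministic", {
  ref <- lm10_synthetic()
  sets <- packaged_signature("both")
  good <- simulate_bulk_cohort(n_per_group = c(NR = 12, R = 12),
                               sigmatrix = ref, noise_alpha = 0.1,
                               dataset = "ok1", seed = 71)
  bad_bulk <- expression_matrix(matrix(1:4, 2,
                                       dimnames = list(c("ZZ1", "ZZ2"),
                                                       c("s1", "s2"))),
                                layer = "counts")
  cohorts <- list(list(bulk = good$bulk, meta = good$meta, dataset = "ok1"),
                  list(bulk = bad_bulk,
                       meta = sample_metadata(c("s1", "s2"), c("NR", "R")),
                       dataset = "broken"))
  panel <- run_dataset_panel(cohorts, ref, sets, cell_type = "Neut_IFN",
                             n_reps = 20, seed = 5)
  expect_identical(unique(panel$table$dataset), "ok1")
  expect_identical(names(panel$failures), "broken")
  expect_identical(sort(unique(panel$table$signature)),
                   sort(c("Neut_IFN-15", "IFNg-6")))
  expect_true(all(panel$table$stars %in% c("NS", "*", "**", "***")))

  panel2 <- run_dataset_panel(cohorts, ref, sets, cell_type = "Neut_IFN",
                              n_reps = 20, seed = 5)
  expect_identical(panel$table, panel2$table)
})

test_that("significance stars reproduce the legend bins", {
  expect_identical(significance_stars(c(0.5, 0.009, 0.0009, 0.00009)),
                   c("NS", "*", "**", "***"))
  expect_identical(significance_stars(c(0.01, 0.001, 0.0001)),
                   c("NS", "*", "**"))
})
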