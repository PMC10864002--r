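#' Null calibration of the panel comparison
#'
#' Simulates panels under the global null — identical NB generating
#' parameters for NR and R — and counts how often the one-sided
#' [score_and_compare()] test rejects at `level`. Used to verify that the
#' model-based bootstrap's type-I error matches its nominal level.
#'
#' @param n_panels number of simulated panels (default 500).
#' @param n_genes gene-universe size per panel (default 100).
#' @param n_reps simulated replicates per group (default 20; the criterion
#'   leaves this free and a small value keeps the run inside CPU budget).
#' @param set_size signature size (default 10).
#' @param level rejection level tested (default 0.01).
#' @param seed root seed.
#' @return Integer number of rejections out of `n_panels`.
#' @export
acceptance_null_calibration <- function(n_panels = 500L, n_genes = 100L,
                                        n_reps = 20L, set_size = 10L,
                                        level = 0.01, seed = 1L) {
  rejections <- 0L
  for (b in seq_len(n_panels)) {
    sb <- derive_seed(seed, paste0("null_panel_", b))
    d <- with_seed(sb, {
      mu <- stats::rlnorm(n_genes, log(50), 1)
      alpha <- stats::runif(n_genes, 0.1, 0.5)
      data.frame(gene = sprintf("g%03d", seq_len(n_genes)), group = "NR",
                 cell_type = "t", mu = mu, cv = sqrt(1 / mu + alpha),
                 alpha = alpha, flagged_zero_mu = FALSE)
    })
    class(d) <- c("DispersionTable", "data.frame")
    dr <- d
    dr$group <- "R"
    reps <- simulate_replicates(list(NR = d, R = dr), n_reps = n_reps,
                                seed = derive_seed(sb, "reps"))
    res <- score_and_compare(reps, gene_set("null_set",
                                            d$gene[seq_len(set_size)]))
    if (res$p_value < level) rejections <- rejections + 1L
  }
  rejections
}

#' Planted-effect recovery pattern on a three-dataset panel
#'
#' Simulates a three-dataset bulk panel with a responder-specific
#' signature-gene shift planted in the first two datasets, runs the full
#' deconvolution-bootstrap chain, and reports whether the IFN-neutrophil
#' signature is starred (p < 0.01) on exactly the planted datasets.
#'
#' The scale-down relative to the 11-dataset panels this emulates is in
#' the number of datasets (3), not their size: each synthetic dataset keeps
#' a realistic ~130 samples (65 per response group).
#'
#' @param seed root seed.
#' @param shift_log2 planted responder shift (default 1, i.e. 2x).
#' @param n_reps simulated replicates per group (default 50).
#' @param n_per_group samples per group per dataset (default 65/65).
#' @param noise_alpha bulk NB dispersion (default 0.1).
#' @return `TRUE` if stars appear on the planted datasets only.
#' @export
acceptance_panel_pattern <- function(seed = 1L, shift_log2 = 1,
                                     n_reps = 50L,
                                     n_per_group = c(NR = 65L, R = 65L),
                                     noise_alpha = 0.1) {
  ref <- lm10_synthetic()
  sets <- packaged_signature("both")
  planted <- c(TRUE, TRUE, FALSE)
  cohorts <- lapply(1:3, function(d) {
    ds <- sprintf("dataset%d", d)
    sim <- simulate_bulk_cohort(
      n_per_group = n_per_group, sigmatrix = ref,
      effect = list(ifnhi_frac = c(NR = 0.10, R = 0.10),
                    signature = if (planted[d]) sets$neut_ifn15 else NULL,
                    shift_log2 = if (planted[d]) shift_log2 else 0),
      noise_alpha = noise_alpha, dataset = ds,
      seed = derive_seed(seed, ds))
    list(bulk = sim$bulk, meta = sim$meta, dataset = ds)
  })
  panel <- run_dataset_panel(cohorts, ref, sets, cell_type = "Neut_IFN",
                             n_reps = n_reps, seed = seed)
  if (length(panel$failures) > 0 || is.null(panel$table)) return(FALSE)
  tab <- panel$table[panel$table$signature == sets$neut_ifn15$name, ]
  starred <- tab$p_value[match(sprintf("dataset%d", 1:3), tab$dataset)] < 0.01
  identical(unname(starred), planted)
}

#' Coverage of the stratified-bootstrap AUC interval
#'
#' Generates cohorts with Beta-distributed biomarker values whose true AUC
#' `P(X_R > X_NR)` is computed by numerical integration, and reports how
#' often the 95% percentile interval of [stratified_bootstrap_ci()] covers
#' the truth. Cohort parameters (fixed a priori): responder frequencies
#' Beta(10, 30) (mean 0.25), non-responder Beta(4, 36) (mean 0.10) —
#' group means 0.25 / 0.10 at concentration 40 — with 30 subjects per
#' group.
#'
#' @param n_cohorts number of generated cohorts (default 500).
#' @param n_per_group subjects per group (default 30).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed root seed.
#' @return Proportion of cohorts whose CI covers the true AUC.
#' @export
acceptance_ci_coverage <- function(n_cohorts = 500L, n_per_group = 30L,
                                   n_boot = 1000L, seed = 1L) {
  a_r <- 10; b_r <- 30
  a_n <- 4; b_n <- 36
  true_auc <- stats::integrate(function(y) {
    stats::dbeta(y, a_n, b_n) * (1 - stats::pbeta(y, a_r, b_r))
  }, 0, 1, rel.tol = 1e-10)$value
  covered <- 0L
  for (b in seq_len(n_cohorts)) {
    sb <- derive_seed(seed, paste0("cohort_", b))
    draws <- with_seed(sb, {
      list(pos = stats::rbeta(n_per_group, a_r, b_r),
           neg = stats::rbeta(n_per_group, a_n, b_n))
    })
    ci <- stratified_bootstrap_ci(draws$pos, draws$neg, n_boot = n_boot,
                                  seed = derive_seed(sb, "boot"))
    if (ci$ci_low <= true_auc && true_auc <= ci$ci_high) {
      covered <- covered + 1L
    }
  }
  covered / n_cohorts
}
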