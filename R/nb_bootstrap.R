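#' Per-gene negative binomial dispersion from mean and CV
#'
#' Method-of-moments NB dispersion under the parameterization
#' `Var = mu + alpha * mu^2` (size = 1/alpha), for which
#' `CV^2 = 1/mu + alpha`; hence `alpha = CV^2 - 1/mu`, clamped below at 0
#' (the Poisson floor for sub-Poisson genes). Genes with `mu = 0` carry
#' `alpha = 0` and are flagged.
#'
#' @param profile a [group_profile()].
#' @return A `data.frame` of class `DispersionTable` with columns `gene`,
#'   `group`, `cell_type`, `mu`, `cv`, `alpha`, `flagged_zero_mu`.
#' @export
#' @examples
#' estimate_dispersion(group_profile_from_values(c(10, 20, 30, 40)))$alpha
estimate_dispersion <- function(profile) {
  stopifnot(inherits(profile, "GroupProfile"))
  mu <- profile$mu
  cv <- profile$cv
  alpha <- ifelse(mu > 0, pmax(0, cv^2 - 1 / mu), 0)
  structure(data.frame(gene = profile$gene_ids, group = profile$group,
                       cell_type = profile$cell_type, mu = mu, cv = cv,
                       alpha = alpha, flagged_zero_mu = mu == 0,
                       stringsAsFactors = FALSE),
            class = c("DispersionTable", "data.frame"))
}

#' Simulate NB model-based replicate samples
#'
#' For each group's dispersion table, draws `n_reps` independent replicate
#' samples per gene from `NB(mean = mu, Var = mu + alpha mu^2)`
#' (`size = 1/alpha`); genes with `alpha = 0` are drawn Poisson, genes with
#' `mu = 0` are all zeros. This is the model-based bootstrap that turns one
#' imputed profile per group into a population of simulated samples.
#'
#' @param disp a `DispersionTable` or named list of them (one per group).
#' @param n_reps replicates per group (minimum 3).
#' @param seed integer seed.
#' @return Named list of [expression_matrix()] objects (layer `counts`),
#'   one per group, with columns `<group>_rep<i>`.
#' @export
simulate_replicates <- function(disp, n_reps = 50L, seed = 1L) {
  if (inherits(disp, "DispersionTable")) {
    disp <- stats::setNames(list(disp), disp$group[[1L]])
  }
  if (n_reps < 3L) stop("n_reps must be >= 3", call. = FALSE)
  with_seed(seed, {
    lapply(stats::setNames(names(disp), names(disp)), function(g) {
      d <- disp[[g]]
      n_genes <- nrow(d)
      vals <- matrix(0, nrow = n_genes, ncol = n_reps)
      pois <- d$mu > 0 & d$alpha == 0
      nb <- d$mu > 0 & d$alpha > 0
      if (any(pois)) {
        vals[pois, ] <- stats::rpois(sum(pois) * n_reps, lambda = d$mu[pois])
      }
      if (any(nb)) {
        vals[nb, ] <- stats::rnbinom(sum(nb) * n_reps, mu = d$mu[nb],
                                     size = 1 / d$alpha[nb])
      }
      expression_matrix(vals, d$gene, paste0(g, "_rep", seq_len(n_reps)),
                        layer = "counts")
    })
  })
}

#' Score simulated replicates and compare response groups
#'
#' Pools the per-group replicate matrices, computes rank-ECDF enrichment
#' scores ([gsva_score()]) for each signature, normalizes scores within the
#' dataset ([normalize_scores()]), and tests R vs NR per signature with a
#' one-sided Mann-Whitney test (direction R greater, the IFN-signature
#' hypothesis; `alternative` is configurable).
#'
#' @param reps_by_group named list of [expression_matrix()] (`NR`, `R`)
#'   over an identical gene universe.
#' @param sets a [gene_set()] or list of them.
#' @param dataset dataset id recorded in the result.
#' @param tau GSVA weight exponent.
#' @param alternative test direction (default `"greater"`: R above NR).
#' @param normalize_method see [normalize_scores()].
#' @return A `data.frame` of class `BootstrapResult`: one row per
#'   signature with medians per group, U, p-value and direction; the
#'   per-replicate normalized scores are attached as attribute `"scores"`.
#' @export
score_and_compare <- function(reps_by_group, sets, dataset = "dataset1",
                              tau = 1, alternative = "greater",
                              normalize_method = "mad") {
  stopifnot(all(c("NR", "R") %in% names(reps_by_group)))
  nr <- reps_by_group[["NR"]]
  rr <- reps_by_group[["R"]]
  if (!identical(nr$gene_ids, rr$gene_ids)) {
    stop("groups must share an identical gene universe", call. = FALSE)
  }
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  pooled <- expression_matrix(cbind(nr$values, rr$values), nr$gene_ids,
                              c(nr$sample_ids, rr$sample_ids),
                              layer = "cpm")
  grp <- c(rep("NR", length(nr$sample_ids)), rep("R", length(rr$sample_ids)))
  scores <- gsva_score(pooled, sets, tau = tau)
  scores$dataset <- dataset
  scores <- normalize_scores(scores, method = normalize_method)
  rows <- lapply(sets, function(set) {
    sc <- scores[scores$signature == set$name, ]
    g <- grp[match(sc$unit_id, pooled$sample_ids)]
    mw <- mann_whitney(sc$score[g == "R"], sc$score[g == "NR"],
                       alternative = alternative)
    data.frame(dataset = dataset, signature = set$name,
               median_NR = stats::median(sc$score[g == "NR"]),
               median_R = stats::median(sc$score[g == "R"]),
               U = mw$statistic, p_value = mw$p_value,
               direction = if (mw$statistic >= mw$n1 * mw$n2 / 2) "R>NR" else "NR>R",
               n_NR = sum(g == "NR"), n_R = sum(g == "R"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  class(out) <- c("BootstrapResult", "data.frame")
  out
}

#' Significance stars at the panel thresholds
#'
#' Bins: `p < 0.01` = `*`, `p < 0.001` = `**`, `p < 0.0001` = `***`,
#' otherwise `NS`.
#'
#' @param p numeric p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**", ifelse(p < 1e-2, "*", "NS")))
}

#' Run the bulk enrichment panel over multiple datasets
#'
#' For each cohort: deconvolve fractions, impute per-group profiles for the
#' target cell type, estimate NB dispersions, simulate replicate samples,
#' and score/compare the signatures. A failing dataset is recorded and does
#' not abort the panel.
#'
#' @param cohorts list of cohorts, each `list(bulk =, meta =, dataset =)`.
#' @param ref a [signature_matrix_ref()].
#' @param sets list of [gene_set()] signatures to score.
#' @param cell_type target cell type in `ref` (e.g. the IFN-neutrophil
#'   column).
#' @param n_reps simulated replicates per group (default 50).
#' @param seed root seed; per-dataset seeds are derived deterministically.
#' @param tau,alternative,normalize_method passed to [score_and_compare()].
#' @param keep_intermediates if `TRUE`, per-dataset fractions, group
#'   profiles and dispersion tables are returned under `intermediates`.
#' @return list with `table` (heatmap-ready data.frame: dataset, signature,
#'   medians, U, p, stars), `failures` (named list of error messages) and,
#'   optionally, `intermediates`.
#' @export
run_dataset_panel <- function(cohorts, ref, sets, cell_type,
                              n_reps = 50L, seed = 1L, tau = 1,
                              alternative = "greater",
                              normalize_method = "mad",
                              keep_intermediates = FALSE) {
  results <- list()
  failures <- list()
  intermediates <- list()
  for (cohort in cohorts) {
    ds <- cohort$dataset
    res <- tryCatch({
      fr <- estimate_fractions(cohort$bulk, ref)
      profiles <- impute_group_profiles(cohort$bulk, fr, cohort$meta,
                                        cell_type)
      disp <- lapply(profiles, estimate_dispersion)
      reps <- simulate_replicates(disp, n_reps = n_reps,
                                  seed = derive_seed(seed, ds))
      if (keep_intermediates) {
        intermediates[[ds]] <- list(fractions = fr, profiles = profiles,
                                    dispersion = disp)
      }
      score_and_compare(reps, sets, dataset = ds, tau = tau,
                        alternative = alternative,
                        normalize_method = normalize_method)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ds]] <- conditionMessage(res)
    } else {
      results[[ds]] <- res
    }
  }
  table <- if (length(results)) {
    tab <- do.call(rbind, lapply(results, as.data.frame))
    tab$stars <- significance_stars(tab$p_value)
    rownames(tab) <- NULL
    tab
  } else {
    NULL
  }
  out <- list(table = table, failures = failures)
  if (keep_intermediates) out$intermediates <- intermediates
  out
}
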