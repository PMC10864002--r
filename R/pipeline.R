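#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter with its default; any subset
#' can be overridden via `override` (shallow-merged per section). The
#' configuration round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param override named list of sections (`sc`, `bulk`, `scoring`) whose
#'   entries replace the defaults.
#' @param seed root seed; all stage seeds derive from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @return A list of class `PipelineConfig`.
#' @export
default_config <- function(override = list(), seed = 1L, out_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sc = list(
      n_cells = 2000L, n_genes = 500L, shift_log2 = 2,
      ifnhi_share = 0.4, n_bins = 24L, n_ctrl = 100L,
      fc_min = 1.5, alpha = 0.001, adjust = "BH",
      frac_in_min = 0.5, frac_out_max = 0.1, k = 15L
    ),
    bulk = list(
      n_datasets = 3L, planted = c(TRUE, TRUE, FALSE), shift_log2 = 1,
      n_per_group = c(NR = 15L, R = 15L), ifnhi_frac = 0.10,
      noise_alpha = 0.1, depth = 2e5, n_reps = 50L,
      cell_type = "Neut_IFN", n_boot = 1000L
    ),
    scoring = list(tau = 1, normalize_method = "mad",
                   alternative = "greater")
  )
  for (sec in names(override)) {
    if (is.list(cfg[[sec]]) && is.list(override[[sec]])) {
      cfg[[sec]][names(override[[sec]])] <- override[[sec]]
    } else {
      cfg[[sec]] <- override[[sec]]
    }
  }
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [default_config()] object.
#' @param path JSON file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  default_config(override = raw[setdiff(names(raw), c("seed", "out_dir"))],
                 seed = raw$seed,
                 out_dir = raw$out_dir)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (config$bulk$n_reps < 3L) {
    stop("config error: bulk$n_reps must be >= 3", call. = FALSE)
  }
  if (config$sc$n_cells < 10L) {
    stop("config error: sc$n_cells must be >= 10", call. = FALSE)
  }
  invisible(config)
}

write_manifest <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # location-independent: reruns must be byte-identical
  manifest <- c(list(package = "ifnsig",
                     version = as.character(utils::packageVersion("ifnsig")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     config = cfg),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the single-cell signature-derivation pipeline
#'
#' End-to-end chain on synthetic data: simulate a single-cell cohort with a
#' planted IFN-high neutrophil state, build the functional signature (union
#' of three hallmark-style programs), score every cell with the
#' binned-control module score, locate the cluster enriched for the
#' signature, derive its markers, and reduce them to a near-exclusive
#' 15-gene signature. When `out_dir` is set, writes the derived GMT, the
#' marker and score CSVs and a reproducibility manifest; reruns with the
#' same seed are byte-identical.
#'
#' @param config a [default_config()] object.
#' @return list: `signature` (derived [gene_set()]), `markers`, `scores`,
#'   `enriched` (cluster call), `truth` (generator ground truth).
#' @export
run_sc_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  p <- config$sc
  planted <- packaged_signature("neut_ifn15")
  msg_stage("sc: simulating ", p$n_cells, " cells x ", p$n_genes, " genes")
  sim <- simulate_single_cell(n_cells = p$n_cells, n_genes = p$n_genes,
                              signature = planted,
                              shift_log2 = p$shift_log2,
                              ifnhi_share_of_neutrophils = p$ifnhi_share,
                              seed = derive_seed(seed, "sc_sim"))
  logcpm <- normalize_expression(sim$matrix, "logcpm")
  hallmark <- synthetic_hallmark_sets(planted, n_genes = p$n_genes,
                                      seed = derive_seed(seed, "hallmark"))
  fsig <- build_functional_signature(hallmark)
  scores <- module_score(logcpm, fsig, n_bins = p$n_bins, n_ctrl = p$n_ctrl,
                         seed = derive_seed(seed, "module"))
  enriched <- find_enriched_cluster(scores, sim$labels)
  target <- names(sim$labels)[sim$labels == enriched$cluster]
  markers <- derive_markers(logcpm, target, fc_min = p$fc_min,
                            alpha = p$alpha, adjust = p$adjust)
  derived <- derive_exclusive_signature(markers, k = p$k,
                                        frac_in_min = p$frac_in_min,
                                        frac_out_max = p$frac_out_max)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (length(derived$genes)) {
      write_gmt(derived, file.path(config$out_dir, "derived_signature.gmt"))
    }
    utils::write.csv(as.data.frame(markers),
                     file.path(config$out_dir, "markers.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(scores),
                     file.path(config$out_dir, "scores.csv"),
                     row.names = FALSE)
    write_manifest(config, file.path(config$out_dir, "manifest.json"),
                   extra = list(pipeline = "sc",
                                enriched_cluster = enriched$cluster))
  }
  list(signature = derived, markers = markers, scores = scores,
       enriched = enriched, truth = sim$truth)
}

#' Run the bulk deconvolution-bootstrap panel pipeline
#'
#' End-to-end chain on a synthetic multi-dataset panel: simulate bulk
#' cohorts (a responder-specific signature shift planted in the datasets
#' flagged by `config$bulk$planted`), deconvolve fractions against the
#' packaged synthetic LM10-shaped reference, impute per-group IFN-neutrophil
#' profiles, estimate NB dispersions, simulate replicate samples, score the
#' packaged signatures and test R vs NR per dataset; finally evaluate the
#' per-sample signature scores as biomarkers (AUC with stratified-bootstrap
#' CI). Per-dataset failures are recorded without aborting the panel.
#'
#' @param config a [default_config()] object.
#' @return list: `panel` (heatmap-ready table with stars), `failures`,
#'   `evaluation` (biomarker comparison per dataset), `cohorts` (the
#'   simulated inputs incl. truth), `intermediates` (fractions, profiles,
#'   dispersions per dataset).
#' @export
run_bulk_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  p <- config$bulk
  ref <- lm10_synthetic()
  sets <- packaged_signature("both")
  planted <- rep_len(p$planted, p$n_datasets)
  cohorts <- lapply(seq_len(p$n_datasets), function(d) {
    ds <- sprintf("dataset%d", d)
    effect <- list(ifnhi_frac = c(NR = p$ifnhi_frac, R = p$ifnhi_frac),
                   signature = if (planted[d]) sets$neut_ifn15 else NULL,
                   shift_log2 = if (planted[d]) p$shift_log2 else 0)
    sim <- simulate_bulk_cohort(n_per_group = p$n_per_group, sigmatrix = ref,
                                target_type = p$cell_type, effect = effect,
                                noise_alpha = p$noise_alpha, depth = p$depth,
                                dataset = ds,
                                seed = derive_seed(seed, ds))
    c(sim, list(dataset = ds))
  })
  panel <- run_dataset_panel(cohorts, ref, sets, cell_type = p$cell_type,
                             n_reps = p$n_reps, seed = seed,
                             tau = config$scoring$tau,
                             alternative = config$scoring$alternative,
                             normalize_method = config$scoring$normalize_method,
                             keep_intermediates = TRUE)
  # per-sample signature scores as competing biomarkers, per dataset
  evaluation <- do.call(rbind, lapply(cohorts, function(cohort) {
    sc <- gsva_score(cohort$bulk, sets, tau = config$scoring$tau)
    wide <- data.frame(sample_id = cohort$bulk$sample_ids)
    for (nm in names(sets)) {
      s <- sc[sc$signature == sets[[nm]]$name, ]
      wide[[nm]] <- s$score[match(wide$sample_id, s$unit_id)]
    }
    wide$group <- cohort$meta$group[match(wide$sample_id,
                                          cohort$meta$sample_id)]
    ev <- evaluate_biomarkers(wide, names(sets), n_boot = p$n_boot,
                              seed = derive_seed(seed, cohort$dataset))
    ev$dataset <- cohort$dataset
    ev
  }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ds in names(panel$intermediates)) {
      it <- panel$intermediates[[ds]]
      utils::write.csv(data.frame(sample_id = it$fractions$sample_ids,
                                  it$fractions$fractions,
                                  check.names = FALSE),
                       file.path(config$out_dir,
                                 paste0(ds, "_fractions.csv")),
                       row.names = FALSE)
      prof <- do.call(rbind, lapply(it$profiles, function(gp) {
        data.frame(group = gp$group, cell_type = gp$cell_type,
                   gene = gp$gene_ids, mu = gp$mu, cv = gp$cv)
      }))
      utils::write.csv(prof,
                       file.path(config$out_dir,
                                 paste0(ds, "_group_profiles.csv")),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, lapply(it$dispersion, as.data.frame)),
                       file.path(config$out_dir,
                                 paste0(ds, "_dispersion.csv")),
                       row.names = FALSE)
    }
    if (!is.null(panel$table)) {
      utils::write.csv(panel$table,
                       file.path(config$out_dir, "bootstrap_panel.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(evaluation,
                     file.path(config$out_dir, "biomarker_comparison.csv"),
                     row.names = FALSE)
    write_manifest(config, file.path(config$out_dir, "manifest.json"),
                   extra = list(pipeline = "bulk",
                                failures = panel$failures))
  }
  list(panel = panel$table, failures = panel$failures,
       evaluation = evaluation, cohorts = cohorts,
       intermediates = panel$intermediates)
}
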