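#' @name synthetic_data
#' @title Synthetic cohorts with planted ground truth
#' @description
#' The generators in this file emulate the statistical structure the
#' downstream analyses assume — NB-distributed counts, a neutrophil
#' subpopulation enriched for IFN-response genes, bulk mixtures with known
#' cell-type fractions, and response labels with a planted enrichment
#' effect — and return a `SyntheticTruth` record sufficient to recompute
#' every planted quantity. All generators are pure functions of
#' (parameters, seed).
NULL

# largest-remainder integer allocation of n among proportions p
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a single-cell count matrix with a planted IFN-high neutrophil state
#'
#' Draws NB counts for `n_cells` cells across `n_genes` genes. Gene means
#' come from one log-normal draw shared across cell types, modulated by a
#' mild per-type log-normal effect (`type_effect_sdlog`); per-gene NB
#' dispersions are uniform on `alpha_range`. Signature genes are given a
#' dedicated mean in neutrophils (`sig_base_mean`) and a near-zero mean in
#' non-neutrophil types (`sig_offtype_mean`); the IFN-high neutrophil
#' subpopulation multiplies the signature-gene means by `2^shift_log2`,
#' planting an exact log2 fold-change of `shift_log2` relative to other
#' neutrophils.
#'
#' @param n_cells number of cells (default 2000).
#' @param cell_type_props named proportions summing to 1; must contain
#'   `"neutrophil"`.
#' @param ifnhi_share_of_neutrophils fraction of neutrophils in the IFN-high
#'   state (default 0.4).
#' @param signature a [gene_set()] of planted genes.
#' @param shift_log2 planted log2 mean shift, >= 0 (default 2). A value of
#'   0 requests a null cohort: the signature genes remain ordinary
#'   background genes with no cell-state structure.
#' @param n_genes gene-universe size (default 500); must be at least the
#'   signature size.
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal gene-mean parameters
#'   (defaults log(2), 1: a median mean of 2 counts/cell, heavy right tail).
#' @param type_effect_sdlog per-type log-normal modulation (default 0.15).
#' @param sig_base_mean signature-gene mean in unshifted neutrophils
#'   (default 0.4 counts/cell).
#' @param sig_offtype_mean signature-gene mean outside neutrophils
#'   (default 0.01).
#' @param alpha_range NB dispersion range (default `c(0.1, 0.5)`).
#' @return list: `matrix` ([expression_matrix()], layer counts), `labels`
#'   (named character vector of cell states, `"neutrophil_ifnhi"` marking
#'   the planted state), `truth` (`SyntheticTruth` list: per-type gene
#'   means, per-gene alpha, planted genes and shift, realized type
#'   fractions, seed).
#' @export
simulate_single_cell <- function(n_cells = 2000L,
                                 cell_type_props = c(neutrophil = 0.25,
                                                     monocyte = 0.20,
                                                     tcell = 0.30,
                                                     bcell = 0.15,
                                                     nk = 0.10),
                                 ifnhi_share_of_neutrophils = 0.4,
                                 signature,
                                 shift_log2 = 2,
                                 n_genes = 500L,
                                 seed = 1L,
                                 base_meanlog = log(2), base_sdlog = 1,
                                 type_effect_sdlog = 0.15,
                                 sig_base_mean = 0.4,
                                 sig_offtype_mean = 0.01,
                                 alpha_range = c(0.1, 0.5)) {
  stopifnot(inherits(signature, "GeneSet"))
  if (abs(sum(cell_type_props) - 1) > 1e-9) {
    stop("cell_type_props must sum to 1", call. = FALSE)
  }
  if (!"neutrophil" %in% names(cell_type_props)) {
    stop("cell_type_props must contain 'neutrophil'", call. = FALSE)
  }
  if (shift_log2 < 0) stop("shift_log2 must be >= 0", call. = FALSE)
  if (length(signature$genes) > n_genes) {
    stop("signature genes exceed n_genes", call. = FALSE)
  }
  n_fill <- n_genes - length(signature$genes)
  gene_ids <- c(signature$genes,
                sprintf("GENE%04d", seq_len(n_fill)))
  sig_idx <- seq_along(signature$genes)
  with_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    base_types <- names(cell_type_props)
    sig_neut_mean <- sig_base_mean * stats::rlnorm(length(sig_idx), 0, 0.2)
    means <- sapply(base_types, function(t) {
      m <- base_mean * stats::rlnorm(n_genes, 0, type_effect_sdlog)
      # shift_log2 = 0 requests a null world: the signature genes stay
      # ordinary background genes, so no cluster is differential at all
      if (shift_log2 > 0) {
        m[sig_idx] <- if (t == "neutrophil") sig_neut_mean else sig_offtype_mean
      }
      m
    })
    # IFN-high neutrophils share the neutrophil profile with the signature
    # genes multiplied by 2^shift
    ifnhi <- means[, "neutrophil"]
    ifnhi[sig_idx] <- ifnhi[sig_idx] * 2^shift_log2
    means <- cbind(means, neutrophil_ifnhi = ifnhi)
    alpha <- stats::runif(n_genes, alpha_range[[1L]], alpha_range[[2L]])
    # state allocation: split neutrophils into ifnhi and baseline
    state_props <- c(cell_type_props, 0)
    names(state_props) <- c(base_types, "neutrophil_ifnhi")
    state_props["neutrophil_ifnhi"] <-
      state_props["neutrophil"] * ifnhi_share_of_neutrophils
    state_props["neutrophil"] <-
      state_props["neutrophil"] * (1 - ifnhi_share_of_neutrophils)
    n_by_state <- allocate_counts(n_cells, state_props)
    labels <- rep(names(state_props), n_by_state)
    labels <- labels[sample.int(n_cells)]
    vals <- matrix(0, nrow = n_genes, ncol = n_cells)
    for (st in names(state_props)) {
      cols <- which(labels == st)
      if (!length(cols)) next
      mu <- means[, st]
      vals[, cols] <- stats::rnbinom(n_genes * length(cols), mu = mu,
                                     size = 1 / alpha)
    }
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    names(labels) <- cell_ids
    m <- expression_matrix(vals, gene_ids, cell_ids, layer = "counts")
    truth <- structure(list(
      kind = "single_cell",
      state_fractions = n_by_state / n_cells,
      ifnhi_share_of_neutrophils = ifnhi_share_of_neutrophils,
      planted_genes = signature$genes,
      shift_log2 = shift_log2,
      gene_means = means,
      alpha = stats::setNames(alpha, gene_ids),
      seed = as.integer(seed)), class = "SyntheticTruth")
    list(matrix = m, labels = labels, truth = truth)
  })
}

#' Simulate a bulk RNA-seq cohort as mixtures of reference profiles
#'
#' Per-sample cell-type fractions are Dirichlet draws whose mean raises the
#' target (IFN-neutrophil) component in the responder group according to
#' `effect$ifnhi_frac`; the expected bulk profile is the fraction-weighted
#' sum of the reference columns (rescaled to `depth` total), with the
#' responder group's target-column signature genes multiplied by
#' `2^effect$shift_log2` when a planted expression effect is requested.
#' Observed values are NB draws around the expectation with dispersion
#' `noise_alpha`; `noise_alpha = 0` returns the exact expectation
#' (expectation mode, layer `"cpm"` since values are continuous).
#'
#' @param n_per_group named counts `c(NR =, R =)`, each >= 3.
#' @param sigmatrix a [signature_matrix_ref()] whose columns include
#'   `target_type`.
#' @param target_type the IFN-neutrophil column of `sigmatrix`.
#' @param effect list with `ifnhi_frac` (named mean target fraction per
#'   group, each in [0, 1]), optional `signature` ([gene_set()]) and
#'   `shift_log2` (default 0) planting a responder-specific expression
#'   shift on the signature genes of the target profile.
#' @param noise_alpha NB dispersion of the bulk noise (default 0.1).
#' @param depth expected total per sample (default 2e5).
#' @param dirichlet_conc Dirichlet concentration (default 20, giving
#'   per-type fraction coefficients of variation around 50-100% — the
#'   compositional spread typical of immune-deconvolution cohorts; larger
#'   values give unrealistically uniform compositions that also make the
#'   fraction design near-collinear).
#' @param dataset dataset id for the metadata.
#' @param seed integer seed.
#' @return list: `bulk` ([expression_matrix()]), `meta`
#'   ([sample_metadata()]), `truth` (`SyntheticTruth`: true fraction
#'   matrix, group mean target fractions, planted genes/shift, per-group
#'   target profiles, seed).
#' @export
simulate_bulk_cohort <- function(n_per_group = c(NR = 15L, R = 15L),
                                 sigmatrix,
                                 target_type = "Neut_IFN",
                                 effect = list(ifnhi_frac = c(NR = 0.10,
                                                              R = 0.10),
                                               signature = NULL,
                                               shift_log2 = 0),
                                 noise_alpha = 0.1,
                                 depth = 2e5,
                                 dirichlet_conc = 20,
                                 dataset = "dataset1",
                                 seed = 1L) {
  stopifnot(inherits(sigmatrix, "SignatureMatrixRef"))
  if (!all(c("NR", "R") %in% names(n_per_group))) {
    stop("n_per_group must be named c(NR=, R=)", call. = FALSE)
  }
  if (any(n_per_group < 3L)) {
    stop("at least 3 samples per group are required (rank tests undefined below)",
         call. = FALSE)
  }
  if (!target_type %in% sigmatrix$cell_type_ids) {
    stop("target_type not in sigmatrix: ", target_type, call. = FALSE)
  }
  ifnhi_frac <- effect$ifnhi_frac
  if (is.null(ifnhi_frac)) ifnhi_frac <- c(NR = 0.10, R = 0.10)
  if (any(ifnhi_frac < 0 | ifnhi_frac > 1)) {
    stop("effect fractions must be in [0, 1]", call. = FALSE)
  }
  shift_log2 <- if (is.null(effect$shift_log2)) 0 else effect$shift_log2
  types <- sigmatrix$cell_type_ids
  t_idx <- match(target_type, types)
  n_types <- length(types)
  with_seed(seed, {
    sample_ids <- c(sprintf("NR%03d", seq_len(n_per_group[["NR"]])),
                    sprintf("R%03d", seq_len(n_per_group[["R"]])))
    groups <- c(rep("NR", n_per_group[["NR"]]), rep("R", n_per_group[["R"]]))
    # group-specific mean fractions: target set per group, rest equal
    frac <- matrix(0, nrow = length(sample_ids), ncol = n_types,
                   dimnames = list(sample_ids, types))
    profiles <- list(NR = sigmatrix$profiles, R = sigmatrix$profiles)
    if (!is.null(effect$signature) && shift_log2 != 0) {
      sig_rows <- match(norm_symbols(effect$signature$genes),
                        norm_symbols(sigmatrix$gene_ids))
      sig_rows <- sig_rows[!is.na(sig_rows)]
      profiles$R[sig_rows, t_idx] <- profiles$R[sig_rows, t_idx] * 2^shift_log2
    }
    for (g in c("NR", "R")) {
      mean_frac <- rep((1 - ifnhi_frac[[g]]) / (n_types - 1), n_types)
      mean_frac[t_idx] <- ifnhi_frac[[g]]
      rows <- which(groups == g)
      frac[rows, ] <- rdirichlet(length(rows), dirichlet_conc * mean_frac)
    }
    # one cohort-wide scale (not per-sample), so the expectation keeps the
    # exact linear mixture structure that group-mode imputation assumes;
    # sampling noise below supplies per-sample depth variation
    scale <- depth / sum(sigmatrix$profiles %*% colMeans(frac))
    expectation <- sapply(seq_along(sample_ids), function(s) {
      as.numeric(profiles[[groups[s]]] %*% frac[s, ]) * scale
    })
    if (noise_alpha == 0) {
      vals <- expectation
      layer <- "cpm"
    } else {
      vals <- matrix(stats::rnbinom(length(expectation),
                                    mu = expectation,
                                    size = 1 / noise_alpha),
                     nrow = nrow(expectation))
      layer <- "counts"
    }
    bulk <- expression_matrix(vals, sigmatrix$gene_ids, sample_ids,
                              layer = layer)
    meta <- sample_metadata(sample_ids, groups, dataset = dataset)
    truth <- structure(list(
      kind = "bulk_cohort",
      fractions = fraction_matrix(frac, sample_ids, types),
      group_mean_target_fraction = ifnhi_frac,
      target_type = target_type,
      planted_genes = if (is.null(effect$signature)) character(0L) else
        effect$signature$genes,
      shift_log2 = shift_log2,
      target_profiles = list(NR = profiles$NR[, t_idx],
                             R = profiles$R[, t_idx]),
      scale = scale,
      noise_alpha = noise_alpha, depth = depth, seed = as.integer(seed)),
      class = "SyntheticTruth")
    list(bulk = bulk, meta = meta, truth = truth)
  })
}

#' Simulate a flow-cytometry style frequency table
#'
#' Per-subject IFN-high (Ly6E-high) neutrophil frequencies drawn from Beta
#' distributions with group-specific means and a common concentration
#' (`Beta(mean * conc, (1 - mean) * conc)`). Defaults state a strong
#' responder effect: mean frequency 0.05 in NR vs 0.30 in R with
#' concentration 50, the regime in which the biomarker separates groups.
#'
#' @param n_per_group named counts `c(NR =, R =)`, each >= 1.
#' @param mean_freqs named group means in (0, 1).
#' @param concentration Beta concentration, > 0.
#' @param seed integer seed.
#' @return A `data.frame` of class `FlowTable`: `subject_id`, `group`,
#'   `ly6e_hi_freq`.
#' @export
simulate_flow_table <- function(n_per_group = c(NR = 25L, R = 25L),
                                mean_freqs = c(NR = 0.05, R = 0.30),
                                concentration = 50,
                                seed = 1L) {
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  if (!all(c("NR", "R") %in% names(n_per_group))) {
    stop("n_per_group must be named c(NR=, R=)", call. = FALSE)
  }
  if (any(n_per_group < 1L)) {
    stop("both groups must have at least 1 subject", call. = FALSE)
  }
  if (any(mean_freqs <= 0 | mean_freqs >= 1)) {
    stop("mean frequencies must be in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(c("NR", "R"), function(g) {
      n <- n_per_group[[g]]
      m <- mean_freqs[[g]]
      data.frame(subject_id = sprintf("%s_subj%03d", g, seq_len(n)),
                 group = g,
                 ly6e_hi_freq = stats::rbeta(n, m * concentration,
                                             (1 - m) * concentration),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("FlowTable", "data.frame")
    out
  })
}

#' Synthetic hallmark-style response programs
#'
#' Builds three gene sets emulating the IFN-alpha response, IFN-gamma
#' response and TNFa/NF-kB programs whose union forms the functional
#' signature: the planted signature genes are split across the two IFN
#' programs (with overlap), and each program carries additional background
#' genes drawn from the filler universe.
#'
#' @param signature the planted [gene_set()].
#' @param n_extra background genes added per program (default 10).
#' @param n_genes size of the gene universe the extras are drawn from
#'   (default 500; must match the simulated matrix).
#' @param seed integer seed.
#' @return list of three [gene_set()] objects.
#' @export
synthetic_hallmark_sets <- function(signature, n_extra = 10L,
                                    n_genes = 500L, seed = 1L) {
  stopifnot(inherits(signature, "GeneSet"))
  genes <- signature$genes
  k <- length(genes)
  fill <- sprintf("GENE%04d", seq_len(n_genes - k))
  with_seed(seed, {
    extras <- sample(fill, 3L * n_extra)
    half <- ceiling(k / 2)
    list(
      gene_set("ifna_response",
               c(genes[seq_len(half + 1L)], extras[seq_len(n_extra)])),
      gene_set("ifng_response",
               c(genes[half:k], extras[n_extra + seq_len(n_extra)])),
      gene_set("tnfa_nfkb",
               c(genes[c(1L, k)], extras[2L * n_extra + seq_len(n_extra)]))
    )
  })
}
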