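#' Combine three hallmark-style response programs into one functional signature
#'
#' The cross-species bridge: the biological processes marking response in
#' mouse (IFN-alpha response, IFN-gamma response, TNFa/NF-kB signalling) are
#' unioned into a single functional signature that is then scored on human
#' neutrophils. Exactly three sets are required; the union preserves first
#' occurrence and de-duplicates case-insensitively.
#'
#' @param sets list of exactly three [gene_set()] objects.
#' @param name name of the combined set (default `"functional_ifn_tnfa"`).
#' @return A [gene_set()].
#' @export
build_functional_signature <- function(sets, name = "functional_ifn_tnfa") {
  if (!is.list(sets) || length(sets) != 3L ||
      !all(vapply(sets, inherits, logical(1L), "GeneSet"))) {
    stop("exactly three GeneSet objects are required", call. = FALSE)
  }
  gene_set(name, unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
}

#' Locate the cluster most enriched for a signature
#'
#' Given per-cell scores and a cluster assignment, returns the cluster with
#' the highest median score together with a one-sided rank test of that
#' cluster against all other cells. Clusters with fewer than 3 cells are
#' excluded with a warning.
#'
#' @param scores a [signature_scores()] table (one signature).
#' @param clusters named vector mapping `unit_id` to cluster id.
#' @return list: `cluster` (winning id), `p_value` (one-sided, winner vs
#'   rest), `summary` (data.frame cluster / n / median_score / p_value).
#' @export
find_enriched_cluster <- function(scores, clusters) {
  stopifnot(inherits(scores, "SignatureScores"))
  if (is.null(names(clusters))) stop("clusters must be named by unit_id", call. = FALSE)
  cl <- as.character(clusters[scores$unit_id])
  if (anyNA(cl)) stop("clusters must cover all units", call. = FALSE)
  if (length(unique(cl)) < 2L) stop("at least 2 clusters required", call. = FALSE)
  counts <- table(cl)
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    warning("excluding cluster(s) with < 3 units: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  eligible <- setdiff(names(counts), small)
  if (length(eligible) == 0L) stop("all clusters excluded (< 3 units each)", call. = FALSE)
  summ <- do.call(rbind, lapply(eligible, function(k) {
    inside <- scores$score[cl == k]
    outside <- scores$score[cl != k]
    data.frame(cluster = k, n = length(inside),
               median_score = stats::median(inside),
               p_value = mann_whitney(inside, outside,
                                      alternative = "greater")$p_value)
  }))
  summ <- summ[order(-summ$median_score), , drop = FALSE]
  rownames(summ) <- NULL
  list(cluster = summ$cluster[[1L]], p_value = summ$p_value[[1L]],
       summary = summ)
}

#' Derive marker genes of a cell subset
#'
#' Two-sample rank-test differential expression of a target subset against
#' all remaining cells. Per gene: log2 fold-change of mean linear expression
#' (pseudocount 1) and a two-sided Mann-Whitney p-value, multiplicity
#' adjusted. Genes passing `p_adj < alpha` and `log2_fc > fc_min` are
#' returned sorted by p-value then fold-change. `frac_in` / `frac_out`
#' report the fraction of target / other cells expressing the gene (linear
#' expression above `expr_threshold`).
#'
#' Defaults mirror the stringent marker thresholds used for IFN-stimulated
#' neutrophil states: FDR < 0.001 and log2 fold-change > 1.5.
#'
#' @param m an [expression_matrix()], layer `logcpm`.
#' @param target character vector of unit ids forming the target subset
#'   (non-empty, proper subset).
#' @param fc_min minimal log2 fold-change (default 1.5).
#' @param alpha adjusted-p threshold (default 0.001).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param expr_threshold linear expression above which a gene counts as
#'   expressed (default 0).
#' @param all_genes if `TRUE`, return every gene without thresholding.
#' @return data.frame of class `MarkerResult` with columns gene, log2_fc,
#'   p_value, p_adj, frac_in, frac_out.
#' @export
derive_markers <- function(m, target, fc_min = 1.5, alpha = 0.001,
                           adjust = c("BH", "bonferroni"),
                           expr_threshold = 0, all_genes = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(m, "ExpressionMatrix"))
  target <- as.character(target)
  in_target <- m$sample_ids %in% target
  if (!any(in_target)) stop("target subset is empty", call. = FALSE)
  if (all(in_target)) stop("target must be a proper subset of units", call. = FALSE)
  vals <- m$values
  lin <- if (m$layer == "logcpm") 2^vals - 1 else vals
  n_in <- sum(in_target); n_out <- sum(!in_target)
  mean_in <- rowMeans(lin[, in_target, drop = FALSE])
  mean_out <- rowMeans(lin[, !in_target, drop = FALSE])
  log2_fc <- log2((mean_in + 1) / (mean_out + 1))
  frac_in <- rowMeans(lin[, in_target, drop = FALSE] > expr_threshold)
  frac_out <- rowMeans(lin[, !in_target, drop = FALSE] > expr_threshold)
  # vectorized two-sided rank test per gene (normal approximation with
  # tie/continuity correction; midranks)
  p_value <- apply(vals, 1L, function(g) {
    mann_whitney(g[in_target], g[!in_target], alternative = "two_sided",
                 exact_max_n = 0L)$p_value
  })
  p_adj <- stats::p.adjust(p_value, method = adjust)
  out <- data.frame(gene = m$gene_ids, log2_fc = log2_fc, p_value = p_value,
                    p_adj = p_adj, frac_in = frac_in, frac_out = frac_out,
                    stringsAsFactors = FALSE)
  if (!all_genes) {
    out <- out[out$p_adj < alpha & out$log2_fc > fc_min, , drop = FALSE]
  }
  out <- out[order(out$p_adj, out$p_value, -out$log2_fc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MarkerResult", "data.frame")
  out
}

#' Derive a near-exclusive marker signature
#'
#' Filters a marker table to genes expressed in most target cells and
#' nearly absent elsewhere, and returns the top `k` (p-value then
#' fold-change) as a named gene set — the construction behind compact
#' IFN-neutrophil signatures. The exclusivity thresholds are this module's
#' own defaults (the notion of "near-exclusive" is not standardized) and
#' are fully configurable.
#'
#' @param markers a [derive_markers()] result.
#' @param k number of genes to keep (default 15).
#' @param frac_in_min minimal expressing fraction inside the target
#'   (default 0.5).
#' @param frac_out_max maximal expressing fraction outside (default 0.1).
#' @param name signature name (default `"neut_ifn_derived"`).
#' @return A [gene_set()] of at most `k` genes; fewer survivors yield a
#'   smaller set with a warning.
#' @export
derive_exclusive_signature <- function(markers, k = 15L, frac_in_min = 0.5,
                                       frac_out_max = 0.1,
                                       name = "neut_ifn_derived") {
  stopifnot(inherits(markers, "data.frame"))
  if (nrow(markers) == 0L) stop("markers must be non-empty", call. = FALSE)
  surv <- markers[markers$frac_in >= frac_in_min &
                    markers$frac_out <= frac_out_max, , drop = FALSE]
  if (nrow(surv) == 0L) {
    warning("no markers pass the exclusivity filter; returning empty set",
            call. = FALSE)
    return(structure(list(name = name, genes = character(0L)),
                     class = "GeneSet"))
  }
  surv <- surv[order(surv$p_adj, surv$p_value, -surv$log2_fc), , drop = FALSE]
  if (nrow(surv) < k) {
    warning(sprintf("only %d of %d requested genes pass the exclusivity filter",
                    nrow(surv), k), call. = FALSE)
  }
  gene_set(name, utils::head(surv$gene, k))
}
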