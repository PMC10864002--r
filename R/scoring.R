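#' Construct a signature-score table
#'
#' Tidy per-unit (cell or sample) scores for one or more signatures.
#'
#' @param unit_id character vector of unit identifiers.
#' @param signature signature name (recycled).
#' @param method scoring method, `"module_score"` or `"gsva"` (recycled).
#' @param score numeric scores, finite.
#' @param dataset optional dataset assignment per unit (recycled).
#' @return A `data.frame` of class `SignatureScores` with columns
#'   `unit_id`, `signature`, `method`, `score`, `dataset`.
#' @export
signature_scores <- function(unit_id, signature, method, score,
                             dataset = NA_character_) {
  n <- length(unit_id)
  score <- as.numeric(score)
  if (length(score) != n) stop("one score per unit required", call. = FALSE)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  structure(data.frame(unit_id = as.character(unit_id),
                       signature = rep_len(as.character(signature), n),
                       method = rep_len(as.character(method), n),
                       score = score,
                       dataset = rep_len(as.character(dataset), n),
                       stringsAsFactors = FALSE),
            class = c("SignatureScores", "data.frame"))
}

rbind_scores <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("SignatureScores", "data.frame")
  out
}

# equal-frequency bins (ntile) of a numeric vector
ntile_bins <- function(x, n_bins) {
  ord <- rank(x, ties.method = "first")
  as.integer(ceiling(ord * n_bins / length(x)))
}

#' Per-cell module score with binned control genes
#'
#' The per-cell signature score used for single-cell analyses: genes are
#' binned by their average expression across all cells, each signature gene
#' draws control genes from its own expression bin, and the score is the
#' mean expression of the signature genes minus the mean expression of the
#' pooled control genes. Controls are matched on expression so the score is
#' centred near zero for an uninformative set, and the construction is
#' invariant to adding a constant to the matrix.
#'
#' Controls are drawn with replacement (`n_ctrl` draws per signature gene,
#' signature genes excluded from the pools); the pooled control mean is taken
#' over the unique control genes drawn.
#'
#' @param m an [expression_matrix()], conventionally layer `logcpm`.
#' @param set a [gene_set()]; at least 2 genes must be present in `m`.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control draws per signature gene (default 100).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A [signature_scores()] table with one row per cell.
#' @export
module_score <- function(m, set, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(set, "GeneSet"))
  # a deliberately single-gene set is scored as-is; the error targets sets
  # reduced below 2 genes by symbols absent from the matrix
  set_idx <- match_set_genes(set, m$gene_ids,
                             min_present = min(2L, length(set$genes)))
  vals <- m$values
  n_genes <- nrow(vals)
  n_bins <- max(1L, min(as.integer(n_bins), n_genes))
  bins <- ntile_bins(rowMeans(vals), n_bins)
  in_set <- seq_len(n_genes) %in% set_idx
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(g) {
      pool <- which(bins == bins[g] & !in_set)
      if (length(pool) == 0L) {
        warning("no non-signature control genes in bin; using all non-signature genes",
                call. = FALSE)
        pool <- which(!in_set)
      }
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  ctrl_idx <- sort(unique(ctrl_idx))
  score <- colMeans(vals[set_idx, , drop = FALSE]) -
    colMeans(vals[ctrl_idx, , drop = FALSE])
  signature_scores(m$sample_ids, set$name, "module_score", score)
}

# midrank of each sample within each gene, scaled to (0, 1]
gene_rank_stat <- function(values) {
  n <- ncol(values)
  t(apply(values, 1L, rank, ties.method = "average")) / n
}

#' Per-sample rank-based enrichment score (GSVA-style)
#'
#' Single-sample gene-set enrichment via a weighted Kolmogorov-like random
#' walk. Per gene, a cross-sample empirical-CDF statistic is computed as the
#' gene's midrank across samples scaled to (0, 1]; per sample, genes are
#' ordered by decreasing statistic (residual ties broken lexicographically by
#' gene id) and a walk accumulates signature genes (weighted by
#' `|stat|^tau`, normalized) against the complement (uniform decrements).
#' The enrichment score is the signed magnitude-difference form:
#' maximum positive deviation plus maximum negative deviation, in [-1, 1].
#'
#' Because the statistic depends only on within-gene cross-sample ranks, the
#' score is exactly invariant under any strictly increasing per-gene
#' transform of the input, making the linear-vs-log scale of imputed
#' profiles immaterial.
#'
#' @param m an [expression_matrix()] with at least 2 samples; any layer.
#' @param sets a [gene_set()] or list of them; each must have at least one
#'   gene present in `m` and must not cover the whole gene universe.
#' @param tau rank-statistic weight exponent (default 1).
#' @return A [signature_scores()] table, one row per sample per set.
#' @export
gsva_score <- function(m, sets, tau = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  if (ncol(m$values) < 2L) stop("gsva_score requires >= 2 samples", call. = FALSE)
  n_genes <- nrow(m$values)
  stat <- gene_rank_stat(m$values)
  # precompute per-sample gene ordering: decreasing stat, ties by gene id
  lex <- order(m$gene_ids)
  lex_rank <- integer(n_genes)
  lex_rank[lex] <- seq_len(n_genes)
  orders <- lapply(seq_len(ncol(stat)), function(j) {
    order(-stat[, j], lex_rank)
  })
  out <- lapply(sets, function(set) {
    set_idx <- match_set_genes(set, m$gene_ids, min_present = 1L)
    if (length(set_idx) >= n_genes) {
      stop(sprintf("gene set '%s' covers all matrix genes; complement walk undefined",
                   set$name), call. = FALSE)
    }
    in_set <- seq_len(n_genes) %in% set_idx
    es <- vapply(seq_len(ncol(stat)), function(j) {
      ord <- orders[[j]]
      set_ord <- in_set[ord]
      w <- abs(stat[ord, j])^tau
      inc <- ifelse(set_ord, w, 0)
      sw <- sum(inc)
      inc <- if (sw > 0) inc / sw else inc
      dec <- ifelse(set_ord, 0, 1 / (n_genes - length(set_idx)))
      walk <- cumsum(inc - dec)
      max(0, max(walk)) + min(0, min(walk))
    }, numeric(1L))
    signature_scores(m$sample_ids, set$name, "gsva", es)
  })
  do.call(rbind_scores, out)
}

#' Normalize enrichment scores within datasets
#'
#' Centers and scales scores within each dataset (per signature) so that
#' datasets of different dynamic range are comparable on one heatmap.
#' The default is robust: subtract the dataset median and divide by the
#' median absolute deviation (MAD, consistency-scaled); `method = "zscore"`
#' uses mean/SD instead.
#'
#' @param s a [signature_scores()] table.
#' @param grouping named character vector mapping `unit_id` to dataset, or
#'   `NULL` to use the table's `dataset` column.
#' @param method `"mad"` (robust, default) or `"zscore"`.
#' @return A [signature_scores()] table with transformed scores.
#' @export
normalize_scores <- function(s, grouping = NULL, method = c("mad", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "SignatureScores"))
  s <- as.data.frame(s)
  if (!is.null(grouping)) {
    if (is.null(names(grouping))) stop("grouping must be named by unit_id", call. = FALSE)
    s$dataset <- unname(grouping[s$unit_id])
  }
  if (anyNA(s$dataset)) stop("every unit must be assigned a dataset", call. = FALSE)
  key <- interaction(s$dataset, s$signature, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    if (length(i) < 2L) {
      stop("dataset with < 2 units: ", s$dataset[i][1L], call. = FALSE)
    }
    x <- s$score[i]
    if (method == "mad") {
      ctr <- stats::median(x)
      scl <- stats::mad(x)
    } else {
      ctr <- mean(x)
      scl <- stats::sd(x)
    }
    if (!is.finite(scl) || scl == 0) {
      warning("zero spread in dataset ", s$dataset[i][1L], "; scores set to 0",
              call. = FALSE)
      s$score[i] <- 0
    } else {
      s$score[i] <- (x - ctr) / scl
    }
  }
  class(s) <- c("SignatureScores", "data.frame")
  s
}
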