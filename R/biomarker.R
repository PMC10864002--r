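#' Mann-Whitney U test
#'
#' Unpaired two-sample rank test. The statistic is the tie-corrected
#' (midrank) U counting pairs where `x` exceeds `y` (+1/2 per tied pair).
#' When the combined sample size is at most 12 and there are no ties, the
#' p-value is exact, by enumeration of all rank assignments; otherwise a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric value vectors, both non-empty.
#' @param alternative `"two_sided"`, `"greater"` (x stochastically larger)
#'   or `"less"`.
#' @param exact_max_n largest combined size for exact enumeration
#'   (default 12).
#' @return A list of class `TestResult`: `statistic` (U), `p_value`,
#'   `alternative`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney(c(3, 4, 5), c(1, 2), alternative = "greater")$p_value
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "greater", "less"),
                         exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  mu <- n1 * n2 / 2
  if (!ties && n <= exact_max_n) {
    ranks <- seq_len(n)
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      greater = mean(u_all >= u),
      less = mean(u_all <= u),
      two_sided = mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    )
    method <- "exact enumeration"
  } else {
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      p <- switch(alternative,
        greater = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((u - mu + 0.5) / sigma),
        two_sided = min(1, 2 * min(
          stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
          stats::pnorm((u - mu + 0.5) / sigma)))
      )
    }
    method <- "normal approximation, tie/continuity corrected"
  }
  structure(list(statistic = u, p_value = p, alternative = alternative,
                 n1 = n1, n2 = n2, method = method),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Empirical AUC by all-pairs counting with the midrank ties convention:
#' `AUC = (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg)`, computed
#' via ranks. Equals `U / (n1 n2)` for the tie-corrected Mann-Whitney U on
#' the same inputs.
#'
#' @param scores_pos,scores_neg numeric scores of the positive (e.g. R) and
#'   negative (e.g. NR) class.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc(c(0.8, 0.35), c(0.1, 0.4))
auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) < 1L || length(scores_neg) < 1L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Resamples within each outcome class independently with replacement,
#' recomputes the AUC per replicate, and reports the percentile interval.
#' Deterministic given `seed`.
#'
#' @param scores_pos,scores_neg class score vectors.
#' @param n_boot number of bootstrap replicates (default 1000, minimum 100).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed.
#' @return A list of class `RocResult`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `n_boot`, `level`, `seed`.
#' @export
stratified_bootstrap_ci <- function(scores_pos, scores_neg, n_boot = 1000L,
                                    level = 0.95, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 < 1L || n2 < 1L) stop("both classes must be non-empty", call. = FALSE)
  if (n1 == 1L || n2 == 1L) {
    warning("a class has a single observation; bootstrap is degenerate",
            call. = FALSE)
  }
  point <- auc(scores_pos, scores_neg)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      auc(scores_pos[sample.int(n1, n1, replace = TRUE)],
          scores_neg[sample.int(n2, n2, replace = TRUE)])
    }, numeric(1L))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(auc = point, ci_low = qs[[1L]], ci_high = qs[[2L]],
                 n_pos = n1, n_neg = n2, n_boot = as.integer(n_boot),
                 level = level, seed = as.integer(seed)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("AUC = %.4f [%.4f, %.4f] (%d%% CI, %d stratified bootstrap reps; n = %d/%d)\n",
              x$auc, x$ci_low, x$ci_high, round(100 * x$level), x$n_boot,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare candidate biomarkers on one cohort
#'
#' For each biomarker column: AUC for discriminating responders (R) from
#' non-responders (NR), stratified-bootstrap CI, and a Mann-Whitney p-value
#' (default one-sided, R greater, the directional hypothesis for
#' IFN-signature biomarkers). Biomarkers absent from the table, or with
#' fewer than 3 subjects per group, are reported as failed rows rather than
#' aborting the comparison.
#'
#' @param table data.frame with a `group` column (NR/R) and one column per
#'   biomarker.
#' @param biomarkers character vector of biomarker column names.
#' @param alternative test direction per biomarker (recycled;
#'   default `"greater"`, i.e. R above NR).
#' @param n_boot,level,seed bootstrap parameters, see
#'   [stratified_bootstrap_ci()].
#' @return data.frame (biomarker, auc, ci_low, ci_high, p_value, n_pos,
#'   n_neg, status), sorted by decreasing AUC with failed rows last.
#' @export
evaluate_biomarkers <- function(table, biomarkers, alternative = "greater",
                                n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  if (!all(table$group %in% c("NR", "R"))) {
    stop("group column must contain only NR / R", call. = FALSE)
  }
  alternative <- rep_len(alternative, length(biomarkers))
  rows <- lapply(seq_along(biomarkers), function(i) {
    b <- biomarkers[[i]]
    fail <- function(status) {
      data.frame(biomarker = b, auc = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_, n_pos = NA_integer_,
                 n_neg = NA_integer_, status = status)
    }
    if (!b %in% names(table)) return(fail("missing column"))
    vals <- table[[b]]
    keep <- !is.na(vals)
    pos <- vals[keep & table$group == "R"]
    neg <- vals[keep & table$group == "NR"]
    if (length(pos) < 3L || length(neg) < 3L) return(fail("fewer than 3 subjects per group"))
    roc <- stratified_bootstrap_ci(pos, neg, n_boot = n_boot, level = level,
                                   seed = derive_seed(seed, b))
    mw <- mann_whitney(pos, neg, alternative = alternative[[i]])
    data.frame(biomarker = b, auc = roc$auc, ci_low = roc$ci_low,
               ci_high = roc$ci_high, p_value = mw$p_value,
               n_pos = roc$n_pos, n_neg = roc$n_neg, status = "ok")
  })
  out <- do.call(rbind, rows)
  out[order(is.na(out$auc), -ifelse(is.na(out$auc), -Inf, out$auc)), ,
      drop = FALSE]
}
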