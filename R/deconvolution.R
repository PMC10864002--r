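#' Non-negative least squares (Lawson-Hanson)
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` by the classic active-set
#' algorithm. Small dense problems only (deconvolution designs are
#' genes x 10 or samples x 10).
#'
#' @param A numeric matrix.
#' @param b numeric vector, `length(b) == nrow(A)`.
#' @param tol dual-feasibility tolerance.
#' @return Non-negative coefficient vector of length `ncol(A)`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 50L * n
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      sp <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      sp[is.na(sp)] <- 0
      s[passive] <- sp
      if (all(s[passive] > tol)) break
      neg <- which(passive & s <= tol)
      ratio <- x[neg] / (x[neg] - s[neg])
      step <- min(ratio[is.finite(ratio)], 1)
      x <- x + step * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Construct a reference signature matrix
#'
#' Gene x cell-type reference expression profiles used for bulk
#' deconvolution (an LM10-shaped matrix: 10 immune subsets by default).
#'
#' @param profiles non-negative numeric matrix, genes in rows, cell types in
#'   columns.
#' @param gene_ids,cell_type_ids identifiers (default from dimnames).
#' @return An object of class `SignatureMatrixRef`.
#' @export
signature_matrix_ref <- function(profiles, gene_ids = rownames(profiles),
                                 cell_type_ids = colnames(profiles)) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_type_ids <- as.character(cell_type_ids)
  stopifnot(nrow(profiles) == length(gene_ids),
            ncol(profiles) == length(cell_type_ids))
  if (anyDuplicated(gene_ids)) stop("duplicate gene id in reference", call. = FALSE)
  if (anyNA(profiles) || any(profiles < 0)) {
    stop("reference profiles must be non-negative", call. = FALSE)
  }
  zero_col <- colSums(profiles) == 0
  if (any(zero_col)) {
    stop("all-zero cell-type column: ", cell_type_ids[zero_col][1L],
         call. = FALSE)
  }
  dimnames(profiles) <- list(gene_ids, cell_type_ids)
  structure(list(gene_ids = gene_ids, cell_type_ids = cell_type_ids,
                 profiles = profiles),
            class = "SignatureMatrixRef")
}

#' Read a signature matrix from CSV
#'
#' First column gene id, remaining columns one per cell type.
#'
#' @param path CSV file path.
#' @return A [signature_matrix_ref()].
#' @export
read_signature_matrix <- function(path) {
  m <- read_expression(path, format = "csv")
  signature_matrix_ref(m$values, m$gene_ids, m$sample_ids)
}

#' Packaged synthetic LM10-shaped reference
#'
#' Loads the synthetic 10-cell-type signature matrix shipped with the
#' package (121 genes including the packaged IFN signatures). This is a
#' synthetic stand-in constructed for testing, not a published reference.
#'
#' @return A [signature_matrix_ref()].
#' @export
lm10_synthetic <- function() {
  read_signature_matrix(system.file("extdata", "lm10_synthetic.csv",
                                    package = "ifnsig"))
}

#' Construct a cell-type fraction matrix
#'
#' @param fractions sample x cell-type matrix, entries >= 0, each row
#'   summing to 1 (tolerance 1e-9).
#' @param sample_ids,cell_type_ids identifiers (default from dimnames).
#' @return An object of class `FractionMatrix`.
#' @export
fraction_matrix <- function(fractions, sample_ids = rownames(fractions),
                            cell_type_ids = colnames(fractions)) {
  fractions <- as.matrix(fractions)
  sample_ids <- as.character(sample_ids)
  cell_type_ids <- as.character(cell_type_ids)
  stopifnot(nrow(fractions) == length(sample_ids),
            ncol(fractions) == length(cell_type_ids))
  if (anyNA(fractions) || any(fractions < 0)) {
    stop("fractions must be non-negative", call. = FALSE)
  }
  if (any(abs(rowSums(fractions) - 1) > 1e-9)) {
    stop("fraction rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  dimnames(fractions) <- list(sample_ids, cell_type_ids)
  structure(list(sample_ids = sample_ids, cell_type_ids = cell_type_ids,
                 fractions = fractions),
            class = "FractionMatrix")
}

#' Estimate cell-type fractions from bulk expression
#'
#' Constrained-regression deconvolution: each bulk sample (after per-sample
#' total normalization) is fit to the reference profiles by non-negative
#' least squares on the shared genes, and the coefficients are rescaled to
#' sum to one. This is a transparent stand-in for support-vector-regression
#' deconvolution with a clean recovery contract on mixtures of the
#' reference profiles. Estimates are scale-invariant per sample.
#'
#' @param bulk an [expression_matrix()] (samples in columns).
#' @param ref a [signature_matrix_ref()].
#' @return A [fraction_matrix()] (samples x cell types).
#' @export
estimate_fractions <- function(bulk, ref) {
  stopifnot(inherits(bulk, "ExpressionMatrix"),
            inherits(ref, "SignatureMatrixRef"))
  shared <- intersect(norm_symbols(bulk$gene_ids), norm_symbols(ref$gene_ids))
  if (length(shared) == 0L) {
    stop("no shared genes between bulk and reference", call. = FALSE)
  }
  n_types <- length(ref$cell_type_ids)
  if (length(shared) < n_types) {
    warning(sprintf("only %d shared genes for %d cell types; fit is underdetermined",
                    length(shared), n_types), call. = FALSE)
  }
  bi <- match(shared, norm_symbols(bulk$gene_ids))
  ri <- match(shared, norm_symbols(ref$gene_ids))
  A <- ref$profiles[ri, , drop = FALSE]
  fr <- t(vapply(seq_along(bulk$sample_ids), function(j) {
    y <- bulk$values[bi, j]
    tot <- sum(y)
    if (tot > 0) y <- y / tot
    coefs <- nnls_solve(A, y)
    s <- sum(coefs)
    if (s <= 0) {
      warning("all-zero coefficient vector for sample ",
              bulk$sample_ids[j], "; returning uniform fractions",
              call. = FALSE)
      rep(1 / n_types, n_types)
    } else {
      coefs / s
    }
  }, numeric(n_types)))
  fraction_matrix(fr, bulk$sample_ids, ref$cell_type_ids)
}

#' Construct a per-group, per-cell-type expression profile
#'
#' Imputed mean expression and per-gene coefficient of variation for one
#' cell type within one response group.
#'
#' @param group `"NR"` or `"R"`.
#' @param cell_type cell-type id.
#' @param gene_ids gene identifiers.
#' @param mu per-gene means, >= 0.
#' @param cv per-gene coefficients of variation, >= 0 (0 where `mu == 0`).
#' @return An object of class `GroupProfile`.
#' @export
group_profile <- function(group, cell_type, gene_ids, mu, cv) {
  stopifnot(group %in% c("NR", "R"), length(mu) == length(gene_ids),
            length(cv) == length(gene_ids))
  if (any(!is.finite(mu)) || any(mu < 0)) stop("mu must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(cv)) || any(cv < 0)) stop("cv must be finite and >= 0", call. = FALSE)
  if (any(mu == 0 & cv != 0)) stop("cv must be 0 where mu is 0", call. = FALSE)
  structure(list(group = group, cell_type = as.character(cell_type),
                 gene_ids = as.character(gene_ids),
                 mu = as.numeric(mu), cv = as.numeric(cv)),
            class = "GroupProfile")
}

#' Build a group profile from replicate expression values
#'
#' Convenience constructor computing per-gene mean and sample coefficient
#' of variation (sd/mean, n-1 denominator) from a genes x replicates value
#' matrix (a vector is treated as one gene).
#'
#' @param values numeric matrix (genes x replicates) or vector.
#' @param group,cell_type annotations, see [group_profile()].
#' @param gene_ids gene identifiers (default rownames or `gene1...`).
#' @return A [group_profile()].
#' @export
#' @examples
#' estimate_dispersion(group_profile_from_values(c(2, 4, 6)))$alpha
group_profile_from_values <- function(values, group = "NR",
                                      cell_type = "Neutrophil",
                                      gene_ids = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  }
  mu <- rowMeans(values)
  sdev <- apply(values, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdev / mu, 0)
  group_profile(group, cell_type, gene_ids, mu, cv)
}

#' Impute per-group cell-type expression profiles from bulk data
#'
#' Group-mode profile imputation: within each response group, every gene's
#' bulk values are modelled as the fraction-weighted sum of unknown
#' cell-type means, solved by non-negative least squares over the group's
#' samples. The requested cell type's mean is returned as `mu`. Per-gene
#' variability (`cv`) is estimated from per-sample attributed expression:
#' each sample's residual is assigned to the target cell type (its share of
#' the fit), giving per-sample profile values `max(0, mu + r_s)` whose
#' sample coefficient of variation is reported.
#'
#' @param bulk an [expression_matrix()].
#' @param fractions a [fraction_matrix()] covering the bulk samples.
#' @param meta a [sample_metadata()] table.
#' @param cell_type target cell-type id present in `fractions`.
#' @return Named list of two [group_profile()] objects (`NR`, `R`).
#' @export
impute_group_profiles <- function(bulk, fractions, meta, cell_type) {
  stopifnot(inherits(bulk, "ExpressionMatrix"),
            inherits(fractions, "FractionMatrix"))
  if (!cell_type %in% fractions$cell_type_ids) {
    stop("cell type not present in fractions: ", cell_type, call. = FALSE)
  }
  t_idx <- match(cell_type, fractions$cell_type_ids)
  out <- lapply(c(NR = "NR", R = "R"), function(g) {
    ids <- meta$sample_id[meta$group == g]
    ids <- intersect(ids, intersect(bulk$sample_ids, fractions$sample_ids))
    if (length(ids) < 3L) {
      stop("fewer than 3 samples in group ", g, call. = FALSE)
    }
    FF <- fractions$fractions[ids, , drop = FALSE]
    qrF <- qr(FF)
    if (qrF$rank < ncol(FF)) {
      dep <- fractions$cell_type_ids[qrF$pivot[(qrF$rank + 1L):ncol(FF)]]
      stop("rank-deficient fraction design in group ", g,
           "; collinear cell type(s): ", paste(dep, collapse = ", "),
           call. = FALSE)
    }
    Y <- bulk$values[, ids, drop = FALSE]
    mu <- numeric(nrow(Y))
    cv <- numeric(nrow(Y))
    # residuals from a p-parameter fit on n samples are underdispersed by
    # (n - p)/n; rescale so the imputed CV reflects between-sample spread
    df_corr <- sqrt(length(ids) / max(1L, length(ids) - ncol(FF)))
    for (gi in seq_len(nrow(Y))) {
      y <- Y[gi, ]
      coefs <- nnls_solve(FF, y)
      mu[gi] <- coefs[t_idx]
      resid <- (y - as.numeric(FF %*% coefs)) * df_corr
      attributed <- pmax(0, mu[gi] + resid)
      m <- mean(attributed)
      # CV is defined 0 where the imputed mean is 0
      cv[gi] <- if (mu[gi] > 0 && m > 0) stats::sd(attributed) / m else 0
    }
    group_profile(g, cell_type, bulk$gene_ids, mu, cv)
  })
  n_zero <- vapply(out, function(p) sum(p$mu == 0), integer(1L))
  if (any(n_zero > 0)) {
    msg_stage(sprintf("genes with zero imputed mean: NR=%d, R=%d (excluded from dispersion)",
                      n_zero[["NR"]], n_zero[["R"]]))
  }
  out
}
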