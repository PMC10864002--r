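#' Construct an expression matrix
#'
#' The central container of the package: a gene x sample (or gene x cell)
#' non-negative matrix tagged with a layer describing its scale. A `counts`
#' layer must be integral; `cpm` and `logcpm` are continuous.
#'
#' @param values numeric matrix, genes in rows, samples/cells in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to colnames of `values`).
#' @param layer one of `"counts"`, `"cpm"`, `"logcpm"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 3,
#'   dimnames = list(c("A", "B", "C"), c("s1", "s2"))), layer = "counts")
#' dim(m$values)
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              layer = c("counts", "cpm", "logcpm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames)", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("dimensions of values do not match id lists", call. = FALSE)
  }
  if (any(!nzchar(gene_ids)) || anyNA(gene_ids)) {
    stop("gene ids must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L],
         call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("expression values must be non-negative and finite", call. = FALSE)
  }
  if (layer == "counts" && any(values != round(values))) {
    stop("layer 'counts' requires integral values", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 values = values, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [layer: %s]\n",
              length(x$gene_ids), length(x$sample_ids), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

infer_layer <- function(values) {
  if (all(values == round(values))) "counts" else "cpm"
}

#' Read an expression matrix from disk
#'
#' Reads either a dense CSV/TSV (first column gene id, header row of sample
#' ids) or a Matrix Market coordinate triplet with plain-text gene and sample
#' id sidecars (`<prefix>.mtx`, `<prefix>.genes.txt`, `<prefix>.samples.txt`).
#' The layer is inferred as `counts` when all entries are integral, `cpm`
#' otherwise.
#'
#' @param path file path; for `format = "mtx"` either the `.mtx` file or the
#'   common prefix.
#' @param format `"csv"` or `"mtx"`. Default guessed from the extension.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "csv") {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    expression_matrix(vals, gene_ids, colnames(df)[-1L],
                      layer = infer_layer(vals))
  } else {
    prefix <- sub("\\.mtx$", "", path)
    mtx_path <- paste0(prefix, ".mtx")
    genes_path <- paste0(prefix, ".genes.txt")
    samples_path <- paste0(prefix, ".samples.txt")
    for (p in c(mtx_path, genes_path, samples_path)) {
      if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(mtx_path))
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    expression_matrix(m, gene_ids, sample_ids, layer = infer_layer(m))
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; `mtx` writes the sparse triplet plus the
#' two id sidecar files.
#'
#' @param m an [expression_matrix()].
#' @param path output path (for mtx, the `.mtx` path or prefix).
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (format == "csv") {
    df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    prefix <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                    paste0(prefix, ".mtx"))
    writeLines(m$gene_ids, paste0(prefix, ".genes.txt"))
    writeLines(m$sample_ids, paste0(prefix, ".samples.txt"))
  }
  invisible(path)
}

#' Library-size normalization
#'
#' Scales each column to counts-per-million (`cpm`: column sum 1e6) or to
#' `logcpm = log2(cpm + 1)`.
#'
#' @param m an [expression_matrix()] with layer `counts`.
#' @param target `"cpm"` or `"logcpm"`.
#' @return An [expression_matrix()] with the requested layer.
#' @export
normalize_expression <- function(m, target = c("cpm", "logcpm")) {
  target <- match.arg(target)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("layer must be counts", call. = FALSE)
  totals <- colSums(m$values)
  if (any(totals == 0)) {
    stop("all-zero column for sample: ",
         m$sample_ids[which(totals == 0)[1L]], call. = FALSE)
  }
  cpm <- sweep(m$values, 2L, totals / 1e6, "/")
  vals <- if (target == "cpm") cpm else log2(cpm + 1)
  expression_matrix(vals, m$gene_ids, m$sample_ids, layer = target)
}

#' Quality-filter cells of a count matrix
#'
#' Retains cells (columns) whose number of detected genes lies in
#' `[min_genes, max_genes]` and whose mitochondrial UMI fraction is at most
#' `max_mito_frac`. Defaults mirror common droplet-QC practice: cells
#' expressing fewer than 500 or more than 5000 unique genes, or with more
#' than 10% mitochondrial UMIs, are discarded. Mitochondrial genes are
#' identified by a case-insensitive id prefix.
#'
#' @param m an [expression_matrix()] with layer `counts`.
#' @param min_genes,max_genes detected-gene bounds (defaults 500 / 5000).
#' @param max_mito_frac maximal mitochondrial UMI fraction (default 0.10).
#' @param mito_prefix gene-id prefix marking mitochondrial genes
#'   (default `"mt-"`, case-insensitive).
#' @return The filtered [expression_matrix()].
#' @export
filter_cells <- function(m, min_genes = 500, max_genes = 5000,
                         max_mito_frac = 0.10, mito_prefix = "mt-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("layer must be counts", call. = FALSE)
  n_detected <- colSums(m$values > 0)
  is_mito <- startsWith(tolower(m$gene_ids), tolower(mito_prefix))
  totals <- colSums(m$values)
  mito_frac <- if (any(is_mito)) {
    ifelse(totals > 0, colSums(m$values[is_mito, , drop = FALSE]) / totals, 0)
  } else {
    rep(0, ncol(m$values))
  }
  keep <- n_detected >= min_genes & n_detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep)) stop("all cells removed by filtering", call. = FALSE)
  expression_matrix(m$values[, keep, drop = FALSE], m$gene_ids,
                    m$sample_ids[keep], layer = "counts")
}
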