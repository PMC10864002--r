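#' Construct a gene set
#'
#' A named, ordered list of unique gene identifiers. Identifiers are
#' de-duplicated case-insensitively (first occurrence wins), since gene-set
#' membership is matched on upper-cased symbols throughout the package.
#'
#' @param name character set name.
#' @param genes character vector of gene identifiers.
#' @return An object of class `GeneSet`.
#' @export
#' @examples
#' gene_set("isg", c("IFIT1", "MX1", "Ifit1"))$genes
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set must be non-empty", call. = FALSE)
  genes <- genes[!duplicated(norm_symbols(genes))]
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more genes, all
#' tab-separated. Genes are de-duplicated preserving first occurrence.
#'
#' @param path file path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields", i),
           call. = FALSE)
    }
    gene_set(fields[[1L]], fields[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1L), "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @param description description field written per line (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(sets[[i]]$name, description[[i]], sets[[i]]$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Packaged interferon signatures
#'
#' Returns the two gene sets shipped with the package: the 15-gene
#' IFN-stimulated neutrophil signature (`neut_ifn15`) and the 6-gene
#' IFN-gamma comparator signature (`ifng6`). The two sets share no genes.
#'
#' @param which `"neut_ifn15"`, `"ifng6"`, or `"both"`.
#' @return A [gene_set()] (or named list of both).
#' @export
#' @examples
#' length(packaged_signature("neut_ifn15"))
packaged_signature <- function(which = c("both", "neut_ifn15", "ifng6")) {
  which <- match.arg(which)
  dir <- system.file("extdata", package = "ifnsig")
  both <- list(
    neut_ifn15 = read_gmt(file.path(dir, "neut_ifn15.gmt"))[[1L]],
    ifng6 = read_gmt(file.path(dir, "ifng6.gmt"))[[1L]]
  )
  if (which == "both") both else both[[which]]
}

#' Match a gene set against a matrix's gene universe
#'
#' Upper-cased symbol matching; genes absent from the matrix are dropped
#' with a warning.
#'
#' @param set a [gene_set()].
#' @param gene_ids character universe.
#' @param min_present minimal number of matched genes required.
#' @return Integer indices of matched genes in `gene_ids`.
#' @keywords internal
match_set_genes <- function(set, gene_ids, min_present = 2L) {
  idx <- match(norm_symbols(set$genes), norm_symbols(gene_ids))
  missing <- set$genes[is.na(idx)]
  if (length(missing)) {
    warning(sprintf("gene set '%s': %d gene(s) absent from matrix: %s",
                    set$name, length(missing),
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) < min_present) {
    stop(sprintf("gene set '%s': fewer than %d genes present (missing: %s)",
                 set$name, min_present, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  idx
}
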