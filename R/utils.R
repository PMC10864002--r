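#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG with `seed`, evaluates `expr`, and restores the caller's
#' RNG state afterwards, so seeded operations never perturb global
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a root seed
#'
#' Deterministic derivation of per-stage seeds from a single root seed, so a
#' pipeline run is reproducible from one integer. Result is always a valid
#' positive 32-bit integer.
#'
#' @param root integer root seed.
#' @param stage character stage label.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  val <- (abs(as.numeric(root)) * 1000003 + h * 7919 + 17) %% 2147483587
  as.integer(val) + 1L
}

#' Upper-case gene symbols for cross-species matching
#'
#' Mouse and human symbols differ only by case for most one-to-one orthologs
#' (Ly6e vs LY6E); matching is therefore done on upper-cased symbols.
#'
#' @param x character vector of gene identifiers.
#' @return Upper-cased identifiers.
#' @keywords internal
norm_symbols <- function(x) toupper(trimws(x))

msg_stage <- function(..., verbose = getOption("ifnsig.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[ifnsig] ", ...)
  invisible(NULL)
}
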