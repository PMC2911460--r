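# internal helpers shared across modules

# Run `expr` under a given RNG seed without disturbing the caller's RNG
# stream; the global seed is restored on exit.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate a genes x samples expression matrix.
check_expr <- function(expr, min_genes = 2L, min_samples = 3L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix (genes as rows, samples as columns)")
  if (anyNA(expr) || any(!is.finite(expr)))
    stop("'expr' contains missing or non-finite values")
  if (nrow(expr) < min_genes)
    stop("'expr' must have at least ", min_genes, " genes")
  if (ncol(expr) < min_samples)
    stop("'expr' must have at least ", min_samples, " samples")
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers in 'expr'")
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample identifiers in 'expr'")
  expr
}

#' Floor p-values at the conventional reporting limit
#'
#' Double-precision p-values below `2.2e-16` are conventionally reported as
#' "<= 2.2e-16"; this helper applies that floor for text output. Machine
#' outputs elsewhere in the package keep the raw values.
#'
#' @param p numeric vector of p-values.
#' @param floor reporting floor (default `2.2e-16`).
#' @return `pmax(p, floor)`, preserving `NA`s.
#' @export
p_floor <- function(p, floor = 2.2e-16) {
  pmax(p, floor)
}

# zero-padded identifier sequences: g0001 ... / s01 ...
make_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}
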