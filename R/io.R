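#' Read an expression matrix from a tab-separated file
#'
#' Expected layout: a header row of sample ids, genes as rows, first column
#' the gene id. Parsing is locale-independent (`.` decimal separator).
#' Ragged rows, non-numeric cells and duplicated identifiers are rejected
#' with an error naming the offending row/column.
#'
#' @param path file path.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fill = FALSE,
                           quote = "")
  if (ncol(tab) < 2) stop("expression file needs gene ids plus >= 1 sample")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene id '", ids[duplicated(ids)][1], "' in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", vals[bad[1], bad[2]], "' at gene '",
         ids[bad[1]], "', column '", colnames(vals)[bad[2]], "' in ", path)
  }
  dimnames(num) <- list(ids, colnames(tab)[-1])
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample ids in ", path)
  num
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: header row of sample ids, first column
#' `gene_id`.
#'
#' @param expr genes x samples matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- check_expr(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample covariate table
#'
#' One row per sample; the first column must be `sample_id`. Column types
#' are inferred (numeric where parseable, character otherwise).
#'
#' @param path file path.
#' @return data.frame with a `sample_id` column.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fill = FALSE, quote = "")
  if (names(tab)[1] != "sample_id")
    stop("first column of ", path, " must be 'sample_id'")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in ", path)
  tab
}

#' Write a sample covariate table
#'
#' @param covars data.frame; a `sample_id` column is added from the row
#'   names if absent.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covars, path) {
  if (!"sample_id" %in% names(covars))
    covars <- cbind(sample_id = rownames(covars), covars)
  utils::write.table(covars, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a factor-model fit to plain-text files
#'
#' Writes `loadings.tsv` (gene_id + one column per factor),
#' `uniquenesses.tsv` (gene_id, psi), `scores.tsv` (sample_id + one column
#' per factor) and `metadata.txt` (Debian-control-style key: value pairs
#' with q, iterations, convergence and rotation status) into `dir`.
#'
#' @param fit a `"factor_fit"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_factor_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "factor_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(gene_id = rownames(fit$B), fit$B, check.names = FALSE),
    file.path(dir, "loadings.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(fit$psi), psi = unname(fit$psi)),
    file.path(dir, "uniquenesses.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(fit$Z), fit$Z, check.names = FALSE),
    file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meta <- c(q = fit$q, iterations = length(fit$loglik_trace),
            converged = fit$converged, rotated = fit$rotated,
            df_residual = fit$df_residual %||% NA,
            x_name = fit$x_name %||% NA)
  writeLines(paste0(names(meta), ": ", unlist(meta)),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Read a factor-model fit written by [write_factor_fit()]
#'
#' Restores the parameters (B, psi, Z) and metadata; the log-likelihood
#' trace is not serialized and comes back empty.
#'
#' @param dir directory containing the fit files.
#' @return A `"factor_fit"`.
#' @export
read_factor_fit <- function(dir) {
  ld <- utils::read.delim(file.path(dir, "loadings.tsv"), check.names = FALSE)
  un <- utils::read.delim(file.path(dir, "uniquenesses.tsv"),
                          check.names = FALSE)
  sc <- utils::read.delim(file.path(dir, "scores.tsv"), check.names = FALSE)
  meta_lines <- readLines(file.path(dir, "metadata.txt"))
  meta <- stats::setNames(
    sub("^[^:]+: ?", "", meta_lines),
    sub(":.*$", "", meta_lines))
  B <- as.matrix(ld[, -1, drop = FALSE])
  rownames(B) <- ld$gene_id
  Z <- as.matrix(sc[, -1, drop = FALSE])
  rownames(Z) <- sc$sample_id
  psi <- stats::setNames(un$psi, un$gene_id)
  structure(list(
    B = B, psi = psi, Z = Z, q = as.integer(meta[["q"]]),
    loglik_trace = numeric(0),
    converged = as.logical(meta[["converged"]]),
    rotated = as.logical(meta[["rotated"]]),
    excluded = which(is.na(psi)),
    df_residual = suppressWarnings(as.integer(meta[["df_residual"]])),
    x = NULL,
    x_name = if (identical(meta[["x_name"]], "NA")) NULL
             else meta[["x_name"]]),
    class = "factor_fit")
}

#' Write a per-gene test table as tab-separated text
#'
#' @param table a test table from [pearson_test()] or [two_group_test()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_test_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
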