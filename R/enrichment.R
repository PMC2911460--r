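#' Exact upper-tail hypergeometric probability
#'
#' The over-representation (one-sided Fisher) p-value: the probability that
#' at least `k` of the `n` genes in a list are annotated to a term, when
#' `K` of the `N` background genes carry the annotation,
#' \deqn{P(X \ge k), \quad X \sim \mathrm{Hypergeometric}(N, K, n).}
#' Computed exactly through the log-space hypergeometric distribution
#' function; no normal or chi-square approximation.
#'
#' @param k observed count of annotated genes in the list.
#' @param K term size in the background.
#' @param n list size.
#' @param N background size.
#' @return The upper-tail probability; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(2, 4, 688, 11213)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != floor(vals)) || any(vals < 0))
    stop("counts must be non-negative integers")
  if (K > N) stop("term size 'K' exceeds background size 'N'")
  if (n > N) stop("list size 'n' exceeds background size 'N'")
  if (k > min(K, n)) stop("'k' cannot exceed min(K, n)")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Build an annotation map
#'
#' Container for term -> gene-set annotations against a declared
#' background. Genes annotated outside the background are dropped from the
#' term sets; empty terms are removed.
#'
#' @param terms named list of character vectors (term id -> gene ids).
#' @param background character vector of all gene ids under consideration
#'   (default: the union of all annotated genes).
#' @param meta optional data.frame of term metadata with a `term_id`
#'   column (e.g. name, source).
#' @return An object of class `"annotation_map"`.
#' @export
annotation_map <- function(terms, background = NULL, meta = NULL) {
  stopifnot(is.list(terms), length(names(terms)) == length(terms))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(background)) background <- sort(unique(unlist(terms)))
  background <- unique(as.character(background))
  terms <- lapply(terms, intersect, y = background)
  terms <- terms[vapply(terms, length, integer(1)) > 0]
  if (!is.null(meta)) stopifnot("term_id" %in% names(meta))
  structure(list(terms = terms, background = background, meta = meta),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", length(x$terms), "terms over",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Read gene-set annotations from a file
#'
#' Two formats are supported: a two-column tab-separated file
#' (gene_id, term_id; a header line is detected and skipped), and the GMT
#' format (one term per line: term id, description, then member genes).
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"tsv"` or `"gmt"`.
#' @param background optional background gene set passed to
#'   [annotation_map()].
#' @return An `"annotation_map"`.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gmt"),
                            background = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, integer(1)) < 3)
    if (length(bad))
      stop("GMT line ", bad[1], " has fewer than 3 fields")
    terms <- lapply(fields, function(f) f[-(1:2)])
    names(terms) <- vapply(fields, `[[`, character(1), 1)
    meta <- data.frame(term_id = names(terms),
                       name = vapply(fields, `[[`, character(1), 2),
                       stringsAsFactors = FALSE)
    annotation_map(terms, background, meta)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) != 2)
      stop("two-column annotation file expected (gene_id, term_id), got ",
           ncol(tab), " columns")
    if (identical(tolower(tab[1, 1]), "gene_id")) tab <- tab[-1, , drop = FALSE]
    terms <- split(tab[[1]], tab[[2]])
    annotation_map(terms, background)
  }
}

#' Hypergeometric term enrichment of a gene list
#'
#' One exact upper-tail hypergeometric test per annotation term against the
#' declared background. List genes outside the background are dropped with
#' a warning (and counted in the `dropped` attribute).
#'
#' @param gene_list character vector of gene ids (non-empty after
#'   background filtering).
#' @param annotation an `"annotation_map"`.
#' @param alpha rows with `p_value <= alpha` are flagged enriched.
#'   Default 0.05, on the raw p-values; `adjust = "BH"` applies
#'   Benjamini-Hochberg first.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame sorted by increasing p-value (ties by term id):
#'   term_id, term name when available, term_size (K), count (k),
#'   list_size (n), background_size (N), p_value, enriched.
#' @examples
#' ann <- annotation_map(list(t1 = c("g1", "g2", "g3")),
#'                       background = paste0("g", 1:50))
#' enrich_table(c("g1", "g2", "g9"), ann)
#' @export
enrich_table <- function(gene_list, annotation, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotation, "annotation_map"))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0) stop("'gene_list' is empty")
  off <- setdiff(gene_list, annotation$background)
  if (length(off)) {
    warning(length(off), " gene(s) not in the background were dropped")
    gene_list <- setdiff(gene_list, off)
  }
  if (length(gene_list) == 0)
    stop("'gene_list' has no genes in the background")

  N <- length(annotation$background)
  n <- length(gene_list)
  K <- vapply(annotation$terms, length, integer(1))
  k <- vapply(annotation$terms,
              function(g) length(intersect(g, gene_list)), integer(1))
  p <- mapply(hypergeom_upper_tail, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  out <- data.frame(term_id = names(annotation$terms), term_size = K,
                    count = k, list_size = n, background_size = N,
                    p_value = p, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotation$meta) && "name" %in% names(annotation$meta))
    out$name <- annotation$meta$name[match(out$term_id,
                                           annotation$meta$term_id)]
  p_flag <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH")
            else out$p_value
  out$enriched <- p_flag <= alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = length(off))
}
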