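#' Per-gene Pearson correlation test against a continuous trait
#'
#' For each gene, the Pearson correlation r between its expression profile
#' and the trait, with the two-sided p-value from the exact transform
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on n-2 degrees of freedom.
#'
#' @param expr genes x samples matrix (raw or factor-adjusted).
#' @param trait numeric covariate of interest, length `ncol(expr)`,
#'   non-constant.
#' @param mode label stored with the result, `"raw"` or `"adjusted"`.
#' @return A data.frame (gene_id, statistic, p_value) with attributes
#'   `n_used` and `mode`. Constant genes get `NA` statistic and p-value 1,
#'   with a warning.
#' @examples
#' d <- simulate_case(1, seed = 1)
#' tt <- pearson_test(d$expr, rnorm(20))
#' head(tt)
#' @export
pearson_test <- function(expr, trait, mode = c("raw", "adjusted")) {
  mode <- match.arg(mode)
  expr <- check_expr(expr, min_samples = 4L)
  n <- ncol(expr)
  if (length(trait) != n) stop("'trait' must have one value per sample")
  if (!is.numeric(trait)) stop("'trait' must be numeric")
  if (stats::sd(trait) == 0) stop("'trait' is constant")

  sds <- apply(expr, 1, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning(sum(constant), " constant gene(s): statistic undefined, p set to 1")
  r <- rep(NA_real_, nrow(expr))
  r[!constant] <- as.vector(stats::cor(t(expr[!constant, , drop = FALSE]),
                                       trait))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[r^2 >= 1] <- 0
  p[constant] <- 1
  structure(
    data.frame(gene_id = rownames(expr), statistic = r, p_value = p,
               row.names = NULL, stringsAsFactors = FALSE),
    n_used = n, mode = mode, test = "pearson")
}

#' Per-gene two-sample t-test between two groups
#'
#' Binary-covariate analog of [pearson_test()] for studies whose variable
#' of interest is a two-level group: a pooled-variance two-sample t-test
#' per gene (Welch optional), two-sided.
#'
#' @param expr genes x samples matrix.
#' @param group two-level grouping (vector or factor), each level with at
#'   least 2 samples.
#' @param pooled use the pooled-variance statistic (default); `FALSE` gives
#'   Welch's test.
#' @param mode label stored with the result.
#' @return A data.frame (gene_id, statistic, p_value) with attributes
#'   `n_used` and `mode`; the statistic is the t value.
#' @export
two_group_test <- function(expr, group, pooled = TRUE,
                           mode = c("raw", "adjusted")) {
  mode <- match.arg(mode)
  expr <- check_expr(expr, min_samples = 4L)
  if (length(group) != ncol(expr))
    stop("'group' must have one value per sample")
  group <- factor(group)
  if (nlevels(group) != 2) stop("'group' must have exactly two levels")
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (min(n1, n2) < 2) stop("each group must contain at least 2 samples")

  X1 <- expr[, group == levels(group)[1], drop = FALSE]
  X2 <- expr[, group == levels(group)[2], drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(expr))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / se
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  constant <- se == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): statistic undefined, p set to 1")
    tt[constant] <- NA_real_
    p[constant] <- 1
  }
  structure(
    data.frame(gene_id = rownames(expr), statistic = tt, p_value = p,
               row.names = NULL, stringsAsFactors = FALSE),
    n_used = ncol(expr), mode = mode,
    test = if (pooled) "t_pooled" else "t_welch")
}

#' Extract the significant gene list from a test table
#'
#' Genes with `p_value < alpha`. No multiplicity correction by default —
#' the raw-cutoff convention used throughout this workflow — with
#' Benjamini-Hochberg available behind a flag.
#'
#' @param table a test table from [pearson_test()] or [two_group_test()].
#' @param alpha significance cutoff. Default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Character vector of gene ids.
#' @export
gene_list <- function(table, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table),
            all(c("gene_id", "p_value") %in% names(table)))
  p <- table$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  table$gene_id[p < alpha]
}

#' Percentage of one gene list contained in another
#'
#' `100 |a intersect b| / |a|`.
#'
#' @param list_a,list_b character vectors of gene ids; `list_a` must be
#'   non-empty.
#' @return A percentage in \[0, 100\].
#' @export
overlap_fraction <- function(list_a, list_b) {
  if (length(list_a) == 0) stop("'list_a' is empty; overlap undefined")
  100 * length(intersect(list_a, list_b)) / length(unique(list_a))
}
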