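# Shared association engine: for every column of `scores` and every
# variable in `vars`, the partial F-test of the variable added last to a
# linear model that already contains `adjust` (possibly empty). For a
# single continuous variable and no adjustment this is exactly the Pearson
# correlation t-test; for a categorical variable and no adjustment it is
# the one-way ANOVA F-test.
assoc_engine <- function(scores, vars, adjust = NULL, per_level = TRUE) {
  stopifnot(is.matrix(scores), is.data.frame(vars))
  if (nrow(vars) != nrow(scores))
    stop("variable table must have one row per unit (", nrow(scores), ")")
  vars <- as.data.frame(vars, stringsAsFactors = FALSE)
  for (j in seq_along(vars))
    if (is.character(vars[[j]])) vars[[j]] <- factor(vars[[j]])
  if (!is.null(adjust)) {
    adjust <- as.data.frame(adjust, stringsAsFactors = FALSE)
    for (j in seq_along(adjust))
      if (is.character(adjust[[j]])) adjust[[j]] <- factor(adjust[[j]])
    # internal syntactic names; user-facing names are reported separately
    names(adjust) <- paste0(".adj", seq_along(adjust))
  }

  q <- ncol(scores)
  p_mat <- matrix(NA_real_, q, ncol(vars),
                  dimnames = list(colnames(scores), names(vars)))
  levels_tab <- NULL
  omitted <- character(0)

  for (v in names(vars)) {
    df <- data.frame(.v = vars[[v]])
    rhs <- ".v"
    if (!is.null(adjust) && ncol(adjust) > 0) {
      df <- cbind(adjust, df)
      rhs <- paste(c(names(adjust), ".v"), collapse = " + ")
    }
    for (k in seq_len(q)) {
      df$.y <- scores[, k]
      a <- stats::anova(stats::lm(stats::as.formula(paste(".y ~", rhs)),
                                  data = df))
      p_mat[k, v] <- a[".v", "Pr(>F)"]
    }
    if (per_level && is.factor(vars[[v]])) {
      for (lev in levels(vars[[v]])) {
        in_lev <- vars[[v]] == lev
        if (sum(in_lev) < 2 || sum(!in_lev) < 2) {
          omitted <- c(omitted, paste0(v, ":", lev))
          next
        }
        for (k in seq_len(q)) {
          tst <- stats::t.test(scores[in_lev, k], scores[!in_lev, k],
                               var.equal = TRUE)
          levels_tab <- rbind(levels_tab, data.frame(
            factor = colnames(scores)[k], variable = v, level = lev,
            n = sum(in_lev), statistic = unname(tst$statistic),
            p_value = tst$p.value, stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(p = p_mat, per_level = levels_tab, omitted_levels = unique(omitted))
}

#' Associate factors with external sample variables
#'
#' The machinery behind a factor-by-covariate description table: each
#' estimated factor is tested against each external sample variable
#' (hatch, dam, weight, batch, ...). Categorical variables are tested by an
#' analysis-of-variance F-test of the factor scores across levels,
#' continuous ones by the correlation t-test; both are computed as the
#' partial F-test of the variable in a linear model for the scores.
#'
#' Because the factors are defined conditionally on the covariate of
#' interest (the model is fitted on residualized expressions), the
#' association model adjusts for that covariate by default whenever the fit
#' carries it: score variation that merely reflects finite-sample imbalance
#' of an external variable across the design is not evidence of
#' heterogeneity. Set `adjust_for = NULL` for plain one-way tests.
#'
#' For every categorical variable, per-level Student t-tests (level versus
#' rest, pooled variance) are also returned; levels with fewer than 2
#' samples are omitted and flagged.
#'
#' @param fit a `"factor_fit"`.
#' @param covars data.frame of external sample variables, one row per
#'   sample in the fit (character columns are treated as categorical).
#' @param adjust_for optional data.frame (or vector) of nuisance covariates
#'   to include in every model; defaults to the covariate of interest
#'   stored in the fit, if any.
#' @param per_level compute per-level t-tests for categorical variables.
#' @return An `"association_report"`: list with `p` (factors x variables
#'   matrix of p-values), `side = "samples"`, `per_level`,
#'   `omitted_levels`, `adjusted_for`.
#' @examples
#' d <- simulate_case(1, seed = 1)
#' f <- fit_em(residualize(d$expr, d$primary_group), 1)
#' rep <- factor_sample_association(f, data.frame(het = factor(d$het_vars[[1]])))
#' rep$p
#' @export
factor_sample_association <- function(fit, covars, adjust_for, per_level = TRUE) {
  stopifnot(inherits(fit, "factor_fit"))
  if (fit$q == 0L) stop("the fit has no factors to interpret")
  if (missing(adjust_for)) {
    adjust_for <- if (!is.null(fit$x))
      stats::setNames(data.frame(fit$x), fit$x_name %||% "x")
  }
  if (!is.null(adjust_for) && !is.data.frame(adjust_for))
    adjust_for <- data.frame(x = adjust_for)
  res <- assoc_engine(fit$Z, covars, adjust = adjust_for,
                      per_level = per_level)
  structure(c(res, list(side = "samples",
                        adjusted_for = names(adjust_for))),
            class = "association_report")
}

#' Associate factor loadings with gene-level features
#'
#' Gene-side counterpart of [factor_sample_association()]: the same tests
#' applied to the loading columns across gene features (oligonucleotide
#' size, array block/row/column, annotation classes, ...). A feature with
#' at least 10 distinct numeric values is treated as continuous, otherwise
#' as categorical.
#'
#' @param fit a `"factor_fit"` (rotated or not; rotation changes which
#'   factor carries which feature, not the overall fit).
#' @param gene_features data.frame of features, one row per gene in the
#'   fit.
#' @param adjust_for optional nuisance features included in every model
#'   (none by default).
#' @param per_level compute per-level t-tests for categorical features.
#' @return An `"association_report"` with `side = "genes"`.
#' @export
factor_gene_association <- function(fit, gene_features, adjust_for = NULL,
                                    per_level = TRUE) {
  stopifnot(inherits(fit, "factor_fit"))
  if (fit$q == 0L) stop("the fit has no factors to interpret")
  gene_features <- as.data.frame(gene_features, stringsAsFactors = FALSE)
  for (j in seq_along(gene_features)) {
    v <- gene_features[[j]]
    if (is.numeric(v) && length(unique(v)) < 10)
      gene_features[[j]] <- factor(v)
  }
  if (!is.null(adjust_for) && !is.data.frame(adjust_for))
    adjust_for <- data.frame(x = adjust_for)
  res <- assoc_engine(fit$B, gene_features, adjust = adjust_for,
                      per_level = per_level)
  structure(c(res, list(side = "genes", adjusted_for = names(adjust_for))),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Factor association report (side: ", x$side, ")\n", sep = "")
  if (!is.null(x$adjusted_for))
    cat("Adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  print(signif(p_floor(x$p), 3))
  if (length(x$omitted_levels))
    cat("Levels omitted from per-level tests (< 2 units):",
        paste(x$omitted_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Genes contributing most to a factor
#'
#' A gene's contribution to factor k is measured on the correlation scale,
#' \deqn{\lambda_{jk} = b_{jk} / \sqrt{b_j b_j' + \psi_j},}
#' the model correlation between the gene and the factor, bounded by 1 in
#' absolute value — the only scale on which a fixed cutoff is meaningful
#' across genes. Returns the genes with |lambda| above the threshold.
#'
#' @param fit a `"factor_fit"`.
#' @param factor factor index in `1..q`.
#' @param threshold cutoff on |lambda|. Default 0.8.
#' @return Character vector of gene ids. Genes excluded from the fit never
#'   qualify.
#' @export
top_genes <- function(fit, factor, threshold = 0.8) {
  stopifnot(inherits(fit, "factor_fit"))
  if (length(factor) != 1 || factor < 1 || factor > fit$q)
    stop("'factor' must be a single index in 1..", fit$q)
  tot <- rowSums(fit$B^2) + fit$psi
  lambda <- fit$B[, factor] / sqrt(tot)
  ids <- rownames(fit$B)[which(abs(lambda) > threshold)]
  ids[!is.na(ids)]
}

#' Project samples on principal components
#'
#' PCA sample map used to contrast raw and factor-adjusted data: the
#' selected genes are row-centered and the samples are scored on the top
#' principal components. The sign of each component is fixed so that its
#' largest-|coefficient| gene has a positive coefficient.
#'
#' @param expr genes x samples matrix.
#' @param gene_subset optional gene ids or indices to restrict to (at least
#'   `n_components` of them).
#' @param n_components number of components. Default 2.
#' @return List of class `"pca_projection"`: `scores` (samples x
#'   components), `sdev` (all singular standard deviations),
#'   `var_explained` (per kept component), `coefficients` (gene
#'   coefficients of the kept components).
#' @export
pca_project <- function(expr, gene_subset = NULL, n_components = 2) {
  expr <- check_expr(expr)
  if (!is.null(gene_subset)) expr <- expr[gene_subset, , drop = FALSE]
  if (nrow(expr) < n_components)
    stop("need at least ", n_components, " genes for ", n_components,
         " components")
  Xc <- expr - rowMeans(expr)
  pc <- stats::prcomp(t(Xc), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  coefs <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coefs[, j]))
    if (coefs[i, j] < 0) {
      coefs[, j] <- -coefs[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, sdev = pc$sdev,
                 var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
                 coefficients = coefs),
            class = "pca_projection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
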