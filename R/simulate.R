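#' Simulate the illustrative heterogeneity scenarios
#'
#' Generates one of three fully specified synthetic expression studies used
#' throughout the package to exercise the factor-model pipeline on data with
#' known structure. Baseline expressions are independent standard normal
#' draws for `m` genes on `n` arrays. The samples are split into two equal
#' groups (the variable of interest) and `de_effect` is added to genes
#' 1-100 in the second group. Heterogeneity is induced by independent
#' grouping variables, each shifting 7 randomly chosen samples by
#' `het_effect`:
#' \describe{
#'   \item{case 1}{one grouping variable affecting all genes;}
#'   \item{case 2}{one grouping variable affecting genes 70-170 only;}
#'   \item{case 3}{two grouping variables affecting genes 70-170 and
#'     171-271 respectively.}
#' }
#' Gene windows are 1-based and inclusive. The 7 shifted samples are drawn
#' uniformly without replacement, independently for each grouping variable
#' (overlap between the two case-3 sets is allowed).
#'
#' @param case_id 1, 2 or 3.
#' @param m number of genes (at least 300, so the fixed windows exist).
#' @param n number of arrays (even, at least 14).
#' @param de_effect constant added to genes 1-100 in the second primary
#'   group; unit-variance scale. Default 1.
#' @param het_effect constant added by each heterogeneity variable to its
#'   affected genes for its 7 samples. Default 2.
#' @param seed integer seed; the generator is reproducible given the seed
#'   and leaves the caller's RNG state untouched.
#' @return An object of class `"simulated_dataset"`: a list with elements
#'   `expr` (m x n matrix with gene/sample ids), `primary_group` (named 0/1
#'   integer vector, the variable of interest), `het_vars` (list of named
#'   0/1 integer vectors), `affected_genes` (list of integer index vectors,
#'   one per heterogeneity variable), `de_genes` (integer indices carrying
#'   the primary effect), `case_id`, and `seed`.
#' @seealso [simulate_factor_model()] for a known-truth factor-model
#'   generator.
#' @examples
#' d <- simulate_case(1, seed = 7)
#' dim(d$expr)
#' length(d$affected_genes[[1]])
#' @export
simulate_case <- function(case_id, m = 1000, n = 20, de_effect = 1,
                          het_effect = 2, seed = 1) {
  if (!case_id %in% 1:3) stop("'case_id' must be 1, 2 or 3")
  if (m < 300) stop("'m' must be at least 300 so the fixed gene windows exist")
  if (n < 14) stop("'n' must be at least 14 (7 heterogeneity samples twice)")
  if (n %% 2 != 0) stop("'n' must be even (two equal primary groups)")

  windows <- switch(case_id,
                    list(seq_len(m)),
                    list(70:170),
                    list(70:170, 171:271))

  with_seed(seed, {
    expr <- matrix(stats::rnorm(m * n), m, n,
                   dimnames = list(make_ids("g", m), make_ids("s", n)))
    primary_group <- rep(c(0L, 1L), each = n / 2)
    names(primary_group) <- colnames(expr)
    de_genes <- 1:100
    expr[de_genes, primary_group == 1L] <-
      expr[de_genes, primary_group == 1L] + de_effect

    het_vars <- vector("list", length(windows))
    for (i in seq_along(windows)) {
      h <- rep(0L, n)
      h[sample.int(n, 7)] <- 1L
      names(h) <- colnames(expr)
      expr[windows[[i]], h == 1L] <- expr[windows[[i]], h == 1L] + het_effect
      het_vars[[i]] <- h
    }
    names(het_vars) <- paste0("het", seq_along(het_vars))

    structure(
      list(expr = expr, primary_group = primary_group, het_vars = het_vars,
           affected_genes = windows, de_genes = de_genes,
           case_id = case_id, seed = seed),
      class = "simulated_dataset")
  })
}

#' Simulate data from the factor model itself
#'
#' Known-truth generator: per gene k the data follow
#' \deqn{y_k = x \beta_k + b_k Z' + \epsilon_k,}
#' with factor scores Z drawn i.i.d. standard normal (n x q), loadings B
#' fixed by `loading_scheme`, and independent gene-specific noise with
#' variance `psi`. The true loadings and scores are returned so parameter
#' recovery can be asserted. The covariate of interest `x` splits the
#' samples into two equal groups; `x_effect` is added to genes
#' 1-min(100, m) in the second group.
#'
#' @param m,n,q numbers of genes, samples and factors (`q < n`; `q = 0`
#'   gives mutually independent genes given `x`).
#' @param loading_scheme either an m x q numeric matrix of loadings, or one
#'   of `"block"` (each factor loads with magnitude `strength` and random
#'   signs on its own disjoint block of `floor(0.4 m / q)` genes; the
#'   remaining genes load on nothing) or `"dense"` (all loadings drawn
#'   N(0, strength^2)).
#' @param strength loading magnitude for the named schemes. Default 0.7.
#' @param psi gene-specific noise variances, recycled to length m; must be
#'   positive. Default 1.
#' @param x_effect effect of the group covariate on genes 1-min(100, m).
#'   Default 0.
#' @param seed integer seed.
#' @return An object of class `"simulated_dataset"` with elements `expr`,
#'   `primary_group`, `de_genes`, `seed`, plus the truth: `B_true` (m x q),
#'   `Z_true` (n x q) and `psi_true` (length m).
#' @examples
#' d <- simulate_factor_model(200, 50, 1, seed = 1)
#' dim(d$B_true)
#' @export
simulate_factor_model <- function(m, n, q, loading_scheme = "block",
                                  strength = 0.7, psi = 1, x_effect = 0,
                                  seed = 1) {
  if (q >= n) stop("'q' must be smaller than 'n'")
  if (q < 0) stop("'q' must be non-negative")
  if (n %% 2 != 0) stop("'n' must be even (two equal groups)")
  psi <- rep_len(psi, m)
  if (any(psi <= 0)) stop("'psi' entries must be positive")

  with_seed(seed, {
    if (is.matrix(loading_scheme)) {
      if (!all(dim(loading_scheme) == c(m, q)))
        stop("loading matrix must be m x q")
      B <- loading_scheme
    } else {
      B <- matrix(0, m, q)
      if (q > 0) {
        if (loading_scheme == "block") {
          bs <- floor(0.4 * m / q)
          if (bs < 1) stop("'m' too small for the block loading scheme")
          for (k in seq_len(q))
            B[((k - 1) * bs + 1):(k * bs), k] <-
              strength * sample(c(-1, 1), bs, replace = TRUE)
        } else if (loading_scheme == "dense") {
          B[] <- stats::rnorm(m * q, 0, strength)
        } else stop("unknown loading scheme: ", loading_scheme)
      }
    }
    Z <- matrix(stats::rnorm(n * q), n, q)
    expr <- matrix(stats::rnorm(m * n, 0, sqrt(psi)), m, n)
    if (q > 0) expr <- expr + B %*% t(Z)
    dimnames(expr) <- list(make_ids("g", m), make_ids("s", n))
    primary_group <- rep(c(0L, 1L), each = n / 2)
    names(primary_group) <- colnames(expr)
    de_genes <- seq_len(min(100L, m))
    if (x_effect != 0)
      expr[de_genes, primary_group == 1L] <-
        expr[de_genes, primary_group == 1L] + x_effect
    rownames(B) <- rownames(expr)
    if (q > 0) colnames(B) <- paste0("factor", seq_len(q))
    rownames(Z) <- colnames(expr)
    if (q > 0) colnames(Z) <- colnames(B)

    structure(
      list(expr = expr, primary_group = primary_group, de_genes = de_genes,
           B_true = B, Z_true = Z, psi_true = psi, seed = seed),
      class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated expression dataset:",
      nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  if (!is.null(x$case_id))
    cat("Illustrative case", x$case_id, "with",
        length(x$het_vars), "heterogeneity variable(s)\n")
  if (!is.null(x$B_true))
    cat("Factor-model truth with q =", ncol(x$B_true), "factor(s)\n")
  cat("Seed:", x$seed, "\n")
  invisible(x)
}
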