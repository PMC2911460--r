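#' Configure an end-to-end analysis
#'
#' Collects and validates everything [run_pipeline()] needs: either paths
#' to an expression matrix and covariate table, or the parameters of a
#' simulated illustrative case; the variable of interest; the number of
#' factors (fixed `q`) or the search bound (`q_max`, mutually exclusive
#' with `q`); the significance cutoff; optional gene features and
#' annotations; the output directory; and one global seed that governs
#' every stochastic stage.
#'
#' @param expression,covariates paths to TSV files (see
#'   [read_expression()], [read_covariates()]); omit when `simulate` is
#'   given.
#' @param variable name of the covariate of interest in the covariate
#'   table (for simulated data this is `"group"`).
#' @param simulate optional list with `case_id` and any of `m`, `n`,
#'   `de_effect`, `het_effect` to analyze a simulated case instead of
#'   files.
#' @param gene_features optional path to a gene feature TSV (first column
#'   `gene_id`).
#' @param annotation optional path to an annotation file (two-column TSV
#'   or GMT).
#' @param alpha significance cutoff in (0, 1). Default 0.05.
#' @param q,q_max exactly one of: a fixed number of factors, or the upper
#'   bound of the selection search. Default `q_max = 5`.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression = NULL, covariates = NULL,
                            variable = "group", simulate = NULL,
                            gene_features = NULL, annotation = NULL,
                            alpha = 0.05, q = NULL, q_max = NULL,
                            seed = 1, out_dir = "fadex_out") {
  if (!is.null(q) && !is.null(q_max))
    stop("give exactly one of 'q' and 'q_max'")
  if (is.null(q) && is.null(q_max)) q_max <- 5
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  if (is.null(simulate)) {
    for (p in c(expression, covariates, gene_features, annotation))
      if (!file.exists(p)) stop("file not found: ", p)
    if (is.null(expression) || is.null(covariates))
      stop("either 'simulate' or both 'expression' and 'covariates' required")
  } else {
    if (is.null(simulate$case_id))
      stop("'simulate' needs at least a 'case_id'")
  }
  structure(list(expression = expression, covariates = covariates,
                 variable = variable, simulate = simulate,
                 gene_features = gene_features, annotation = annotation,
                 alpha = alpha, q = q, q_max = q_max, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full heterogeneity-analysis workflow
#'
#' Composes the pipeline stages in order: load (or simulate) the data;
#' residualize the expressions on the variable of interest; select the
#' number of factors (unless fixed); fit the factor model by EM and apply
#' the VARIMAX rotation; produce the factor-adjusted expression data; test
#' every gene against the variable of interest on raw and adjusted data;
#' extract and compare the significant gene lists; associate the factors
#' with the remaining sample covariates (and gene features when given);
#' and run the term enrichment of the adjusted gene list (when an
#' annotation is given). All machine outputs are written under
#' `config$out_dir` as tab-separated text re-readable by the package's own
#' readers and are byte-identical across runs with the same configuration
#' and seed; progress is logged to stderr.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a result bundle: list with the selected `q`,
#'   criterion profile, `fit`, adjusted matrix, both test tables, gene
#'   lists and their overlap, association reports, and the enrichment
#'   table (or NULL).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    s <- config$simulate
    log_msg("simulating illustrative case ", s$case_id, " (seed ",
            config$seed, ")")
    d <- simulate_case(s$case_id,
                       m = s$m %||% 1000, n = s$n %||% 20,
                       de_effect = s$de_effect %||% 1,
                       het_effect = s$het_effect %||% 2,
                       seed = config$seed)
    expr <- d$expr
    covars <- data.frame(sample_id = colnames(expr),
                         group = d$primary_group,
                         lapply(d$het_vars, factor),
                         check.names = FALSE)
    config$variable <- "group"
    write_expression(expr, file.path(config$out_dir, "expression_raw.tsv"))
    write_covariates(covars, file.path(config$out_dir, "covariates.tsv"))
  } else {
    log_msg("reading expression from ", config$expression)
    expr <- read_expression(config$expression)
    covars <- read_covariates(config$covariates)
    if (!all(covars$sample_id == colnames(expr)))
      stop("sample ids of covariate table and expression matrix differ")
  }
  if (!config$variable %in% names(covars))
    stop("variable of interest '", config$variable,
         "' not found in the covariate table")
  x <- covars[[config$variable]]

  log_msg("residualizing on '", config$variable, "'")
  R <- residualize(expr, x, x_name = config$variable)

  sel <- NULL
  if (is.null(config$q)) {
    log_msg("selecting the number of factors (q_max = ", config$q_max, ")")
    sel <- select_nbfactors(R, q_max = config$q_max)
    q_use <- sel$q
    utils::write.table(
      data.frame(q = as.integer(names(sel$criterion)),
                 criterion = sel$criterion,
                 criterion_centered = sel$criterion_centered,
                 selected = as.integer(names(sel$criterion)) == sel$q),
      file.path(config$out_dir, "nbfactors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else q_use <- config$q
  log_msg("fitting the factor model with q = ", q_use)
  fit <- fit_em(R, q_use)
  if (q_use > 0) fit <- varimax_rotate(fit)
  write_factor_fit(fit, file.path(config$out_dir, "factor_fit"))

  adjusted <- factor_adjust(expr, fit)
  write_expression(adjusted,
                   file.path(config$out_dir, "expression_adjusted.tsv"))

  binary <- length(unique(x)) == 2
  run_test <- function(mat, mode) {
    if (binary) two_group_test(mat, x, mode = mode)
    else pearson_test(mat, as.numeric(x), mode = mode)
  }
  log_msg("testing genes against '", config$variable, "' (",
          if (binary) "two-group t" else "Pearson", ")")
  tt_raw <- run_test(expr, "raw")
  tt_adj <- run_test(adjusted, "adjusted")
  write_test_table(tt_raw, file.path(config$out_dir, "test_raw.tsv"))
  write_test_table(tt_adj, file.path(config$out_dir, "test_adjusted.tsv"))

  list_raw <- gene_list(tt_raw, config$alpha)
  list_adj <- gene_list(tt_adj, config$alpha)
  overlap <- if (length(list_raw)) overlap_fraction(list_raw, list_adj)
             else NA_real_
  writeLines(list_raw, file.path(config$out_dir, "genes_raw.txt"))
  writeLines(list_adj, file.path(config$out_dir, "genes_adjusted.txt"))
  log_msg(length(list_raw), " raw / ", length(list_adj),
          " adjusted significant genes; overlap ",
          if (is.na(overlap)) "undefined" else sprintf("%.1f%%", overlap))

  assoc_samples <- NULL
  ext <- setdiff(names(covars), c("sample_id", config$variable))
  if (fit$q > 0 && length(ext)) {
    assoc_samples <- factor_sample_association(
      fit, covars[, ext, drop = FALSE])
    utils::write.table(
      data.frame(factor = rownames(assoc_samples$p), assoc_samples$p,
                 check.names = FALSE),
      file.path(config$out_dir, "association_samples.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(assoc_samples$per_level))
      utils::write.table(assoc_samples$per_level,
                         file.path(config$out_dir,
                                   "association_samples_levels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  assoc_genes <- NULL
  if (fit$q > 0 && !is.null(config$gene_features)) {
    feats <- utils::read.delim(config$gene_features, check.names = FALSE)
    if (names(feats)[1] != "gene_id")
      stop("first column of the gene feature table must be 'gene_id'")
    if (!all(feats$gene_id == rownames(expr)))
      stop("gene ids of the feature table and expression matrix differ")
    assoc_genes <- factor_gene_association(
      fit, feats[, -1, drop = FALSE])
    utils::write.table(
      data.frame(factor = rownames(assoc_genes$p), assoc_genes$p,
                 check.names = FALSE),
      file.path(config$out_dir, "association_genes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enrichment <- NULL
  if (!is.null(config$annotation) && length(list_adj)) {
    log_msg("term enrichment of the adjusted gene list")
    ann <- read_annotation(config$annotation,
                           background = rownames(expr))
    enrichment <- enrich_table(list_adj, ann, alpha = config$alpha)
    utils::write.table(enrichment,
                       file.path(config$out_dir, "enrichment_adjusted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  params <- c(variable = config$variable, alpha = config$alpha,
              q = q_use, q_fixed = !is.null(config$q),
              q_max = config$q_max %||% NA, seed = config$seed,
              m = nrow(expr), n = ncol(expr),
              simulated_case = config$simulate$case_id %||% NA)
  writeLines(paste0(names(params), ": ", unlist(params)),
             file.path(config$out_dir, "run_info.txt"))
  log_msg("done; outputs in ", config$out_dir)

  invisible(list(q = q_use, selection = sel, fit = fit,
                 adjusted = adjusted, test_raw = tt_raw,
                 test_adjusted = tt_adj, genes_raw = list_raw,
                 genes_adjusted = list_adj, overlap = overlap,
                 association_samples = assoc_samples,
                 association_genes = assoc_genes,
                 enrichment = enrichment, config = config))
}
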