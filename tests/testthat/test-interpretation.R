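# a fixed fit shared by several interpretation tests
case1_fit <- local({
  d <- simulate_case(1, seed = 3)
  list(d = d,
       fit = varimax_rotate(fit_em(residualize(d$expr, d$primary_group), 1)))
})

test_that("categorical association reduces to one-way ANOVA sums of squares", {
  f <- case1_fit$fit
  set.seed(5)
  g <- factor(sample(letters[1:3], 20, replace = TRUE))
  rep <- factor_sample_association(f, data.frame(g = g), adjust_for = NULL,
                                   per_level = FALSE)
  oracle <- anova_by_sums(f$Z[, 1], g)
  expect_equal(unname(rep$p[1, "g"]), oracle$p, tolerance = 1e-12)
})

test_that("continuous associations equal the Pearson correlation test", {
  f <- case1_fit$fit
  set.seed(6)
  v <- rnorm(20)
  rep <- factor_sample_association(f, data.frame(v = v), adjust_for = NULL)
  expect_equal(unname(rep$p[1, "v"]),
               cor.test(f$Z[, 1], v)$p.value, tolerance = 1e-12)
  # gene side: continuous feature against the loadings
  feat <- rnorm(1000)
  repg <- factor_gene_association(f, data.frame(size = feat))
  expect_equal(unname(repg$p[1, "size"]),
               cor.test(f$B[, 1], feat)$p.value, tolerance = 1e-12)
})

test_that("sample-side and gene-side engines are the same test", {
  f <- case1_fit$fit
  set.seed(8)
  M <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  vars <- data.frame(a = factor(rep(1:4, 5)), b = rnorm(20))
  fake_s <- structure(list(Z = M, B = M, psi = rep(1, 20), q = 2L,
                           x = NULL, x_name = NULL),
                      class = "factor_fit")
  s_side <- factor_sample_association(fake_s, vars, adjust_for = NULL)
  g_side <- factor_gene_association(fake_s, vars)
  expect_identical(s_side$p, g_side$p)
  expect_identical(s_side$per_level[, -1], g_side$per_level[, -1])
})

test_that("associations with pure noise covariates are calibrated", {
  f <- case1_fit$fit
  set.seed(17)
  ps <- vapply(1:200, function(i) {
    v <- rnorm(20)
    unname(factor_sample_association(f, data.frame(v = v),
                                     per_level = FALSE)$p[1, "v"])
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("per-level Student tests match t.test and skip tiny levels", {
  f <- case1_fit$fit
  g <- factor(c(rep("a", 9), rep("b", 10), "c"))  # level c has 1 sample
  rep <- factor_sample_association(f, data.frame(g = g), adjust_for = NULL)
  expect_true("g:c" %in% rep$omitted_levels)
  row_a <- rep$per_level[rep$per_level$level == "a", ]
  ref <- t.test(f$Z[g == "a", 1], f$Z[g != "a", 1], var.equal = TRUE)
  expect_equal(row_a$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(row_a$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("association reports are invariant to relabeling and affine maps", {
  f <- case1_fit$fit
  set.seed(23)
  g <- factor(sample(c("x", "y", "z"), 20, replace = TRUE))
  v <- rnorm(20)
  a <- factor_sample_association(f, data.frame(g = g, v = v),
                                 adjust_for = NULL, per_level = FALSE)
  g2 <- factor(g, levels = c("z", "x", "y"), labels = c("L3", "L1", "L2"))
  b <- factor_sample_association(f, data.frame(g = g2, v = -2 * v + 7),
                                 adjust_for = NULL, per_level = FALSE)
  expect_equal(unname(a$p), unname(b$p), tolerance = 1e-10)
})

test_that("top_genes applies the correlation-scale cutoff", {
  f <- case1_fit$fit
  expect_length(top_genes(f, 1, threshold = 1.01), 0)
  lambda <- f$B[, 1] / sqrt(rowSums(f$B^2) + f$psi)
  expect_setequal(top_genes(f, 1, 0.5),
                  rownames(f$B)[abs(lambda) > 0.5])
  expect_error(top_genes(f, 3), "index")
})

test_that("top_genes recovers a planted high-correlation block", {
  ok <- vapply(1:5, function(s) {
    B <- matrix(0, 100, 1)
    B[1:50, 1] <- 0.95
    psi <- c(rep(0.0975, 50), rep(1, 50))  # corr scale 0.95 for loaded genes
    d <- simulate_factor_model(100, 200, 1, loading_scheme = B, psi = psi,
                               seed = s)
    f <- fit_em(residualize(d$expr, d$primary_group), 1)
    got <- match(top_genes(f, 1, 0.8), rownames(d$expr))
    length(intersect(got, 1:50)) >= 45 && all(got <= 60)
  }, logical(1))
  expect_gte(sum(ok), 3)
})

test_that("pca_project matches an eigen-decomposition oracle", {
  set.seed(11)
  Y <- matrix(rnorm(40 * 15), 40, 15)
  p <- pca_project(Y, n_components = 3)
  Xc <- Y - rowMeans(Y)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)  # n x n covariance kernel
  for (j in 1:3) {
    sc <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_equal(abs(unname(p$scores[, j])), abs(sc), tolerance = 1e-8)
  }
  expect_equal(sum(p$var_explained), sum(ev$values[1:3]) / sum(ev$values),
               tolerance = 1e-8)

  # rank-1 input: one component explains everything
  Y1 <- outer(rnorm(30), rnorm(12))
  p1 <- pca_project(Y1, n_components = 2)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)

  expect_error(pca_project(Y, gene_subset = 1, n_components = 2),
               "at least")
})

test_that("factor adjustment sharpens the PCA group contrast", {
  better <- vapply(1:20, function(s) {
    d <- simulate_case(1, seed = s)
    fit <- varimax_rotate(fit_em(residualize(d$expr, d$primary_group), 1))
    adj <- factor_adjust(d$expr, fit)
    sig <- gene_list(two_group_test(adj, d$primary_group))
    if (length(sig) < 2) return(NA)
    fratio <- function(M) {
      pc1 <- pca_project(M, gene_subset = sig)$scores[, 1]
      anova_by_sums(pc1, d$primary_group)$f
    }
    fratio(adj) > fratio(d$expr)
  }, logical(1))
  expect_gte(mean(better, na.rm = TRUE), 0.8)
})
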