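test_that("residualize matches gene-by-gene least squares", {
  d <- simulate_case(2, m = 300, seed = 4)
  x <- rnorm(20)
  R <- residualize(d$expr, x)
  for (g in sample(300, 15)) {
    fit <- lm(d$expr[g, ] ~ x)
    expect_equal(unname(R[g, ]), unname(resid(fit)), tolerance = 1e-10)
  }
  # residuals orthogonal to the design
  design <- cbind(1, x)
  expect_lt(max(abs(R %*% design)) /
              (max(abs(R)) * max(abs(design)) * 20), 1e-8)
  expect_equal(attr(R, "df_residual"), 18)
})

test_that("degenerate designs fall back to centering", {
  d <- simulate_case(1, m = 300, seed = 1)
  expect_warning(R <- residualize(d$expr, rep(1, 20)), "constant")
  expect_equal(as_plain <- matrix(R, 300, 20), d$expr - rowMeans(d$expr),
               ignore_attr = TRUE)
  # rows already orthogonal to a centered covariate: residualizing = centering
  x <- rep(c(-1, 1), 10)
  Y <- matrix(rnorm(50 * 20), 50, 20)
  Y <- Y - (Y %*% x) %*% t(x) / sum(x^2)  # strip the x-component
  R2 <- residualize(Y, x)
  expect_equal(matrix(R2, 50, 20), Y - rowMeans(Y), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("EM log-likelihood is monotone over many random datasets", {
  worst <- Inf
  for (s in 1:50) {
    d <- simulate_factor_model(60, 16, sample(0:2, 1), strength = 0.5,
                               seed = s)
    f <- fit_em(d$expr - rowMeans(d$expr), 2, tol = 1e-8)
    if (length(f$loglik_trace) > 1) {
      rel <- diff(f$loglik_trace) / abs(f$loglik_trace[-1])
      worst <- min(worst, min(rel))
    }
  }
  expect_gte(worst, -1e-8)
})

test_that("EM recovers known factor scores and loadings", {
  d <- simulate_factor_model(500, 80, 1, loading_scheme = "dense",
                             strength = 0.8, seed = 2)
  f <- fit_em(residualize(d$expr, d$primary_group), 1)
  expect_true(f$converged)
  expect_gte(abs(cor(f$Z[, 1], d$Z_true[, 1])), 0.95)
  expect_gte(abs(cor(f$B[, 1], d$B_true[, 1])), 0.95)
})

test_that("fitted models satisfy the structural invariants", {
  d <- simulate_factor_model(80, 30, 2, seed = 9)
  R <- residualize(d$expr, d$primary_group)
  f <- fit_em(R, 2)
  expect_true(all(f$psi > 0))
  expect_lt(max(abs(colMeans(f$Z))), 1e-8)
  Sigma <- tcrossprod(f$B) + diag(f$psi)
  expect_true(all(eigen(Sigma, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # communalities bounded by the gene residual variances
  Sd <- rowSums((R - rowMeans(R))^2) / ncol(R)
  expect_true(all(rowSums(f$B^2) <= Sd + 1e-8))
})

test_that("the null model behaves as the identity", {
  d <- simulate_case(1, m = 300, seed = 5)
  R <- residualize(d$expr, d$primary_group)
  f0 <- fit_em(R, 0)
  expect_equal(ncol(f0$B), 0L)
  expect_equal(unname(f0$psi),
               unname(rowSums((R - rowMeans(R))^2) / ncol(R)))
  expect_identical(factor_adjust(d$expr, f0), d$expr)
})

test_that("invalid fits are rejected and degenerate genes pass through", {
  d <- simulate_case(1, m = 300, seed = 1)
  R <- residualize(d$expr, d$primary_group)
  expect_error(fit_em(R, 19), "at most")
  Rb <- R; Rb[1, 1] <- NA
  expect_error(fit_em(Rb, 1), "non-finite")

  Y <- d$expr
  Y[5, ] <- 3.14  # constant gene: zero residual variance
  Rc <- suppressWarnings(residualize(Y, d$primary_group))
  f <- fit_em(Rc, 1)
  expect_equal(f$excluded, 5L)
  expect_true(all(f$B[5, ] == 0))
  expect_true(is.na(f$psi[5]))
  adj <- factor_adjust(Y, f)
  expect_equal(unname(adj[5, ]), rep(3.14, 20))
})

test_that("varimax rotation preserves the common part and sharpens loadings", {
  d <- simulate_factor_model(120, 40, 3, strength = 0.8, seed = 6)
  f <- fit_em(residualize(d$expr, d$primary_group), 3)
  fr <- varimax_rotate(f)
  expect_true(fr$rotated)
  # BB' and communalities invariant
  expect_lt(max(abs(tcrossprod(fr$B) - tcrossprod(f$B))),
            1e-10 * max(abs(tcrossprod(f$B))))
  # common component of the data unchanged
  expect_lt(max(abs(fr$B %*% t(fr$Z) - f$B %*% t(f$Z))), 1e-8)
  # beats 1000 random orthogonal rotations
  set.seed(42)
  crit_rand <- vapply(1:1000, function(i)
    vmax_crit(f$B %*% random_rotation(3)), numeric(1))
  expect_gte(vmax_crit(fr$B), max(crit_rand) - 1e-12)
  # ordering and sign conventions
  ss <- colSums(fr$B^2)
  expect_true(all(diff(ss) <= 1e-12))
  for (k in 1:3) expect_gt(fr$B[which.max(abs(fr$B[, k])), k], 0)
})

test_that("one-factor rotation is a sign convention; q = 0 is a no-op", {
  d <- simulate_case(1, m = 300, seed = 2)
  f <- fit_em(residualize(d$expr, d$primary_group), 1)
  fr <- varimax_rotate(f)
  expect_true(max(abs(fr$B - f$B)) < 1e-12 || max(abs(fr$B + f$B)) < 1e-12)
  f0 <- fit_em(residualize(d$expr, d$primary_group), 0)
  expect_warning(fr0 <- varimax_rotate(f0), "q = 0")
  expect_equal(fr0$B, f0$B)
})

test_that("factor adjustment removes the heterogeneity it models", {
  d <- simulate_case(1, seed = 3)
  R <- residualize(d$expr, d$primary_group)
  f <- varimax_rotate(fit_em(R, 1))
  adj <- factor_adjust(d$expr, f)

  # deterministic given the fit
  expect_identical(adj, factor_adjust(d$expr, f))

  # adjusted data decorrelated from the scores
  Radj <- residualize(adj, d$primary_group)
  cors <- cor(t(matrix(Radj, nrow(Radj), ncol(Radj))), f$Z)
  expect_lte(max(abs(cors)), 0.05)

  # the het-group mean gap on affected genes shrinks by >= 50%
  h <- d$het_vars[[1]]
  gap <- function(M) mean(abs(rowMeans(M[, h == 1, drop = FALSE]) -
                              rowMeans(M[, h == 0, drop = FALSE])))
  expect_lte(gap(adj), 0.5 * gap(d$expr))

  expect_error(factor_adjust(d$expr[1:10, ], f), "do not match")
})

test_that("the criterion profile identifies the planted number of factors", {
  # exact criterion equals the naive O(m^2) computation
  d <- simulate_case(1, m = 300, seed = 8)
  R <- residualize(d$expr, d$primary_group)
  sel <- select_nbfactors(R, q_max = 2)
  E <- matrix(R, 300, 20)
  expect_equal(unname(sel$criterion["0"]),
               naive_mean_sq_cor(E - rowMeans(E)), tolerance = 1e-10)

  qs <- vapply(1:5, function(s) {
    d <- simulate_case(1, seed = s)
    select_nbfactors(residualize(d$expr, d$primary_group), q_max = 4)$q
  }, integer(1))
  expect_gte(sum(qs == 1L), 3)

  q0 <- vapply(1:5, function(s) {
    d <- simulate_case(1, de_effect = 0, het_effect = 0, seed = s)
    select_nbfactors(residualize(d$expr, d$primary_group), q_max = 4)$q
  }, integer(1))
  expect_gte(sum(q0 == 0L), 3)

  expect_error(select_nbfactors(R, q_max = 17), "q_max")
})
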