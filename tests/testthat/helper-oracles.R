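# Independent oracles used by several test files. These deliberately avoid
# the code paths they check.

# One-way ANOVA F statistic and p-value from explicit between/within sums
# of squares.
anova_by_sums <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_within <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Upper-tail hypergeometric probability by direct summation of the pmf
# over the tail only: the starting mass from binomial coefficients, then a
# multiplicative recurrence on integer ratios (no distribution functions).
hyper_upper_sum <- function(k, K, n, N) {
  j0 <- max(0, n + K - N, k)
  j_max <- min(K, n)
  if (j0 > j_max) return(0)
  pmf <- exp(lchoose(K, j0) + lchoose(N - K, n - j0) - lchoose(N, n))
  total <- pmf
  if (j0 < j_max) for (j in j0:(j_max - 1)) {
    pmf <- pmf * (K - j) * (n - j) / ((j + 1) * (N - K - n + j + 1))
    total <- total + pmf
  }
  total
}

# Exact rational-arithmetic evaluation through the system python's
# fractions module; returns the probability as a double converted from the
# exact fraction.
hyper_upper_bigint <- function(k, K, n, N) {
  code <- sprintf(paste0(
    "from fractions import Fraction\n",
    "from math import comb\n",
    "k,K,n,N=%d,%d,%d,%d\n",
    "p=sum(Fraction(comb(K,j)*comb(N-K,n-j),comb(N,n))",
    " for j in range(k,min(K,n)+1))\n",
    "print(repr(float(p)))"), k, K, n, N)
  out <- system2("python", "-", stdout = TRUE, input = code)
  as.numeric(out[length(out)])
}

# random orthogonal matrix (Haar via QR with sign fix)
random_rotation <- function(q) {
  qr_d <- qr(matrix(stats::rnorm(q * q), q, q))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), q)
}

# fadex-internal varimax criterion, re-derived here for rotation tests
vmax_crit <- function(B) {
  sc <- sqrt(rowSums(B^2)); sc[sc == 0] <- 1
  L2 <- (B / sc)^2
  sum(apply(L2, 2, stats::var))
}

# mean squared off-diagonal correlation by the naive route (small m only)
naive_mean_sq_cor <- function(E) {
  C <- stats::cor(t(E))
  m <- nrow(C)
  (sum(C^2) - m) / (m * (m - 1))
}
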