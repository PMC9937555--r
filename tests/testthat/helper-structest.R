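# Shared fixture builders. Everything is generated in code at test time.

# Shift columns within Z-levels so the sample group means equal `target`
# (p x d) exactly.
set_group_means <- function(values, zcodes, target) {
  for (z in seq_len(nrow(target))) {
    idx <- zcodes == z
    cur <- colMeans(values[idx, , drop = FALSE])
    values[idx, ] <- sweep(values[idx, , drop = FALSE], 2L,
                           target[z, ] - cur, "+")
  }
  values
}

# N x d matrix whose sample covariance (divisor N) equals Sigma exactly and
# whose columns have mean 0: draw, center, whiten, recolor.
matrix_with_cov <- function(Sigma, N, seed = 1) {
  set.seed(seed)
  d <- ncol(Sigma)
  Y <- matrix(stats::rnorm(N * d), N, d)
  Y <- sweep(Y, 2L, colMeans(Y), "-")
  Y <- Y %*% solve(chol(crossprod(Y) / N))
  Y %*% chol(Sigma)
}

# Dataset whose group-mean contrasts are exactly proportional to the
# reliabilities estimated from the dataset itself: iterate
# (estimate lambda) -> (set contrasts to b * lambda) to a fixed point.
make_proportional_t0_dataset <- function(seed = 21, N = 800, b = 0.5,
                                         max_iter = 50L) {
  ds <- generate_null_dataset(generator_config(N = N, seed = seed))
  v <- ds$X$values; z <- ds$Z$codes
  p <- ds$Z$p
  for (it in seq_len(max_iter)) {
    lam <- estimate_reliabilities(indicator_matrix(v))$lambda
    m1 <- colMeans(v[z == 1, , drop = FALSE])
    target <- rbind(m1, sweep(outer(b * seq_len(p - 1L), lam), 2L, m1, "+"))
    v <- set_group_means(v, z, target)
    lam2 <- estimate_reliabilities(indicator_matrix(v))$lambda
    D <- sweep(rowsum(v, z)[-1L, , drop = FALSE] /
                 tabulate(z, p)[-1L], 2L,
               colMeans(v[z == 1, , drop = FALSE]), "-")
    if (max(abs(D - outer(b * seq_len(p - 1L), lam2))) < 1e-13) break
  }
  list(X = indicator_matrix(v), Z = grouping_variable(z))
}

# Dataset whose group-mean contrast matrix is exactly rank 1.
make_rank1_t1_dataset <- function(seed = 22, N = 2000, p = 4,
                                  alpha = c(1, 0.8, 0.9, 0.7, 0.6),
                                  beta = c(0.3, 0.5, 0.8)) {
  ds <- generate_null_dataset(generator_config(N = N, p = p, seed = seed))
  v <- ds$X$values; z <- ds$Z$codes
  m1 <- colMeans(v[z == 1, , drop = FALSE])
  target <- rbind(m1, sweep(outer(beta, alpha), 2L, m1, "+"))
  v <- set_group_means(v, z, target)
  list(X = indicator_matrix(v), Z = grouping_variable(z))
}

# Central finite-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}
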