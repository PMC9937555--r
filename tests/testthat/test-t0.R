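test_that("T0 moment vector matches hand arithmetic", {
  # d = 2, p = 2, lambda = (0.8, 0.4), gamma = 0, beta2 = 0.6
  u <- u_vector_t0(c(0.5, 0.4), z = 2L, gamma = c(0, 0), beta = 0.6,
                   lambda = c(0.8, 0.4), ref = 1L)
  expect_equal(u, c(0, 0, -0.1, 0.1), tolerance = 1e-12)
  # reference-level subject with x = gamma gives the zero vector
  u0 <- u_vector_t0(c(0.3, -0.2), z = 1L, gamma = c(0.3, -0.2), beta = 0.6,
                    lambda = c(0.8, 0.4))
  expect_equal(u0, rep(0, 4))
})

test_that("analytic dU/dlambda matches central finite differences", {
  set.seed(61)
  for (rep in 1:5) {
    d <- 4; p <- 3
    x <- rnorm(d); gam <- rnorm(d); bet <- rnorm(p - 1)
    lam <- runif(d, 0.3, 0.9)
    ref <- sample.int(d, 1)
    z <- sample.int(p, 1)
    A <- du_dlambda_t0(x, z, bet, lam, ref)
    Anum <- num_jacobian(function(l) u_vector_t0(x, z, gam, bet, l, ref), lam)
    expect_equal(A, Anum, tolerance = 1e-5)
    # reference indicator rows vanish (the ratio is identically 1)
    expect_equal(A[(z - 1) * d + ref, ], rep(0, d))
  }
  # beta = 0: lambda enters only multiplied by beta
  expect_equal(du_dlambda_t0(rnorm(3), 2L, c(0, 0), c(.8, .7, .6), 1L),
               matrix(0, 9, 3))
})

test_that("vanishing adjustment leaves the corrected weight equal to the uncorrected one", {
  set.seed(62)
  U <- matrix(rnorm(500), 100, 5)
  V <- matrix(rnorm(300), 100, 3)
  B <- diag(3) + matrix(rnorm(9, sd = .1), 3, 3)
  w_corr <- corrected_weight_t0(U, V, matrix(0, 5, 3), B)
  w_unc <- empirical_weight(U)
  expect_equal(w_corr$sigma, w_unc$sigma, tolerance = 1e-12)
  # singular B is refused with advice
  expect_error(corrected_weight_t0(U, V, matrix(1, 5, 3), matrix(1, 3, 3)),
               "singular")
})

test_that("corrected weight reproduces the Monte-Carlo covariance of the averaged moments", {
  lam <- c(0.8, 0.7, 0.75, 0.65, 0.6)
  # true parameters under the default design: Z = I(eta > 0),
  # E(eta | eta < 0) = -sqrt(2/pi)
  g0 <- -sqrt(2 / pi) * lam
  b0 <- lam[1] * 2 * sqrt(2 / pi)
  reps <- 1500; n <- 2000
  Us <- matrix(NA_real_, reps, 10)
  for (r in seq_len(reps)) {
    ds <- generate_null_dataset(generator_config(N = n, seed = 100000 + r))
    lh <- estimate_reliabilities(ds$X)$lambda
    U <- structest:::u_rows_t0(ds$X$values, ds$Z$codes, g0, b0, lh, 1L)
    Us[r, ] <- sqrt(n) * colMeans(U)
  }
  Smc <- stats::cov(Us)
  ds <- generate_null_dataset(generator_config(N = 20000, seed = 7))
  X <- ds$X; Z <- ds$Z
  lamh <- estimate_reliabilities(X)$lambda
  gm <- group_means(X, Z)
  piz <- gm$counts / 20000
  D <- sweep(gm$means[-1, , drop = FALSE], 2, gm$means[1, ], "-")
  bp <- as.vector(D %*% lamh) / sum(lamh^2)
  U0 <- structest:::u_rows_saturated(X$values, Z$codes, gm$means)
  V <- structest:::reliability_moment_rows(X$values, lamh)
  A <- structest:::mean_du_dlambda_t0(piz, lamh[1] * bp, lamh, 1L)
  B <- reliability_jacobian(X, lamh)
  S_corr <- corrected_weight_t0(U0, V, A, B)$sigma
  S_unc <- empirical_weight(U0)$sigma
  expect_lt(norm(Smc - S_corr, "F") / norm(S_corr, "F"), 0.10)
  # and the correction matters: the uncorrected covariance is far off
  expect_gt(norm(Smc - S_unc, "F") / norm(S_unc, "F"), 0.5)
})

test_that("correcting for estimated reliabilities moves the null rejection rate toward its nominal level", {
  mc <- monte_carlo_statistics(generator_config(N = 1000), "t0", reps = 600,
                               seed = 63, uncorrected_t0 = TRUE)
  rate_corr <- mean(mc$p_values < 0.05)
  rate_unc <- mean(mc$p_values_uncorrected < 0.05)
  expect_lt(abs(rate_corr - 0.05), abs(rate_unc - 0.05))
})

test_that("T0 has (d-1)(p-1) degrees of freedom and fits exact proportional contrasts perfectly", {
  fix <- make_proportional_t0_dataset(seed = 21, N = 800)
  res <- run_test_t0(fix$X, fix$Z)
  expect_equal(res$df, 4L)                  # d = 5, p = 2
  expect_lt(res$statistic, 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
  # equal group means are trivially proportional: statistic ~ 0 too
  ds <- generate_null_dataset(generator_config(N = 600, seed = 64))
  v <- ds$X$values
  m <- colMeans(v)
  v <- set_group_means(v, ds$Z$codes, rbind(m, m))
  res2 <- run_test_t0(indicator_matrix(v), ds$Z)
  expect_lt(res2$statistic, 1e-8)
})

test_that("supplied reliabilities are treated as known: no correction, works at d = 2", {
  ds <- generate_null_dataset(generator_config(d = 2, lambda = c(0.8, 0.6),
                                               N = 800, seed = 65))
  res <- run_test_t0(ds$X, ds$Z, lambda = c(0.8, 0.6))
  expect_false(res$corrected)
  expect_equal(res$df, 1L)                  # (2-1)(2-1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # estimating reliabilities at d = 2 is impossible
  expect_error(run_test_t0(ds$X, ds$Z), "d >= 3")
})

test_that("T0 statistic is invariant to the reference indicator and to subject order", {
  ds <- generate_null_dataset(generator_config(seed = 66))
  Xs <- standardize(ds$X)
  base <- run_test_t0(Xs, ds$Z)
  for (r in c(1L, 3L, 5L)) {
    alt <- run_test_t0(Xs, ds$Z, ref = r)
    expect_equal(alt$statistic, base$statistic, tolerance = 1e-4)
  }
  set.seed(67)
  perm <- sample.int(nrow(Xs$values))
  permuted <- run_test_t0(indicator_matrix(Xs$values[perm, ]),
                          grouping_variable(ds$Z$codes[perm]))
  expect_equal(permuted$statistic, base$statistic, tolerance = 1e-6)
})

test_that("T0 refuses a single-level grouping variable", {
  X <- indicator_matrix(matrix(rnorm(60), 20, 3))
  expect_error(run_test_t0(X, grouping_variable(rep(1, 20))), "p >= 2")
})
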