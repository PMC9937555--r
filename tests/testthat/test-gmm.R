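test_that("empirical weight matrix matches the direct covariance formula", {
  U <- rbind(c(1, 0), c(0, 2), c(-1, 1), c(0, -3))
  w <- empirical_weight(U)
  Uc <- sweep(U, 2, colMeans(U))
  expect_equal(w$sigma, crossprod(Uc) / 4, tolerance = 1e-12)
  expect_equal(w$rank, 2L)
  expect_false(w$ridge_used)
})

test_that("rank deficiency is detected and the pseudo-inverse acts on the row space", {
  set.seed(51)
  base <- matrix(rnorm(300), 100, 3)
  U <- cbind(base, base[, 3])               # duplicated coordinate
  w <- empirical_weight(U, expected_deficiency = 1L)
  expect_equal(w$rank, 3L)
  expect_false(w$ridge_used)
  # inverse * sigma idempotent on the row space
  P <- w$inverse %*% w$sigma
  expect_equal(P %*% P, P, tolerance = 1e-6)
  expect_equal(w$sigma %*% w$inverse %*% w$sigma, w$sigma, tolerance = 1e-8)
  # without the expected deficiency the ridge path engages
  w2 <- empirical_weight(U)
  expect_true(w2$ridge_used)
})

test_that("all-zero moments are rejected", {
  expect_error(empirical_weight(matrix(0, 10, 2)), "degenerate")
})

test_that("chi-square p-values cover the boundary, quantile and extreme cases", {
  expect_equal(chi_square_pvalue(0, 4), 1)
  expect_equal(chi_square_pvalue(qchisq(0.95, 4), 4), 0.05, tolerance = 1e-4)
  expect_equal(chi_square_pvalue(9.4877, 4), 0.05, tolerance = 1e-4)
  expect_lt(chi_square_pvalue(141.73, 8), 1e-10)
  expect_error(chi_square_pvalue(-1, 4), "nonnegative")
})

test_that("exactly identified systems reach a zero minimum", {
  b <- c(0.3, -0.2)
  spec <- moment_spec(2, 2, 100,
                      mean_fn = function(th) b - th,
                      jac_fn = function(th) -diag(2))
  w <- empirical_weight(matrix(rnorm(200), 100, 2))
  fit <- minimize_distance_metric(spec, w, c(0, 0))
  expect_lt(fit$statistic, 1e-10)
  expect_equal(fit$params, b, tolerance = 1e-6)
})

test_that("optimizer minimum matches a two-stage grid-search oracle", {
  set.seed(52)
  G <- matrix(rnorm(6), 3, 2)
  b <- c(1.2, -0.4, 0.7)
  n <- 200
  w <- empirical_weight(matrix(rnorm(3 * n), n, 3))
  spec <- moment_spec(3, 2, n,
                      mean_fn = function(th) b - as.vector(G %*% th),
                      jac_fn = function(th) -G)
  fit <- minimize_distance_metric(spec, w, c(0, 0))
  obj <- function(t1, t2) {
    u <- b - as.vector(G %*% c(t1, t2))
    n * sum(u * (w$inverse %*% u))
  }
  # coarse lattice, then refined lattice around the coarse argmin
  g1 <- seq(-3, 3, by = 0.05)
  vals <- outer(g1, g1, Vectorize(obj))
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  g2a <- seq(g1[idx[1]] - 0.06, g1[idx[1]] + 0.06, by = 5e-4)
  g2b <- seq(g1[idx[2]] - 0.06, g1[idx[2]] + 0.06, by = 5e-4)
  vals2 <- outer(g2a, g2b, Vectorize(obj))
  expect_equal(fit$statistic, min(vals2), tolerance = 1e-4)
})

test_that("minimized statistic is invariant to invertible linear reparameterization", {
  set.seed(53)
  for (rep in 1:5) {
    q <- 3; m <- 6; n <- 500
    G <- matrix(rnorm(m * q), m, q)
    b <- rnorm(m)
    w <- empirical_weight(matrix(rnorm(m * n), n, m))
    spec1 <- moment_spec(m, q, n,
                         mean_fn = function(th) b - as.vector(G %*% th),
                         jac_fn = function(th) -G)
    M <- matrix(rnorm(q * q), q, q) + diag(q)  # generically invertible
    GM <- G %*% M
    spec2 <- moment_spec(m, q, n,
                         mean_fn = function(ph) b - as.vector(GM %*% ph),
                         jac_fn = function(ph) -GM)
    f1 <- minimize_distance_metric(spec1, w, rnorm(q))
    f2 <- minimize_distance_metric(spec2, w, rnorm(q))
    expect_equal(f1$statistic, f2$statistic, tolerance = 1e-5)
  }
})

test_that("one-step GMM statistic follows its chi-square limit on a toy moment model", {
  # x ~ N(theta, 1); moments (x - theta, x^2 - theta^2 - 1, x^3 - theta^3 - 3*theta)
  # m = 3, q = 1 => chi-square(2)
  theta0 <- 0.5
  reps <- 2000; n <- 2000
  stats_vec <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(60000 + r)
    x <- rnorm(n, theta0)
    mhat <- mean(x)
    U <- cbind(x - mhat, x^2 - mhat^2 - 1, x^3 - mhat^3 - 3 * mhat)
    w <- empirical_weight(U)
    m1 <- mean(x); m2 <- mean(x^2); m3 <- mean(x^3)
    spec <- moment_spec(3, 1, n,
      mean_fn = function(th) c(m1 - th, m2 - th^2 - 1, m3 - th^3 - 3 * th),
      jac_fn = function(th) matrix(c(-1, -2 * th, -3 * th^2 - 3), 3, 1))
    stats_vec[r] <- minimize_distance_metric(spec, w, mhat)$statistic
  }
  ks <- suppressWarnings(stats::ks.test(stats_vec, stats::pchisq, df = 2))
  expect_lt(unname(ks$statistic), 0.05)
})
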