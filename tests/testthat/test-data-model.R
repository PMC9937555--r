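test_that("load_dataset removes incomplete rows, codes Z levels in sorted order", {
  tab <- data.frame(
    a = c(1, 2, NA, 4, 5, 6),
    b = c(2, 1, 3, 2, 4, 1),
    c = c(0.5, 1, 2, 0.1, 3, 2),
    status = c("dead", "alive", "alive", "dead", "alive", "alive"),
    stringsAsFactors = FALSE)
  expect_message(
    ld <- load_dataset(tab, c("a", "b", "c"), "status"),
    "kept 5 \\(1 removed")
  expect_equal(nrow(ld$X$values), 5L)
  expect_equal(ld$n_removed, 1L)
  # alphabetical coding: alive -> 1, dead -> 2
  expect_equal(unname(ld$Z$level_map), c(1L, 2L))
  expect_equal(names(ld$Z$level_map), c("alive", "dead"))
  expect_equal(ld$Z$codes, c(2L, 1L, 2L, 1L, 1L))
})

test_that("load_dataset rejects bad configurations and emptied levels", {
  tab <- data.frame(a = 1:6, b = c(2, 1, NA, 2, 4, 1), c = rnorm(6),
                    z = c("x", "x", "y", "x", "x", "x"))
  expect_error(load_dataset(tab, "a", "z"), "at least 2 indicator")
  expect_error(load_dataset(tab, c("a", "nope"), "z"), "not found")
  # level "y" only occurs on the incomplete row
  expect_error(load_dataset(tab, c("a", "b", "c"), "z"), "0 subjects")
})

test_that("standardize centers and scales with divisor N and is idempotent", {
  X <- indicator_matrix(cbind(x1 = c(1, 2, 3), x2 = c(5, 1, 0)))
  Xs <- standardize(X)
  expect_true(Xs$standardized)
  expect_equal(colMeans(Xs$values), c(x1 = 0, x2 = 0), tolerance = 1e-12)
  expect_equal(unname(colMeans(Xs$values^2)), c(1, 1), tolerance = 1e-12)
  # divisor N, not N-1: column (1,2,3) maps to (-1,0,1)/sqrt(2/3)
  expect_equal(unname(Xs$values[, 1]), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  Xss <- standardize(Xs)
  expect_equal(Xss$values, Xs$values, tolerance = 1e-12)
})

test_that("standardize names the degenerate column in its error", {
  X <- indicator_matrix(cbind(ok = rnorm(10), flat = rep(5, 10)))
  expect_error(standardize(X), "flat")
})

test_that("auto_reverse_code flips a negated indicator and restores positive covariances", {
  ds <- generate_null_dataset(generator_config(d = 3, lambda = c(0.8, 0.7, 0.6),
                                               N = 500, seed = 31))
  v <- ds$X$values
  v[, 3] <- -v[, 3]
  Xs <- standardize(indicator_matrix(v))
  C_before <- crossprod(Xs$values) / nrow(v)
  Xr <- auto_reverse_code(Xs)
  expect_equal(Xr$flipped, 3L)
  C_after <- crossprod(Xr$values) / nrow(v)
  expect_true(all(C_after[upper.tri(C_after)] > 0))
  # flips change only signs, never magnitudes
  expect_equal(abs(C_after), abs(C_before), tolerance = 1e-12)
})

test_that("auto_reverse_code is a no-op when covariances are already positive", {
  ds <- generate_null_dataset(generator_config(N = 400, seed = 32))
  Xr <- auto_reverse_code(standardize(ds$X))
  expect_length(Xr$flipped, 0L)
  expect_equal(Xr$values, standardize(ds$X)$values)
})

test_that("auto_reverse_code warns when positivity is unattainable", {
  # frustrated sign pattern: sign(C12) * sign(C13) * sign(C23) = -1
  Sigma <- matrix(c(1, .45, .45,
                    .45, 1, -.45,
                    .45, -.45, 1), 3, 3)
  v <- matrix_with_cov(Sigma, 300, seed = 33)
  Xs <- standardize(indicator_matrix(v))
  expect_warning(auto_reverse_code(Xs), "unattainable")
})

test_that("group_means computes within-level means and counts", {
  X <- indicator_matrix(cbind(a = c(1, 3, 5, 7), b = c(0, 2, 2, 8)))
  Z <- grouping_variable(c(1, 1, 2, 2))
  gm <- group_means(X, Z)
  expect_equal(unname(gm$means[, "a"]), c(2, 6))
  expect_equal(gm$counts, c(2L, 2L))
  expect_equal(sum(gm$counts), 4L)
  # weighted average of level means recovers the overall mean
  expect_equal(colSums(gm$means * gm$counts) / 4, colMeans(X$values),
               tolerance = 1e-12)
  # invariant to row permutation
  perm <- c(3, 1, 4, 2)
  gm2 <- group_means(indicator_matrix(X$values[perm, ]),
                     grouping_variable(c(1, 1, 2, 2)[perm]))
  expect_equal(gm2$means, gm$means, tolerance = 1e-12)
})

test_that("group_means handles a single degenerate level", {
  X <- indicator_matrix(cbind(rnorm(10), rnorm(10)))
  gm <- group_means(X, grouping_variable(rep("only", 10)))
  expect_equal(unname(gm$means[1, ]), unname(colMeans(X$values)),
               tolerance = 1e-12)
})

test_that("under the null, group-mean contrasts are proportional to the reliabilities", {
  lam <- c(0.8, 0.7, 0.75, 0.65, 0.6)
  ds <- generate_null_dataset(generator_config(N = 100000, lambda = lam,
                                               seed = 34))
  gm <- group_means(ds$X, ds$Z)
  contrast <- gm$means[2, ] - gm$means[1, ]
  scaled <- contrast / lam      # should be constant across indicators
  expect_lt(max(scaled) - min(scaled), 0.05)
})
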