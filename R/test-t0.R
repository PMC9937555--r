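# Reliability-dependent structural test (T0).
#
# Under the null that Z is independent of the indicators given the latent,
# the within-level means obey E(Xi | Z = z) = gamma_i + (lambda_i/lambda_r) *
# beta_z with beta_1 = 0 and r a reference indicator with nonzero
# reliability. T0 is the minimized GMM quadratic form over (gamma, beta);
# it is chi-square with (d-1)(p-1) df under the null. When the reliabilities
# are estimated rather than known, the weight matrix is the empirical
# covariance of the corrected moments U_k - A B^{-1} V_k, which accounts for
# the first-stage estimation uncertainty.

# Moment element ordering throughout: index (z-1)*d + i, i.e. level-major.

#' Per-subject T0 moment vector
#'
#' Element (z, i) is `I(z_k = z) * [x_i - gamma_i - (lambda_i/lambda_ref) *
#' beta_z]` with `beta_1 = 0`; only the d entries in the subject's own level
#' block can be nonzero. Elements are ordered level-major: index
#' `(z-1)*d + i`.
#'
#' @param x_row numeric d-vector of one subject's indicator values.
#' @param z integer level code in `1..p`.
#' @param gamma numeric d-vector of reference-level means.
#' @param beta numeric (p-1)-vector of level contrasts for the reference
#'   indicator (levels `2..p`).
#' @param lambda numeric d-vector of reliabilities.
#' @param ref reference indicator index (must have nonzero reliability).
#' @return numeric (p*d)-vector.
#' @export
u_vector_t0 <- function(x_row, z, gamma, beta, lambda, ref = 1L) {
  d <- length(x_row); p <- length(beta) + 1L
  stopifnot(length(gamma) == d, length(lambda) == d, z >= 1, z <= p)
  if (lambda[ref] == 0) stop("reference reliability must be nonzero")
  rho <- lambda / lambda[ref]
  bz <- if (z == 1L) 0 else beta[z - 1L]
  u <- numeric(p * d)
  u[(z - 1L) * d + seq_len(d)] <- x_row - gamma - rho * bz
  u
}

# N x (p*d) matrix of per-subject T0 moments.
u_rows_t0 <- function(values, zcodes, gamma, beta, lambda, ref) {
  d <- ncol(values); p <- length(beta) + 1L; n <- nrow(values)
  rho <- lambda / lambda[ref]
  U <- matrix(0, n, p * d)
  for (z in seq_len(p)) {
    idx <- zcodes == z
    if (!any(idx)) next
    bz <- if (z == 1L) 0 else beta[z - 1L]
    U[idx, (z - 1L) * d + seq_len(d)] <-
      sweep(values[idx, , drop = FALSE], 2L, gamma + rho * bz, "-")
  }
  U
}

#' Per-subject derivative of the T0 moments in the reliabilities
#'
#' The reliabilities enter the moments only through the ratio
#' `lambda_i / lambda_ref`, so for a subject in level z the only nonzero
#' entries are, for i != ref: `-beta_z / lambda_ref` with respect to
#' `lambda_i`, and `+lambda_i * beta_z / lambda_ref^2` with respect to
#' `lambda_ref`. The reference indicator's own rows vanish identically.
#'
#' @inheritParams u_vector_t0
#' @return (p*d) x d numeric matrix.
#' @export
du_dlambda_t0 <- function(x_row, z, beta, lambda, ref = 1L) {
  d <- length(lambda); p <- length(beta) + 1L
  out <- matrix(0, p * d, d)
  if (z == 1L) return(out)
  bz <- beta[z - 1L]
  lr <- lambda[ref]
  for (i in seq_len(d)) {
    if (i == ref) next
    row <- (z - 1L) * d + i
    out[row, i] <- -bz / lr
    out[row, ref] <- lambda[i] * bz / lr^2
  }
  out
}

# Per-subject moments at the saturated (level-wise mean) fit:
# I(z_k = z) * (x_i - Mhat[z, i]). These are the natural inefficient
# consistent estimates at which the weight matrix is evaluated; they do not
# depend on the reference indicator (T0) or normalization convention (T1),
# which keeps the minimized statistic exactly invariant to those choices.
u_rows_saturated <- function(values, zcodes, M) {
  d <- ncol(values); p <- nrow(M); n <- nrow(values)
  U <- matrix(0, n, p * d)
  for (z in seq_len(p)) {
    idx <- zcodes == z
    if (!any(idx)) next
    U[idx, (z - 1L) * d + seq_len(d)] <-
      sweep(values[idx, , drop = FALSE], 2L, M[z, ], "-")
  }
  U
}

# (1/N) sum_k dU_k/dlambda, analytic: block z carries weight pi_z.
mean_du_dlambda_t0 <- function(pi_z, beta, lambda, ref) {
  d <- length(lambda); p <- length(beta) + 1L
  A <- matrix(0, p * d, d)
  lr <- lambda[ref]
  for (z in 2:p) {
    bz <- beta[z - 1L]
    for (i in seq_len(d)) {
      if (i == ref) next
      row <- (z - 1L) * d + i
      A[row, i] <- -pi_z[z] * bz / lr
      A[row, ref] <- pi_z[z] * lambda[i] * bz / lr^2
    }
  }
  A
}

#' Plug-in corrected weight matrix for T0
#'
#' When the reliabilities are estimated from the same sample, the empirical
#' covariance of the raw moments U_k understates (or misstates) the
#' variability of their average. It suffices to take the empirical
#' covariance of the adjusted rows `U_k - A B^{-1} V_k`, where
#' `A = (1/N) sum dU_k/dlambda`, `B = (1/N) sum dV_k/dlambda` and V_k are
#' the per-subject reliability moments.
#'
#' @param U_rows N x m matrix of per-subject test moments.
#' @param V_rows N x d matrix of per-subject reliability moments.
#' @param mean_dU_dlambda m x d mean Jacobian of U in lambda.
#' @param mean_dV_dlambda d x d mean Jacobian of V in lambda.
#' @param ... passed to [empirical_weight()].
#' @return A [empirical_weight()] object computed from the adjusted rows.
#' @export
corrected_weight_t0 <- function(U_rows, V_rows, mean_dU_dlambda,
                                mean_dV_dlambda, ...) {
  if (!all(is.finite(mean_dV_dlambda)) ||
      kappa(mean_dV_dlambda, exact = TRUE) > 1e10)
    stop("correction error: mean reliability Jacobian is (near-)singular; ",
         "consider supplying known reliabilities (uncorrected variant)")
  adj <- mean_dU_dlambda %*% solve(mean_dV_dlambda)
  empirical_weight(U_rows - V_rows %*% t(adj), ...)
}

#' Reliability-dependent test of the structural interpretation (T0)
#'
#' Fits the null model E(Xi | Z = z) = gamma_i + (lambda_i/lambda_ref) *
#' beta_z by distance-metric GMM and returns the minimized statistic, which
#' is chi-square with (d-1)(p-1) degrees of freedom under the null
#' hypothesis that Z is independent of the indicators conditional on the
#' latent. If `lambda` is not supplied it is estimated from the pairwise
#' covariances (requires d >= 3) and the weight matrix is corrected for the
#' estimation uncertainty; a supplied `lambda` is treated as known and the
#' uncorrected weight is used.
#'
#' The reference indicator defaults to the one with the largest absolute
#' estimated reliability (the null constraint is symmetric in indicators;
#' the choice only affects numerical conditioning of the ratio
#' lambda_i/lambda_ref).
#'
#' @param X an [indicator_matrix] (standardize first for the reliability
#'   model to apply; see [standardize()]).
#' @param Z a [grouping_variable] with p >= 2 levels.
#' @param lambda optional known reliabilities: numeric d-vector or a
#'   `reliability_estimate`.
#' @param ref optional reference indicator index; default argmax |lambda|.
#' @param correct logical; correct the weight matrix for estimated
#'   reliabilities. Defaults to TRUE exactly when lambda is estimated
#'   internally.
#' @param seed optional seed for optimizer restarts.
#' @return Object of class `structest_result` with elements `test` ("t0"),
#'   `statistic`, `df`, `p_value`, `lambda`, `gamma`, `beta`, `ref`,
#'   `corrected`, `converged`, `n_used`, `diagnostics`.
#' @export
run_test_t0 <- function(X, Z, lambda = NULL, ref = NULL,
                        correct = is.null(lambda), seed = NULL) {
  stopifnot(inherits(X, "indicator_matrix"), inherits(Z, "grouping_variable"))
  values <- X$values
  d <- ncol(values); n <- nrow(values); p <- Z$p
  if (length(Z$codes) != n)
    stop("indicator matrix and grouping variable have different lengths")
  if (p < 2L)
    stop("design error: T0 requires a grouping variable with p >= 2 levels")

  correct <- correct  # force before lambda is (possibly) filled in below
  if (is.null(lambda)) {
    lam_est <- estimate_reliabilities(X)
    lambda <- lam_est$lambda
  } else {
    if (inherits(lambda, "reliability_estimate")) lambda <- lambda$lambda
    if (length(lambda) != d)
      stop("supplied lambda must have length d = ", d)
  }
  if (is.null(ref)) ref <- which.max(abs(lambda))
  if (lambda[ref] == 0)
    stop("reference reliability lambda[", ref, "] is zero")

  gm <- group_means(X, Z)
  counts <- gm$counts
  pi_z <- counts / n
  M <- gm$means
  gamma0 <- M[1L, ]
  rho <- lambda / lambda[ref]
  # reference-free contrast profile b_w ~ beta_w / lambda_ref, pooled across
  # indicators by projecting the observed contrasts on lambda; consistent
  # under the null by the proportionality of group-mean contrasts
  D <- sweep(M[-1L, , drop = FALSE], 2L, M[1L, ], "-")
  b_pool <- as.vector(D %*% lambda) / sum(lambda^2)
  beta0 <- lambda[ref] * b_pool
  theta0 <- c(gamma0, beta0)

  U0 <- u_rows_saturated(values, Z$codes, M)
  weight <- if (correct) {
    V <- reliability_moment_rows(values, lambda)
    A <- mean_du_dlambda_t0(pi_z, beta0, lambda, ref)
    B <- reliability_jacobian(X, lambda)
    corrected_weight_t0(U0, V, A, B)
  } else {
    empirical_weight(U0)
  }

  # moments are linear in theta: ubar(theta) = b - G theta
  b <- as.vector(t(M * pi_z))
  m <- p * d; q <- d + p - 1L
  G <- matrix(0, m, q)
  for (z in seq_len(p)) {
    for (i in seq_len(d)) {
      row <- (z - 1L) * d + i
      G[row, i] <- pi_z[z]
      if (z >= 2L) G[row, d + z - 1L] <- pi_z[z] * rho[i]
    }
  }
  spec <- moment_spec(
    m = m, q = q, n = n,
    mean_fn = function(th) b - as.vector(G %*% th),
    jac_fn = function(th) -G)

  fit <- minimize_distance_metric(spec, weight, theta0, seed = seed)
  df <- (d - 1L) * (p - 1L)
  structure(list(
    test = "t0",
    statistic = fit$statistic,
    df = df,
    p_value = chi_square_pvalue(fit$statistic, df),
    lambda = lambda,
    gamma = fit$params[seq_len(d)],
    beta = fit$params[d + seq_len(p - 1L)],
    ref = ref,
    corrected = correct,
    converged = fit$converged,
    n_used = n,
    diagnostics = list(weight_rank = weight$rank,
                       ridge_used = weight$ridge_used,
                       iterations = fit$iterations,
                       gradient_norm = fit$gradient_norm,
                       restarts = fit$restarts)),
    class = "structest_result")
}

#' @export
print.structest_result <- function(x, ...) {
  lab <- switch(x$test,
                t0 = "T0 (reliability-dependent structural test)",
                t1 = "T1 (reliability-free rank-1 structural test)",
                x$test)
  cat(lab, "\n")
  cat(sprintf("  statistic = %s on %s df, p = %s  (N = %d)\n",
              format(x$statistic, digits = 6), format(x$df),
              format(x$p_value, digits = 4), x$n_used))
  if (x$test == "t0")
    cat(sprintf("  weight matrix %s for estimated reliabilities\n",
                if (x$corrected) "corrected" else "not corrected"))
  invisible(x)
}
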