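# Reliability-free structural test (T1).
#
# The structural interpretation is equivalent to a rank-1 restriction on the
# group-mean contrasts: E(Xi | Z = z) - E(Xi | Z = 1) = alpha_i * beta_z for
# some parameters alpha, beta (beta_1 = 0). T1 is the minimized GMM
# quadratic form over (gamma, alpha, beta); chi-square with (d-1)(p-2) df
# under the null. No reliability estimates are needed, so the test is
# immune to misspecified error covariance structure, but Z must have at
# least three levels.

#' Per-subject T1 moment vector
#'
#' Element (w, i) is `I(z_k = w) * (x_i - gamma_i - alpha_i * beta_w)` with
#' `beta_1 = 0`; ordered level-major (index `(w-1)*d + i`). The moments are
#' invariant to the rescaling `alpha/tau, beta*tau` for any nonzero tau,
#' which is why one coordinate must be frozen during estimation.
#'
#' @param x_row numeric d-vector of one subject's indicator values.
#' @param z integer level code in `1..p`.
#' @param gamma numeric d-vector of reference-level means.
#' @param alpha numeric d-vector of indicator loadings on the contrast.
#' @param beta numeric (p-1)-vector of level effects (levels `2..p`).
#' @return numeric (d*p)-vector.
#' @export
u_vector_t1 <- function(x_row, z, gamma, alpha, beta) {
  d <- length(x_row); p <- length(beta) + 1L
  stopifnot(length(gamma) == d, length(alpha) == d, z >= 1, z <= p)
  bz <- if (z == 1L) 0 else beta[z - 1L]
  u <- numeric(p * d)
  u[(z - 1L) * d + seq_len(d)] <- x_row - gamma - alpha * bz
  u
}

# N x (p*d) matrix of per-subject T1 moments.
u_rows_t1 <- function(values, zcodes, gamma, alpha, beta) {
  d <- ncol(values); p <- length(beta) + 1L; n <- nrow(values)
  U <- matrix(0, n, p * d)
  for (z in seq_len(p)) {
    idx <- zcodes == z
    if (!any(idx)) next
    bz <- if (z == 1L) 0 else beta[z - 1L]
    U[idx, (z - 1L) * d + seq_len(d)] <-
      sweep(values[idx, , drop = FALSE], 2L, gamma + alpha * bz, "-")
  }
  U
}

#' Reliability-free test of the structural interpretation (T1)
#'
#' Tests the rank-1 restriction on group-mean contrasts implied by the
#' structural interpretation, without estimating reliabilities. The model
#' E(Xi | Z = z) = gamma_i + alpha_i * beta_z (beta_1 = 0) is fitted by
#' distance-metric GMM; the minimized statistic is chi-square with
#' (d-1)(p-2) degrees of freedom under the null.
#'
#' Because only the products alpha_i * beta_z are identified, one
#' coordinate is frozen at its initial value during optimization. Initial
#' values come from the best rank-1 approximation (SVD) of the
#' (p-1) x d matrix of observed group-mean contrasts; the minimized
#' statistic does not depend on the normalization convention.
#'
#' @param X an [indicator_matrix].
#' @param Z a [grouping_variable] with p >= 3 levels.
#' @param normalization `"alpha_max"` (freeze the alpha coordinate of
#'   largest initial magnitude, default) or `"beta2"` (freeze beta_2).
#' @param seed optional seed for optimizer restarts.
#' @return Object of class `structest_result` with elements `test` ("t1"),
#'   `statistic`, `df`, `p_value`, `gamma`, `alpha`, `beta`,
#'   `normalization`, `converged`, `n_used`, `diagnostics`.
#' @export
run_test_t1 <- function(X, Z, normalization = c("alpha_max", "beta2"),
                        seed = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(X, "indicator_matrix"), inherits(Z, "grouping_variable"))
  values <- X$values
  d <- ncol(values); n <- nrow(values); p <- Z$p
  if (length(Z$codes) != n)
    stop("indicator matrix and grouping variable have different lengths")
  if (p < 3L)
    stop("design error: T1 requires Z with at least three levels (got p = ",
         p, "); use run_test_t0() for p = 2")

  gm <- group_means(X, Z)
  counts <- gm$counts
  pi_z <- counts / n
  M <- gm$means
  D <- sweep(M[-1L, , drop = FALSE], 2L, M[1L, ], "-")  # (p-1) x d contrasts
  if (max(abs(D)) < 1e-10)
    warning("all group-mean contrasts are (near) zero; the rank-1 test is ",
            "uninformative and the statistic will be near 0")

  gamma0 <- M[1L, ]
  sv <- svd(D)
  alpha0 <- sv$v[, 1L]
  beta0 <- sv$u[, 1L] * sv$d[1L]
  # sign convention: make the largest-|alpha| coordinate positive
  jmax <- which.max(abs(alpha0))
  if (alpha0[jmax] < 0) { alpha0 <- -alpha0; beta0 <- -beta0 }

  if (normalization == "alpha_max") {
    frozen <- list(kind = "alpha", index = jmax, value = alpha0[jmax])
  } else {
    frozen <- list(kind = "beta", index = 1L, value = beta0[1L])
  }
  if (abs(frozen$value) < 1e-12)
    stop("normalization error: frozen coordinate has (near) zero initial ",
         "value; choose the other normalization")

  # pack/unpack free parameters: gamma (d), alpha (d or d-1), beta (p-1 or p-2)
  unpack <- function(th) {
    gamma <- th[seq_len(d)]
    if (frozen$kind == "alpha") {
      alpha <- numeric(d)
      alpha[-frozen$index] <- th[d + seq_len(d - 1L)]
      alpha[frozen$index] <- frozen$value
      beta <- th[(2L * d - 1L) + seq_len(p - 1L)]
    } else {
      alpha <- th[d + seq_len(d)]
      beta <- numeric(p - 1L)
      beta[1L] <- frozen$value
      if (p > 2L) beta[-1L] <- th[2L * d + seq_len(p - 2L)]
    }
    list(gamma = gamma, alpha = alpha, beta = beta)
  }
  pack <- function(gamma, alpha, beta) {
    if (frozen$kind == "alpha") c(gamma, alpha[-frozen$index], beta)
    else c(gamma, alpha, beta[-1L])
  }
  theta0 <- pack(gamma0, alpha0, beta0)
  q <- length(theta0)            # 2d + p - 2 under either convention
  m <- p * d

  bmat <- M * pi_z               # (1/N) within-level sums, p x d
  mean_fn <- function(th) {
    pr <- unpack(th)
    bfull <- c(0, pr$beta)
    fitted <- outer(bfull, pr$alpha) +
      matrix(pr$gamma, p, d, byrow = TRUE)       # p x d fitted means
    as.vector(t(bmat - fitted * pi_z))
  }
  jac_fn <- function(th) {
    pr <- unpack(th)
    bfull <- c(0, pr$beta)
    J <- matrix(0, m, q)
    for (z in seq_len(p)) {
      rows <- (z - 1L) * d + seq_len(d)
      # d/dgamma_i
      J[cbind(rows, seq_len(d))] <- -pi_z[z]
      # d/dalpha_i
      if (frozen$kind == "alpha") {
        free_i <- setdiff(seq_len(d), frozen$index)
        J[cbind(rows[free_i], d + seq_along(free_i))] <- -pi_z[z] * bfull[z]
      } else {
        J[cbind(rows, d + seq_len(d))] <- -pi_z[z] * bfull[z]
      }
      # d/dbeta_z
      if (z >= 2L) {
        col <- if (frozen$kind == "alpha") (2L * d - 1L) + (z - 1L)
               else if (z >= 3L) 2L * d + (z - 2L) else NA_integer_
        if (!is.na(col)) J[rows, col] <- -pi_z[z] * pr$alpha
      }
    }
    J
  }

  U0 <- u_rows_saturated(values, Z$codes, M)
  weight <- empirical_weight(U0)
  spec <- moment_spec(m = m, q = q, n = n, mean_fn = mean_fn, jac_fn = jac_fn)
  fit <- minimize_distance_metric(spec, weight, theta0, seed = seed)
  pr <- unpack(fit$params)
  df <- (d - 1L) * (p - 2L)
  structure(list(
    test = "t1",
    statistic = fit$statistic,
    df = df,
    p_value = chi_square_pvalue(fit$statistic, df),
    gamma = pr$gamma,
    alpha = pr$alpha,
    beta = pr$beta,
    normalization = normalization,
    corrected = FALSE,
    converged = fit$converged,
    n_used = n,
    diagnostics = list(weight_rank = weight$rank,
                       ridge_used = weight$ridge_used,
                       iterations = fit$iterations,
                       gradient_norm = fit$gradient_norm,
                       restarts = fit$restarts)),
    class = "structest_result")
}

#' Cross-classify two grouping variables
#'
#' Builds a composite grouping variable from two discrete variables, with
#' levels ordered lexicographically by (Z2, Z1) — i.e. Z1 cycles fastest —
#' and empty cross-cells dropped with a warning.
#'
#' @param Z1,Z2 [grouping_variable] objects of equal length.
#' @return A [grouping_variable] with up to p1*p2 levels.
#' @export
build_composite_z <- function(Z1, Z2) {
  stopifnot(inherits(Z1, "grouping_variable"), inherits(Z2, "grouping_variable"))
  if (length(Z1$codes) != length(Z2$codes))
    stop("grouping variables have different lengths")
  raw <- (Z2$codes - 1L) * Z1$p + Z1$codes
  lab1 <- names(Z1$level_map); lab2 <- names(Z2$level_map)
  labs <- as.vector(t(outer(lab2, lab1, function(a, b) paste(b, a, sep = ":"))))
  present <- sort(unique(raw))
  if (length(present) < Z1$p * Z2$p)
    warning("dropping ", Z1$p * Z2$p - length(present),
            " empty cross-cell(s) from the composite grouping variable")
  grouping_variable(factor(labs[raw], levels = labs[present]))
}
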