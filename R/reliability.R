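#' Pairwise sample covariances (divisor N)
#'
#' Computes Cij = (1/N) sum_k (Xik - Xbar_i)(Xjk - Xbar_j) for all pairs of
#' indicators. Under the basic factor model with unit-variance latent and
#' mutually independent errors, Cov(Xi, Xj) = lambda_i * lambda_j for i != j,
#' which identifies the reliabilities from d >= 3 indicators. The diagonal is
#' returned for completeness but is not used by the reliability estimator.
#'
#' @param X an [indicator_matrix].
#' @return Object of class `covariance_set`: list with `C` (d x d symmetric
#'   matrix) and `n` (subject count).
#' @export
pairwise_covariances <- function(X) {
  stopifnot(inherits(X, "indicator_matrix"))
  v <- X$values
  vc <- sweep(v, 2L, colMeans(v), "-")
  structure(list(C = crossprod(vc) / nrow(v), n = nrow(v)),
            class = "covariance_set")
}

#' Per-subject reliability moment vector V_k
#'
#' Element i is V_ik = sum_{j != i} lambda_j * [(x_i - xbar_i)(x_j - xbar_j)
#' - lambda_i lambda_j]; the d estimating functions whose sample average is
#' zero at the reliability solution. Exposed per subject because the T0
#' weight-matrix correction needs the empirical covariance of these moments
#' jointly with the test moments U_k.
#'
#' @param x_row numeric d-vector, one subject's indicator values.
#' @param xbar numeric d-vector of overall indicator means.
#' @param lambda numeric d-vector of (strictly positive) reliabilities.
#' @return numeric d-vector.
#' @export
reliability_moment_vector <- function(x_row, xbar, lambda) {
  stopifnot(length(x_row) == length(xbar), length(x_row) == length(lambda),
            all(lambda > 0))
  xc <- x_row - xbar
  # sum_{j != i} lambda_j xc_i xc_j  =  xc_i (sum_j lambda_j xc_j - lambda_i xc_i)
  s <- sum(lambda * xc)
  xc * (s - lambda * xc) - lambda * (sum(lambda^2) - lambda^2)
}

# Vectorized V_k over all subjects: N x d matrix of per-subject moments.
reliability_moment_rows <- function(values, lambda) {
  xc <- sweep(values, 2L, colMeans(values), "-")
  s <- as.vector(xc %*% lambda)
  cross <- xc * s - sweep(xc^2, 2L, lambda, "*")
  sweep(cross, 2L, lambda * (sum(lambda^2) - lambda^2), "-")
}

# Residual of the d estimating equations at lambda, given off-diagonal C:
# F_i = sum_{j != i} lambda_j (C_ij - lambda_i lambda_j)
reliability_residual <- function(C0, lambda) {
  as.vector(C0 %*% lambda) - lambda * (sum(lambda^2) - lambda^2)
}

#' Mean Jacobian of the reliability moments
#'
#' Returns (1/N) sum_k dV_k / dlambda, the d x d matrix with entries
#' C_im - 2 lambda_i lambda_m off the diagonal and -sum_{j != i} lambda_j^2
#' on it. Used both by the Newton solver and as the B block of the T0
#' plug-in variance correction.
#'
#' @param X an [indicator_matrix].
#' @param lambda numeric d-vector of reliabilities.
#' @return d x d numeric matrix.
#' @export
reliability_jacobian <- function(X, lambda) {
  C <- pairwise_covariances(X)$C
  J <- C - 2 * tcrossprod(lambda)
  diag(J) <- -(sum(lambda^2) - lambda^2)
  J
}

#' Estimate indicator reliabilities from pairwise covariances
#'
#' Solves the d unbiased estimating equations
#' sum_{j != i} lambda_j (C_ij - lambda_i lambda_j) = 0, i = 1..d, implied
#' by the rank-1 covariance structure Cov(Xi, Xj) = lambda_i lambda_j.
#' Two equivalent solvers are provided:
#' \describe{
#'   \item{`"root"`}{damped Newton iteration on log(lambda), which enforces
#'     positivity; initialization from pairwise covariance means.}
#'   \item{`"quasi-poisson"`}{fits the working log-linear model
#'     log E(Cij) = sum_s Lambda_s I(s in \{i,j\}) to the d(d-1) vector of
#'     off-diagonal sample covariances (both orderings, no intercept) by
#'     quasi-Poisson maximum pseudo-likelihood and exponentiates the
#'     coefficients.}
#' }
#' Requires d >= 3 (the system is underidentified otherwise) and all
#' pairwise covariances positive, possibly after [auto_reverse_code()].
#' For d = 3 the solution has the closed form
#' lambda_1 = sqrt(C12 * C13 / C23) (and permutations).
#'
#' @param X an [indicator_matrix].
#' @param solver `"root"` (default) or `"quasi-poisson"`.
#' @param max_iter,tol Newton iteration cap and residual tolerance
#'   (max-norm of the estimating equations).
#' @return Object of class `reliability_estimate`: list with `lambda`,
#'   `log_lambda`, `converged`, `solver`, `n_used`, `residual`.
#' @export
estimate_reliabilities <- function(X, solver = c("root", "quasi-poisson"),
                                   max_iter = 200L, tol = 1e-10) {
  solver <- match.arg(solver)
  stopifnot(inherits(X, "indicator_matrix"))
  d <- ncol(X$values)
  if (d < 3L)
    stop("identification error: reliability estimation requires d >= 3 ",
         "indicators (got ", d, "); supply known reliabilities instead")
  C <- pairwise_covariances(X)$C
  off <- C[upper.tri(C)]
  if (any(off <= 0)) {
    idx <- which(upper.tri(C) & (C <= 0), arr.ind = TRUE)[1, ]
    stop("estimation error: non-positive pairwise covariance between ",
         "indicators ", idx[1], " and ", idx[2],
         "; apply auto_reverse_code() or drop the offending indicator")
  }
  C0 <- C
  diag(C0) <- 0

  if (solver == "quasi-poisson") {
    pairs <- which(upper.tri(C), arr.ind = TRUE)
    ij <- rbind(pairs, pairs[, 2:1, drop = FALSE])  # both orderings: d(d-1) rows
    y <- C[ij]
    M <- matrix(0, nrow(ij), d)
    M[cbind(seq_len(nrow(ij)), ij[, 1])] <- 1
    M[cbind(seq_len(nrow(ij)), ij[, 2])] <- 1
    # pseudo-likelihood under the log-link working model with mutually
    # independent, homoscedastic errors: constant working variance, so the
    # score equations reduce exactly to the weighted estimating equations
    fit <- stats::glm.fit(M, y,
                          family = stats::quasi(link = "log",
                                                variance = "constant"),
                          control = stats::glm.control(epsilon = 1e-12,
                                                       maxit = 100L))
    log_lambda <- fit$coefficients
    lambda <- exp(log_lambda)
    res <- reliability_residual(C0, lambda)
    return(structure(list(lambda = lambda, log_lambda = log_lambda,
                          converged = fit$converged, solver = "quasi-poisson",
                          n_used = nrow(X$values), residual = max(abs(res))),
                     class = "reliability_estimate"))
  }

  # Newton on Lambda = log(lambda), damped line search on the residual norm
  pair_mean_s <- (rowSums(C0)) / (d - 1)
  all_mean <- mean(off)
  Lam <- 0.5 * log(pmax(pair_mean_s^2 / all_mean, 1e-3))
  lambda <- exp(Lam)
  fval <- reliability_residual(C0, lambda)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(fval)) < tol) { converged <- TRUE; break }
    Jlam <- C0 - 2 * tcrossprod(lambda)
    diag(Jlam) <- -(sum(lambda^2) - lambda^2)
    JLam <- Jlam * rep(lambda, each = d)    # chain rule d/dLambda
    step <- tryCatch(solve(JLam, -fval),
                     error = function(e) NULL)
    if (is.null(step))
      stop("convergence error: singular Jacobian in reliability Newton ",
           "solve; final residual ", format(max(abs(fval))))
    t <- 1
    repeat {
      Lam_new <- Lam + t * step
      lam_new <- exp(Lam_new)
      f_new <- reliability_residual(C0, lam_new)
      if (max(abs(f_new)) < max(abs(fval)) || t < 2^-30) break
      t <- t / 2
    }
    Lam <- Lam_new; lambda <- lam_new; fval <- f_new
  }
  if (!converged && max(abs(fval)) >= tol)
    stop("convergence error: reliability estimating equations did not ",
         "converge in ", max_iter, " iterations; final residual ",
         format(max(abs(fval))))
  structure(list(lambda = as.vector(lambda), log_lambda = as.vector(Lam),
                 converged = TRUE, solver = "root",
                 n_used = nrow(X$values), residual = max(abs(fval))),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("reliability_estimate (%s solver, N = %d)\n", x$solver, x$n_used))
  print(round(x$lambda, 4))
  invisible(x)
}
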