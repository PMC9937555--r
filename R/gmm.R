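#' Specify a set of moment conditions for distance-metric GMM
#'
#' The engine works with the averaged moment vector
#' `ubar(theta) = (1/N) sum_k U_k(theta)` and (optionally) its analytic
#' Jacobian in the nuisance parameters. A nondegenerate overidentification
#' test needs more moments than parameters (m > q).
#'
#' @param m number of moment conditions.
#' @param q number of free nuisance parameters.
#' @param n number of subjects behind the average.
#' @param mean_fn function(theta) -> m-vector, the averaged moments.
#' @param jac_fn optional function(theta) -> m x q Jacobian of `mean_fn`;
#'   finite differences are used when absent.
#' @return Object of class `moment_spec`.
#' @export
moment_spec <- function(m, q, n, mean_fn, jac_fn = NULL) {
  stopifnot(is.function(mean_fn), m >= 1, q >= 0, n >= 1)
  structure(list(m = as.integer(m), q = as.integer(q), n = as.integer(n),
                 mean_fn = mean_fn, jac_fn = jac_fn),
            class = "moment_spec")
}

#' Empirical GMM weight matrix from per-subject moment rows
#'
#' Sigma = (1/N) sum_k (U_k - Ubar)(U_k - Ubar)', inverted by
#' eigendecomposition with a relative eigenvalue cutoff so that
#' near-singular directions are truncated (pseudo-inverse). If the rank
#' falls below `m - expected_deficiency`, a small ridge
#' (1e-8 * trace(Sigma)/m) is added before inversion and flagged.
#'
#' @param U_rows N x m matrix of per-subject moment vectors.
#' @param expected_deficiency structurally expected rank deficiency (0 by
#'   default).
#' @param eig_tol relative eigenvalue cutoff for the pseudo-inverse.
#' @return Object of class `weight_matrix`: list with `sigma`, `inverse`,
#'   `rank`, `ridge_used`, `m`.
#' @export
empirical_weight <- function(U_rows, expected_deficiency = 0L,
                             eig_tol = 1e-10) {
  U_rows <- as.matrix(U_rows)
  n <- nrow(U_rows); m <- ncol(U_rows)
  if (all(U_rows == 0))
    stop("degenerate moments: all per-subject moment vectors are zero")
  if (n <= m)
    warning("fewer subjects (", n, ") than moment dimensions (", m,
            "); weight matrix will be singular or ill-conditioned")
  Uc <- sweep(U_rows, 2L, colMeans(U_rows), "-")
  sigma <- crossprod(Uc) / n
  sigma <- (sigma + t(sigma)) / 2
  make_inverse <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > eig_tol * max(e$values, 0)
    rank <- sum(keep)
    inv <- if (rank == 0) matrix(0, m, m) else
      e$vectors[, keep, drop = FALSE] %*%
        (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
    list(inverse = inv, rank = rank)
  }
  dec <- make_inverse(sigma)
  ridge_used <- FALSE
  if (dec$rank < m - expected_deficiency) {
    ridge_used <- TRUE
    sigma_r <- sigma + diag(1e-8 * sum(diag(sigma)) / m, m)
    dec <- make_inverse(sigma_r)
  }
  structure(list(sigma = sigma, inverse = dec$inverse, rank = dec$rank,
                 ridge_used = ridge_used, m = m),
            class = "weight_matrix")
}

#' Minimize the GMM distance-metric quadratic form
#'
#' Minimizes `Q(theta) = N * ubar(theta)' W ubar(theta)` (W the inverse of
#' the empirical weight matrix) with BFGS, using the analytic moment
#' Jacobian when the spec provides one. If the first solve ends with
#' gradient norm above `grad_tol`, up to 5 perturbed restarts are tried and
#' the smallest minimum is kept.
#'
#' @param spec a [moment_spec].
#' @param weight a [weight_matrix] whose dimension matches `spec$m`.
#' @param init numeric q-vector of starting values.
#' @param seed optional seed controlling the restart perturbations.
#' @param grad_tol gradient-norm threshold that triggers restarts.
#' @param max_iter BFGS iteration cap per solve.
#' @return list with `params`, `statistic`, `converged`, `iterations`,
#'   `gradient_norm`, `restarts`.
#' @export
minimize_distance_metric <- function(spec, weight, init, seed = NULL,
                                     grad_tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(spec, "moment_spec"), inherits(weight, "weight_matrix"))
  if (weight$m != spec$m)
    stop("weight matrix dimension (", weight$m,
         ") does not match moment dimension (", spec$m, ")")
  if (!all(is.finite(init)) || length(init) != spec$q)
    stop("init must be a finite vector of length ", spec$q)
  W <- weight$inverse
  n <- spec$n
  fn <- function(th) {
    u <- spec$mean_fn(th)
    n * sum(u * (W %*% u))
  }
  gr <- if (!is.null(spec$jac_fn)) {
    function(th) {
      u <- spec$mean_fn(th)
      2 * n * as.vector(crossprod(spec$jac_fn(th), W %*% u))
    }
  } else NULL

  solve_once <- function(start) {
    if (spec$q == 0L)
      return(list(par = numeric(0), value = fn(numeric(0)),
                  counts = c(0L, 0L), convergence = 0L))
    stats::optim(start, fn, gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-14))
  }
  grad_norm <- function(th) {
    if (!is.null(gr)) return(sqrt(sum(gr(th)^2)))
    # forward-difference fallback
    g <- vapply(seq_along(th), function(j) {
      h <- 1e-6 * (abs(th[j]) + 1e-6)
      e <- th; e[j] <- e[j] + h
      (fn(e) - fn(th)) / h
    }, numeric(1))
    sqrt(sum(g^2))
  }

  best <- solve_once(init)
  gnorm <- if (spec$q) grad_norm(best$par) else 0
  restarts <- 0L
  if (spec$q && gnorm > grad_tol) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(5L)) {
      restarts <- restarts + 1L
      start <- init + stats::rnorm(spec$q, sd = 0.25 * (abs(init) + 0.1))
      cand <- solve_once(start)
      if (cand$value < best$value) best <- cand
    }
    gnorm <- grad_norm(best$par)
    if (gnorm > sqrt(grad_tol))
      stop("convergence error: distance-metric minimization failed across ",
           "restarts; best value ", format(best$value),
           ", gradient norm ", format(gnorm))
  }
  list(params = best$par, statistic = max(0, best$value),
       converged = TRUE, iterations = unname(best$counts[1]),
       gradient_norm = gnorm, restarts = restarts)
}

#' Upper-tail chi-square p-value
#'
#' @param statistic nonnegative test statistic.
#' @param df positive integer degrees of freedom.
#' @return P(chi-square(df) > statistic).
#' @export
chi_square_pvalue <- function(statistic, df) {
  if (!is.finite(statistic) || statistic < 0)
    stop("domain error: statistic must be nonnegative")
  if (df < 1) stop("domain error: df must be >= 1")
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}
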