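# Synthetic data with the exact structure the tests assume: indicators
# X_i = lambda_i * eta + eps_i with standard-normal latent eta, mean-zero
# errors of variance 1 - lambda_i^2 (so each indicator has population mean 0
# and variance 1), and a discrete Z generated either from eta alone (null:
# Z independent of the indicators given eta) or with additional direct
# dependence on chosen indicators (alternative).

#' Configuration for the synthetic factor-model generator
#'
#' Defaults describe the reference study design used throughout the
#' package's simulations: d = 5 indicators with reliabilities
#' (0.8, 0.7, 0.75, 0.65, 0.6), N = 2000 subjects, and a binary Z obtained
#' by thresholding the latent at equal-probability cutpoints.
#'
#' @param d number of indicators.
#' @param N number of subjects.
#' @param lambda numeric d-vector of reliabilities, each in `[0, 1)`
#'   (error variance `1 - lambda^2` must be nonnegative; 0 is allowed only
#'   as a degenerate sanity case).
#' @param p number of Z levels.
#' @param z_mechanism `"eta_threshold"` (default: Z = level of eta between
#'   consecutive cutpoints) or `"eta_logistic"` (multinomial logit in eta).
#' @param z_cutpoints_or_coefs for `"eta_threshold"`, a strictly increasing
#'   (p-1)-vector of cutpoints (default: standard-normal quantiles giving
#'   equal level probabilities); for `"eta_logistic"`, a (p-1) x 2 matrix of
#'   (intercept, slope) rows for levels `2..p` against the baseline level 1.
#' @param direct_effects d x (p-1) matrix of per-indicator mean shifts
#'   applied to subjects in levels `2..p` (all zero under the null).
#' @param error_correlation exchangeable correlation among the errors, in
#'   `[0, 1)`; 0 (independent errors) is the model the tests assume.
#' @param error_dist `"normal"` (default) or `"t5"` (scaled t with 5 df,
#'   rescaled to the target variance) to probe robustness to heavy tails.
#' @param seed optional integer seed; identical configs and seeds yield
#'   identical datasets.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(d = 5L, N = 2000L,
                             lambda = c(0.8, 0.7, 0.75, 0.65, 0.6),
                             p = 2L,
                             z_mechanism = c("eta_threshold", "eta_logistic"),
                             z_cutpoints_or_coefs = NULL,
                             direct_effects = NULL,
                             error_correlation = 0,
                             error_dist = c("normal", "t5"),
                             seed = NULL) {
  z_mechanism <- match.arg(z_mechanism)
  error_dist <- match.arg(error_dist)
  d <- as.integer(d); N <- as.integer(N); p <- as.integer(p)
  if (length(lambda) == 1L) lambda <- rep(lambda, d)
  if (length(lambda) != d)
    stop("config error: lambda must have length d = ", d)
  if (any(lambda < 0) || any(lambda^2 >= 1))
    stop("config error: each lambda must lie in [0, 1) so that the error ",
         "variance 1 - lambda^2 is positive")
  if (p < 2L) stop("config error: p must be >= 2")
  if (N < 2L * p) stop("config error: N too small for p levels")
  if (error_correlation < 0 || error_correlation >= 1)
    stop("config error: error_correlation must be in [0, 1)")
  if (is.null(z_cutpoints_or_coefs)) {
    z_cutpoints_or_coefs <- if (z_mechanism == "eta_threshold")
      stats::qnorm(seq_len(p - 1L) / p)
    else cbind(intercept = rep(0, p - 1L), slope = rep(1, p - 1L))
  }
  if (z_mechanism == "eta_threshold") {
    cp <- as.numeric(z_cutpoints_or_coefs)
    if (length(cp) != p - 1L || is.unsorted(cp, strictly = TRUE))
      stop("config error: need p - 1 strictly increasing cutpoints")
    z_cutpoints_or_coefs <- cp
  } else {
    co <- as.matrix(z_cutpoints_or_coefs)
    if (nrow(co) != p - 1L || ncol(co) != 2L)
      stop("config error: logistic coefs must be a (p-1) x 2 matrix")
    z_cutpoints_or_coefs <- co
  }
  if (is.null(direct_effects)) direct_effects <- matrix(0, d, p - 1L)
  direct_effects <- as.matrix(direct_effects)
  if (!all(dim(direct_effects) == c(d, p - 1L)))
    stop("config error: direct_effects must be a d x (p-1) matrix")
  structure(list(d = d, N = N, lambda = as.numeric(lambda), p = p,
                 z_mechanism = z_mechanism,
                 z_cutpoints_or_coefs = z_cutpoints_or_coefs,
                 direct_effects = direct_effects,
                 error_correlation = error_correlation,
                 error_dist = error_dist, seed = seed),
            class = "generator_config")
}

# Draw one dataset from a generator_config (shared null/alternative path).
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$d; N <- config$N; p <- config$p
  lambda <- config$lambda
  svec <- sqrt(1 - lambda^2)
  rho <- config$error_correlation
  draw_err <- function(n) {
    if (config$error_dist == "normal") stats::rnorm(n)
    else stats::rt(n, df = 5) / sqrt(5 / 3)    # unit variance
  }
  for (attempt in seq_len(10L)) {
    eta <- stats::rnorm(N)
    if (rho > 0) {
      g <- draw_err(N)
      u <- matrix(draw_err(N * d), N, d)
      eps <- (sqrt(rho) * g + sqrt(1 - rho) * u) %*% diag(svec, d)
    } else {
      eps <- matrix(draw_err(N * d), N, d) %*% diag(svec, d)
    }
    Xv <- tcrossprod(eta, lambda) + eps
    z <- if (config$z_mechanism == "eta_threshold") {
      findInterval(eta, config$z_cutpoints_or_coefs) + 1L
    } else {
      co <- config$z_cutpoints_or_coefs
      lp <- cbind(0, matrix(co[, 1L], N, p - 1L, byrow = TRUE) +
                       outer(eta, co[, 2L]))
      pr <- exp(lp - apply(lp, 1L, max))
      pr <- pr / rowSums(pr)
      cum <- t(apply(pr, 1L, cumsum))
      rowSums(stats::runif(N) > cum) + 1L
    }
    if (any(tabulate(z, nbins = p) == 0L)) {
      warning("empty grouping level in synthetic draw; regenerating (attempt ",
              attempt, ")")
      if (attempt == 10L)
        stop("config error: could not populate all ", p,
             " levels in 10 attempts; adjust cutpoints or N")
      next
    }
    break
  }
  delta <- config$direct_effects
  if (any(delta != 0)) {
    for (w in 2:p) {
      idx <- z == w
      if (any(idx))
        Xv[idx, ] <- sweep(Xv[idx, , drop = FALSE], 2L, delta[, w - 1L], "+")
    }
  }
  colnames(Xv) <- paste0("x", seq_len(d))
  structure(list(X = indicator_matrix(Xv),
                 Z = grouping_variable(z),
                 eta = eta, truth = config),
            class = "synthetic_dataset")
}

#' Generate a dataset satisfying the structural null
#'
#' Z depends on the indicators only through the latent eta, so the
#' Theorem-1 proportionality of group-mean contrasts holds in the
#' population and both tests are (asymptotically) calibrated.
#'
#' @param config a [generator_config] with all-zero `direct_effects`.
#' @return Object of class `synthetic_dataset`: list with `X`
#'   ([indicator_matrix]), `Z` ([grouping_variable]), `eta` (latent draws,
#'   diagnostics only) and `truth` (the config).
#' @export
generate_null_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(config$direct_effects != 0))
    stop("generate_null_dataset requires all-zero direct_effects; ",
         "use generate_alternative_dataset()")
  generate_dataset(config)
}

#' Generate a dataset violating the structural null
#'
#' As [generate_null_dataset()], then subjects in level w receive the mean
#' shift `direct_effects[i, w-1]` on indicator i — direct dependence of Z
#' on the indicators beyond the latent, which breaks the proportionality of
#' group-mean contrasts whenever the shifts are not proportional to lambda.
#'
#' @param config a [generator_config] with nonzero `direct_effects`.
#' @return A `synthetic_dataset`; see [generate_null_dataset()].
#' @export
generate_alternative_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  delta <- config$direct_effects
  if (all(delta == 0))
    warning("direct_effects are all zero; this reduces to the null generator")
  else {
    # if every shift column is proportional to lambda the alternative is
    # indistinguishable from the null in the group means
    resid <- apply(delta, 2L, function(col) {
      if (all(col == 0)) return(0)
      fit <- sum(col * config$lambda) / sum(config$lambda^2)
      max(abs(col - fit * config$lambda))
    })
    if (all(resid < 1e-12))
      warning("direct_effects are proportional to lambda in every level; ",
              "the alternative is indistinguishable from the null in means")
  }
  generate_dataset(config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$truth
  cat(sprintf("synthetic_dataset: N = %d, d = %d, p = %d (%s%s)\n",
              cfg$N, cfg$d, cfg$p,
              if (any(cfg$direct_effects != 0)) "alternative" else "null",
              if (cfg$error_correlation > 0)
                sprintf(", error corr %.2f", cfg$error_correlation) else ""))
  invisible(x)
}
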