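# Monte-Carlo evaluation of type-I error, power and chi-square calibration.
# Per-replicate seeds are base_seed + replicate index, so any replicate can
# be reproduced in isolation and scenario runs are order-independent.

#' Run one test on many independent synthetic datasets
#'
#' The workhorse behind [estimate_rejection_rate()] and [ks_calibration()]:
#' draws `reps` datasets from `config` (seed `seed + r` for replicate r),
#' standardizes the indicators as in the real-data pipeline, runs the chosen
#' test, and collects statistics and p-values. Replicates whose fit fails
#' are recorded, not silently dropped into the denominator.
#'
#' @param config a [generator_config].
#' @param test `"t0"` or `"t1"`.
#' @param reps number of replicates.
#' @param seed integer base seed.
#' @param lambda optional known reliabilities forwarded to [run_test_t0()]
#'   (skips estimation and the weight correction).
#' @param uncorrected_t0 also record the T0 statistic computed with the
#'   uncorrected weight matrix (for calibration comparisons).
#' @return Object of class `mc_statistics`: list with `statistics`,
#'   `p_values` (vectors over successful replicates), `df`, `n_failed`,
#'   `reps`, `test`, and optionally `statistics_uncorrected`,
#'   `p_values_uncorrected`.
#' @export
monte_carlo_statistics <- function(config, test = c("t0", "t1"), reps,
                                   seed = 1L, lambda = NULL,
                                   uncorrected_t0 = FALSE) {
  test <- match.arg(test)
  stopifnot(inherits(config, "generator_config"), reps >= 1)
  stat <- pval <- stat_u <- pval_u <- rep(NA_real_, reps)
  df <- NA_integer_
  n_failed <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seed + r
    res <- tryCatch({
      ds <- generate_dataset(cfg)
      Xs <- standardize(ds$X)
      if (test == "t0") {
        main <- run_test_t0(Xs, ds$Z, lambda = lambda)
        unc <- if (uncorrected_t0 && is.null(lambda))
          run_test_t0(Xs, ds$Z, lambda = main$lambda, correct = FALSE)
        else NULL
        list(main = main, unc = unc)
      } else {
        list(main = run_test_t1(Xs, ds$Z), unc = NULL)
      }
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    stat[r] <- res$main$statistic
    pval[r] <- res$main$p_value
    df <- res$main$df
    if (!is.null(res$unc)) {
      stat_u[r] <- res$unc$statistic
      pval_u[r] <- res$unc$p_value
    }
  }
  ok <- !is.na(stat)
  out <- list(statistics = stat[ok], p_values = pval[ok], df = df,
              n_failed = n_failed, reps = reps, test = test)
  if (uncorrected_t0) {
    out$statistics_uncorrected <- stat_u[ok]
    out$p_values_uncorrected <- pval_u[ok]
  }
  structure(out, class = "mc_statistics")
}

#' Monte-Carlo rejection rate with exact binomial confidence interval
#'
#' @param config a [generator_config] (null or alternative).
#' @param test `"t0"` or `"t1"`.
#' @param alpha nominal level.
#' @param reps number of replicates (>= 100 for a meaningful rate).
#' @param seed integer base seed.
#' @param mc optional precomputed [monte_carlo_statistics()] result to
#'   avoid re-simulation.
#' @param ... forwarded to [monte_carlo_statistics()].
#' @return list with `rate`, `ci` (exact binomial 95\% CI), `n_used`,
#'   `n_failed`, `reliable` (FALSE if more than 5\% of fits failed),
#'   `alpha`, `test`.
#' @export
estimate_rejection_rate <- function(config, test = c("t0", "t1"),
                                    alpha = 0.05, reps = 1000L, seed = 1L,
                                    mc = NULL, ...) {
  test <- match.arg(test)
  if (reps < 100L) stop("use at least 100 replicates for a rejection rate")
  if (is.null(mc))
    mc <- monte_carlo_statistics(config, test, reps = reps, seed = seed, ...)
  n_ok <- length(mc$p_values)
  hits <- sum(mc$p_values < alpha)
  bt <- stats::binom.test(hits, n_ok)
  reliable <- mc$n_failed <= 0.05 * mc$reps
  if (!reliable)
    warning("more than 5% of fits failed (", mc$n_failed, "/", mc$reps,
            "); rejection rate flagged unreliable")
  list(rate = hits / n_ok, ci = as.vector(bt$conf.int), n_used = n_ok,
       n_failed = mc$n_failed, reliable = reliable, alpha = alpha,
       test = test)
}

#' Kolmogorov-Smirnov distance of null statistics to their chi-square limit
#'
#' @inheritParams estimate_rejection_rate
#' @return list with `distance`, `df`, `n_used`, `n_failed`, `test`.
#' @export
ks_calibration <- function(config, test = c("t0", "t1"), reps = 1000L,
                           seed = 1L, mc = NULL, ...) {
  test <- match.arg(test)
  if (any(config$direct_effects != 0))
    stop("usage error: ks_calibration is meaningful only under a null ",
         "configuration (direct_effects all zero)")
  if (is.null(mc))
    mc <- monte_carlo_statistics(config, test, reps = reps, seed = seed, ...)
  ks <- suppressWarnings(
    stats::ks.test(mc$statistics, stats::pchisq, df = mc$df))
  list(distance = unname(ks$statistic), df = mc$df,
       n_used = length(mc$statistics), n_failed = mc$n_failed, test = test)
}

#' Run a grid of calibration/power scenarios
#'
#' @param scenarios list of scenario lists, each with elements `config`
#'   (a [generator_config]), `test`, `alpha` (default 0.05) and `reps`.
#' @param seed integer base seed (per-scenario streams are offset so
#'   scenarios are independent).
#' @return list of per-scenario reports: rejection rate with CI, KS
#'   distance against the reference chi-square when the scenario is a null,
#'   and failure counts.
#' @export
run_calibration_grid <- function(scenarios, seed = 1L) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  out <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    alpha <- if (is.null(sc$alpha)) 0.05 else sc$alpha
    base <- seed + (s - 1L) * 1000000L
    mc <- monte_carlo_statistics(sc$config, sc$test, reps = sc$reps,
                                 seed = base)
    rr <- estimate_rejection_rate(sc$config, sc$test, alpha = alpha,
                                  reps = sc$reps, seed = base, mc = mc)
    is_null <- all(sc$config$direct_effects == 0)
    ks <- if (is_null)
      ks_calibration(sc$config, sc$test, reps = sc$reps, seed = base, mc = mc)
    else NULL
    out[[s]] <- list(test = sc$test, alpha = alpha, reps = sc$reps,
                     null = is_null,
                     rejection_rate = rr$rate, ci = rr$ci,
                     ks_distance = if (is.null(ks)) NA_real_ else ks$distance,
                     df = mc$df, n_failed = mc$n_failed,
                     reliable = rr$reliable)
  }
  out
}
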