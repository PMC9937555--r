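# End-to-end pipeline: load -> standardize -> reverse-code -> test(s) ->
# JSON report. This is what the command-line wrapper (inst/cli/structest)
# drives; the functions are equally usable interactively.

#' Run the structural-interpretation tests on prepared data
#'
#' Applies the default preprocessing (standardization to mean 0 / variance
#' 1 with divisor N, then automatic reverse-coding so all pairwise
#' covariances are positive) and runs the selected test(s).
#'
#' @param X an [indicator_matrix].
#' @param Z a [grouping_variable].
#' @param test `"t0"`, `"t1"` or `"both"`.
#' @param standardize logical; standardize the indicators first (the
#'   reliability model assumes unit-variance indicators; the rank-1
#'   restriction behind T1 is scale-equivariant, so disabling this mainly
#'   affects T0).
#' @param reverse_code logical; apply [auto_reverse_code()] after
#'   standardization.
#' @param lambda optional known reliabilities for T0 (skips estimation and
#'   the weight-matrix correction).
#' @param seed optional seed for optimizer restarts.
#' @return list with elements `results` (named list of `structest_result`),
#'   `flips`, `n_used`, `standardized`.
#' @export
structural_test <- function(X, Z, test = c("both", "t0", "t1"),
                            standardize = TRUE, reverse_code = TRUE,
                            lambda = NULL, seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(X, "indicator_matrix"), inherits(Z, "grouping_variable"))
  if (standardize) X <- standardize(X)
  if (reverse_code) {
    if (!X$standardized)
      stop("reverse coding requires standardized indicators")
    X <- auto_reverse_code(X)
  }
  results <- list()
  if (test %in% c("both", "t0"))
    results$t0 <- run_test_t0(X, Z, lambda = lambda, seed = seed)
  if (test %in% c("both", "t1"))
    results$t1 <- run_test_t1(X, Z, seed = seed)
  list(results = results, flips = X$flipped, n_used = nrow(X$values),
       standardized = X$standardized)
}

# Serialize one structest_result to a plain list for JSON output.
result_to_list <- function(r) {
  out <- list(test = r$test, statistic = r$statistic, df = r$df,
              p_value = r$p_value, n_used = r$n_used,
              corrected = r$corrected, converged = r$converged,
              gamma = r$gamma, diagnostics = r$diagnostics)
  if (!is.null(r$lambda)) out$lambda <- r$lambda
  if (!is.null(r$alpha)) out$alpha <- r$alpha
  out$beta <- r$beta
  if (!is.null(r$normalization)) out$normalization <- r$normalization
  out
}

#' Write a self-describing JSON report for a set of test results
#'
#' @param run a list as returned by [structural_test()].
#' @param path output file path.
#' @param extra optional named list merged into the report (e.g. input
#'   paths, seeds, level maps).
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path, extra = list()) {
  report <- c(list(
    package = "structest",
    version = as.character(utils::packageVersion("structest")),
    n_used = run$n_used,
    standardized = run$standardized,
    flips = run$flips,
    results = lapply(run$results, result_to_list)), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Build a generator_config from a plain (YAML-derived) list.
config_from_list <- function(cfg) {
  args <- cfg[intersect(names(cfg),
                        names(formals(generator_config)))]
  if (!is.null(args$direct_effects))
    args$direct_effects <- matrix(unlist(args$direct_effects),
                                  nrow = as.integer(cfg$d))
  do.call(generator_config, args)
}

#' Run the full pipeline from a configuration list
#'
#' Configuration fields: `input` (CSV/TSV path), `indicator_cols`,
#' `z_col` (or `z_cols`, two column names cross-classified via
#' [build_composite_z()]), `test` ("t0"/"t1"/"both"), `standardize`,
#' `reverse_code`, `lambda` (optional known reliabilities), `seed`,
#' `output` (JSON report path).
#'
#' @param config named list (typically parsed from YAML).
#' @return the [structural_test()] run, invisibly; the report is written
#'   to `config$output` when set.
#' @export
run_pipeline <- function(config) {
  zcols <- if (!is.null(config$z_cols)) config$z_cols else config$z_col
  if (is.null(config$input) || is.null(config$indicator_cols) ||
      is.null(zcols))
    stop("config must name input, indicator_cols and z_col/z_cols")
  if (length(zcols) == 2L) {
    ld1 <- load_dataset(config$input, config$indicator_cols, zcols[1L])
    ld2 <- load_dataset(config$input, config$indicator_cols, zcols[2L])
    # identical complete-case filters only if both z columns are complete
    # on the same rows; enforce by filtering on all selected columns
    tab <- if (is.character(config$input)) {
      sep <- if (grepl("\\.(tsv|txt)$", config$input, ignore.case = TRUE))
        "\t" else ","
      utils::read.table(config$input, header = TRUE, sep = sep,
                        stringsAsFactors = FALSE, check.names = FALSE)
    } else config$input
    keep <- stats::complete.cases(tab[c(config$indicator_cols, zcols)])
    tab <- tab[keep, , drop = FALSE]
    ld <- load_dataset(tab, config$indicator_cols, zcols[1L], quiet = TRUE)
    Z <- build_composite_z(grouping_variable(tab[[zcols[1L]]]),
                           grouping_variable(tab[[zcols[2L]]]))
    X <- ld$X
  } else {
    ld <- load_dataset(config$input, config$indicator_cols, zcols)
    X <- ld$X; Z <- ld$Z
  }
  test <- if (is.null(config$test)) "both" else config$test
  if (test %in% c("t1", "both") && Z$p < 3L && test == "t1")
    stop("test = t1 requires Z with at least three levels (got p = ",
         Z$p, ")")
  run <- structural_test(
    X, Z, test = test,
    standardize = !isFALSE(config$standardize),
    reverse_code = !isFALSE(config$reverse_code),
    lambda = config$lambda,
    seed = config$seed)
  if (!is.null(config$output))
    write_report(run, config$output,
                 extra = list(input = if (is.character(config$input))
                   config$input else "data.frame",
                   z_levels = names(Z$level_map),
                   seed = config$seed))
  invisible(run)
}

#' Write a synthetic dataset to CSV
#'
#' Columns `x1..xd` plus integer column `z`; the simulate subcommand of the
#' command-line wrapper writes its output through this.
#'
#' @param ds a `synthetic_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(ds, path) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  df <- as.data.frame(ds$X$values)
  df$z <- ds$Z$codes
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
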