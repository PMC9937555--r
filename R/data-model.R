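#' Construct an indicator matrix
#'
#' Container for an N x d table of approximately continuous item responses
#' ("indicators"), the observed variables assumed to load on a single
#' univariate latent variable. All downstream estimation assumes complete
#' cases; rows with missing values must be removed before construction
#' (see [load_dataset()]).
#'
#' @param values numeric matrix, subjects in rows, indicators in columns.
#' @param indicator_names optional character vector of column labels;
#'   defaults to existing column names or `x1..xd`.
#' @param standardized logical; `TRUE` if each column has sample mean 0 and
#'   sample variance 1 (divisor N).
#' @param flipped integer vector of indicator indices whose sign has been
#'   reversed by [auto_reverse_code()].
#' @return An object of class `indicator_matrix` with elements `values`,
#'   `standardized`, `flipped`.
#' @seealso [standardize()], [auto_reverse_code()], [group_means()]
#' @export
indicator_matrix <- function(values, indicator_names = NULL,
                             standardized = FALSE, flipped = integer(0)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("indicator values must be numeric")
  if (anyNA(values))
    stop("indicator matrix contains missing values; remove incomplete rows first")
  d <- ncol(values)
  n <- nrow(values)
  if (d < 2L)
    stop("at least 2 indicator columns are required, got ", d)
  if (n <= d)
    stop("need more subjects (", n, ") than indicators (", d, ")")
  if (is.null(indicator_names)) {
    indicator_names <- colnames(values)
    if (is.null(indicator_names)) indicator_names <- paste0("x", seq_len(d))
  }
  colnames(values) <- indicator_names
  if (isTRUE(standardized)) {
    mu <- colMeans(values)
    v <- colMeans(values^2) - mu^2
    if (any(abs(mu) >= 1e-10) || any(abs(v - 1) >= 1e-8))
      stop("standardized = TRUE but columns are not mean-0 / variance-1 (divisor N)")
  }
  structure(
    list(values = values, standardized = isTRUE(standardized),
         flipped = as.integer(flipped)),
    class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("indicator_matrix: %d subjects x %d indicators (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw",
              if (length(x$flipped))
                paste0(", flipped: ", paste(x$flipped, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

#' Construct a discrete grouping variable
#'
#' Codes an external discrete variable Z into integer levels `1..p`, sorted
#' by original value; level 1 is the reference level against which
#' group-mean contrasts are formed.
#'
#' @param z vector of discrete values (character, factor, integer, ...).
#' @return Object of class `grouping_variable` with elements `codes`
#'   (integers in `1..p`), `p`, `level_map` (named integer vector mapping
#'   original value to code) and `reference_level` (always 1).
#' @export
grouping_variable <- function(z) {
  if (anyNA(z)) stop("grouping variable contains missing values")
  if (is.factor(z)) {
    lev <- levels(z)[levels(z) %in% as.character(unique(z))]
    codes <- match(as.character(z), lev)
  } else {
    lev <- sort(unique(as.vector(z)))
    codes <- match(z, lev)
  }
  level_map <- stats::setNames(seq_along(lev), as.character(lev))
  structure(
    list(codes = as.integer(codes), p = length(lev), level_map = level_map,
         reference_level = 1L),
    class = "grouping_variable")
}

#' @export
print.grouping_variable <- function(x, ...) {
  cat(sprintf("grouping_variable: N = %d, p = %d levels (%s)\n",
              length(x$codes), x$p,
              paste(names(x$level_map), collapse = ", ")))
  invisible(x)
}

#' Load indicators and grouping variable from a delimited file
#'
#' Reads a CSV or TSV table with a header row, extracts the named indicator
#' columns and the grouping column, applies complete-case filtering across
#' the selected columns, and reports the number of rows removed.
#'
#' @param table path to a CSV/TSV file, or a `data.frame`.
#' @param indicator_cols character vector (length >= 2) of indicator column
#'   names.
#' @param z_col name of the discrete grouping column.
#' @param quiet suppress the retention log message.
#' @return list with elements `X` ([indicator_matrix]), `Z`
#'   ([grouping_variable]), `n_read`, `n_kept`, `n_removed`.
#' @export
load_dataset <- function(table, indicator_cols, z_col, quiet = FALSE) {
  if (length(indicator_cols) < 2L)
    stop("configuration error: need at least 2 indicator columns")
  if (is.character(table)) {
    sep <- if (grepl("\\.(tsv|txt)$", table, ignore.case = TRUE)) "\t" else ","
    table <- utils::read.table(table, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE,
                               fileEncoding = "UTF-8")
  }
  missing_cols <- setdiff(c(indicator_cols, z_col), names(table))
  if (length(missing_cols))
    stop("configuration error: column(s) not found: ",
         paste(missing_cols, collapse = ", "))
  n_read <- nrow(table)
  xs <- table[indicator_cols]
  if (!all(vapply(xs, is.numeric, logical(1))))
    stop("indicator columns must be numeric")
  z_raw <- table[[z_col]]
  keep <- stats::complete.cases(xs) & !is.na(z_raw)
  n_kept <- sum(keep)
  levels_all <- sort(unique(as.vector(z_raw[!is.na(z_raw)])))
  z_kept <- z_raw[keep]
  lost <- setdiff(levels_all, unique(as.vector(z_kept)))
  if (length(lost))
    stop("validation error: grouping level(s) with 0 subjects after ",
         "complete-case filtering: ", paste(lost, collapse = ", "))
  if (!quiet)
    message(sprintf("load_dataset: read %d rows, kept %d (%d removed as incomplete)",
                    n_read, n_kept, n_read - n_kept))
  list(X = indicator_matrix(as.matrix(xs[keep, , drop = FALSE])),
       Z = grouping_variable(z_kept),
       n_read = n_read, n_kept = n_kept, n_removed = n_read - n_kept)
}

#' Standardize indicators to mean 0, variance 1
#'
#' Centers and scales each indicator column to sample mean 0 and sample
#' variance 1 using divisor N (not N-1), matching the 1/N convention of the
#' pairwise-covariance estimating equations used throughout the package.
#'
#' @param X an [indicator_matrix].
#' @return A standardized [indicator_matrix]; idempotent on already
#'   standardized input.
#' @export
standardize <- function(X) {
  stopifnot(inherits(X, "indicator_matrix"))
  v <- X$values
  mu <- colMeans(v)
  s2 <- colMeans(v^2) - mu^2
  if (any(s2 <= 0)) {
    bad <- colnames(v)[s2 <= 0]
    stop("degenerate indicator(s) with zero variance: ",
         paste(bad, collapse = ", "))
  }
  out <- sweep(sweep(v, 2L, mu, "-"), 2L, sqrt(s2), "/")
  indicator_matrix(out, standardized = TRUE, flipped = X$flipped)
}

#' Reverse-code indicators until pairwise covariances are positive
#'
#' The rank-1 reliability model assumes all pairwise covariances are
#' positive, possibly after reversing the coding of some indicators.
#' This greedily flips the sign of the indicator whose mean pairwise
#' covariance with the others is most negative, until no indicator has a
#' negative mean pairwise covariance. Flips change only the signs of the
#' covariances, never their magnitudes. If some pairwise covariance remains
#' non-positive after the greedy pass (possible e.g. for mutually
#' independent noise columns), a warning is issued.
#'
#' @param X a standardized [indicator_matrix].
#' @param max_passes safety cap on greedy iterations.
#' @return An [indicator_matrix] with `flipped` recording the reversed
#'   indicator indices.
#' @export
auto_reverse_code <- function(X, max_passes = NULL) {
  stopifnot(inherits(X, "indicator_matrix"))
  if (!X$standardized)
    stop("auto_reverse_code expects standardized indicators")
  v <- X$values
  d <- ncol(v)
  if (is.null(max_passes)) max_passes <- 4L * d
  C <- crossprod(v) / nrow(v)   # columns mean-0 already
  sgn <- rep(1, d)
  for (pass in seq_len(max_passes)) {
    Cs <- C * tcrossprod(sgn)
    rowmean <- (rowSums(Cs) - diag(Cs)) / (d - 1)
    if (min(rowmean) >= 0) break
    i <- which.min(rowmean)
    sgn[i] <- -sgn[i]
  }
  Cs <- C * tcrossprod(sgn)
  if (any(Cs[upper.tri(Cs)] <= 0))
    warning("auto_reverse_code: a fully positive pairwise covariance matrix ",
            "is unattainable; some pairwise covariances remain non-positive")
  flips <- which(sgn < 0)
  newflipped <- sort(union(setdiff(X$flipped, flips), setdiff(flips, X$flipped)))
  indicator_matrix(sweep(v, 2L, sgn, "*"), standardized = TRUE,
                   flipped = newflipped)
}

#' Within-level indicator means
#'
#' Sample analogues of the conditional expectations E(Xi | Z = z) that the
#' structural-interpretation tests constrain.
#'
#' @param X an [indicator_matrix].
#' @param Z a [grouping_variable] of matching length.
#' @return Object of class `group_means`: list with `means` (p x d matrix)
#'   and `counts` (p group sizes).
#' @export
group_means <- function(X, Z) {
  stopifnot(inherits(X, "indicator_matrix"), inherits(Z, "grouping_variable"))
  v <- X$values
  if (nrow(v) != length(Z$codes))
    stop("indicator matrix and grouping variable have different lengths")
  counts <- tabulate(Z$codes, nbins = Z$p)
  if (any(counts == 0L))
    stop("validation error: empty grouping level")
  sums <- rowsum(v, Z$codes, reorder = TRUE)
  structure(list(means = sums / counts, counts = counts),
            class = "group_means")
}
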