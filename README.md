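# structest

Tests for rejecting the **structural interpretation** of a univariate
latent factor model.

## The problem

A reflective measurement model assumes each of `d` observed indicators
(items of a psychosocial scale, say) is a linear function of one latent
variable:

    X_i = lambda_i * eta + eps_i,    i = 1..d,

with `eta` standard normal, mean-zero errors `eps_i` independent of `eta`
and of each other, and indicators standardized to mean 0 / variance 1, so
`lambda_i` is the *reliability* of indicator `i`. Even when this model
fits the covariance of the indicators well, researchers usually go one
step further and treat it as *structural*: the latent, not the
indicators, is assumed to be what acts on (and is acted on by) everything
else. That extra assumption says any external variable `Z` is independent
of `(X_1, ..., X_d)` given `eta` — and it is testable, despite `eta`
being unobserved.

For a discrete `Z` with levels `1..p`, the structural assumption forces
the group-mean contrasts to be proportional to the reliabilities:

    { E(X_i | Z = z) - E(X_i | Z = 1) } / lambda_i   is the same for all i,

equivalently, the `(p-1) x d` contrast matrix has rank 1. `structest`
implements two generalized-method-of-moments (GMM) distance-metric tests
of this constraint:

| test | model for E(X_i | Z = z) | needs | df | function |
|------|--------------------------|-------|----|----------|
| T0 | `gamma_i + (lambda_i / lambda_ref) * beta_z` | reliability estimates (d >= 3) | (d-1)(p-1) | `run_test_t0()` |
| T1 | `gamma_i + alpha_i * beta_z` (rank-1, no reliabilities) | p >= 3 levels of Z | (d-1)(p-2) | `run_test_t1()` |

Reliabilities for T0 are estimated from the pairwise covariances
(`Cov(X_i, X_j) = lambda_i * lambda_j` for `i != j`) by unbiased
estimating equations (`estimate_reliabilities()`), and the GMM weight
matrix is corrected for the first-stage estimation uncertainty using the
per-subject reliability moments. T1 needs no reliabilities, so it is
robust to a misspecified error covariance — at the price of requiring at
least three levels of `Z`.

Each test statistic is `N` times the minimized weighted quadratic form of
the averaged moment conditions; under the structural null it follows the
chi-square distribution with the df above, so small p-values are evidence
*against* the structural interpretation (not against the scale itself).

## Worked example

```r
library(structest)

# a synthetic cohort: 5 items, reliabilities (0.8, 0.7, 0.75, 0.65, 0.6),
# binary Z thresholded on the latent (the structural null holds)
ds <- generate_null_dataset(generator_config(N = 2000, seed = 42))
X <- standardize(ds$X)

run_test_t0(X, ds$Z)
#> T0 (reliability-dependent structural test)
#>   statistic = 0.162382 on 4 df, p = 0.9969  (N = 2000)
#>   weight matrix corrected for estimated reliabilities

# now break the null: Z acts directly on item 5 (mean shift 0.4)
dm <- matrix(0, 5, 1); dm[5, 1] <- 0.4
da <- generate_alternative_dataset(generator_config(direct_effects = dm,
                                                    seed = 42))
run_test_t0(standardize(da$X), da$Z)
#> T0 (reliability-dependent structural test)
#>   statistic = 23.1189 on 4 df, p = 0.0001199  (N = 2000)
#>   weight matrix corrected for estimated reliabilities
```

Under the null the statistic is small relative to its chi-square(4)
reference (p = 0.997: no evidence against the structural reading). With a
direct effect of `Z` on one item, the proportionality of contrasts is
violated and the test rejects decisively (p ≈ 1e-4). The reliability-free
test works the same way with a `Z` of at least three levels:
`run_test_t1(X, Z)`.

For file-based workflows, `run_pipeline()` (or the thin CLI wrapper in
`inst/cli/structest`) reads a CSV, standardizes, reverse-codes indicators
with negative pairwise covariances, runs the selected tests and writes a
self-describing JSON report.

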