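#' Exact (Clopper-Pearson) binomial confidence limits
#'
#' Exact two-sided limits for a binomial proportion from beta-distribution
#' quantiles: `lower = qbeta(alpha/2, x, n - x + 1)` and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)`, with `lower = 0` when `x = 0`
#' and `upper = 1` when `x = n`. Equivalent to inverting the binomial tail
#' tests, so the tail probability at each limit equals `alpha/2`.
#'
#' @param x number of successes (vectorised).
#' @param n number of trials (>= 1).
#' @param alpha two-sided significance level (default 0.05 for 95\% limits).
#' @return a tibble with columns `x`, `n`, `alpha`, `lower`, `upper`.
#' @export
#' @examples
#' clopper_pearson(83, 576)
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (any(n < 1)) abort("n must be at least 1")
  if (any(x < 0 | x > n)) abort("x must satisfy 0 <= x <= n")
  if (any(x != round(x) | n != round(n))) abort("x and n must be integers")
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble(x = x, n = n, alpha = alpha, lower = lower, upper = upper)
}

#' Percent culturability with exact confidence limits
#'
#' Limiting-dilution viability estimation: with wells inoculated with a mean
#' of `X` cells each, the fraction of cells able to grow to detection is
#' `V = -ln(1 - p)/X`, where `p` is the proportion of wells positive for
#' growth. This inverts the Poisson void probability `P(no viable cell) =
#' exp(-V * X)` and is exact when cell numbers per well are Poisson. The 95\%
#' limits are obtained by computing exact (Clopper-Pearson) binomial limits
#' for `p` and inserting them back into the viability equation in place of
#' `p`.
#'
#' @param x_pos number of positive cultures (here: cultures screened as
#'   monocultures or mixed cultures).
#' @param n_wells number of inoculated cultures.
#' @param X mean cells per inoculation (> 0).
#' @param alpha two-sided significance level for the limits.
#' @param experiment,scope optional labels carried into the output.
#' @return a one-row tibble of class `htc_culturability`: `experiment`,
#'   `scope`, `x_pos`, `n_wells`, `p`, `cells_per_well`, `V`, `ci_low`,
#'   `ci_high`, `alpha`. Viabilities are fractions; see [tidy()] for
#'   rounded percentages. `x_pos = n_wells` yields an infinite estimate
#'   (flagged, not an error), since `-ln(0)` diverges.
#' @export
#' @examples
#' culturability(83, 576, X = 5)
culturability <- function(x_pos, n_wells, X, alpha = 0.05,
                          experiment = NA_character_, scope = NA_character_) {
  if (!is.finite(X) || X <= 0) abort("X (cells per well) must be positive")
  if (n_wells < 1) abort("n_wells must be at least 1")
  if (x_pos < 0 || x_pos > n_wells) abort("x_pos must satisfy 0 <= x_pos <= n_wells")
  p <- x_pos / n_wells
  ci <- clopper_pearson(x_pos, n_wells, alpha)
  v_of <- function(q) ifelse(q < 1, -log(1 - q) / X, Inf)
  out <- tibble(
    experiment = experiment,
    scope = scope,
    x_pos = as.integer(x_pos),
    n_wells = as.integer(n_wells),
    p = p,
    cells_per_well = X,
    V = v_of(p),
    ci_low = v_of(ci$lower),
    ci_high = v_of(ci$upper),
    alpha = alpha
  )
  class(out) <- c("htc_culturability", class(out))
  out
}

#' Culturability estimates for one experiment's culture calls
#'
#' Computes the two standard culturability statistics from classified
#' cultures: one counting monocultures only and one counting monocultures
#' plus mixed cultures as positives. The denominator is the number of
#' inoculated cultures, which may exceed the number of sequenced cultures
#' (wells lost before or during subculturing still count as inoculated).
#'
#' @param calls tibble from [classify_cultures()] for one experiment.
#' @param n_wells number of inoculated cultures.
#' @param X mean cells per inoculation.
#' @param alpha two-sided significance level.
#' @param experiment experiment label; defaults to the label in `calls`.
#' @return a two-row `htc_culturability` tibble (scopes `mono_only` and
#'   `mono_plus_mixed`).
#' @export
experiment_summary <- function(calls, n_wells, X, alpha = 0.05,
                               experiment = NULL) {
  if (nrow(calls) == 0) abort("no culture calls supplied")
  if (is.null(experiment)) {
    experiment <- as.character(unique(calls$experiment))[1]
  }
  n_mono <- sum(calls$category == "monoculture")
  n_mixed <- sum(calls$category == "mixed")
  if (n_mono + n_mixed > n_wells) {
    abort("positive cultures exceed the number of inoculated wells")
  }
  out <- dplyr::bind_rows(
    culturability(n_mono + n_mixed, n_wells, X, alpha, experiment,
                  scope = "mono_plus_mixed"),
    culturability(n_mono, n_wells, X, alpha, experiment, scope = "mono_only")
  )
  class(out) <- c("htc_culturability", class(out))
  out
}

#' @describeIn culturability tidy method: percentages rounded half-up to one
#'   decimal (`V_pct`, `ci_low_pct`, `ci_high_pct`) alongside the fractions.
#' @param x an `htc_culturability` tibble.
#' @param ... unused.
#' @export
tidy.htc_culturability <- function(x, ...) {
  out <- as_tibble(x)
  out$V_pct <- round_half_up(100 * out$V, 1)
  out$ci_low_pct <- round_half_up(100 * out$ci_low, 1)
  out$ci_high_pct <- round_half_up(100 * out$ci_high, 1)
  out
}

#' @describeIn culturability glance method: one row per estimate with the
#'   printed-form percentage string, e.g. `"3.1 (2.5, 3.9)"`.
#' @export
glance.htc_culturability <- function(x, ...) {
  td <- tidy.htc_culturability(x)
  tibble(
    experiment = td$experiment,
    scope = td$scope,
    x_pos = td$x_pos,
    n_wells = td$n_wells,
    culturability_pct = sprintf("%.1f (%.1f, %.1f)", td$V_pct, td$ci_low_pct,
                                td$ci_high_pct)
  )
}
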