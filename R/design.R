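#' Body-surface-area conversion factors (km)
#'
#' Species km factors of the standard body-surface-area dose-conversion
#' table (FDA guidance): mg/kg times km gives mg/m2. Supplied as data so a
#' user can extend or override the table.
#'
#' @return Named numeric vector of km factors.
#' @export
km_factors <- function() {
  c(mouse = 3, rat = 6, human = 37)
}

#' Human-equivalent dose on a body-surface-area basis
#'
#' Single-dose BSA equivalent: `dose_mg_per_kg * km(species)`. For the rat
#' (km = 6), 1/10/20 mg/kg translate to 6/60/120 mg/m2.
#'
#' @param dose_mg_per_kg Dose in mg per kg body weight (>= 0).
#' @param species Species name, resolved against the km table.
#' @param km Named km table (default [km_factors()]).
#' @return Dose in mg per m2 body surface area.
#' @export
hed_mg_per_m2 <- function(dose_mg_per_kg, species = "rat",
                          km = km_factors()) {
  if (dose_mg_per_kg < 0) stop("dose must be non-negative")
  if (!species %in% names(km)) stop("unknown species: ", species)
  unname(dose_mg_per_kg * km[[species]])
}

#' Cumulative human-equivalent dose of a repeated regimen
#'
#' @inheritParams hed_mg_per_m2
#' @param n_days Number of daily administrations (integer >= 1).
#' @return Cumulative dose in mg per m2.
#' @export
cumulative_hed <- function(dose_mg_per_kg, n_days, species = "rat",
                           km = km_factors()) {
  if (n_days < 1L) stop("n_days must be >= 1")
  hed_mg_per_m2(dose_mg_per_kg, species, km) * n_days
}

#' Power of a balanced one-way ANOVA
#'
#' `power = P(F' > F_crit)` where `F_crit` is the `(1 - alpha)` quantile of
#' the central `F(k - 1, k(n - 1))` distribution and `F'` is noncentral
#' `F(k - 1, k(n - 1), lambda)` with `lambda = f^2 * k * n` (Cohen's f,
#' total-sample noncentrality convention). At `f = 0` the power equals
#' `alpha` exactly.
#'
#' @param k Number of groups (>= 2).
#' @param n Per-group sample size (>= 2, so that `k(n-1) >= 1`).
#' @param f Cohen's effect size (>= 0).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Power in (0, 1).
#' @export
anova_power <- function(k, n, f, alpha = 0.05) {
  if (k < 2L) stop("k must be >= 2")
  if (n < 2L) stop("n must be >= 2 (k(n-1) >= 1 denominator df required)")
  if (f < 0) stop("f must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df1 <- k - 1
  df2 <- k * (n - 1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f^2 * k * n, lower.tail = FALSE)
}

#' Minimal balanced group size for a target ANOVA power
#'
#' Returns the smallest integer `n >= 2` whose exact noncentral-F power
#' reaches the target. The result also carries the continuous sample-size
#' solution `n_continuous` -- the real-valued root of `power(n) = target`
#' that sample-size software (e.g. the balanced one-way ANOVA power
#' calculator in base R) reports; study reports often round that value to
#' whole subjects.
#'
#' @inheritParams anova_power
#' @param power Target power in (0, 1), default 0.8.
#' @param n_max Search cap; an error is raised if the target is unreachable
#'   below it.
#' @return Integer minimal `n`, with attribute `n_continuous`.
#' @export
min_n_for_power <- function(k, f, alpha = 0.05, power = 0.8, n_max = 1000L) {
  if (f <= 0) stop("f must be positive to reach power above alpha")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  n <- 2L
  while (anova_power(k, n, f, alpha) < power) {
    n <- n + 1L
    if (n > n_max) stop("target power unreachable below n_max = ", n_max)
  }
  g <- function(x) {
    df1 <- k - 1; df2 <- k * (x - 1)
    stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
              ncp = f^2 * k * x, lower.tail = FALSE) - power
  }
  n_cont <- if (g(2) >= 0) 2 else stats::uniroot(g, c(2, n), tol = 1e-9)$root
  structure(n, n_continuous = n_cont)
}
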