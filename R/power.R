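# Exact noncentral-t power and sample size for paired designs.

#' Power of a paired t test (exact noncentral t)
#'
#' `1 - F_nct(t_crit; df = n - 1, ncp = d * sqrt(n))` with `t_crit` the
#' central-t critical value; the two-sided version also counts rejections in
#' the opposite tail. Vectorized over `n` and `d`.
#'
#' @param n Number of pairs (may be fractional; df = n - 1).
#' @param d Standardized paired effect size (Cohen's d_z).
#' @param alpha Significance level.
#' @param sided `"two"` or `"one"`.
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, d, alpha = 0.05, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(all(n >= 2), alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sided == "one") {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
}

#' Required sample size for a paired t test
#'
#' Smallest integer n whose exact noncentral-t power reaches the target.
#' Also reports the fractional root of the continuous power function and the
#' normal-approximation size `((z_alpha + z_power) / d)^2` (with its
#' ceiling), so the integer can be audited under either convention.
#'
#' @param d Standardized paired effect size (nonzero).
#' @param power Target power in (alpha, 1).
#' @param alpha Significance level.
#' @param sided `"two"` or `"one"`.
#' @return One-row tibble: `n_exact` (integer, exact noncentral-t), `n_frac`
#'   (fractional root), `n_approx` (normal approximation, raw),
#'   `n_approx_int` (its ceiling), `power_at_n` (exact power at `n_exact`),
#'   `d`, `alpha`, `sided`.
#' @export
required_n <- function(d, power = 0.80, alpha = 0.05,
                       sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(d != 0, power > alpha, power < 1)
  d <- abs(d)
  f <- function(n) power_paired_t(n, d, alpha, sided) - power
  hi <- 4
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e7) stop("required_n: target power unreachable", call. = FALSE)
  }
  n_frac <- stats::uniroot(f, c(2, hi), tol = 1e-9)$root
  n_exact <- ceiling(n_frac - 1e-9)
  # the discrete check: integer power is the continuous function at integer n
  while (power_paired_t(n_exact, d, alpha, sided) < power) n_exact <- n_exact + 1
  while (n_exact > 2 && power_paired_t(n_exact - 1, d, alpha, sided) >= power) {
    n_exact <- n_exact - 1
  }
  za <- if (sided == "one") stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  n_approx <- ((za + stats::qnorm(power)) / d)^2
  tibble::tibble(n_exact = as.integer(n_exact), n_frac = n_frac,
                 n_approx = n_approx, n_approx_int = as.integer(ceiling(n_approx)),
                 power_at_n = power_paired_t(n_exact, d, alpha, sided),
                 d = d, alpha = alpha, sided = sided)
}

#' Sample-size audit table for a paired design
#'
#' Computes the required n under both sidedness conventions and both
#' computations (exact noncentral t and normal approximation) for a given
#' effect size, so a planned or published sample size can be checked against
#' every convention at once.
#'
#' @inheritParams required_n
#' @return Tibble with one row per sidedness.
#' @export
sample_size_audit <- function(d, power = 0.80, alpha = 0.05) {
  dplyr::bind_rows(required_n(d, power, alpha, sided = "one"),
                   required_n(d, power, alpha, sided = "two"))
}
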