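#' Probability that one library member is picked exactly m times
#'
#' Treats each of the `n` picks as an independent Bernoulli trial for a
#' designated library member whose per-pick selection probability is `weight`
#' (default `1/N`, the equiprobable pool). The number of hits on that member
#' is then binomial, and this returns `P(X = m) = C(n, m) p^m (1 - p)^(n - m)`.
#'
#' Note the denominator: this is a per-member probability. It is related to,
#' but not the same thing as, the empirical relative occurrence of
#' multiplicity `m` in a campaign (members hit exactly `m` times divided by
#' the number of picks); see [empirical_relative_occurrence()].
#'
#' @param n non-negative integer, number of picks.
#' @param N positive integer, library size.
#' @param m integer multiplicity, `0 <= m <= n`. May be a vector.
#' @param weight per-pick selection probability of the designated member;
#'   default `1/N`.
#' @return Numeric vector of probabilities, one per value of `m`.
#' @examples
#' multiplicity_pmf(66, 148, 1:4)
#' @seealso [coverage_probability()], [expected_multiplicity_spectrum()]
#' @export
multiplicity_pmf <- function(n, N, m, weight = 1 / N) {
  check_n_N(n, N)
  if (any(m < 0) || any(m > n) || any(m != floor(m))) {
    stop("`m` must be integer(s) in [0, n]", call. = FALSE)
  }
  if (weight < 0 || weight > 1) {
    stop("`weight` must lie in [0, 1]", call. = FALSE)
  }
  stats::dbinom(m, size = n, prob = weight)
}

#' Probability that a designated library member is picked at least once
#'
#' Under the urn model with replacement (uniform picking), the chance that a
#' given member of a library of size `N` appears at least once among `n`
#' picks is `P(X >= 1) = 1 - (1 - 1/N)^n`. For libraries of typical size
#' (`N >= 100`) this depends essentially only on the oversampling factor
#' `k = n/N`, approaching `1 - exp(-k)`: about 0.95 for threefold and 0.98
#' for fourfold oversampling.
#'
#' @param n non-negative integer number of picks (vectorised).
#' @param N positive integer library size.
#' @return Numeric vector of coverage probabilities.
#' @examples
#' coverage_probability(3 * 148, 148)  # ~0.95
#' coverage_probability(4 * 148, 148)  # ~0.98
#' @export
coverage_probability <- function(n, N) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("`n` must be non-negative integer(s)", call. = FALSE)
  }
  if (length(N) != 1L || N < 1 || N != floor(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  ## log1p formulation keeps precision for large n / large N
  1 - exp(n * log1p(-1 / N))
}

#' Smallest number of picks reaching a target coverage
#'
#' Inverts the coverage relation: returns the smallest integer `n` such that
#' [coverage_probability()]`(n, N) >= target_coverage`. With replacement the
#' coverage never reaches 1 exactly, so `target_coverage` must be `< 1`.
#'
#' @param target_coverage probability in `[0, 1)`.
#' @param N positive integer library size.
#' @return Integer pick count.
#' @examples
#' required_picks(0.95, 148)  # close to threefold oversampling
#' @export
required_picks <- function(target_coverage, N) {
  if (length(target_coverage) != 1L || !is.finite(target_coverage) ||
      target_coverage < 0 || target_coverage >= 1) {
    stop("`target_coverage` must lie in [0, 1); coverage 1 is unreachable ",
         "when sampling with replacement", call. = FALSE)
  }
  if (length(N) != 1L || N < 1 || N != floor(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  if (target_coverage == 0) return(0L)
  if (N == 1L) return(1L)
  ## closed form, then verify the ceiling against the exact recurrence so a
  ## floating-point boundary never returns an n one too high or too low
  n <- ceiling(log1p(-target_coverage) / log1p(-1 / N))
  while (n > 0 && coverage_probability(n - 1, N) >= target_coverage) n <- n - 1
  while (coverage_probability(n, N) < target_coverage) n <- n + 1
  as.integer(n)
}

#' Expected number of members hit exactly m times
#'
#' Under equiprobable picking the expected count of library members recovered
#' with multiplicity `m` is `N * P(X = m)` with `X ~ Binomial(n, 1/N)`. The
#' spectrum conserves picks: `sum_m m * E[count_m] = n`.
#'
#' @param n non-negative integer, number of picks.
#' @param N positive integer, library size.
#' @param m_max largest multiplicity to report (default `n`).
#' @return A data frame with columns `m` (0..`m_max`) and `expected_members`.
#' @examples
#' expected_multiplicity_spectrum(66, 148, m_max = 6)
#' @export
expected_multiplicity_spectrum <- function(n, N, m_max = n) {
  check_n_N(n, N)
  m_max <- min(m_max, n)
  m <- 0:m_max
  data.frame(m = m, expected_members = N * multiplicity_pmf(n, N, m))
}

check_n_N <- function(n, N) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != floor(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Used when comparing computed probabilities and relative activities to
#' values printed at fixed precision (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.2875, 3)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
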