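#' Probability that a doped-library member carries exactly n mismatches
#'
#' Under per-position independent doping at frequency `f`, the number of
#' mismatches in an `L`-nt sequence is binomial:
#' \deqn{P(n; L, f) = \binom{L}{n} f^n (1-f)^{L-n}.}
#'
#' @param n Number of mismatches (vectorized), `0 <= n <= L`.
#' @param L Sequence length (default 20).
#' @param f Doping frequency in \[0, 1\].
#' @return Numeric vector of probabilities; sums to 1 over `n = 0..L`.
#' @examples
#' mismatch_probability(0:20, L = 20, f = 0.15)
#' @export
mismatch_probability <- function(n, L = 20L, f = 0.15) {
  check_n_L(n, L)
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort("`f` must be a probability in [0, 1].",
          class = "cas9profiler_domain_error")
  }
  stats::dbinom(n, size = L, prob = f)
}

#' Number of distinct sequences with exactly n mismatches to a reference
#'
#' Each of the \eqn{\binom{L}{n}} position sets can carry any of 3 substitute
#' bases per position, so the count is \eqn{3^n \binom{L}{n}}, independent of
#' the doping frequency. For L = 20 this gives 60 single-mismatch, 1710
#' two-mismatch and 30,780 three-mismatch sequences.
#'
#' @inheritParams mismatch_probability
#' @return Numeric vector of counts.
#' @examples
#' mismatch_combinations(1:3, L = 20)
#' @export
mismatch_combinations <- function(n, L = 20L) {
  check_n_L(n, L)
  3^n * choose(L, n)
}

#' Tabulate the expected mismatch-count distribution of a doped library
#'
#' Tabulates [mismatch_probability()] and [mismatch_combinations()] for
#' `n = 0..n_max`; the probability mass beyond `n_max` is reported in the
#' `tail_probability` attribute so the full distribution accounts for 1.
#'
#' @inheritParams mismatch_probability
#' @param n_max Largest mismatch count tabulated (default 10, the practical
#'   upper bound of library representation at f = 0.15).
#' @return A tibble with columns `n`, `probability`, `combinations`, carrying
#'   attribute `tail_probability`.
#' @export
expected_mismatch_distribution <- function(L = 20L, f = 0.15, n_max = 10L) {
  n_max <- as.integer(n_max)
  if (n_max > L) {
    abort("`n_max` must be <= L.", class = "cas9profiler_domain_error")
  }
  n <- 0:n_max
  out <- tibble(
    n = n,
    probability = mismatch_probability(n, L, f),
    combinations = mismatch_combinations(n, L)
  )
  attr(out, "tail_probability") <- 1 - sum(out$probability)
  out
}

#' Write a mismatch-distribution table as TSV
#'
#' @param dist A tibble from [expected_mismatch_distribution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mismatch_distribution <- function(dist, path) {
  readr::write_tsv(dist, path)
  invisible(path)
}

check_n_L <- function(n, L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 || L != round(L)) {
    abort("`L` must be a positive integer.", class = "cas9profiler_domain_error")
  }
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) || any(n != round(n))) {
    abort("`n` must be nonnegative integer(s).",
          class = "cas9profiler_domain_error")
  }
  if (any(n > L)) {
    abort("`n` must not exceed `L`.", class = "cas9profiler_domain_error")
  }
  invisible(TRUE)
}
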