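#' Pool fractions from gel band intensities
#'
#' Converts supercoiled/nicked/linear band intensities into DNA mass
#' fractions: `fr_sc = I_SC / S`, `fr_n = I_N / S`, `fr_l = I_L / S` with
#' `S = I_SC + I_N + I_L`, and the cleaved fraction
#' `fr_c = (I_N + I_L) / S = 1 - fr_sc`. Accepts a single lane (three
#' scalars) or a lane table.
#'
#' @param lanes A data frame with columns `i_sc`, `i_n`, `i_l` (extra columns
#'   such as `t` or `replicate` are carried through), or a single numeric
#'   `i_sc` when `i_n`/`i_l` are given.
#' @param i_n,i_l Band intensities when `lanes` is a scalar intensity.
#' @return A tibble with `fr_sc`, `fr_n`, `fr_l`, `fr_c` appended (or
#'   computed from the scalars).
#' @examples
#' pool_fractions(1, 1, 2) # fr_c = 0.75
#' @export
pool_fractions <- function(lanes, i_n = NULL, i_l = NULL) {
  if (!is.data.frame(lanes)) {
    lanes <- tibble(i_sc = lanes, i_n = i_n, i_l = i_l)
  }
  need <- c("i_sc", "i_n", "i_l")
  if (!all(need %in% names(lanes))) {
    abort("lane table needs columns i_sc, i_n, i_l.",
          class = "cas9profiler_config_error")
  }
  if (any(lanes$i_sc < 0 | lanes$i_n < 0 | lanes$i_l < 0, na.rm = TRUE)) {
    abort("band intensities must be nonnegative.",
          class = "cas9profiler_domain_error")
  }
  total <- lanes$i_sc + lanes$i_n + lanes$i_l
  if (any(total <= 0)) {
    abort("all-zero lane: intensities sum to zero, lane unquantifiable.",
          class = "cas9profiler_data_error")
  }
  mutate(as_tibble(lanes),
         fr_sc = .data$i_sc / total,
         fr_n = .data$i_n / total,
         fr_l = .data$i_l / total,
         fr_c = (.data$i_n + .data$i_l) / total)
}

#' Fit an apparent cleavage rate by one-phase association
#'
#' Fits `FR(t) = FR_0 + (FR_final - FR_0) (1 - e^(-k t))` to a cleavage time
#' course by least squares. `FR_0` is fixed to the t = 0 (negative-control)
#' value and `FR_final` to the last-time-point value, leaving the apparent
#' rate constant `k >= 0` as the only free parameter; `free_plateau = TRUE`
#' additionally frees `FR_final` for sensitivity analysis.
#'
#' @param course A data frame with columns `t` (time) and either `fr_c` /
#'   `fr_l` (which one is chosen by `which`) or a generic `fr` column.
#'   Times must be unique and include `t = 0`; seconds are converted to
#'   minutes when `unit = "s"`.
#' @param which Fit the cleaved (`"cleaved"`, default) or linearized
#'   (`"linearized"`) fraction.
#' @param unit Time unit of `t` (`"min"` default, or `"s"`).
#' @param free_plateau Also fit the plateau instead of pinning it to the last
#'   time point.
#' @return An object of class `rate_fit`: `k` (per minute), `se_k`, `fr0`,
#'   `fr_final`, `rss`, `n_obs`, `degenerate` (TRUE when the series is flat
#'   and k is reported as 0), plus the fitted data. Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
fit_one_phase <- function(course, which = c("cleaved", "linearized"),
                          unit = c("min", "s"), free_plateau = FALSE) {
  which <- match.arg(which)
  unit <- match.arg(unit)
  course <- as_tibble(course)
  frcol <- if ("fr" %in% names(course)) "fr"
           else if (which == "cleaved") "fr_c" else "fr_l"
  if (!all(c("t", frcol) %in% names(course))) {
    abort(paste0("course needs columns `t` and `", frcol, "`."),
          class = "cas9profiler_config_error")
  }
  dat <- tibble(t = course$t, fr = course[[frcol]])
  if (unit == "s") dat$t <- dat$t / 60
  dat <- arrange(dat, .data$t)
  if (anyDuplicated(dat$t)) {
    dat <- dat |> group_by(.data$t) |>
      summarise(fr = mean(.data$fr), .groups = "drop")
  }
  if (nrow(dat) < 4L || !any(dat$t == 0)) {
    abort("need a t = 0 control plus at least 3 time points.",
          class = "cas9profiler_data_error")
  }
  fr0 <- dat$fr[dat$t == 0]
  fr_final <- dat$fr[nrow(dat)]

  if (isTRUE(all.equal(fr_final, fr0)) && var(dat$fr) < 1e-20) {
    fit <- rate_fit(k = 0, se_k = NA_real_, fr0 = fr0, fr_final = fr_final,
                    rss = 0, n_obs = nrow(dat), degenerate = TRUE,
                    data = dat, free_plateau = free_plateau)
    return(fit)
  }

  span <- fr_final - fr0
  # crude initial rate from the first point that moves appreciably
  moved <- which(abs(dat$fr - fr0) > 0.2 * abs(span) & dat$t > 0)
  k_start <- if (length(moved)) min(1 / dat$t[moved[1]], 50) else 0.1

  if (free_plateau) {
    fit <- minpack.lm::nlsLM(
      fr ~ fr0 + (plateau - fr0) * (1 - exp(-k * t)),
      data = dat, start = list(k = k_start, plateau = fr_final),
      lower = c(0, -Inf), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    )
    est <- summary(fit)$coefficients
    return(rate_fit(
      k = unname(est["k", "Estimate"]), se_k = unname(est["k", "Std. Error"]),
      fr0 = fr0, fr_final = unname(coef(fit)["plateau"]),
      rss = sum(stats::resid(fit)^2), n_obs = nrow(dat),
      degenerate = FALSE, data = dat, free_plateau = TRUE
    ))
  }

  # single free parameter: high-precision 1-D least squares
  solve_k <- function(plateau) {
    rss_of <- function(k) {
      sum((dat$fr - (fr0 + (plateau - fr0) * (1 - exp(-k * dat$t))))^2)
    }
    # the RSS is numerically flat for k far above the identifiable range, so
    # bracket the basin on a log grid before polishing with Brent's method
    k_hi <- max(200, 100 / min(dat$t[dat$t > 0]))
    ks <- c(0, exp(seq(log(1e-5), log(k_hi), length.out = 100)))
    vals <- vapply(ks, rss_of, numeric(1))
    i <- which.min(vals)
    lo <- ks[max(i - 1L, 1L)]
    hi <- ks[min(i + 1L, length(ks))]
    optimize(rss_of, interval = c(lo, hi), tol = 1e-12)
  }
  opt <- solve_k(fr_final)
  k <- opt$minimum
  rss <- opt$objective
  # gradient of the model in k; classical nls standard error
  g <- (fr_final - fr0) * dat$t * exp(-k * dat$t)
  df <- nrow(dat) - 1L
  sigma2 <- rss / df
  se_fit <- sqrt(sigma2 / sum(g^2))
  # the plateau is pinned to a noisy observation; propagate its variance
  # into the rate (delta method, dk/dFR_final by finite difference)
  h <- max(abs(fr_final - fr0), 0.01) * 1e-4
  dk_dplateau <- (solve_k(fr_final + h)$minimum -
                    solve_k(fr_final - h)$minimum) / (2 * h)
  se_k <- sqrt(se_fit^2 + dk_dplateau^2 * sigma2)
  rate_fit(k = k, se_k = se_k, fr0 = fr0, fr_final = fr_final,
           rss = rss, n_obs = nrow(dat),
           degenerate = FALSE, data = dat, free_plateau = FALSE)
}

rate_fit <- function(k, se_k, fr0, fr_final, rss, n_obs, degenerate, data,
                     free_plateau) {
  structure(
    list(k = k, se_k = se_k, fr0 = fr0, fr_final = fr_final, rss = rss,
         n_obs = n_obs, degenerate = degenerate, data = data,
         free_plateau = free_plateau),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> k =", signif(x$k, 4), "per min",
      if (!is.na(x$se_k)) paste0("(se ", signif(x$se_k, 3), ")"), "\n")
  cat("  FR_0 =", signif(x$fr0, 4), " FR_final =", signif(x$fr_final, 4),
      " RSS =", signif(x$rss, 4),
      if (x$degenerate) " [degenerate: flat series]", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = "k", estimate = x$k, std.error = x$se_k)
}

#' @export
glance.rate_fit <- function(x, ...) {
  tibble(k = x$k, se_k = x$se_k, fr0 = x$fr0, fr_final = x$fr_final,
         rss = x$rss, n_obs = x$n_obs, degenerate = x$degenerate)
}

#' Predict a one-phase association curve
#'
#' @param object A `rate_fit`.
#' @param t Times (minutes) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of fitted FR values.
#' @export
predict.rate_fit <- function(object, t = object$data$t, ...) {
  object$fr0 + (object$fr_final - object$fr0) * (1 - exp(-object$k * t))
}

#' Compare replicate cleavage rates between two groups
#'
#' Two-sample t-test of replicate measurements (e.g. fitted rates for a
#' variant vs a reference enzyme). Equal-variance Student's test by default;
#' `welch = TRUE` drops the equal-variance assumption. Two degenerate cases
#' the test statistic cannot express are handled by convention: identical
#' constant groups give `t = 0, p = 1`; distinct constant groups give
#' `t = Inf, p = 0`.
#'
#' @param values_a,values_b Numeric replicate measurements (>= 2 each).
#' @param welch Use Welch's unequal-variance test.
#' @param alpha Significance threshold reported alongside (default 0.05).
#' @return A tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `alpha`, `significant`.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE, alpha = 0.05) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("need at least 2 replicates per group.",
          class = "cas9profiler_data_error")
  }
  res <- tryCatch(
    t.test(values_a, values_b, var.equal = !welch),
    error = function(e) NULL
  )
  if (is.null(res)) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    stat <- if (same) 0 else Inf
    pval <- if (same) 1 else 0
    df <- length(values_a) + length(values_b) - 2L
  } else {
    stat <- unname(res$statistic)
    pval <- res$p.value
    df <- unname(res$parameter)
  }
  tibble(statistic = stat, p_value = pval, df = df,
         mean_a = mean(values_a), mean_b = mean(values_b),
         alpha = alpha, significant = pval < alpha)
}

#' Read a gel lane table from TSV
#'
#' Expected columns: `replicate`, `t`, `unit` (`"min"` or `"s"`), `i_sc`,
#' `i_n`, `i_l`. Times are normalized to minutes.
#'
#' @param path TSV file path.
#' @return A tibble with `t` in minutes plus the intensity columns.
#' @export
read_lane_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("t", "i_sc", "i_n", "i_l")
  if (!all(need %in% names(x))) {
    abort("lane table needs columns t, i_sc, i_n, i_l.",
          class = "cas9profiler_config_error")
  }
  if ("unit" %in% names(x)) {
    x$t <- ifelse(x$unit == "s", x$t / 60, x$t)
    x$unit <- NULL
  }
  x
}
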