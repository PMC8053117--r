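#' Fraction of pool reads carrying n mismatches
#'
#' `F_n` = total counts of sequences with exactly `n` mismatches divided by
#' total counts of all sequences in the pool.
#'
#' @param table A `target_count_table` (or any data frame with `count` and
#'   `n_mm`).
#' @param n Mismatch stratum (vectorized); `NULL` returns all strata present.
#' @return A tibble with columns `n` and `f` (fractions summing to 1 over
#'   all strata).
#' @export
mismatch_fraction <- function(table, n = NULL) {
  if (nrow(table) == 0L) {
    abort("empty count table.", class = "cas9profiler_data_error")
  }
  total <- sum(table$count)
  out <- table |>
    group_by(n = .data$n_mm) |>
    summarise(f = sum(.data$count) / total, .groups = "drop") |>
    arrange(.data$n)
  if (!is.null(n)) {
    out <- left_join(tibble(n = as.integer(n)), out, by = "n") |>
      mutate(f = dplyr::coalesce(.data$f, 0))
  }
  out
}

#' Estimated abundance: read fraction scaled by pool DNA mass
#'
#' `EA_n = F_n * FR`, where `FR` is the DNA mass fraction of the sequenced
#' pool (supercoiled or nicked) at that time point, from gel quantification.
#' Summed over strata, `sum(EA_n) = FR`.
#'
#' @param f Numeric vector of mismatch-stratum fractions `F_n`.
#' @param fr Pool DNA mass fraction in \[0, 1\].
#' @return Numeric vector of estimated abundances.
#' @export
estimated_abundance <- function(f, fr) {
  if (any(is.na(fr)) || any(fr < 0 | fr > 1)) {
    abort("`fr` must be in [0, 1]; missing FR for this lane.",
          class = "cas9profiler_data_error")
  }
  f * fr
}

#' Relative abundance versus the negative control
#'
#' `RA = EA_t / EA_control`; values below 1 mark depletion, above 1
#' enrichment. Strata absent from the control (control EA = 0) are undefined
#' and returned as `NA`, never infinity.
#'
#' @param ea Estimated abundance at time t.
#' @param ea_control Estimated abundance in the untreated control.
#' @return Numeric vector of relative abundances.
#' @export
relative_abundance <- function(ea, ea_control) {
  m <- max(length(ea), length(ea_control))
  ea <- rep_len(ea, m)
  ea_control <- rep_len(ea_control, m)
  ifelse(ea_control > 0, ea / ea_control, NA_real_)
}

#' Log2 fold change of a relative abundance
#'
#' `log2(RA)`. Exact zeros (complete depletion) are floored at a configurable
#' sentinel so heatmaps remain finite; floored values are flagged via the
#' `floored` attribute.
#'
#' @param ra Relative abundances (`>= 0` or `NA`).
#' @param floor Value substituted for `RA = 0` before taking logs. The
#'   default, half the smallest positive RA observed (or 1e-6 if none),
#'   keeps floored cells below every measured value.
#' @return Numeric vector of log2 fold changes with attribute `floored`.
#' @export
log_fold_change <- function(ra, floor = NULL) {
  if (any(ra < 0, na.rm = TRUE)) {
    abort("negative relative abundance.", class = "cas9profiler_domain_error")
  }
  floored <- !is.na(ra) & ra == 0
  if (is.null(floor)) {
    pos <- ra[!is.na(ra) & ra > 0]
    floor <- if (length(pos)) min(pos) / 2 else 1e-6
  }
  out <- log2(ifelse(floored, floor, ra))
  attr(out, "floored") <- floored
  out
}

#' Aggregate off-target relative abundance over 1-5 mismatch strata
#'
#' Ratio of sums: `RA_1-5 = sum(EA_n at t, n = 1..5) / sum(EA_n in control)`.
#'
#' @param ea A numeric vector of per-stratum EA at time t, named or indexed
#'   by `n` via the `n` argument.
#' @param ea_control Matching control EAs.
#' @param n Stratum indices aligned with `ea` (default `seq_along(ea)` i.e.
#'   values 1..5 when five strata are passed).
#' @param strata Which strata to aggregate (default 1:5).
#' @return A single relative abundance (NA when the control sum is zero).
#' @export
off_target_abundance <- function(ea, ea_control, n = seq_along(ea),
                                 strata = 1:5) {
  keep <- n %in% strata
  num <- sum(ea[keep])
  den <- sum(ea_control[keep])
  if (!any(keep) || den <= 0) return(NA_real_)
  num / den
}

#' On- and off-target cleaved fractions from relative abundances
#'
#' `on = 1 - RA_0MM`, `off = 1 - RA_1-5MM`. Negative values (enrichment
#' beyond the control) are kept as-is and flagged.
#'
#' @param ra_0mm Relative abundance of the perfect target.
#' @param ra_off Aggregate 1-5 mismatch relative abundance.
#' @return A tibble: `on`, `off`, `on_flagged`, `off_flagged`.
#' @export
cleaved_fractions <- function(ra_0mm, ra_off) {
  on <- 1 - ra_0mm
  off <- 1 - ra_off
  tibble(on = on, off = off,
         on_flagged = !is.na(on) & on < 0,
         off_flagged = !is.na(off) & off < 0)
}

#' Specificity score: on-target over off-target cleaved fraction
#'
#' `SS = on / off`. Undefined (NA) when the off-target cleaved fraction is
#' zero; negative off-target values yield a score flagged unreliable.
#'
#' @param on,off Cleaved fractions from [cleaved_fractions()].
#' @return A tibble: `ss`, `unreliable`.
#' @export
specificity_score <- function(on, off) {
  ss <- ifelse(!is.na(off) & off != 0, on / off, NA_real_)
  tibble(ss = ss, unreliable = !is.na(off) & off < 0)
}

#' Relative specificity of a variant versus a reference enzyme
#'
#' Per-time ratio of specificity scores with first-order (quadrature) error
#' propagation of the SEMs:
#' `sem(ratio)/ratio = sqrt((sem_v/ss_v)^2 + (sem_r/ss_r)^2)`.
#'
#' @param ss_variant,ss_reference Data frames with columns `time`, `ss` and
#'   optionally `sem`.
#' @return A tibble: `time`, `relative_ss`, `sem`.
#' @export
relative_specificity <- function(ss_variant, ss_reference) {
  v <- as_tibble(ss_variant)
  r <- as_tibble(ss_reference)
  if (!"sem" %in% names(v)) v$sem <- NA_real_
  if (!"sem" %in% names(r)) r$sem <- NA_real_
  j <- inner_join(v, r, by = "time", suffix = c("_v", "_r"))
  j |>
    mutate(
      relative_ss = .data$ss_v / .data$ss_r,
      sem = abs(.data$relative_ss) *
        sqrt((.data$sem_v / .data$ss_v)^2 + (.data$sem_r / .data$ss_r)^2)
    ) |>
    select("time", "relative_ss", "sem")
}

#' Mismatch-stratified abundance course for one pool
#'
#' Computes, per time point, the stratum fractions `F_n`, estimated
#' abundances `EA_n = F_n * FR`, relative abundances `RA_n` against the
#' matched-pool t = 0 control, and `log2(RA_n)`.
#'
#' @param counts A count table covering one pool over several time points
#'   (columns `pool`, `time`, `sequence`, `count`, `n_mm`), e.g. rows of a
#'   simulation truth table or stacked [extract_variable_regions()] outputs.
#' @param fr A tibble of pool DNA mass fractions: columns `pool`, `time`,
#'   `fr` (as produced in `cas_run$fr`, or assembled from
#'   [pool_fractions()]).
#' @param n_max Strata 0..n_max are always tabulated (default 10); strata
#'   beyond it are included whenever the pool contains such sequences, so
#'   the fractions always sum to 1.
#' @return A tibble: `pool`, `time`, `n`, `f`, `ea`, `ra`, `log2fc`.
#' @export
abundance_course <- function(counts, fr, n_max = 10L) {
  counts <- as_tibble(counts)
  need <- c("pool", "time", "count", "n_mm")
  if (!all(need %in% names(counts))) {
    abort("counts need columns pool, time, count, n_mm.",
          class = "cas9profiler_config_error")
  }
  strata <- 0:max(n_max, counts$n_mm)
  out <- counts |>
    group_by(.data$pool, .data$time) |>
    dplyr::group_modify(function(g, key) {
      mismatch_fraction(g, n = strata)
    }) |>
    ungroup()
  out <- left_join(out, as_tibble(fr), by = c("pool", "time"))
  if (any(is.na(out$fr))) {
    bad <- distinct(filter(out, is.na(.data$fr)), .data$pool, .data$time)
    abort(paste0("missing FR for lane(s): ",
                 paste(paste0(bad$pool, "@t=", bad$time), collapse = ", ")),
          class = "cas9profiler_data_error")
  }
  out <- out |>
    mutate(ea = estimated_abundance(.data$f, .data$fr)) |>
    group_by(.data$pool, .data$n) |>
    mutate(ra = relative_abundance(.data$ea, .data$ea[.data$time == 0])) |>
    ungroup()
  out$log2fc <- as.numeric(log_fold_change(out$ra))
  select(out, "pool", "time", "n", "f", "ea", "ra", "log2fc")
}

#' Specificity-score time course from a supercoiled-pool abundance course
#'
#' Collapses an [abundance_course()] of the supercoiled pool into per-time
#' on-target (`1 - RA_0MM`) and off-target (`1 - RA_1-5MM`) cleaved
#' fractions and their ratio, the specificity score. The off-target
#' aggregate is a ratio of summed estimated abundances over the 1-5 mismatch
#' strata.
#'
#' @param course An [abundance_course()] tibble (supercoiled pool rows are
#'   used; pass `pool_label` to pick a different pool).
#' @param pool_label Pool to score (default `"supercoiled"`).
#' @param strata Off-target strata (default 1:5).
#' @return A tibble: `time`, `ra_on`, `ra_off`, `on`, `off`, `ss`.
#' @export
specificity_course <- function(course, pool_label = "supercoiled",
                               strata = 1:5) {
  sc <- filter(as_tibble(course), .data$pool == pool_label)
  if (nrow(sc) == 0L) {
    abort(paste0("no rows for pool '", pool_label, "'."),
          class = "cas9profiler_data_error")
  }
  ctrl <- filter(sc, .data$time == 0)
  out <- sc |>
    group_by(.data$time) |>
    summarise(
      ra_on = relative_abundance(.data$ea[.data$n == 0],
                                 ctrl$ea[ctrl$n == 0]),
      ra_off = off_target_abundance(.data$ea[.data$n %in% strata],
                                    ctrl$ea[ctrl$n %in% strata],
                                    n = .data$n[.data$n %in% strata],
                                    strata = strata),
      .groups = "drop"
    )
  cf <- cleaved_fractions(out$ra_on, out$ra_off)
  ss <- specificity_score(cf$on, cf$off)
  bind_cols(out, cf[c("on", "off")], ss["ss"])
}
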