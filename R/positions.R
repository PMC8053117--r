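#' Position-by-nucleotide relative abundance over time
#'
#' For every combination of nucleotide `N`, PAM-proximal position `P`,
#' mismatch stratum `n` and time point, computes the estimated abundance of
#' pool sequences carrying `N` at `P` among `n`-mismatch sequences
#' (`EA = count fraction * FR`), then the relative abundance against the
#' same cell in the t = 0 original library. Cells where `N` equals the
#' reference base are canonical base pairs: computed, but flagged so plots
#' can grey them out. Cells absent from the control are `NA`, never 0/0.
#'
#' @param counts Count table with columns `pool`, `time`, `sequence`,
#'   `count` (e.g. a `cas_run$truth` or stacked extraction outputs),
#'   covering the t = 0 control.
#' @param fr Pool DNA mass fractions (`pool`, `time`, `fr`).
#' @param spec A [target_spec()].
#' @param strata Mismatch strata analyzed (default 1:5).
#' @return A tibble of class `position_matrix`: `pool`, `n`, `position`,
#'   `nucleotide`, `label` (crRNA:DNA pair), `canonical`, `time`, `ea`, `ra`.
#' @export
positional_abundance <- function(counts, fr, spec, strata = 1:5) {
  counts <- as_tibble(counts)
  fr <- as_tibble(fr)
  seqs <- unique(counts$sequence)
  ann <- annotate_sequences(seqs, spec)
  L <- spec$length
  # character matrix in PAM-proximal column order
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  if (spec$pam_side == "3prime") mat <- mat[, L:1, drop = FALSE]
  ref_pos <- spacer_positions(spec)$ref_base

  groups <- distinct(counts, .data$pool, .data$time)
  cells <- purrr::pmap(groups, function(pool, time) {
    g <- counts[counts$pool == pool & counts$time == time, ]
    cnt <- setNames(rep(0, length(seqs)), seqs)
    cnt[g$sequence] <- g$count
    total <- sum(cnt)
    fr_here <- fr$fr[fr$pool == pool & fr$time == time]
    if (length(fr_here) != 1L || is.na(fr_here)) {
      abort(paste0("missing FR for ", pool, " @t=", time),
            class = "cas9profiler_data_error")
    }
    purrr::map(strata, function(nn) {
      rows <- ann$n_mm == nn
      sub <- mat[rows, , drop = FALSE]
      w <- cnt[rows]
      ea <- purrr::map(DNA_BASES, function(N) {
        hits <- (sub == N) * w
        colSums(hits) / max(total, 1) * fr_here
      })
      tibble(
        pool = pool, n = nn, time = time,
        position = rep(seq_len(L), times = 4L),
        nucleotide = rep(DNA_BASES, each = L),
        ea = unlist(ea)
      )
    }) |> bind_rows()
  }) |> bind_rows()

  out <- cells |>
    group_by(.data$pool, .data$n, .data$position, .data$nucleotide) |>
    mutate(ra = relative_abundance(.data$ea, .data$ea[.data$time == 0])) |>
    ungroup() |>
    mutate(
      canonical = .data$nucleotide == ref_pos[.data$position],
      label = rna_dna_label(ref_pos[.data$position], .data$nucleotide)
    ) |>
    select("pool", "n", "position", "nucleotide", "label", "canonical",
           "time", "ea", "ra") |>
    arrange(.data$pool, .data$n, .data$position, .data$nucleotide, .data$time)
  class(out) <- c("position_matrix", class(out))
  out
}

#' Maximum per-interval depletion rate of a relative-abundance series
#'
#' Over consecutive time pairs, `max((RA[T-1] - RA[T]) / (t[T] - t[T-1]))`:
#' positive values mark depletion. Missing observations are dropped and
#' slopes run between the surviving neighbours; series with fewer than two
#' defined values return `NA`.
#'
#' @param ra Relative abundances ordered with `t`.
#' @param t Time points (>= 2).
#' @return A single rate (per time unit).
#' @export
delta_max <- function(ra, t) {
  sl <- interval_slopes(ra, t)
  if (all(is.na(sl))) return(NA_real_)
  max(-sl, na.rm = TRUE)
}

#' Average per-interval change of a relative-abundance series
#'
#' Mean of consecutive-pair slopes `(RA[T] - RA[T-1]) / (t[T] - t[T-1])`:
#' positive values mark accumulation, negative depletion.
#'
#' @inheritParams delta_max
#' @return A single rate (per time unit).
#' @export
delta_avg <- function(ra, t) {
  sl <- interval_slopes(ra, t)
  if (all(is.na(sl))) return(NA_real_)
  mean(sl, na.rm = TRUE)
}

interval_slopes <- function(ra, t) {
  if (length(t) < 2L) {
    abort("need at least 2 time points.", class = "cas9profiler_data_error")
  }
  o <- order(t)
  ra <- ra[o]; t <- t[o]
  # missing observations are dropped; slopes run between surviving neighbours
  ok <- !is.na(ra)
  if (sum(ok) < 2L) return(NA_real_)
  diff(ra[ok]) / diff(t[ok])
}

#' Extent of cleavage or nicking across the time course
#'
#' Per-cell minimum RA (supercoiled pool: how far a sequence was depleted,
#' the extent of cleavage) or maximum RA (nicked pool: how strongly a
#' sequence accumulated as nicked).
#'
#' @inheritParams delta_max
#' @param pool `"supercoiled"` (min) or `"nicked"` (max).
#' @return A single extent value (`NA` if all values missing).
#' @export
extent_abundance <- function(ra, pool = c("supercoiled", "nicked")) {
  pool <- match.arg(pool)
  if (all(is.na(ra))) return(NA_real_)
  if (pool == "supercoiled") min(ra, na.rm = TRUE) else max(ra, na.rm = TRUE)
}

#' Per-cell bubble-heatmap statistics
#'
#' Collapses a [positional_abundance()] matrix into one row per
#' (pool, stratum, position, nucleotide) cell: a rate metric (max per-interval
#' depletion for the supercoiled pool over the full grid including t = 0;
#' mean per-interval change for the nicked pool over post-cleavage times
#' only) and an extent metric (minimum RA for supercoiled, maximum RA for
#' nicked). Extent normalization across a comparison set is a separate step,
#' [normalize_extents()].
#'
#' @param pm A `position_matrix` tibble (may contain both pools).
#' @return A tibble: grouping columns plus `rate_metric`, `extent`.
#' @export
bubble_summary <- function(pm) {
  pm <- as_tibble(pm)
  pm |>
    group_by(.data$pool, .data$n, .data$position, .data$nucleotide,
             .data$label, .data$canonical) |>
    summarise(
      rate_metric = if (first(.data$pool) == "supercoiled") {
        delta_max(.data$ra, .data$time)
      } else {
        keep <- .data$time > 0
        delta_avg(.data$ra[keep], .data$time[keep])
      },
      extent = extent_abundance(.data$ra, first(.data$pool)),
      .groups = "drop"
    )
}

#' Normalize extent metrics across a comparison set
#'
#' Divides every extent by the global maximum over the whole comparison set
#' (all libraries, enzymes and strata supplied), so normalized extents lie
#' in \[0, 1\] and the argmax cell maps to exactly 1.
#'
#' @param ... Bubble-summary tibbles (or a single list of them), each with
#'   an `extent` column; an identifying `set` label is added from argument
#'   names when provided.
#' @return One combined tibble with `extent_normalized` added.
#' @export
normalize_extents <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  nm <- names(dots) %||% rep("", length(dots))
  nm[nm == ""] <- paste0("set", seq_along(dots))[nm == ""]
  all <- bind_rows(purrr::map2(dots, nm, function(d, set_label) {
    d <- as_tibble(d)
    d$set <- set_label
    select(d, "set", dplyr::everything())
  }))
  gmax <- suppressWarnings(max(all$extent, na.rm = TRUE))
  if (!is.finite(gmax) || gmax <= 0) {
    abort("degenerate comparison set: global maximum extent is not positive.",
          class = "cas9profiler_data_error")
  }
  mutate(all, extent_normalized = .data$extent / gmax)
}
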