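#' Distance between two mismatch positions
#'
#' Number of intervening nucleotides: adjacent mismatches are distance 0,
#' and mismatches at the two ends of a 20-nt target are distance 18.
#'
#' @param p1,p2 Mismatch positions with `p1 < p2` (vectorized).
#' @return Integer distances `p2 - p1 - 1`.
#' @examples
#' pair_distance(1, 2)  # 0
#' pair_distance(1, 20) # 18
#' @export
pair_distance <- function(p1, p2) {
  if (any(p1 >= p2)) {
    abort("`p1` must be strictly less than `p2`.",
          class = "cas9profiler_domain_error")
  }
  if (any(p1 < 1)) {
    abort("positions start at 1.", class = "cas9profiler_domain_error")
  }
  as.integer(p2 - p1 - 1L)
}

#' Number of two-mismatch configurations at a given spacing
#'
#' Within a span of `span_len` positions there are `span_len - 1 - d`
#' position pairs separated by `d` intervening nucleotides, each with
#' `3 x 3` substitute-base identities, so
#' `ways = 9 * (span_len - 1 - d)`. Dividing raw distance-class counts by
#' this removes the combinatorial advantage of small spacings; summed over
#' `d` the ways reproduce the total two-mismatch sequence count
#' (`1710` for a 20-nt target).
#'
#' @param d Distances (vectorized), `>= 0`.
#' @param span_len Length of the span the two mismatches live in
#'   (20 for the whole target, `seed_len` for the seed scope).
#' @return Numeric counts (0 when the span cannot hold the spacing).
#' @export
pair_ways <- function(d, span_len = 20L) {
  if (any(d < 0)) abort("`d` must be >= 0.", class = "cas9profiler_domain_error")
  pmax(9 * (span_len - 1 - d), 0)
}

#' Two-mismatch spacing profile of a cleavage time course
#'
#' Restricts the count tables to two-mismatch sequences, groups counts by the
#' distance between the two mismatches, optionally restricted to pairs lying
#' entirely inside the seed or the PAM-distal region, then computes
#' per-distance estimated and relative abundance against the t = 0 control
#' (ways-normalized counts are carried alongside; the normalization cancels
#' in the RA ratio but makes raw distance histograms comparable). Per-pool
#' rate and extent metrics follow the same conventions as the
#' position-by-nucleotide analysis.
#'
#' @param counts Count table (`pool`, `time`, `sequence`, `count`) including
#'   the t = 0 control.
#' @param fr Pool DNA mass fractions (`pool`, `time`, `fr`).
#' @param spec A [target_spec()].
#' @param scope `"whole"` (default), `"seed"` or `"distal"`. Scoped analyses
#'   require both mismatches inside the span and cap the distance at 8.
#' @param d_cap Maximum distance reported for scoped analyses (default 8).
#' @return A tibble of class `pair_spacing`: `scope`, `pool`, `time`, `d`,
#'   `count`, `ways`, `normalized_count`, `ea`, `ra`.
#' @export
spacing_profile <- function(counts, fr, spec,
                            scope = c("whole", "seed", "distal"),
                            d_cap = 8L) {
  scope <- match.arg(scope)
  counts <- as_tibble(counts)
  fr <- as_tibble(fr)
  seqs <- unique(counts$sequence)
  ann <- annotate_sequences(seqs, spec)
  two <- which(ann$n_mm == 2L)
  pos <- ann$mm_pos[two]
  p1 <- vapply(pos, min, numeric(1))
  p2 <- vapply(pos, max, numeric(1))
  span <- switch(scope,
    whole = c(1L, 20L),
    seed = c(1L, spec$seed_len),
    distal = c(spec$seed_len + 1L, 20L)
  )
  span_len <- span[2] - span[1] + 1L
  in_span <- p1 >= span[1] & p2 <= span[2]
  keep_seqs <- seqs[two][in_span]
  d_seq <- pair_distance(p1[in_span], p2[in_span])
  d_max <- if (scope == "whole") span_len - 2L else min(d_cap, span_len - 2L)
  sel <- d_seq <= d_max
  keep_seqs <- keep_seqs[sel]
  d_seq <- d_seq[sel]
  d_of <- setNames(d_seq, keep_seqs)

  grid <- crossing(distinct(counts, .data$pool, .data$time),
                   d = 0:d_max)
  totals <- counts |>
    group_by(.data$pool, .data$time) |>
    summarise(total = sum(.data$count), .groups = "drop")
  by_d <- counts |>
    filter(.data$sequence %in% keep_seqs) |>
    mutate(d = d_of[.data$sequence]) |>
    group_by(.data$pool, .data$time, .data$d) |>
    summarise(count = sum(.data$count), .groups = "drop")
  out <- grid |>
    left_join(by_d, by = c("pool", "time", "d")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    left_join(totals, by = c("pool", "time")) |>
    left_join(fr, by = c("pool", "time")) |>
    mutate(
      ways = pair_ways(.data$d, span_len),
      normalized_count = ifelse(.data$ways > 0, .data$count / .data$ways,
                                NA_real_),
      ea = .data$count / .data$total * .data$fr
    ) |>
    group_by(.data$pool, .data$d) |>
    mutate(ra = relative_abundance(.data$ea, .data$ea[.data$time == 0])) |>
    ungroup() |>
    mutate(scope = scope, .before = 1) |>
    select("scope", "pool", "time", "d", "count", "ways",
           "normalized_count", "ea", "ra") |>
    arrange(.data$pool, .data$d, .data$time)
  class(out) <- c("pair_spacing", class(out))
  out
}

#' Per-distance bubble statistics for a spacing profile
#'
#' Rate metric (max depletion slope for supercoiled, mean post-cleavage
#' slope for nicked) and extent (min / max RA) per distance class, as in
#' [bubble_summary()].
#'
#' @param profile A `pair_spacing` tibble from [spacing_profile()].
#' @return A tibble: `scope`, `pool`, `d`, `rate_metric`, `extent`.
#' @export
spacing_summary <- function(profile) {
  as_tibble(profile) |>
    group_by(.data$scope, .data$pool, .data$d) |>
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
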