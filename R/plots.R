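#' Plot supercoiled/nicked/linear pool kinetics
#'
#' Time course of the three gel pools (as DNA mass fractions), the standard
#' view of a plasmid cleavage assay.
#'
#' @param lanes A lane table (`t`, `i_sc`, `i_n`, `i_l`), e.g. from
#'   [render_gel()] or [read_lane_table()].
#' @return A ggplot object.
#' @export
plot_cleavage_course <- function(lanes) {
  fr <- pool_fractions(lanes) |>
    select("t", "fr_sc", "fr_n", "fr_l") |>
    pivot_longer(-"t", names_to = "pool", values_to = "fraction") |>
    mutate(pool = dplyr::recode(.data$pool, fr_sc = "supercoiled",
                                fr_n = "nicked", fr_l = "linear"))
  ggplot2::ggplot(fr, ggplot2::aes(.data$t, .data$fraction,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(supercoiled = "#1b9e77",
                                            nicked = "#d95f02",
                                            linear = "#7570b3")) +
    ggplot2::labs(x = "time (min)", y = "fraction of DNA", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of log2 fold change by mismatch stratum and time
#'
#' Depletion (negative, red) and accumulation (positive, blue) of mismatch
#' strata relative to the untreated control.
#'
#' @param course An [abundance_course()] tibble.
#' @param n_max Largest stratum drawn (default 5).
#' @return A ggplot object.
#' @export
plot_fold_change_heatmap <- function(course, n_max = 5L) {
  d <- filter(as_tibble(course), .data$n <= n_max, .data$time > 0)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$time), factor(.data$n),
                                  fill = .data$log2fc)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_wrap(~pool) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "time (min)", y = "mismatches",
                  fill = "log2 fold\nchange") +
    ggplot2::theme_minimal()
}

#' Plot specificity scores over time
#'
#' @param specificity A [specificity_course()] tibble, or a named list of
#'   them (one per enzyme).
#' @return A ggplot object.
#' @export
plot_specificity_course <- function(specificity) {
  if (is.data.frame(specificity)) specificity <- list(enzyme = specificity)
  d <- bind_rows(purrr::imap(specificity, function(s, nm) {
    mutate(as_tibble(s), enzyme = nm)
  }))
  d <- filter(d, .data$time > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$ss,
                                  colour = .data$enzyme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (min)", y = "specificity score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bubble heatmap of positional cleavage/nicking statistics
#'
#' Colour encodes the rate metric (max depletion slope for the supercoiled
#' pool, mean change for the nicked pool), bubble size the normalized extent
#' metric, one panel per mismatch stratum; canonical cells are dropped.
#'
#' @param bubbles A [normalize_extents()] output (with `extent_normalized`).
#' @param pool_label Which pool to draw (default `"supercoiled"`).
#' @return A ggplot object.
#' @export
plot_bubble_heatmap <- function(bubbles, pool_label = "supercoiled") {
  d <- filter(as_tibble(bubbles), .data$pool == pool_label,
              !.data$canonical, !is.na(.data$extent_normalized))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$position), .data$label,
                                  colour = .data$rate_metric,
                                  size = .data$extent_normalized)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(set ~ n) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b", midpoint = 0) +
    ggplot2::scale_size(range = c(0, 3), limits = c(0, 1)) +
    ggplot2::labs(x = "position (1 = PAM-proximal)", y = "crRNA:DNA pair",
                  colour = "rate", size = "extent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a one-phase association rate fit
#'
#' Observed fractions with the fitted exponential overlaid.
#'
#' @param object A [fit_one_phase()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_fit <- function(object, ...) {
  grid <- tibble(t = seq(0, max(object$data$t), length.out = 200))
  grid$fr <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$t, .data$fr)) +
    ggplot2::geom_line(data = grid, colour = "#d95f02") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "fraction cleaved",
                  subtitle = sprintf("k = %.3g per min", object$k)) +
    ggplot2::theme_minimal()
}
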