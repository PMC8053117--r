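#' Run the full specificity-profiling pipeline
#'
#' Orchestrates simulate -> extract -> gel quantification -> mismatch
#' abundance -> specificity -> position and two-mismatch analyses for one or
#' more enzymes against one target, writing tidy TSVs (and optionally plots)
#' to an output directory. With identical seeds the outputs are
#' byte-identical across reruns.
#'
#' @param config A YAML path or a nested list with entries:
#'   `target` (`protospacer`, `pam`, `pam_side`, `seed_len`), `doping`
#'   (`f`), `simulate` (`time_points`, `depth`, `n_members`, `prep_nick`,
#'   `seed`, `render_fastq`), `enzymes` (named list; each `"wt"`, `"hf"`, or
#'   a list of [variant_profile()] arguments), `reference_enzyme`,
#'   `out_dir`, `strata` (default 1:5), `plots` (logical).
#' @return (Invisibly) a list of class `cas_report`: per-enzyme runs, count
#'   tables, abundance and specificity courses, relative specificity versus
#'   the reference, normalized bubble summaries, spacing summaries, and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  tg <- cfg$target
  if (is.null(tg$protospacer)) {
    abort("config$target$protospacer is required.",
          class = "cas9profiler_config_error")
  }
  spec <- target_spec(tg$protospacer, pam = tg$pam %||% "NGG",
                      pam_side = tg$pam_side %||% "3prime",
                      seed_len = tg$seed_len %||% 10L)
  scheme <- doping_scheme(cfg$doping$f %||% 0.15)
  sim <- cfg$simulate %||% list()
  time_points <- sim$time_points %||% c(0, 1, 5, 30, 60, 180)
  depth <- sim$depth %||% 20000L
  n_members <- sim$n_members %||% 20000L
  prep_nick <- sim$prep_nick %||% 0.05
  seed <- sim$seed %||% 1L
  render_fastq <- isTRUE(sim$render_fastq)
  strata <- cfg$strata %||% 1:5
  out_dir <- cfg$out_dir %||% tempfile("cas9profiler_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  enzymes <- cfg$enzymes %||% list(WT = "wt", HF = "hf")
  if (is.null(names(enzymes)) || any(names(enzymes) == "")) {
    abort("config$enzymes must be a named list.",
          class = "cas9profiler_config_error")
  }
  reference <- cfg$reference_enzyme %||% names(enzymes)[1]
  if (!reference %in% names(enzymes)) {
    abort(paste0("reference enzyme '", reference, "' not among enzymes."),
          class = "cas9profiler_config_error")
  }

  results <- purrr::imap(enzymes, function(ez, name) {
    profile <- resolve_profile(ez, seed_len = spec$seed_len)
    run <- simulate_cleavage_run(
      spec, scheme, profile, time_points = time_points, depth = depth,
      n_members = n_members, prep_nick = prep_nick,
      seed = seed + match(name, names(enzymes))
    )
    counts <- if (render_fastq) {
      fq_dir <- file.path(out_dir, paste0("fastq_", name))
      manifest <- render_reads(run, fq_dir)
      bind_rows(purrr::pmap(manifest, function(pool, time, path, n_reads) {
        extract_variable_regions(path, spec, pool = pool, time = time)
      }))
    } else {
      run$truth
    }
    course <- abundance_course(counts, run$fr)
    specs <- specificity_course(course)
    pm <- positional_abundance(counts, run$fr, spec, strata = strata)
    bubbles <- bubble_summary(pm)
    spacing <- bind_rows(
      spacing_summary(spacing_profile(counts, run$fr, spec, "whole")),
      spacing_summary(spacing_profile(counts, run$fr, spec, "seed")),
      spacing_summary(spacing_profile(counts, run$fr, spec, "distal"))
    )
    list(run = run, counts = counts, abundance = course,
         specificity = specs, bubbles = bubbles, spacing = spacing)
  })

  rel <- purrr::imap(results[names(results) != reference], function(r, name) {
    mutate(relative_specificity(r$specificity,
                                results[[reference]]$specificity),
           enzyme = name, reference = reference, .before = 1)
  }) |> bind_rows()

  bubbles_norm <- normalize_extents(
    purrr::map(results, function(r) filter(r$bubbles, !.data$canonical))
  )

  paths <- write_report(results, rel, bubbles_norm, out_dir)
  if (isTRUE(cfg$plots)) {
    paths <- c(paths, write_plots(results, bubbles_norm, out_dir))
  }
  log <- list(seed = seed, depth = depth, n_members = n_members,
              time_points = time_points, prep_nick = prep_nick,
              enzymes = names(enzymes), reference = reference,
              package_version = as.character(utils::packageVersion("cas9profiler")))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  invisible(structure(
    list(results = results, relative_specificity = rel,
         bubbles = bubbles_norm, out_dir = out_dir, paths = paths,
         spec = spec, config = cfg),
    class = "cas_report"
  ))
}

resolve_profile <- function(ez, seed_len) {
  if (inherits(ez, "variant_profile")) return(ez)
  if (is.character(ez)) {
    return(switch(tolower(ez),
      wt = wt_profile(seed_len),
      hf = hf_profile(seed_len),
      abort(paste0("unknown enzyme preset '", ez, "'."),
            class = "cas9profiler_config_error")
    ))
  }
  do.call(variant_profile, c(ez, list(seed_len = seed_len)))
}

write_report <- function(results, rel, bubbles_norm, out_dir) {
  paths <- character()
  for (name in names(results)) {
    r <- results[[name]]
    p <- file.path(out_dir, paste0(name, c("_counts.tsv", "_gel.tsv",
                                           "_abundance.tsv",
                                           "_specificity.tsv",
                                           "_spacing.tsv")))
    readr::write_tsv(select(as_tibble(r$counts), -dplyr::any_of("mm_pos")), p[1])
    readr::write_tsv(render_gel(r$run), p[2])
    readr::write_tsv(r$abundance, p[3])
    readr::write_tsv(r$specificity, p[4])
    readr::write_tsv(r$spacing, p[5])
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, c("relative_specificity.tsv",
                            "bubble_summary.tsv"))
  readr::write_tsv(rel, p[1])
  readr::write_tsv(bubbles_norm, p[2])
  c(paths, p)
}

write_plots <- function(results, bubbles_norm, out_dir) {
  paths <- character()
  for (name in names(results)) {
    r <- results[[name]]
    p1 <- file.path(out_dir, paste0(name, "_kinetics.png"))
    ggplot2::ggsave(p1, plot_cleavage_course(render_gel(r$run)),
                    width = 6, height = 4, dpi = 120)
    p2 <- file.path(out_dir, paste0(name, "_log2fc.png"))
    ggplot2::ggsave(p2, plot_fold_change_heatmap(r$abundance),
                    width = 6, height = 4, dpi = 120)
    paths <- c(paths, p1, p2)
  }
  p3 <- file.path(out_dir, "bubble_heatmap.png")
  ggplot2::ggsave(p3, plot_bubble_heatmap(bubbles_norm),
                  width = 10, height = 6, dpi = 120)
  c(paths, p3)
}

#' @export
print.cas_report <- function(x, ...) {
  cat("<cas_report>", length(x$results), "enzyme(s);",
      "outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Validate the internal consistency of a pipeline report
#'
#' Re-asserts the framework identities on a completed report: stratum
#' fractions summing to 1, estimated abundances summing to the pool FR,
#' control relative abundances of 1 (log2 fold change 0), nonnegative
#' counts, and normalized extents in \[0, 1\] with the argmax at 1.
#' Failures are reported, not raised.
#'
#' @param report A `cas_report` from [run_pipeline()].
#' @param tol Numeric tolerance for the sum identities.
#' @return A tibble: `check`, `enzyme`, `pass`, `detail`.
#' @export
validate_run <- function(report, tol = 1e-9) {
  checks <- list()
  add <- function(check, enzyme, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(
      check = check, enzyme = enzyme, pass = pass, detail = detail)
  }
  for (name in names(report$results)) {
    r <- report$results[[name]]
    ab <- r$abundance
    fsum <- ab |> group_by(.data$pool, .data$time) |>
      summarise(s = sum(.data$f), .groups = "drop")
    add("stratum fractions sum to 1", name,
        all(abs(fsum$s - 1) < 1e-6),
        sprintf("max |sum-1| = %.3g", max(abs(fsum$s - 1))))
    easum <- ab |> group_by(.data$pool, .data$time) |>
      summarise(s = sum(.data$ea), .groups = "drop") |>
      left_join(r$run$fr, by = c("pool", "time"))
    add("estimated abundances sum to FR", name,
        all(abs(easum$s - easum$fr) < 1e-6),
        sprintf("max |sum-FR| = %.3g", max(abs(easum$s - easum$fr))))
    ctrl <- filter(ab, .data$time == 0, .data$f > 0)
    add("control RA = 1 and log2FC = 0", name,
        all(abs(ctrl$ra - 1) < tol, na.rm = TRUE) &&
          all(abs(ctrl$log2fc) < tol, na.rm = TRUE))
    add("counts nonnegative", name, all(r$counts$count >= 0))
  }
  bn <- report$bubbles$extent_normalized
  add("normalized extents in [0,1], argmax = 1", "all",
      all(bn >= 0 & bn <= 1, na.rm = TRUE) &&
        isTRUE(all.equal(max(bn, na.rm = TRUE), 1)))
  bind_rows(checks)
}
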