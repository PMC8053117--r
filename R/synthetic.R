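#' Sample a doped target library
#'
#' Draws `n_members` sequences position-by-position from the doping
#' composition (reference base with probability `1 - f`, each alternative
#' with `f/3`), collapses duplicates, and annotates each unique member with
#' its mismatch count. Multiplicities are returned as weights summing to 1.
#'
#' @param spec A [target_spec()].
#' @param scheme A [doping_scheme()].
#' @param n_members Number of oligonucleotide draws (default 100000).
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `sequence` (5'->3', same orientation as the
#'   protospacer), `weight`, `n_mm`, and `mm_pos` (list column of
#'   PAM-proximal mismatch positions).
#' @export
sample_library <- function(spec, scheme, n_members = 100000L, seed = 1L) {
  stopifnot(inherits(spec, "target_spec"), inherits(scheme, "doping_scheme"))
  if (n_members < 1L) {
    abort("`n_members` must be >= 1.", class = "cas9profiler_domain_error")
  }
  f <- scheme$f
  ref <- strsplit(spec$protospacer, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    L <- spec$length
    cols <- vector("list", L)
    for (j in seq_len(L)) {
      others <- setdiff(DNA_BASES, ref[j])
      hit <- runif(n_members) < f
      col <- rep(ref[j], n_members)
      if (any(hit)) {
        col[hit] <- sample(others, sum(hit), replace = TRUE)
      }
      cols[[j]] <- col
    }
    seqs <- do.call(paste0, cols)
  })
  tab <- table(seqs)
  members <- tibble(
    sequence = names(tab),
    weight = as.numeric(tab) / n_members
  )
  ann <- annotate_sequences(members$sequence, spec)
  members$n_mm <- ann$n_mm
  members$mm_pos <- ann$mm_pos
  arrange(members, dplyr::desc(.data$weight), .data$sequence)
}

#' Describe a Cas9-variant kinetic behaviour for simulation
#'
#' Encodes how a (real or hypothetical) Cas9 variant's two cleavage steps —
#' first-strand nicking and second-strand linearization — respond to
#' mismatches. Nick rates are penalized multiplicatively per mismatch
#' position (seed positions carry a stronger penalty); the linearization rate
#' is penalized per PAM-distal mismatch, modelling the second-strand cleavage
#' defect of high-fidelity variants.
#'
#' @param name Label for the profile.
#' @param k_nick_base Nick rate for the perfect target, per minute.
#' @param k_lin_base Linearization rate for the perfect target, per minute.
#' @param seed_penalty Multiplier on the nick rate per seed mismatch, in (0, 1].
#' @param distal_penalty Multiplier on the nick rate per PAM-distal mismatch.
#' @param distal_second_strand_penalty Multiplier on the linearization rate
#'   per PAM-distal mismatch.
#' @param position_penalties Optional length-20 numeric vector of per-position
#'   nick-rate multipliers (PAM-proximal order) overriding the seed/distal
#'   defaults.
#' @param seed_len Seed length used to build default position penalties.
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(name, k_nick_base, k_lin_base,
                            seed_penalty = 0.25, distal_penalty = 0.6,
                            distal_second_strand_penalty = 0.7,
                            position_penalties = NULL, seed_len = 10L) {
  if (is.null(position_penalties)) {
    position_penalties <- ifelse(seq_len(20L) <= seed_len,
                                 seed_penalty, distal_penalty)
  }
  if (length(position_penalties) != 20L ||
      any(position_penalties <= 0) || any(position_penalties > 1)) {
    abort("`position_penalties` must be 20 values in (0, 1].",
          class = "cas9profiler_domain_error")
  }
  if (k_nick_base < 0 || k_lin_base < 0) {
    abort("base rates must be >= 0.", class = "cas9profiler_domain_error")
  }
  if (distal_second_strand_penalty <= 0 || distal_second_strand_penalty > 1) {
    abort("`distal_second_strand_penalty` must be in (0, 1].",
          class = "cas9profiler_domain_error")
  }
  structure(
    list(
      name = name,
      k_nick_base = k_nick_base,
      k_lin_base = k_lin_base,
      position_penalties = position_penalties,
      distal_second_strand_penalty = distal_second_strand_penalty,
      seed_len = as.integer(seed_len)
    ),
    class = "variant_profile"
  )
}

#' @rdname variant_profile
#' @details `wt_profile()` emulates a wild-type-like enzyme: fast on-target
#' cleavage, strong seed-mismatch intolerance, mild second-strand penalty so
#' nicked intermediates are converted to double-strand breaks.
#' `hf_profile()` emulates a high-fidelity-like enzyme: slightly slower
#' on-target cleavage, stronger mismatch penalties throughout, and a severe
#' second-strand penalty per PAM-distal mismatch so mismatched targets
#' accumulate as nicked rather than linear DNA.
#' @export
wt_profile <- function(seed_len = 10L) {
  variant_profile("WT-like", k_nick_base = 2, k_lin_base = 1.8,
                  seed_penalty = 0.25, distal_penalty = 0.6,
                  distal_second_strand_penalty = 0.7, seed_len = seed_len)
}

#' @rdname variant_profile
#' @export
hf_profile <- function(seed_len = 10L) {
  variant_profile("HF-like", k_nick_base = 1.5, k_lin_base = 1.5,
                  seed_penalty = 0.15, distal_penalty = 0.35,
                  distal_second_strand_penalty = 0.2, seed_len = seed_len)
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("<variant_profile>", x$name, "\n")
  cat("  k_nick =", x$k_nick_base, "/min, k_lin =", x$k_lin_base, "/min\n")
  cat("  second-strand penalty per PAM-distal mismatch:",
      x$distal_second_strand_penalty, "\n")
  invisible(x)
}

#' Assign per-member nick and linearization rates
#'
#' For a library member with mismatches at PAM-proximal positions `p`:
#' `k1 = k_nick_base * prod(position_penalties[p])` and
#' `k2 = k_lin_base * distal_second_strand_penalty ^ n_distal`, where
#' `n_distal` counts mismatches beyond the seed. Deterministic given inputs.
#'
#' @param members A tibble from [sample_library()] (needs `mm_pos`).
#' @param profile A [variant_profile()].
#' @return `members` with numeric columns `k1` and `k2` added.
#' @export
assign_kinetics <- function(members, profile) {
  stopifnot(inherits(profile, "variant_profile"))
  pos_list <- members$mm_pos
  pen <- profile$position_penalties
  logprod <- vapply(pos_list, function(p) sum(log(pen[p])), numeric(1))
  n_distal <- vapply(pos_list, function(p) sum(p > profile$seed_len), numeric(1))
  members$k1 <- profile$k_nick_base * exp(logprod)
  members$k2 <- profile$k_lin_base * profile$distal_second_strand_penalty^n_distal
  members
}

#' Closed-form pool fractions under sequential first-order cleavage
#'
#' Each plasmid species follows supercoiled -> nicked -> linear with
#' irreversible first-order steps at rates `k1` and `k2`:
#' `SC(t) = SC0 e^(-k1 t)`,
#' `N(t) = N0 e^(-k2 t) + SC0 k1 t e^(-k1 t) phi((k2-k1) t)` with
#' `phi(x) = (1 - e^(-x))/x` (so the k1 = k2 limit is `k1 t e^(-k1 t)`), and
#' `L(t) = 1 - SC - N`. Arguments are vectorized and recycled.
#'
#' @param k1,k2 Nick and linearization rates (per minute), `>= 0`.
#' @param t Time in minutes, `>= 0`.
#' @param sc0,n0 Fractions at t = 0 (default intact supercoiled plasmid; set
#'   `n0 > 0` for a prep-derived nicked background).
#' @return A tibble with columns `t`, `sc`, `nicked`, `linear`.
#' @export
evolve_pools <- function(k1, k2, t, sc0 = 1, n0 = 0) {
  if (any(t < 0)) abort("`t` must be >= 0.", class = "cas9profiler_domain_error")
  if (any(k1 < 0) || any(k2 < 0)) {
    abort("rates must be >= 0.", class = "cas9profiler_domain_error")
  }
  m <- max(length(k1), length(k2), length(t), length(sc0), length(n0))
  k1 <- rep_len(k1, m); k2 <- rep_len(k2, m); t <- rep_len(t, m)
  sc0 <- rep_len(sc0, m); n0 <- rep_len(n0, m)
  sc <- sc0 * exp(-k1 * t)
  x <- (k2 - k1) * t
  phi <- ifelse(abs(x) < 1e-8, 1 - x / 2 + x^2 / 6, -expm1(-x) / x)
  nicked <- n0 * exp(-k2 * t) + sc0 * k1 * t * exp(-k1 * t) * phi
  nicked <- pmin(pmax(nicked, 0), 1)
  linear <- pmax(1 - sc - nicked, 0)
  tibble(t = t, sc = sc, nicked = nicked, linear = linear)
}

#' Simulate a full library cleavage time course
#'
#' Samples a doped library, assigns per-member two-step kinetics under a
#' variant profile, evolves the supercoiled/nicked/linear pools analytically
#' at each time point, and draws multinomial sequencing counts of the
#' configured depth from the supercoiled and nicked pools (the linearized
#' pool never yields amplicons, mirroring PCR across a double-strand break).
#' Gel-lane intensities are the multiplicity-weighted aggregate pool masses.
#'
#' @param spec,scheme,profile Target, doping and kinetic descriptions.
#' @param time_points Sampling times in minutes; must include 0, the
#'   negative-control library (default `c(0, 1, 5, 30, 60, 180)`).
#' @param depth Reads per sampled pool per time point (default 100000).
#' @param n_members Library draws for [sample_library()].
#' @param prep_nick Fraction of every member nicked during plasmid prep
#'   (uniform aberrant nicking; default 0.05).
#' @param seed Integer seed controlling library sampling and read sampling.
#' @return An object of class `cas_run`: a list with `members` (including
#'   `k1`, `k2`), `states` (per-member pool fractions by time), `truth`
#'   (sampled counts: `pool`, `time`, `sequence`, `count`, `n_mm`), `gel`
#'   (lane intensities by time) and `fr` (per-pool DNA mass fractions used
#'   for abundance scaling), plus the inputs and seed as metadata.
#' @export
simulate_cleavage_run <- function(spec, scheme, profile,
                                  time_points = c(0, 1, 5, 30, 60, 180),
                                  depth = 100000L, n_members = 100000L,
                                  prep_nick = 0.05, seed = 1L) {
  if (!0 %in% time_points) {
    abort("`time_points` must include 0 (the negative-control library).",
          class = "cas9profiler_config_error")
  }
  time_points <- sort(unique(time_points))
  members <- sample_library(spec, scheme, n_members = n_members, seed = seed)
  members <- assign_kinetics(members, profile)

  sc0 <- 1 - prep_nick
  states <- purrr::map(time_points, function(tt) {
    st <- evolve_pools(members$k1, members$k2, tt, sc0 = sc0, n0 = prep_nick)
    tibble(time = tt, sequence = members$sequence, weight = members$weight,
           sc = st$sc, nicked = st$nicked, linear = st$linear)
  })
  states <- bind_rows(states)

  gel <- states |>
    group_by(time = .data$time) |>
    summarise(
      i_sc = sum(.data$weight * .data$sc),
      i_n = sum(.data$weight * .data$nicked),
      i_l = sum(.data$weight * .data$linear),
      .groups = "drop"
    )
  # per-pool DNA mass fraction at each time (the FR used to scale abundances)
  fr <- gel |>
    mutate(total = .data$i_sc + .data$i_n + .data$i_l) |>
    transmute_fr()

  truth <- with_seed(seed + 1L, {
    bind_rows(purrr::map(time_points, function(tt) {
      st <- states[states$time == tt, ]
      bind_rows(purrr::map(c("supercoiled", "nicked"), function(pool) {
        w <- st$weight * if (pool == "supercoiled") st$sc else st$nicked
        if (sum(w) <= 0) {
          return(tibble(pool = character(), time = numeric(),
                        sequence = character(), count = integer()))
        }
        cnt <- as.integer(rmultinom(1, depth, prob = w))
        keep <- cnt > 0L
        tibble(pool = pool, time = tt,
               sequence = st$sequence[keep], count = cnt[keep])
      }))
    }))
  })
  truth <- left_join(truth,
                     select(members, "sequence", "n_mm"),
                     by = "sequence")

  structure(
    list(
      spec = spec, scheme = scheme, profile = profile,
      time_points = time_points, depth = as.integer(depth),
      prep_nick = prep_nick, seed = as.integer(seed),
      members = members, states = states,
      truth = truth, gel = gel, fr = fr
    ),
    class = "cas_run"
  )
}

transmute_fr <- function(gel_tot) {
  bind_rows(
    tibble(pool = "supercoiled", time = gel_tot$time,
           fr = gel_tot$i_sc / gel_tot$total),
    tibble(pool = "nicked", time = gel_tot$time,
           fr = gel_tot$i_n / gel_tot$total)
  )
}

#' @export
print.cas_run <- function(x, ...) {
  cat("<cas_run>", x$profile$name, "profile;",
      nrow(x$members), "unique members;",
      length(x$time_points), "time points; depth", x$depth, "\n")
  invisible(x)
}

#' Render simulated sequencing reads as FASTQ files
#'
#' Each read is `upstream flank + member sequence + downstream flank`,
#' replicated according to the sampled truth counts, with optional uniform
#' per-base substitution noise, written as standard 4-line FASTQ records with
#' constant Phred+33 qualities.
#'
#' @param run A `cas_run` from [simulate_cleavage_run()].
#' @param dir Output directory (created if needed).
#' @param config An [amplicon_config()] supplying the flanks.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed for error injection and read shuffling.
#' @return A manifest tibble: `pool`, `time`, `path`, `n_reads`.
#' @export
render_reads <- function(run, dir, config = amplicon_config(),
                         error_rate = 0, seed = run$seed + 2L) {
  stopifnot(inherits(run, "cas_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- dplyr::group_split(group_by(run$truth, .data$pool, .data$time))
  manifest <- purrr::map(seq_along(groups), function(i) {
    g <- groups[[i]]
    pool <- g$pool[1]; tt <- g$time[1]
    reads <- rep(paste0(config$flank_up, g$sequence, config$flank_down),
                 times = g$count)
    reads <- with_seed(seed + i, inject_errors(sample(reads), error_rate))
    path <- file.path(dir, sprintf("%s_t%03d.fastq", pool, as.integer(tt)))
    write_fastq(reads, path, prefix = sprintf("sim:%s:t%g", pool, tt))
    tibble(pool = pool, time = tt, path = path, n_reads = length(reads))
  })
  bind_rows(manifest)
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  width <- nchar(reads[1])
  n_bases <- length(reads) * width
  hits <- which(runif(n_bases) < error_rate)
  for (h in hits) {
    ri <- ((h - 1) %/% width) + 1L
    pos <- ((h - 1) %% width) + 1L
    old <- substr(reads[ri], pos, pos)
    substr(reads[ri], pos, pos) <- sample(setdiff(DNA_BASES, old), 1)
  }
  reads
}

write_fastq <- function(reads, path, prefix = "sim") {
  dna <- Biostrings::DNAStringSet(reads)
  if (length(dna)) {
    names(dna) <- sprintf("%s:%06d", prefix, seq_along(dna))
  }
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Render simulated gel-lane intensities
#'
#' Aggregates the per-member pool fractions into supercoiled/nicked/linear
#' band intensities per time point, with optional multiplicative lognormal
#' densitometry noise. With `noise_sd = 0` the lanes reproduce the
#' simulator's aggregate fractions exactly.
#'
#' @param run A `cas_run`.
#' @param noise_sd Standard deviation of lognormal noise on each band
#'   (default 0).
#' @param seed Integer seed for the noise draw.
#' @return A tibble: `t` (minutes), `i_sc`, `i_n`, `i_l`.
#' @export
render_gel <- function(run, noise_sd = 0, seed = run$seed + 99L) {
  stopifnot(inherits(run, "cas_run"))
  out <- tibble(t = run$gel$time, i_sc = run$gel$i_sc,
                i_n = run$gel$i_n, i_l = run$gel$i_l)
  if (noise_sd > 0) {
    with_seed(seed, {
      for (col in c("i_sc", "i_n", "i_l")) {
        out[[col]] <- out[[col]] * exp(rnorm(nrow(out), 0, noise_sd))
      }
    })
  }
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
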