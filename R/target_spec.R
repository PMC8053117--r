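DNA_BASES <- c("A", "C", "G", "T")

#' Define a reference target (protospacer) for library profiling
#'
#' A target specification pins down the 20-nt protospacer, its PAM, which end
#' of the protospacer the PAM sits on, and the seed/PAM-distal partition. All
#' downstream position numbering is PAM-proximal: position 1 is the base next
#' to the PAM, position 20 the PAM-distal end.
#'
#' @param protospacer 20-nt DNA string over A/C/G/T, written 5'->3' as the
#'   crRNA-matching (non-target) strand.
#' @param pam Short DNA string (e.g. "TGG" for an NGG PAM).
#' @param pam_side Which end of the protospacer string the PAM is adjacent to:
#'   `"3prime"` (SpCas9-style, default) or `"5prime"`.
#' @param seed_len Number of PAM-proximal positions that make up the seed
#'   (default 10). Seed = positions `1..seed_len`, PAM-distal =
#'   `seed_len+1..20`.
#' @return An object of class `target_spec`.
#' @examples
#' ts <- target_spec("GGTGATCCAGGCACTTAAGC", pam = "TGG")
#' spacer_positions(ts)
#' @export
target_spec <- function(protospacer, pam = "NGG", pam_side = c("3prime", "5prime"),
                        seed_len = 10L) {
  pam_side <- match.arg(pam_side)
  protospacer <- toupper(protospacer)
  check_dna(protospacer, len = 20L, what = "protospacer")
  seed_len <- as.integer(seed_len)
  if (seed_len < 1L || seed_len >= 20L) {
    abort("`seed_len` must be in 1..19.", class = "cas9profiler_domain_error")
  }
  structure(
    list(
      protospacer = protospacer,
      pam = toupper(pam),
      pam_side = pam_side,
      seed_len = seed_len,
      length = 20L
    ),
    class = "target_spec"
  )
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec>\n")
  cat("  protospacer:", x$protospacer, "\n")
  cat("  PAM:", x$pam, "on", x$pam_side, "end; seed = positions 1..",
      x$seed_len, " (PAM-proximal)\n", sep = "")
  invisible(x)
}

#' Per-position view of a target specification
#'
#' Expands a [target_spec()] into one row per position in PAM-proximal
#' numbering, with the reference base, the crRNA base (T written as U) and
#' whether the position lies in the seed.
#'
#' @param spec A [target_spec()].
#' @return A tibble with columns `position`, `ref_base`, `crrna_base`, `seed`.
#' @export
spacer_positions <- function(spec) {
  stopifnot(inherits(spec, "target_spec"))
  bases <- strsplit(spec$protospacer, "", fixed = TRUE)[[1]]
  # string index 1 is the 5' end; with a 3' PAM, position 1 (PAM-proximal)
  # is the last character of the string
  if (spec$pam_side == "3prime") bases <- rev(bases)
  tibble(
    position = seq_len(20L),
    ref_base = bases,
    crrna_base = chartr("T", "U", bases),
    seed = seq_len(20L) <= spec$seed_len
  )
}

#' Map PAM-proximal positions to protospacer string indices
#' @noRd
position_to_index <- function(spec, position) {
  if (spec$pam_side == "3prime") 21L - position else position
}

#' Define a doping scheme for partially randomized library synthesis
#'
#' During doped oligonucleotide synthesis each position receives the reference
#' base with probability `1 - f` and each of the other three bases with
#' probability `f/3` (an 85:5:5:5 dispense ratio at `f = 0.15`).
#'
#' @param f Per-position substitution probability in \[0, 1\].
#' @return An object of class `doping_scheme`.
#' @export
doping_scheme <- function(f = 0.15) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort("`f` must be a single probability in [0, 1].",
          class = "cas9profiler_domain_error")
  }
  structure(list(f = f), class = "doping_scheme")
}

#' @export
print.doping_scheme <- function(x, ...) {
  w <- round(c(1 - x$f, rep(x$f / 3, 3)) * 100, 2)
  cat("<doping_scheme> f =", x$f, "(ref:other =", paste(w, collapse = ":"), ")\n")
  invisible(x)
}

#' Read a target specification and doping scheme from a YAML config
#'
#' The config file carries keyed fields `protospacer`, `pam`, `pam_side`,
#' `seed_len` and `f` (see `inst/extdata/demo_run.yaml` for a full example).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `spec` ([target_spec()]) and `scheme`
#'   ([doping_scheme()]), plus the raw config as `config`.
#' @export
read_target_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tg <- cfg$target %||% cfg
  spec <- target_spec(
    protospacer = tg$protospacer,
    pam = tg$pam %||% "NGG",
    pam_side = tg$pam_side %||% "3prime",
    seed_len = tg$seed_len %||% 10L
  )
  scheme <- doping_scheme(f = cfg$doping$f %||% tg$f %||% 0.15)
  list(spec = spec, scheme = scheme, config = cfg)
}

#' Bundled synthetic example targets
#'
#' Two synthetic 20-nt stand-in targets whose base composition matches the
#' GC content of the two target classes the assay is typically run against
#' (a 55% GC protospacer-4-like target and an 80% GC EMX1-like target).
#' These are constructed sequences for examples and tests, not sequences
#' from any sequencing study.
#'
#' @return A tibble with columns `name`, `protospacer`, `pam`, `pam_side`,
#'   `seed_len`, `gc_percent`.
#' @export
demo_targets <- function() {
  path <- system.file("extdata", "targets_synthetic.tsv",
                      package = "cas9profiler", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' GC content of a DNA sequence, in percent
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector, percent G+C.
#' @export
gc_percent <- function(x) {
  sets <- Biostrings::DNAStringSet(x)
  fr <- Biostrings::letterFrequency(sets, letters = c("G", "C"))
  as.numeric(rowSums(fr) / Biostrings::width(sets) * 100)
}

check_dna <- function(x, len = NULL, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", what, "` must be a single string."),
          class = "cas9profiler_domain_error")
  }
  if (!is.null(len) && nchar(x) != len) {
    abort(paste0("`", what, "` must be ", len, " nt, got ", nchar(x), "."),
          class = "cas9profiler_domain_error")
  }
  if (grepl("[^ACGT]", x)) {
    abort(paste0("`", what, "` contains characters outside A/C/G/T."),
          class = "cas9profiler_domain_error")
  }
  invisible(x)
}
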