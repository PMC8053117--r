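#' Amplicon layout configuration for variable-region extraction
#'
#' Describes the fixed flanks that anchor the 20-nt variable region inside an
#' amplicon read. The defaults match the flanks used by the synthetic read
#' generator, giving 75-nt reads (25 + 20 + 30).
#'
#' @param flank_up,flank_down Fixed sequences immediately up/downstream of the
#'   variable region (each >= 10 nt).
#' @param var_len Variable-region length (default 20, the protospacer length).
#' @param max_flank_mm Maximum mismatches tolerated when locating the
#'   upstream anchor (default 0, exact matching).
#' @param both_strands Also scan the reverse complement of each read
#'   (default TRUE); reads matching in both orientations are discarded as
#'   ambiguous.
#' @param min_quality Optional minimum Phred quality; reads with any
#'   variable-region base below it are discarded. `NULL` (default) disables
#'   quality filtering.
#' @return An object of class `amplicon_config`.
#' @export
amplicon_config <- function(flank_up = "ACGGTTCACGTAGTGGGCCATCGAT",
                            flank_down = "GCTAGCTTGGCGTAATCATGGTCATAGCTG",
                            var_len = 20L, max_flank_mm = 0L,
                            both_strands = TRUE, min_quality = NULL) {
  flank_up <- toupper(flank_up); flank_down <- toupper(flank_down)
  if (nchar(flank_up) < 10L || nchar(flank_down) < 10L) {
    abort("flanks must be at least 10 nt.", class = "cas9profiler_config_error")
  }
  structure(
    list(flank_up = flank_up, flank_down = flank_down,
         var_len = as.integer(var_len), max_flank_mm = as.integer(max_flank_mm),
         both_strands = isTRUE(both_strands), min_quality = min_quality),
    class = "amplicon_config"
  )
}

#' Extract and count variable regions from amplicon reads
#'
#' Locates the upstream and downstream flanks in each read (exact match by
#' default), keeps the enclosed region only if it has exactly the configured
#' length (regions of any other length indicate indels and are discarded),
#' collapses identical regions with summed counts, and annotates each unique
#' sequence with its mismatches against the target. Extraction is
#' deterministic and independent of read order.
#'
#' @param fastq Path to a FASTQ file (optionally gzip-compressed), or a
#'   character vector of read sequences.
#' @param spec A [target_spec()] used for mismatch annotation.
#' @param config An [amplicon_config()].
#' @param pool,time Optional labels stored on the output.
#' @return A tibble of class `target_count_table` with columns `pool`,
#'   `time`, `sequence`, `count`, `n_mm`, `mm_descriptor`. Attribute
#'   `discards` is a tibble of per-reason discard tallies and `reads_parsed`
#'   the total input reads; counts + discards = reads parsed.
#' @export
extract_variable_regions <- function(fastq, spec, config = amplicon_config(),
                                     pool = NA_character_, time = NA_real_) {
  stopifnot(inherits(spec, "target_spec"), inherits(config, "amplicon_config"))
  if (length(fastq) == 1L && file.exists(fastq)) {
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                          with.qualities = !is.null(config$min_quality))
  } else {
    reads <- Biostrings::DNAStringSet(toupper(fastq))
  }
  n_parsed <- length(reads)
  if (n_parsed == 0L) {
    warn("no reads parsed; returning an empty table.")
    return(empty_count_table(pool, time, n_parsed))
  }

  hit_f <- locate_region(reads, config)
  if (config$both_strands) {
    rc <- Biostrings::reverseComplement(reads)
    hit_r <- locate_region(rc, config)
    ambiguous <- !is.na(hit_f$region) & !is.na(hit_r$region)
    region <- ifelse(is.na(hit_f$region), hit_r$region, hit_f$region)
    bad_len <- hit_f$bad_len | hit_r$bad_len
    region[ambiguous] <- NA_character_
  } else {
    ambiguous <- rep(FALSE, n_parsed)
    region <- hit_f$region
    bad_len <- hit_f$bad_len
  }

  reason <- rep(NA_character_, n_parsed)
  reason[is.na(region) & bad_len] <- "bad_length"
  reason[is.na(region) & !bad_len] <- "no_anchor"
  reason[ambiguous] <- "ambiguous"

  low_q <- rep(FALSE, n_parsed)
  if (!is.null(config$min_quality)) {
    qual <- S4Vectors::mcols(reads)$qualities
    if (!is.null(qual)) {
      # minimum quality within the whole read is a conservative proxy when
      # the region came from either strand
      minq <- min_phred(qual)
      low_q <- !is.na(region) & minq < config$min_quality
      reason[low_q] <- "low_quality"
      region[low_q] <- NA_character_
    }
  }

  has_bad_alpha <- !is.na(region) & grepl("[^ACGT]", region)
  reason[has_bad_alpha] <- "ambiguous_base"
  region[has_bad_alpha] <- NA_character_

  kept <- region[!is.na(region)]
  dtab <- table(reason[!is.na(reason)])
  discards <- tibble(reason = names(dtab), reads = as.integer(dtab))

  if (length(kept) == 0L) {
    warn("zero reads extracted.")
    out <- empty_count_table(pool, time, n_parsed)
    attr(out, "discards") <- discards
    return(out)
  }

  tab <- table(kept)
  out <- tibble(
    pool = pool, time = time,
    sequence = names(tab), count = as.integer(tab)
  )
  ann <- annotate_sequences(out$sequence, spec)
  out$n_mm <- ann$n_mm
  out$mm_descriptor <- ann$mm_descriptor
  out <- arrange(out, dplyr::desc(.data$count), .data$sequence)
  class(out) <- c("target_count_table", class(out))
  attr(out, "reads_parsed") <- n_parsed
  attr(out, "discards") <- discards
  out
}

locate_region <- function(reads, config) {
  if (config$max_flank_mm == 0L) {
    return(locate_region_exact(as.character(reads), config))
  }
  up <- config$flank_up
  m_up <- Biostrings::vmatchPattern(up, reads,
                                    max.mismatch = config$max_flank_mm)
  n_up <- S4Vectors::elementNROWS(m_up)
  region <- rep(NA_character_, length(reads))
  bad_len <- rep(FALSE, length(reads))
  cand <- which(n_up == 1L)
  if (length(cand) == 0L) return(list(region = region, bad_len = bad_len))
  up_end <- unlist(BiocGenerics::end(m_up[cand]))
  # search downstream flank after the anchor; its start fixes region length
  rest_start <- up_end + 1L
  widths <- Biostrings::width(reads)[cand]
  ok_space <- rest_start + 9L <= widths
  cand <- cand[ok_space]; up_end <- up_end[ok_space]
  if (length(cand) == 0L) return(list(region = region, bad_len = bad_len))
  rest <- Biostrings::subseq(reads[cand], start = up_end + 1L)
  dn_probe <- substr(config$flank_down, 1L,
                     min(nchar(config$flank_down), 15L))
  m_dn <- Biostrings::vmatchPattern(dn_probe, rest,
                                    max.mismatch = config$max_flank_mm)
  n_dn <- S4Vectors::elementNROWS(m_dn)
  has_dn <- n_dn >= 1L
  if (!any(has_dn)) return(list(region = region, bad_len = bad_len))
  dn_start <- rep(NA_integer_, length(cand))
  dn_start[has_dn] <- as.integer(min(BiocGenerics::start(m_dn)[has_dn]))
  reg_len <- dn_start - 1L
  good <- has_dn & reg_len == config$var_len
  bad <- has_dn & reg_len != config$var_len
  bad_len[cand[bad]] <- TRUE
  if (any(good)) {
    region[cand[good]] <- as.character(
      Biostrings::subseq(rest[good], start = 1L, width = config$var_len)
    )
  }
  list(region = region, bad_len = bad_len)
}

# Vectorized exact-match anchor search; the first upstream anchor hit wins.
locate_region_exact <- function(chr, config) {
  n <- length(chr)
  region <- rep(NA_character_, n)
  bad_len <- rep(FALSE, n)
  up_pos <- regexpr(config$flank_up, chr, fixed = TRUE, useBytes = TRUE)
  cand <- which(up_pos > 0L)
  if (length(cand) == 0L) return(list(region = region, bad_len = bad_len))
  up_end <- up_pos[cand] + nchar(config$flank_up) - 1L
  rest <- substr(chr[cand], up_end + 1L, nchar(chr[cand]))
  dn_probe <- substr(config$flank_down, 1L,
                     min(nchar(config$flank_down), 15L))
  dn_pos <- regexpr(dn_probe, rest, fixed = TRUE, useBytes = TRUE)
  reg_len <- dn_pos - 1L
  good <- dn_pos > 0L & reg_len == config$var_len
  bad <- dn_pos > 0L & reg_len != config$var_len
  bad_len[cand[bad]] <- TRUE
  region[cand[good]] <- substr(rest[good], 1L, config$var_len)
  list(region = region, bad_len = bad_len)
}

min_phred <- function(qual) {
  vapply(as.character(qual), function(q) {
    if (nchar(q) == 0L) return(Inf)
    min(utf8ToInt(q)) - 33L
  }, numeric(1), USE.NAMES = FALSE)
}

empty_count_table <- function(pool, time, reads_parsed) {
  out <- tibble(pool = pool[0], time = numeric(), sequence = character(),
                count = integer(), n_mm = integer(), mm_descriptor = character())
  class(out) <- c("target_count_table", class(out))
  attr(out, "reads_parsed") <- reads_parsed
  attr(out, "discards") <- tibble(reason = character(), reads = integer())
  out
}

#' Annotate a target sequence's mismatches against the reference
#'
#' Positions are numbered with 1 at the PAM-proximal end. Each mismatch is
#' labelled `rX:dY` where `rX` is the crRNA base at that position (the
#' reference protospacer base with T written as U) and `dY` is the DNA
#' target-strand base the crRNA faces, i.e. the complement of the observed
#' non-target-strand base. A reference G read as A is therefore the rG:dT
#' wobble pair.
#'
#' @param sequence A 20-nt DNA string (same orientation as the protospacer).
#' @param spec A [target_spec()].
#' @return A list with `n` (mismatch count) and `mismatches`, a tibble with
#'   columns `position`, `ref_base`, `obs_base`, `label`.
#' @examples
#' ts <- target_spec("GGTGATCCAGGCACTTAAGC", pam = "TGG")
#' annotate_mismatches(ts$protospacer, ts)
#' @export
annotate_mismatches <- function(sequence, spec) {
  sequence <- toupper(sequence)
  check_dna(sequence, len = spec$length, what = "sequence")
  ref <- strsplit(spec$protospacer, "", fixed = TRUE)[[1]]
  obs <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- which(obs != ref)
  pos <- if (spec$pam_side == "3prime") 21L - idx else idx
  ord <- order(pos)
  idx <- idx[ord]; pos <- pos[ord]
  mm <- tibble(
    position = as.integer(pos),
    ref_base = ref[idx],
    obs_base = obs[idx],
    label = rna_dna_label(ref[idx], obs[idx])
  )
  list(n = nrow(mm), mismatches = mm)
}

#' crRNA:DNA mismatch label for a reference/observed base pair
#' @noRd
rna_dna_label <- function(ref_base, obs_base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0("r", chartr("T", "U", ref_base), ":d", comp[obs_base])
}

# Vectorized annotation over many sequences; returns n_mm, mm_pos (list of
# PAM-proximal positions) and a compact descriptor string.
annotate_sequences <- function(seqs, spec) {
  K <- length(seqs)
  if (K == 0L) {
    return(list(n_mm = integer(), mm_pos = list(), mm_descriptor = character()))
  }
  L <- spec$length
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = K, ncol = L, byrow = TRUE)
  ref <- strsplit(spec$protospacer, "", fixed = TRUE)[[1]]
  mm <- mat != matrix(ref, nrow = K, ncol = L, byrow = TRUE)
  n_mm <- as.integer(rowSums(mm))
  if (!any(mm)) {
    return(list(n_mm = n_mm, mm_pos = rep(list(integer(0)), K),
                mm_descriptor = rep("", K)))
  }
  which_mm <- which(mm, arr.ind = TRUE)
  idx <- which_mm[, 2L]
  pos <- if (spec$pam_side == "3prime") 21L - idx else idx
  row <- which_mm[, 1L]
  ord <- order(row, pos)
  row <- row[ord]; pos <- pos[ord]; idx <- idx[ord]
  labels <- paste0("p", pos, ":",
                   rna_dna_label(ref[idx], mat[cbind(row, idx)]))
  mm_pos <- split(as.integer(pos), factor(row, levels = seq_len(K)))
  names(mm_pos) <- NULL
  desc <- vapply(split(labels, factor(row, levels = seq_len(K))),
                 paste, character(1), collapse = ";", USE.NAMES = FALSE)
  list(n_mm = n_mm, mm_pos = mm_pos, mm_descriptor = desc)
}

#' Write / read a target count table as TSV
#'
#' @param table A `target_count_table` tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(select(as_tibble(table), "pool", "time", "sequence",
                          "count", "n_mm", "mm_descriptor"), path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           pool = "c", time = "d", sequence = "c",
                           count = "i", n_mm = "i", mm_descriptor = "c"))
  class(out) <- c("target_count_table", class(out))
  out
}
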