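# TargetScan-style seed-match scanner: classifies 8mer, 7mer-m8 and 7mer-1A
# sites for a mature microRNA in 3'UTR sequences.
#
# Site anatomy on the UTR (5'->3'): [m8 complement][6mer core][A]
#   core     = reverse complement of miRNA positions 2-7
#   7mer-m8  = m8 complement + core        (exact match to positions 2-8)
#   7mer-1A  = core + literal A            (target-position-1 adenine)
#   8mer     = m8 complement + core + A
# The A at target position 1 is required as a literal A in the UTR (the
# TargetScan convention), not as a complement of miRNA position 1.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Reverse complement of a DNA or RNA sequence
#'
#' @param seq A single sequence over A/C/G/T(/N) for DNA or A/C/G/U(/N) for
#'   RNA; case-insensitive, returned uppercase.
#' @param alphabet `"dna"` or `"rna"`.
#' @return The antiparallel complement.
#' @export
#' @examples
#' reverse_complement("GUGCAGC", "rna") # "GCUGCAC"
reverse_complement <- function(seq, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  comp <- if (alphabet == "dna") DNA_COMP else RNA_COMP
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% names(comp)))
  if (length(bad) > 0) {
    abort(sprintf("Invalid %s character '%s' at position %d.",
      toupper(alphabet), chars[bad[1]], bad[1]))
  }
  paste(rev(unname(comp[chars])), collapse = "")
}

normalise_dna <- function(seq) chartr("Uu", "Tt", toupper(seq))

#' Scan a 3'UTR for microRNA seed-match sites
#'
#' Finds every occurrence of the 6mer core (reverse complement of miRNA
#' positions 2-7) in the UTR and classifies each locus by its strongest site
#' type: `8mer` (m8 match upstream and an A downstream), `7mer-m8` (m8 match
#' only; an exact match to miRNA positions 2-8), or `7mer-1A` (downstream A
#' only). A core occurrence with neither feature is not reported. Overlapping
#' sites at different core offsets are all reported; only same-locus type
#' shadowing is collapsed (each locus reports one best type). Coordinates are
#' 1-based and inclusive on the input UTR; `site_seq` echoes the input
#' sequence (and therefore its alphabet).
#'
#' @param mature_mirna Mature microRNA sequence, 5'->3', at least 8 nt
#'   (RNA; T accepted and treated as U).
#' @param utr_seq 3'UTR sequence (DNA or RNA; normalised internally).
#' @param utr_id Identifier carried into the output (default `"utr"`).
#' @return A tibble with columns `utr_id`, `site_type`, `start`, `end`,
#'   `site_seq`, ordered by `start`.
#' @export
#' @examples
#' mir <- "AGUGCAGCA" # positions 2-8 = GUGCAGC
#' find_seed_sites(mir, "AAAGCTGCACTTT") # one 7mer-m8 at [4, 10]
find_seed_sites <- function(mature_mirna, utr_seq, utr_id = "utr") {
  mir <- chartr("Tt", "Uu", toupper(mature_mirna))
  if (nchar(mir) < 8) {
    abort("The mature microRNA must be at least 8 nt to define the m8 seed site.")
  }
  mir_chars <- strsplit(mir, "", fixed = TRUE)[[1]]
  bad <- which(!(mir_chars %in% names(RNA_COMP)))
  if (length(bad) > 0) {
    abort(sprintf("Invalid RNA character '%s' at position %d of the microRNA.",
      mir_chars[bad[1]], bad[1]))
  }
  utr <- normalise_dna(utr_seq)
  utr_chars <- strsplit(utr, "", fixed = TRUE)[[1]]
  len <- length(utr_chars)
  seed27 <- substr(mir, 2, 7)
  core <- reverse_complement(chartr("U", "T", seed27), "dna")
  m8c <- unname(DNA_COMP[chartr("U", "T", substr(mir, 8, 8))])

  out <- list()
  if (len >= 6) {
    core_chars <- strsplit(core, "", fixed = TRUE)[[1]]
    for (i in seq_len(len - 5)) {
      if (!all(utr_chars[i:(i + 5)] == core_chars)) next
      has_m8 <- i >= 2 && utr_chars[i - 1] == m8c
      has_a1 <- (i + 6) <= len && utr_chars[i + 6] == "A"
      if (has_m8 && has_a1) {
        out[[length(out) + 1L]] <- tibble(site_type = "8mer", start = i - 1L,
          end = i + 6L)
      } else if (has_m8) {
        out[[length(out) + 1L]] <- tibble(site_type = "7mer-m8", start = i - 1L,
          end = i + 5L)
      } else if (has_a1) {
        out[[length(out) + 1L]] <- tibble(site_type = "7mer-1A", start = i,
          end = i + 6L)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(utr_id = character(), site_type = character(),
      start = integer(), end = integer(), site_seq = character()))
  }
  sites <- bind_rows(out)
  sites$utr_id <- utr_id
  sites$site_seq <- substring(utr_seq, sites$start, sites$end)
  arrange(sites[, c("utr_id", "site_type", "start", "end", "site_seq")],
    .data$start, .data$site_type)
}

#' Scan every sequence of a 3'UTR FASTA file
#'
#' @inheritParams find_seed_sites
#' @param fasta Path to a FASTA file of 3'UTR sequences (DNA or RNA).
#' @return A tibble of seed sites across all records (see
#'   [find_seed_sites()]).
#' @export
scan_utrs <- function(mature_mirna, fasta) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  bind_rows(purrr::map2(as.character(seqs), ids, function(s, id) {
    find_seed_sites(mature_mirna, s, utr_id = id)
  }))
}

#' Convert seed sites to BED intervals
#'
#' BED uses 0-based, half-open coordinates: `start0 = start - 1`, `end`
#' unchanged.
#'
#' @param sites Tibble from [find_seed_sites()].
#' @return Tibble with columns `chrom`, `start`, `end`, `name` (BED 4).
#' @export
seed_sites_to_bed <- function(sites) {
  tibble(
    chrom = sites$utr_id,
    start = sites$start - 1L,
    end = sites$end,
    name = sites$site_type
  )
}
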