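# Shared helpers: variant keys, closed vocabularies, error classes.

GENOTYPE_CODES <- c("hom_ref", "het", "hom_alt", "missing")
DE_STATUS <- c("OK", "LOWDATA", "HIDATA", "FAIL")
PHENOTYPES <- c("case", "control", "unknown")
ROLES <- c("discovery", "verification", "replication")

format_error <- function(msg, ...) {
  abort(msg, class = "omicsfunnel_format_error", ...)
}

#' Build a variant identifier from its key fields
#'
#' A variant is identified by chromosome, 1-based position, reference and
#' alternate allele (VCF convention, coordinates fully closed). Equality of
#' variants throughout the package is equality of this key.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate alleles (uppercased).
#' @return Character vector of identifiers, `"chrom:pos_ref/alt"`.
#' @export
#' @examples
#' variant_id("10", 135186806, "T", "C")
variant_id <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !is.na(ref) & !is.na(alt) & ref == alt
  if (any(bad)) {
    abort("`ref` and `alt` must differ for a valid variant key.")
  }
  paste0(chrom, ":", pos, "_", ref, "/", alt)
}

dosage_to_code <- function(dosage) {
  dplyr::case_when(
    is.na(dosage) ~ "missing",
    dosage == 0L ~ "hom_ref",
    dosage == 1L ~ "het",
    dosage == 2L ~ "hom_alt"
  )
}

check_dosage <- function(dosage, arg = "dosage") {
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))) {
    abort(sprintf("`%s` must contain only 0, 1, 2 or NA.", arg))
  }
  as.integer(dosage)
}

check_probability <- function(p, arg = "p") {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1] with no missing values.", arg))
  }
  p
}

variant_key_cols <- c("chrom", "pos", "ref", "alt")

assert_key_cols <- function(df, arg = "variants") {
  missing_cols <- setdiff(variant_key_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` must contain columns %s (missing: %s).",
      arg, paste(variant_key_cols, collapse = ", "),
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}
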