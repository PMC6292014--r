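# Readers for the external formats the pipeline consumes: VCF 4.x, DE tables
# (Cuffdiff-style .diff or generic TSV), GMT gene sets and the sample sheet.

#' Read per-sample genotype calls from a VCF file
#'
#' Parses a VCF 4.x file into one long tibble with one row per
#' (variant, sample) call. Multi-allelic sites are split into one record per
#' alternate allele; dosages count copies of that allele only, so the total
#' number of alternate-allele observations is conserved across the derived
#' records. Phased (`|`) and unphased (`/`) separators are treated identically:
#' the pipeline is genotype-based, not phase-based.
#'
#' Genotype coding: `0/0` is `hom_ref` (dosage 0), `0/1`/`1/0` is `het`
#' (dosage 1), `1/1` is `hom_alt` (dosage 2) and any allele of `.` gives a
#' `missing` call with missing dosage. The rsID is taken from the ID column;
#' the gene symbol and population minor-allele frequency are read from
#' configurable INFO keys.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @param sample_sheet Optional cohort design as returned by
#'   [read_sample_sheet()]. When supplied, VCF samples absent from the design
#'   are skipped with a warning (or rejected, see `unknown_samples`).
#' @param gene_key,maf_key INFO keys holding the gene symbol and the
#'   population minor-allele frequency.
#' @param unknown_samples `"skip"` (default) or `"error"`: what to do with VCF
#'   samples that are not in `sample_sheet`.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `variant_id`,
#'   `rsid`, `gene`, `maf`, `sample_id`, `genotype`, `dosage`, `gq`, `dp`.
#' @export
read_vcf <- function(path, sample_sheet = NULL,
                     gene_key = "GENE", maf_key = "MAF",
                     unknown_samples = c("skip", "error")) {
  unknown_samples <- match.arg(unknown_samples)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    format_error(sprintf(
      "Malformed VCF header in '%s': first line must start with '##fileformat=VCF'.",
      path
    ))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]

  if (!is.null(sample_sheet)) {
    extra <- setdiff(samples, sample_sheet$sample_id)
    if (length(extra) > 0) {
      msg <- sprintf(
        "%d VCF sample(s) absent from the cohort design: %s",
        length(extra), paste(extra, collapse = ", ")
      )
      if (unknown_samples == "error") format_error(msg)
      warn(paste0(msg, " (skipped)"))
      keep <- c(TRUE, !(samples %in% extra))
      gt <- gt[, keep, drop = FALSE]
      samples <- setdiff(samples, extra)
    }
  }
  if (length(samples) == 0) {
    format_error("VCF contains no samples usable under the cohort design.")
  }

  info_field <- function(info, key) {
    if (is.na(info)) return(NA_character_)
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) >= 2) m[2] else NA_character_
  }

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    gq_idx <- match("GQ", fmt)
    dp_idx <- match("DP", fmt)
    if (is.na(gt_idx)) {
      format_error(sprintf("VCF record %d has no GT in FORMAT.", i))
    }
    cells <- strsplit(unname(gt[i, -1]), ":", fixed = TRUE)
    gt_str <- purrr::map_chr(cells, gt_idx, .default = NA_character_)
    gq <- if (is.na(gq_idx)) rep(NA_integer_, length(cells)) else {
      suppressWarnings(as.integer(purrr::map_chr(cells, gq_idx, .default = NA_character_)))
    }
    dp <- if (is.na(dp_idx)) rep(NA_integer_, length(cells)) else {
      suppressWarnings(as.integer(purrr::map_chr(cells, dp_idx, .default = NA_character_)))
    }
    alleles <- strsplit(gt_str, "[/|]")
    info <- fix[i, "INFO"]
    gene <- info_field(info, gene_key)
    maf <- suppressWarnings(as.numeric(info_field(info, maf_key)))
    if (!is.na(maf) && (maf < 0 || maf > 1)) {
      format_error(sprintf("MAF outside [0, 1] at record %d.", i))
    }
    rsid <- fix[i, "ID"]
    if (is.na(rsid) || rsid == ".") rsid <- NA_character_

    purrr::map(seq_along(alts), function(k) {
      dosage <- purrr::map_int(alleles, function(a) {
        if (length(a) == 0 || any(is.na(a)) || any(a == ".")) {
          return(NA_integer_)
        }
        sum(a == as.character(k))
      })
      tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = toupper(fix[i, "REF"]),
        alt = toupper(alts[k]),
        rsid = rsid,
        gene = gene,
        maf = maf,
        sample_id = samples,
        dosage = dosage,
        gq = gq,
        dp = dp
      )
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  out$variant_id <- variant_id(out$chrom, out$pos, out$ref, out$alt)
  out$genotype <- dosage_to_code(out$dosage)
  out[, c(
    "chrom", "pos", "ref", "alt", "variant_id", "rsid", "gene", "maf",
    "sample_id", "genotype", "dosage", "gq", "dp"
  )]
}

#' Per-variant metadata from a calls tibble
#'
#' @param calls A calls tibble from [read_vcf()].
#' @return One row per variant with the key and annotation columns.
#' @export
variant_info <- function(calls) {
  distinct(calls, .data$variant_id, .data$chrom, .data$pos, .data$ref,
    .data$alt, .data$rsid, .data$gene, .data$maf)
}

cuffdiff_cols <- c(
  "test_id", "gene_id", "gene", "locus", "sample_1", "sample_2", "status",
  "value_1", "value_2", "log2(fold_change)", "test_stat", "p_value",
  "q_value", "significant"
)

#' Read a differential-expression table
#'
#' Supports a generic TSV (columns `gene`, `fpkm_case`, `fpkm_control`,
#' `log2_ratio`, `test_stat`, `p`, `q`, `status`) and the Cuffdiff `.diff`
#' layout, where `value_1` is the control FPKM, `value_2` the case FPKM and
#' `log2(fold_change)` is log2(case/control). Status strings are mapped onto
#' the closed vocabulary OK / LOWDATA / HIDATA / FAIL (anything else, e.g.
#' Cuffdiff's NOTEST, becomes FAIL with a warning). Rows whose numeric fields
#' do not parse are rejected with their line number.
#'
#' @param path Path to the TSV file.
#' @param dialect `"generic_tsv"` or `"cuffdiff_diff"`.
#' @return A tibble with one row per gene test.
#' @export
read_de_table <- function(path, dialect = c("generic_tsv", "cuffdiff_diff")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  required <- if (dialect == "generic_tsv") {
    c("gene", "fpkm_case", "fpkm_control", "log2_ratio", "test_stat", "p", "q", "status")
  } else {
    cuffdiff_cols
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    format_error(sprintf(
      "DE table '%s' is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    return(tibble(
      gene = character(), fpkm_case = double(), fpkm_control = double(),
      log2_ratio = double(), test_stat = double(), p = double(), q = double(),
      status = character()
    ))
  }
  if (dialect == "cuffdiff_diff") {
    raw <- tibble(
      gene = raw$gene,
      fpkm_case = raw$value_2,
      fpkm_control = raw$value_1,
      log2_ratio = raw$`log2(fold_change)`,
      test_stat = raw$test_stat,
      p = raw$p_value,
      q = raw$q_value,
      status = raw$status
    )
  }
  num_cols <- c("fpkm_case", "fpkm_control", "log2_ratio", "test_stat", "p", "q")
  parsed <- raw
  for (col in num_cols) {
    x <- raw[[col]]
    x[x %in% c("inf", "Inf", "+inf")] <- "Inf"
    x[x %in% c("-inf", "-Inf")] <- "-Inf"
    parsed[[col]] <- suppressWarnings(as.numeric(x))
  }
  bad <- rowSums(is.na(as.matrix(parsed[num_cols])) &
    !is.na(as.matrix(raw[num_cols]))) > 0
  if (any(bad)) {
    format_error(sprintf(
      "DE table '%s': unparseable numeric value(s) on data line(s) %s.",
      path, paste(which(bad), collapse = ", ")
    ))
  }
  status <- toupper(parsed$status)
  unknown <- !(status %in% DE_STATUS)
  if (any(unknown)) {
    warn(sprintf(
      "%d DE status value(s) outside {%s} mapped to FAIL.",
      sum(unknown), paste(DE_STATUS, collapse = ", ")
    ))
    status[unknown] <- "FAIL"
  }
  parsed$status <- status
  check_probability(parsed$p[!is.na(parsed$p)], "p")
  check_probability(parsed$q[!is.na(parsed$q)], "q")
  parsed[, c("gene", "fpkm_case", "fpkm_control", "log2_ratio", "test_stat",
    "p", "q", "status")]
}

#' Read pathway gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#' Gene symbols are uppercased on load and duplicates within a set are stored
#' once. Order of sets is preserved.
#'
#' @param path Path to the GMT file.
#' @return A long tibble with columns `pathway`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      format_error(sprintf(
        "GMT '%s' line %d has %d field(s); at least 3 (name, description, gene) required.",
        path, i, length(fields)
      ))
    }
    tibble(
      pathway = fields[1],
      description = fields[2],
      gene = unique(toupper(fields[-c(1, 2)]))
    )
  })
  bind_rows(sets)
}

#' Convert a long pathway tibble to a named list of gene sets
#'
#' @param pathways Long tibble from [read_gmt()].
#' @return Named list of character vectors, in first-appearance order.
#' @export
pathway_sets <- function(pathways) {
  split(pathways$gene, factor(pathways$pathway, levels = unique(pathways$pathway)))
}

#' Read the phenotype sample sheet
#'
#' TSV with columns `sample_id`, `phenotype` (case/control/unknown), `cohort`
#' (free label, e.g. a pedigree name) and `role` (discovery/verification/
#' replication). Sample identifiers must be unique and the closed
#' vocabularies are enforced.
#'
#' @param path Path to the TSV sample sheet.
#' @return A tibble with the four design columns.
#' @export
read_sample_sheet <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  required <- c("sample_id", "phenotype", "cohort", "role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    format_error(sprintf(
      "Sample sheet '%s' is missing column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup) > 0) {
    format_error(sprintf(
      "Duplicate sample_id(s) in sample sheet: %s", paste(unique(dup), collapse = ", ")
    ))
  }
  bad_ph <- is.na(raw$phenotype) | !(raw$phenotype %in% PHENOTYPES)
  if (any(bad_ph)) {
    format_error(sprintf(
      "Unknown or empty phenotype token(s) on row(s) %s (allowed: %s).",
      paste(which(bad_ph), collapse = ", "), paste(PHENOTYPES, collapse = ", ")
    ))
  }
  bad_role <- is.na(raw$role) | !(raw$role %in% ROLES)
  if (any(bad_role)) {
    format_error(sprintf(
      "Unknown role token(s) on row(s) %s (allowed: %s).",
      paste(which(bad_role), collapse = ", "), paste(ROLES, collapse = ", ")
    ))
  }
  raw[, required]
}
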