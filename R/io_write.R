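# Writers. All outputs are deterministic: fixed column orders, fixed float
# formatting, no timestamps — identical inputs give byte-identical files.

fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "NA",
    ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
      formatC(x, digits = digits, format = "g")
    )
  )
  out
}

write_tsv_det <- function(df, path) {
  df <- as.data.frame(df)
  is_num <- vapply(df, is.double, logical(1))
  for (col in names(df)[is_num]) df[[col]] <- fmt_num(df[[col]])
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0) {
      do.call(paste, c(lapply(df, function(x) {
        x <- as.character(x)
        x[is.na(x)] <- "NA"
        x
      }), sep = "\t"))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write genotype calls as a VCF 4.2 file
#'
#' One record per variant with GT:GQ:DP for every sample; gene and MAF
#' annotations are emitted under the configured INFO keys. Records are sorted
#' by (chrom, pos, ref, alt) so output is byte-identical for identical input.
#'
#' @param calls Calls tibble (see [read_vcf()]).
#' @param path Output path.
#' @param gene_key,maf_key INFO keys for gene symbol and minor-allele frequency.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, path, gene_key = "GENE", maf_key = "MAF") {
  samples <- sort(unique(calls$sample_id))
  info <- variant_info(calls)
  info <- arrange(info, .data$chrom, .data$pos, .data$ref, .data$alt)
  gt_of <- function(dosage) {
    dplyr::case_when(
      is.na(dosage) ~ "./.",
      dosage == 0 ~ "0/0",
      dosage == 1 ~ "0/1",
      dosage == 2 ~ "1/1"
    )
  }
  wide <- calls |>
    mutate(cell = paste(gt_of(.data$dosage),
      if_else(is.na(.data$gq), ".", as.character(.data$gq)),
      if_else(is.na(.data$dp), ".", as.character(.data$dp)),
      sep = ":"
    )) |>
    select("variant_id", "sample_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell",
      values_fill = "./.:.:.")
  wide <- wide[match(info$variant_id, wide$variant_id), c("variant_id", samples)]
  info_str <- paste0(
    ifelse(is.na(info$gene), "", paste0(gene_key, "=", info$gene)),
    ifelse(is.na(info$gene) | is.na(info$maf), "", ";"),
    ifelse(is.na(info$maf), "", paste0(maf_key, "=", fmt_num(info$maf)))
  )
  info_str[info_str == ""] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", gene_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Minor allele frequency\">", maf_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    info$chrom, info$pos, ifelse(is.na(info$rsid), ".", info$rsid),
    info$ref, info$alt, ".", "PASS", info_str, "GT:GQ:DP",
    do.call(paste, c(wide[samples], sep = "\t")),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a sample sheet TSV
#' @param samples Sample sheet tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  write_tsv_det(samples[, c("sample_id", "phenotype", "cohort", "role")], path)
}

#' Write a generic differential-expression TSV
#' @param de DE tibble (see [read_de_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_de_table <- function(de, path) {
  write_tsv_det(de[, c("gene", "fpkm_case", "fpkm_control", "log2_ratio",
    "test_stat", "p", "q", "status")], path)
}

#' Write pathway gene sets as GMT
#' @param pathways Long pathway tibble (see [read_gmt()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  if (!"description" %in% names(pathways)) pathways$description <- "na"
  lines <- pathways |>
    group_by(.data$pathway) |>
    summarise(
      line = paste(c(.data$pathway[1], .data$description[1], unique(.data$gene)),
        collapse = "\t"),
      .groups = "drop"
    )
  ord <- match(unique(pathways$pathway), lines$pathway)
  writeLines(lines$line[ord], path)
  invisible(path)
}

#' Write the report bundle to a directory
#'
#' Emits deterministic TSV files (funnel, enrichment, associations,
#' classifications, LD, hubs, pathogenic pathways) plus JSON copies of the
#' classification table and the provenance block. Missing bundle components
#' are written as empty-but-valid files with headers.
#'
#' @param bundle A report bundle as produced by [run_pipeline()], or any list
#'   with a subset of its components.
#' @param out_dir Output directory (created if needed).
#' @return A tibble manifest with columns `file` and `n_rows`.
#' @export
write_reports <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      abort(sprintf("Cannot create report directory '%s'.", out_dir))
    }
  }
  empty <- list(
    funnel = tibble(stage = character(), count = integer()),
    enrichment = tibble(pathway = character(), overlap = integer(),
      pathway_size = integer(), query_size = integer(), universe_size = integer(),
      p = double(), neg_log10_p = double(), p_bh = double(), significant = logical()),
    associations = tibble(variant_id = character(), construction = character(),
      partner = character(), statistic = double(), df = integer(), p = double(),
      p_bh = double(), expected_warning = logical()),
    classifications = tibble(variant_id = character(), gene = character(),
      verdict = character(), direct_construction = character(), direct_statistic = double(),
      direct_df = integer(), direct_p = double(), direct_p_adj = double(),
      best_partner = character(), interaction_p = double(), joint_disease_p = double()),
    ld = tibble(variant_a = character(), variant_b = character(), f_AB = double(),
      f_Ab = double(), f_aB = double(), f_ab = double(), D = double(),
      D_prime = double(), r2 = double(), n = integer(), n_iterations = integer()),
    hubs = tibble(gene = character(), n_significant_pathways = integer(),
      pathways = character(), min_pathway_p = double(), is_hub = logical()),
    pathogenic_pathways = tibble(pathway = character(), hub_genes = character(),
      pathogenic = logical(), effect_modifying = logical())
  )
  files <- character()
  n_rows <- integer()
  for (name in names(empty)) {
    df <- bundle[[name]] %||% empty[[name]]
    df <- as_tibble(df)[, names(empty[[name]]), drop = FALSE]
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_det(df, path)
    files <- c(files, path)
    n_rows <- c(n_rows, nrow(df))
  }
  cls <- as_tibble(bundle$classifications %||% empty$classifications)
  cls <- cls[, intersect(names(empty$classifications), names(cls)), drop = FALSE]
  json_path <- file.path(out_dir, "classifications.json")
  writeLines(jsonlite::toJSON(cls, dataframe = "rows", na = "null", digits = 10,
    pretty = TRUE), json_path)
  prov <- bundle$provenance %||% list()
  prov_path <- file.path(out_dir, "provenance.json")
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = 10, pretty = TRUE,
    null = "null"), prov_path)
  tibble(
    file = c(files, json_path, prov_path),
    n_rows = c(n_rows, nrow(cls), NA_integer_)
  )
}
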