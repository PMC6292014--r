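# The integration funnel: cross-case variant intersection, quality
# stratification, overlap with DE genes and significant pathways, and the
# verification-cohort rules that separate possible putative mutations from
# potential putative effect modifiers.

#' Per-case lists of variants present in each case sample
#'
#' A variant is "present" in a sample when its alt-allele dosage is at least
#' one (a carrier call). This mirrors per-case VCFs from a variant caller,
#' which list only non-reference sites.
#'
#' @param calls Calls tibble (see [read_vcf()]).
#' @param case_ids Sample identifiers of the case samples.
#' @return A named list (one element per case) of variant-key tibbles.
#' @export
case_variant_lists <- function(calls, case_ids) {
  purrr::map(setNames(case_ids, case_ids), function(s) {
    calls |>
      filter(.data$sample_id == s, !is.na(.data$dosage), .data$dosage >= 1) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$variant_id)
  })
}

#' Intersect per-case variant lists
#'
#' Returns the variants present in every case list, keyed by (chrom, pos,
#' ref, alt) only — genotypes may differ across cases and are analysed later
#' by the association battery, not here.
#'
#' @param per_case_lists A list of at least two variant tibbles, each with the
#'   key columns `chrom`, `pos`, `ref`, `alt` (e.g. from
#'   [case_variant_lists()]).
#' @return A tibble of the shared variant keys (plus `variant_id`).
#' @export
intersect_case_variants <- function(per_case_lists) {
  if (!is.list(per_case_lists) || length(per_case_lists) < 2) {
    abort("At least two per-case variant lists are required for an intersection.")
  }
  keys <- purrr::map(per_case_lists, function(df) {
    assert_key_cols(df)
    distinct(as_tibble(df)[, variant_key_cols])
  })
  shared <- purrr::reduce(keys, function(a, b) semi_join(a, b, by = variant_key_cols))
  shared$variant_id <- variant_id(shared$chrom, shared$pos, shared$ref, shared$alt)
  arrange(shared, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Stratify variants by genotype quality
#'
#' A variant passes iff every non-missing call in the inspected samples has
#' genotype quality `>= min_gq` and depth `>= min_dp`. Calls lacking a GQ or
#' DP value are treated according to `missing_quality` (`"pass"` by default:
#' absence of the annotation is not evidence of poor quality).
#'
#' @param calls Calls tibble.
#' @param min_gq,min_dp Non-negative thresholds (defaults 20 and 10).
#' @param samples Optional sample ids to inspect (default: all in `calls`);
#'   typically the discovery samples.
#' @param missing_quality `"pass"` or `"fail"` for calls without GQ/DP.
#' @return The variant-key tibble with a logical `quality_pass` column.
#' @export
quality_stratify <- function(calls, min_gq = 20, min_dp = 10, samples = NULL,
                             missing_quality = c("pass", "fail")) {
  missing_quality <- match.arg(missing_quality)
  if (min_gq < 0 || min_dp < 0) abort("Quality thresholds must be non-negative.")
  inspected <- calls
  if (!is.null(samples)) inspected <- filter(inspected, .data$sample_id %in% samples)
  default_ok <- missing_quality == "pass"
  per_call <- inspected |>
    filter(!is.na(.data$dosage)) |>
    mutate(
      ok_gq = if_else(is.na(.data$gq), default_ok, .data$gq >= min_gq),
      ok_dp = if_else(is.na(.data$dp), default_ok, .data$dp >= min_dp)
    )
  status <- per_call |>
    group_by(.data$variant_id) |>
    summarise(quality_pass = all(.data$ok_gq & .data$ok_dp), .groups = "drop")
  variant_info(calls) |>
    left_join(status, by = "variant_id") |>
    mutate(quality_pass = if_else(is.na(.data$quality_pass), default_ok,
      .data$quality_pass))
}

#' Integrate shared variants with DE genes and significant pathways
#'
#' A candidate is emitted for every shared variant whose annotated gene both
#' passed the DE significance filter and belongs to at least one significant
#' pathway. The `rare` flag is `maf < rare_maf` when the population MAF is
#' known and stays undefined (NA) otherwise — an unknown frequency is not
#' evidence that a variant is common.
#'
#' @param shared Variant tibble (the intersection output), carrying
#'   `variant_id`, the key columns and annotations (`gene`, `maf`, `rsid`).
#' @param de_retained DE tibble after [filter_de()].
#' @param enrichment Result of [enrich_pathways()].
#' @param pathways Long pathway tibble.
#' @param rare_maf MAF threshold below which a variant is flagged rare
#'   (default 0.01).
#' @return A candidate tibble: key and annotation columns, `log2_ratio`, `q`,
#'   `pathways` (list-column of significant pathway names containing the
#'   gene), `n_pathways`, `rare`.
#' @export
integrate_candidates <- function(shared, de_retained, enrichment, pathways,
                                 rare_maf = 0.01) {
  sig_sets <- pathways |>
    filter(.data$pathway %in% enrichment$pathway[enrichment$significant])
  cand <- shared |>
    filter(!is.na(.data$gene), .data$gene %in% de_retained$gene) |>
    left_join(de_retained[, c("gene", "log2_ratio", "q")], by = "gene")
  cand$pathways <- purrr::map(cand$gene, function(g) {
    sort(unique(sig_sets$pathway[sig_sets$gene == g]))
  })
  cand$n_pathways <- lengths(cand$pathways)
  cand <- filter(cand, .data$n_pathways > 0)
  cand$rare <- if_else(is.na(cand$maf), NA, cand$maf < rare_maf)
  cand
}

#' Verify candidates in pedigree and control cohorts
#'
#' Applies the verification rule to each candidate variant over the
#' verification samples: a variant found with the required genotype in at
#' least `min_carriers` member(s) of at least one case cohort (pedigree) and
#' in no control is a `possible_putative_mutation`; found in a case cohort and
#' also in at least one control it is a `potential_putative_effect_modifier`;
#' otherwise it is `unsupported`.
#'
#' @param calls Calls tibble covering the verification samples.
#' @param samples Sample sheet rows with role `verification`; case rows are
#'   grouped into cohorts by their `cohort` label, control rows form the
#'   control pool. Must be non-empty.
#' @param variants Variant ids to verify (default: all in `calls`).
#' @param required_genotype `"carrier"` (dosage >= 1) or `"hom_alt"`.
#' @param min_carriers Members of a case cohort required (default 1,
#'   operationalising "some members of at least one pedigree").
#' @return A tibble: `variant_id`, `verdict`, `supporting_cohorts`
#'   (comma-separated), `n_supporting_cohorts`, `control_carriers`.
#' @export
verify_in_cohorts <- function(calls, samples, variants = NULL,
                              required_genotype = c("carrier", "hom_alt"),
                              min_carriers = 1) {
  required_genotype <- match.arg(required_genotype)
  ver <- samples[samples$role == "verification", , drop = FALSE]
  if (nrow(ver) == 0) abort("The verification sample set is empty.")
  case_ids <- ver$sample_id[ver$phenotype == "case"]
  ctrl_ids <- ver$sample_id[ver$phenotype %in% c("control", "unknown")]
  cohort_of <- setNames(ver$cohort, ver$sample_id)
  has_required <- function(dosage) {
    if (required_genotype == "carrier") !is.na(dosage) & dosage >= 1 else
      !is.na(dosage) & dosage == 2
  }
  calls_v <- calls[calls$sample_id %in% ver$sample_id, , drop = FALSE]
  variants <- variants %||% unique(calls_v$variant_id)
  if (length(variants) == 0) {
    return(tibble(variant_id = character(), verdict = character(),
      supporting_cohorts = character(), n_supporting_cohorts = integer(),
      control_carriers = integer()))
  }
  rows <- purrr::map(variants, function(v) {
    vc <- calls_v[calls_v$variant_id == v, , drop = FALSE]
    hits <- vc$sample_id[has_required(vc$dosage)]
    case_hits <- intersect(hits, case_ids)
    support <- names(which(table(cohort_of[case_hits]) >= min_carriers))
    control_carriers <- length(intersect(hits, ctrl_ids))
    verdict <- if (length(support) > 0 && control_carriers == 0) {
      "possible_putative_mutation"
    } else if (length(support) > 0) {
      "potential_putative_effect_modifier"
    } else {
      "unsupported"
    }
    tibble(
      variant_id = v, verdict = verdict,
      supporting_cohorts = paste(sort(support), collapse = ","),
      n_supporting_cohorts = length(support),
      control_carriers = control_carriers
    )
  })
  bind_rows(rows)
}

FUNNEL_STAGES <- c("total", "intersection", "dbsnp_known", "in_de_genes",
  "rare", "in_significant_pathways")

#' Funnel counts down the integration stages
#'
#' Stage semantics: `total` (all variants seen), `intersection` (present in
#' all cases), `dbsnp_known` (shared variants with an rsID), `in_de_genes`
#' (shared variants whose gene passed the DE filter), then two parallel
#' refinements of the in-DE set: `rare` (population MAF below the rare
#' threshold) and `in_significant_pathways` (gene in at least one significant
#' pathway). Counts along the nested prefix are monotone non-increasing; the
#' last two stages are siblings, not nested in each other.
#'
#' @param all_variants Variant tibble of everything seen (one row per
#'   variant).
#' @param shared Intersection output (see [intersect_case_variants()]),
#'   annotated with `rsid`, `gene`, `maf` columns.
#' @param de_retained DE tibble after [filter_de()].
#' @param enrichment Result of [enrich_pathways()].
#' @param pathways Long pathway tibble.
#' @param rare_maf Rare-MAF threshold (default 0.01).
#' @return A tibble with ordered `stage` and `count` columns (class
#'   `funnel_counts`).
#' @export
funnel_counts <- function(all_variants, shared, de_retained, enrichment,
                          pathways, rare_maf = 0.01) {
  sig_genes <- unique(pathways$gene[
    pathways$pathway %in% enrichment$pathway[enrichment$significant]
  ])
  in_de <- shared[!is.na(shared$gene) & shared$gene %in% de_retained$gene, ,
    drop = FALSE]
  counts <- c(
    total = nrow(all_variants),
    intersection = nrow(shared),
    dbsnp_known = sum(!is.na(shared$rsid)),
    in_de_genes = nrow(in_de),
    rare = sum(!is.na(in_de$maf) & in_de$maf < rare_maf),
    in_significant_pathways = sum(in_de$gene %in% sig_genes)
  )
  out <- tibble(stage = FUNNEL_STAGES, count = as.integer(counts[FUNNEL_STAGES]))
  class(out) <- c("funnel_counts", class(out))
  out
}

#' Bar chart of the integration funnel
#'
#' @param funnel Result of [funnel_counts()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  df <- as_tibble(funnel)
  df$stage <- factor(df$stage, levels = rev(FUNNEL_STAGES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "variants", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.funnel_counts <- function(object, ...) plot_funnel(object)
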