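# End-to-end orchestration: DE filter -> enrichment -> intersection ->
# quality stratification -> integration -> verification -> association and
# classification -> LD -> hub ranking -> reports.

#' Pipeline parameter set
#'
#' All tunable thresholds in one place, defaulting to the reference values:
#' DE q < 0.05, pathway alpha 0.05, association alpha 0.05, rare MAF 0.01,
#' genotype quality GQ >= 20 / DP >= 10 (discovery samples), hub membership
#' of at least 2 significant pathways.
#'
#' @param q_max DE q-value threshold (strict).
#' @param alpha_pathway Pathway significance level on raw p.
#' @param alpha_assoc Association/classification significance level.
#' @param rare_maf Rare-MAF threshold.
#' @param min_gq,min_dp Genotype quality thresholds.
#' @param hub_min Minimum number of significant pathways for a hub gene.
#' @param required_genotype Verification genotype rule (`"carrier"` or
#'   `"hom_alt"`).
#' @param direct_adjust Direct-test family adjustment driving classification
#'   verdicts (`"BH"` default, `"none"` for raw alpha).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(q_max = 0.05, alpha_pathway = 0.05,
                            alpha_assoc = 0.05, rare_maf = 0.01,
                            min_gq = 20, min_dp = 10, hub_min = 2,
                            required_genotype = "carrier",
                            direct_adjust = "BH") {
  list(
    q_max = q_max, alpha_pathway = alpha_pathway, alpha_assoc = alpha_assoc,
    rare_maf = rare_maf, min_gq = min_gq, min_dp = min_dp, hub_min = hub_min,
    required_genotype = required_genotype, direct_adjust = direct_adjust
  )
}

#' Rank hub genes among putative mutations
#'
#' A gene carrying at least one putative-mutation variant is scored by the
#' number of significant pathways it contributes to; genes in at least
#' `hub_min` of them are hubs. Ordering is deterministic: pathway count
#' descending, then smallest pathway p ascending, then gene name.
#'
#' @param classifications Result of [classify_variants()] joined with a
#'   `gene` column (as in the pipeline bundle), or any tibble with
#'   `variant_id`, `gene`, `verdict`.
#' @param enrichment Result of [enrich_pathways()].
#' @param pathways Long pathway tibble.
#' @param hub_min Minimum significant-pathway count for `is_hub`
#'   (default 2).
#' @return A tibble: `gene`, `n_significant_pathways`, `pathways`
#'   (comma-separated), `min_pathway_p`, `is_hub`.
#' @export
rank_hubs <- function(classifications, enrichment, pathways, hub_min = 2) {
  mut_genes <- unique(classifications$gene[
    classifications$verdict == "putative_mutation" & !is.na(classifications$gene)])
  if (length(mut_genes) == 0) {
    return(tibble(gene = character(), n_significant_pathways = integer(),
      pathways = character(), min_pathway_p = double(), is_hub = logical()))
  }
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  rows <- purrr::map(mut_genes, function(g) {
    in_sets <- unique(pathways$pathway[pathways$gene == g])
    in_sig <- sig[sig$pathway %in% in_sets, , drop = FALSE]
    tibble(
      gene = g,
      n_significant_pathways = nrow(in_sig),
      pathways = paste(sort(in_sig$pathway), collapse = ","),
      min_pathway_p = if (nrow(in_sig) > 0) min(in_sig$p) else NA_real_
    )
  })
  out <- bind_rows(rows)
  out$is_hub <- out$n_significant_pathways >= hub_min
  arrange(out, desc(.data$n_significant_pathways), .data$min_pathway_p,
    .data$gene)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = "omicsfunnel_stage_error")
  })
}

#' Run the full integration pipeline
#'
#' Executes the stages in order on a cohort directory (as written by
#' [emit_cohort()]) or on an in-memory `sim_cohort`: DE significance filter,
#' pathway over-representation, cross-case intersection, genotype-quality
#' stratification, variant-DE-pathway integration, verification-cohort
#' rules, the chi-square classification battery on the replication arm,
#' linkage disequilibrium on the designated pair plus the top classified
#' pair, and hub/pathogenic-pathway ranking. The result is a pure function of
#' the inputs and parameters: repeated runs produce byte-identical reports.
#'
#' @param input A directory containing `cohort.vcf`, `samples.tsv`,
#'   `de_table.tsv`, `pathways.gmt` (see [emit_cohort()]), or a `sim_cohort`
#'   object.
#' @param params A [pipeline_params()] list.
#' @param ld_pairs Optional two-column matrix/list of variant-id pairs for LD
#'   estimation; defaults to the best classified mutation/modifier pair and,
#'   for simulated cohorts, the designated LD pair.
#' @return A report bundle (list of class `report_bundle`): `funnel`,
#'   `enrichment`, `candidates`, `verification`, `associations`,
#'   `classifications`, `ld`, `hubs`, `pathogenic_pathways`, `provenance`.
#' @export
run_pipeline <- function(input, params = pipeline_params(), ld_pairs = NULL) {
  if (inherits(input, "sim_cohort")) {
    calls <- input$calls
    samples <- input$samples
    de <- input$de
    pathways <- input$pathways
    source_label <- "in-memory simulated cohort"
  } else {
    samples <- pipeline_stage("read_sample_sheet",
      read_sample_sheet(file.path(input, "samples.tsv")))
    calls <- pipeline_stage("read_vcf",
      read_vcf(file.path(input, "cohort.vcf"), sample_sheet = samples))
    de <- pipeline_stage("read_de_table",
      read_de_table(file.path(input, "de_table.tsv")))
    pathways <- pipeline_stage("read_gmt",
      read_gmt(file.path(input, "pathways.gmt")))
    source_label <- input
  }

  disc <- samples[samples$role == "discovery", , drop = FALSE]
  disc_cases <- disc$sample_id[disc$phenotype == "case"]
  rep_samples <- samples[samples$role == "replication", , drop = FALSE]

  retained <- pipeline_stage("de_filter", filter_de(de, q_max = params$q_max))
  universe <- de$gene[de$status == "OK"]
  enrichment <- pipeline_stage("enrichment",
    enrich_pathways(retained$gene, pathways, universe,
      alpha = params$alpha_pathway))

  shared <- pipeline_stage("intersection",
    intersect_case_variants(case_variant_lists(calls, disc_cases)))
  quality <- pipeline_stage("quality_stratification",
    quality_stratify(calls, min_gq = params$min_gq, min_dp = params$min_dp,
      samples = disc$sample_id))
  shared_pass <- shared |>
    semi_join(quality[quality$quality_pass, ], by = "variant_id") |>
    left_join(
      distinct(calls, .data$variant_id, .data$rsid, .data$gene, .data$maf),
      by = "variant_id")

  candidates <- pipeline_stage("integration",
    integrate_candidates(shared_pass, retained, enrichment, pathways,
      rare_maf = params$rare_maf))
  funnel <- pipeline_stage("funnel",
    funnel_counts(distinct(calls, .data$variant_id), shared_pass, retained,
      enrichment, pathways, rare_maf = params$rare_maf))

  verification <- pipeline_stage("verification",
    verify_in_cohorts(calls, samples, variants = candidates$variant_id,
      required_genotype = params$required_genotype))

  classifications <- pipeline_stage("classification",
    classify_variants(calls, rep_samples, alpha = params$alpha_assoc,
      variants = candidates$variant_id,
      direct_adjust = params$direct_adjust))
  classifications <- left_join(classifications,
    candidates[, c("variant_id", "gene")], by = "variant_id")

  associations <- if (nrow(classifications) == 0) {
    tibble(variant_id = character(), construction = character(),
      partner = character(), statistic = double(), df = integer(),
      p = double(), p_bh = double(), expected_warning = logical())
  } else {
    classifications |>
      select("tests") |>
      tidyr::unnest("tests") |>
      select("variant_id", "construction", "partner", "statistic", "df", "p",
        p_bh = "p_adj", "expected_warning")
  }

  if (is.null(ld_pairs)) {
    ld_pairs <- list()
    if (inherits(input, "sim_cohort") && length(input$truth$ld_pair) == 2) {
      ld_pairs <- c(ld_pairs, list(input$truth$ld_pair))
    }
    mods <- classifications$variant_id[
      classifications$verdict == "putative_effect_modifier"]
    muts <- classifications$variant_id[
      classifications$verdict == "putative_mutation"]
    if (length(mods) >= 1 && length(muts) >= 1) {
      ld_pairs <- c(ld_pairs, list(c(muts[1], mods[1])))
    }
    if (length(mods) >= 2) ld_pairs <- c(ld_pairs, list(mods[1:2]))
  }
  geno_of <- function(v) {
    sub <- calls[calls$variant_id == v & calls$sample_id %in% rep_samples$sample_id, ]
    sub$dosage[match(rep_samples$sample_id, sub$sample_id)]
  }
  ld_empty <- tibble(variant_a = character(), variant_b = character(),
    f_AB = double(), f_Ab = double(), f_aB = double(), f_ab = double(),
    D = double(), D_prime = double(), r2 = double(), n = integer(),
    n_iterations = integer())
  ld <- pipeline_stage("ld", bind_rows(ld_empty, purrr::map(ld_pairs, function(pair) {
    fit <- em_haplotype_freqs(geno_of(pair[1]), geno_of(pair[2]))
    tibble(
      variant_a = pair[1], variant_b = pair[2],
      f_AB = fit$hap_freqs[["AB"]], f_Ab = fit$hap_freqs[["Ab"]],
      f_aB = fit$hap_freqs[["aB"]], f_ab = fit$hap_freqs[["ab"]],
      D = fit$D, D_prime = fit$D_prime, r2 = fit$r2,
      n = fit$n, n_iterations = fit$n_iterations
    )
  })))
  classifications$gene <- classifications$gene %||% character(0)

  hubs <- pipeline_stage("hub_ranking",
    rank_hubs(classifications, enrichment, pathways, hub_min = params$hub_min))

  hub_genes <- hubs$gene[hubs$is_hub]
  mod_genes <- unique(classifications$gene[
    classifications$verdict == "putative_effect_modifier" &
      !is.na(classifications$gene)])
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  pathogenic <- purrr::map(sig$pathway, function(pname) {
    genes <- pathways$gene[pathways$pathway == pname]
    tibble(
      pathway = pname,
      hub_genes = paste(sort(intersect(genes, hub_genes)), collapse = ","),
      pathogenic = length(intersect(genes, hub_genes)) > 0,
      effect_modifying = length(intersect(genes, mod_genes)) > 0
    )
  })
  pathogenic <- bind_rows(
    tibble(pathway = character(), hub_genes = character(),
      pathogenic = logical(), effect_modifying = logical()),
    pathogenic)
  if (nrow(pathogenic) > 0) {
    pathogenic <- pathogenic[pathogenic$pathogenic | pathogenic$effect_modifying, ,
      drop = FALSE]
  }

  bundle <- list(
    funnel = funnel,
    enrichment = enrichment,
    candidates = candidates,
    verification = verification,
    associations = associations,
    classifications = select(classifications, -"tests"),
    ld = ld,
    hubs = hubs,
    pathogenic_pathways = pathogenic,
    provenance = list(
      source = as.character(source_label),
      params = params,
      n_samples = nrow(samples),
      n_variants = dplyr::n_distinct(calls$variant_id),
      package_version = as.character(utils::packageVersion("omicsfunnel"))
    )
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("omicsfunnel report bundle\n")
  cat("funnel:\n")
  print(as.data.frame(x$funnel), row.names = FALSE)
  cat(sprintf("candidates: %d; significant pathways: %d\n",
    nrow(x$candidates), sum(x$enrichment$significant)))
  verd <- table(x$classifications$verdict)
  cat("classifications:", paste(names(verd), verd, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
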