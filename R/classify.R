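# Variant classification: putative mutation (direct genotype-disease
# association) vs putative effect modifier (no direct association, but the
# joint genotype pattern with a partner variant is associated with disease).

canonical_2x2 <- function(tab) {
  rows <- apply(tab, 1, paste, collapse = ",")
  paste(sort(rows), collapse = ";")
}

direct_family <- function(dosage, phenotype) {
  tests <- list()
  seen <- character()
  add <- function(tab, construction) {
    key <- canonical_2x2(tab)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    tests[[length(tests) + 1L]] <<- chi2_independence(tab, yates = "auto",
      construction = construction)
  }
  add(build_table(dosage, phenotype, "carrier"), "carrier")
  observed <- intersect(c("het", "hom_alt"), unique(dosage_to_code(dosage)))
  for (g in observed) {
    tab <- tryCatch(
      build_table(dosage, phenotype, "stratum", focus_genotype = g),
      error = function(e) NULL
    )
    if (!is.null(tab) && nrow(tab) == 2) add(tab, paste0("stratum_", g))
  }
  tests
}

#' Classify candidate variants into putative mutations and effect modifiers
#'
#' For every candidate variant a family of direct genotype-disease tests is
#' run: the carrier-level 2x2 test plus one stratum test (focus genotype vs
#' all others) for each observed non-reference genotype class, all with Yates'
#' correction. Duplicated constructions (e.g. the hom_ref stratum, whose table
#' is the row-swapped carrier table) are counted once. A variant with a
#' significant direct test is a `putative_mutation`. Otherwise partner
#' variants are searched: if for some partner both the genotype-by-genotype
#' dependence test and the joint-genotype-by-disease test are significant at
#' `alpha`, the variant is a `putative_effect_modifier`, with the partner of
#' smallest joint-test p recorded. Anything else is `unclassified`. Direct
#' effects take precedence: a variant meeting both conditions is a mutation.
#'
#' By default the direct verdict is driven by BH-adjusted p-values within each
#' variant's direct-test family, which keeps the per-variant false
#' putative-mutation rate at the nominal level; `direct_adjust = "none"`
#' reproduces the historical raw-alpha behaviour (each member test compared to
#' `alpha` unadjusted). Raw and adjusted values are both reported either way.
#'
#' @param calls Long genotype tibble with columns `variant_id`, `sample_id`,
#'   `dosage` (e.g. from [read_vcf()]), covering the association cohort.
#' @param samples Sample sheet restricted to the association cohort; must
#'   contain both cases and controls.
#' @param alpha Significance threshold (default 0.05).
#' @param variants Candidate variant ids (default: all in `calls`).
#' @param partner_set Partner variant ids (default: the candidates).
#' @param direct_adjust `"BH"` (default) or `"none"`.
#' @return A tibble with one row per candidate: `variant_id`, `verdict`,
#'   `direct_construction`, `direct_statistic`, `direct_df`, `direct_p`,
#'   `direct_p_adj`, `best_partner`, `interaction_p`, `joint_disease_p`,
#'   `alpha`, and a `tests` list-column holding every test performed.
#' @export
classify_variants <- function(calls, samples, alpha = 0.05, variants = NULL,
                              partner_set = NULL,
                              direct_adjust = c("BH", "none")) {
  direct_adjust <- match.arg(direct_adjust)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  samples <- samples[samples$phenotype %in% c("case", "control"), , drop = FALSE]
  if (!all(c("case", "control") %in% samples$phenotype)) {
    abort("The association cohort must contain both cases and controls.")
  }
  calls <- calls[calls$sample_id %in% samples$sample_id, , drop = FALSE]
  wide <- calls |>
    select("variant_id", "sample_id", "dosage") |>
    tidyr::pivot_wider(names_from = "variant_id", values_from = "dosage")
  wide <- wide[match(samples$sample_id, wide$sample_id), , drop = FALSE]
  phen <- samples$phenotype
  variants <- variants %||% setdiff(names(wide), "sample_id")
  partner_set <- partner_set %||% variants
  if (length(variants) == 0) {
    return(tibble(
      variant_id = character(), verdict = character(),
      direct_construction = character(), direct_statistic = double(),
      direct_df = integer(), direct_p = double(), direct_p_adj = double(),
      best_partner = character(), interaction_p = double(),
      joint_disease_p = double(), alpha = double(), tests = list()
    ))
  }
  missing_v <- setdiff(union(variants, partner_set), names(wide))
  if (length(missing_v) > 0) {
    abort(sprintf("No genotype calls for variant(s): %s",
      paste(missing_v, collapse = ", ")))
  }

  rows <- purrr::map(variants, function(v) {
    dv <- wide[[v]]
    fam <- direct_family(dv, phen)
    fam_tidy <- bind_rows(purrr::map(fam, tidy))
    fam_tidy$p_adj <- bh_adjust(fam_tidy$p.value)
    decisive <- if (direct_adjust == "BH") fam_tidy$p_adj else fam_tidy$p.value
    best_i <- which.min(fam_tidy$p.value)
    direct_hit <- any(decisive < alpha)

    tests <- fam_tidy |>
      mutate(variant_id = v, partner = NA_character_) |>
      select("variant_id", "construction", "partner", statistic = "statistic",
        df = "df", p = "p.value", p_adj = "p_adj",
        expected_warning = "expected_warning")

    verdict <- "unclassified"
    best_partner <- NA_character_
    interaction_p <- NA_real_
    joint_p <- NA_real_

    if (direct_hit) {
      verdict <- "putative_mutation"
    } else {
      partners <- setdiff(partner_set, v)
      part_rows <- purrr::map(partners, function(w) {
        dw <- wide[[w]]
        inter <- tryCatch(
          chi2_independence(build_joint_table(dv, dw), yates = "auto",
            construction = "joint2"),
          error = function(e) NULL
        )
        joint <- tryCatch(
          chi2_independence(build_joint_table(dv, dw, phen), yates = "auto",
            construction = "joint3"),
          error = function(e) NULL
        )
        if (is.null(inter) || is.null(joint)) return(NULL)
        tibble(
          partner = w,
          interaction_statistic = inter$statistic, interaction_df = inter$df,
          interaction_p = inter$p.value,
          joint_statistic = joint$statistic, joint_df = joint$df,
          joint_p = joint$p.value,
          expected_warning = inter$expected_warning || joint$expected_warning
        )
      })
      part_tbl <- bind_rows(part_rows)
      if (nrow(part_tbl) > 0) {
        tests <- bind_rows(
          tests,
          part_tbl |>
            mutate(variant_id = v) |>
            select("variant_id", "partner", statistic = "interaction_statistic",
              df = "interaction_df", p = "interaction_p") |>
            mutate(construction = "joint2", p_adj = NA_real_,
              expected_warning = NA),
          part_tbl |>
            mutate(variant_id = v) |>
            select("variant_id", "partner", statistic = "joint_statistic",
              df = "joint_df", p = "joint_p") |>
            mutate(construction = "joint3", p_adj = NA_real_,
              expected_warning = NA)
        )
        qual <- part_tbl$interaction_p < alpha & part_tbl$joint_p < alpha
        if (any(qual)) {
          hit <- part_tbl[qual, , drop = FALSE]
          hit <- hit[which.min(hit$joint_p), ]
          verdict <- "putative_effect_modifier"
          best_partner <- hit$partner
          interaction_p <- hit$interaction_p
          joint_p <- hit$joint_p
        }
      }
    }

    tibble(
      variant_id = v,
      verdict = verdict,
      direct_construction = fam_tidy$construction[best_i],
      direct_statistic = fam_tidy$statistic[best_i],
      direct_df = fam_tidy$df[best_i],
      direct_p = fam_tidy$p.value[best_i],
      direct_p_adj = fam_tidy$p_adj[best_i],
      best_partner = best_partner,
      interaction_p = interaction_p,
      joint_disease_p = joint_p,
      alpha = alpha,
      tests = list(tests)
    )
  })
  bind_rows(rows)
}

#' Stacked summary plot of classification verdicts
#'
#' @param classifications Result of [classify_variants()].
#' @return A ggplot bar chart of verdict counts.
#' @export
plot_classification <- function(classifications) {
  df <- count(classifications, .data$verdict)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$verdict, y = .data$n,
    fill = .data$verdict)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal()
}
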