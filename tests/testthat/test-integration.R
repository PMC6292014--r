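# Intersection, quality stratification, candidate integration, verification
# rules and the funnel.

key_tbl <- function(ids) {
  tibble::tibble(chrom = "1", pos = ids, ref = "A", alt = "G")
}

test_that("intersection keeps exactly the variants present in every list", {
  lists <- list(key_tbl(c(1, 2, 3)), key_tbl(c(2, 3, 4)), key_tbl(c(2, 3)))
  shared <- intersect_case_variants(lists)
  expect_equal(shared$pos, c(2, 3))
  # idempotence on six identical lists
  same <- replicate(6, key_tbl(c(5, 6, 7)), simplify = FALSE)
  expect_equal(intersect_case_variants(same)$pos, c(5, 6, 7))
  expect_error(intersect_case_variants(list(key_tbl(1))), "At least two")
})

test_that("intersection equals the brute-force membership oracle and is commutative", {
  set.seed(13)
  for (i in 1:15) {
    lists <- lapply(1:4, function(j) key_tbl(sort(sample(1:30, sample(5:20, 1)))))
    shared <- intersect_case_variants(lists)
    ids <- lapply(lists, function(x) x$pos)
    oracle <- sort(Filter(function(v) all(vapply(ids, function(l) v %in% l,
      logical(1))), unique(unlist(ids))))
    expect_equal(shared$pos, oracle)
    # commutative / associative and a subset of every input
    perm <- intersect_case_variants(rev(lists))
    expect_equal(shared$pos, perm$pos)
    for (l in ids) expect_true(all(shared$pos %in% l))
  }
})

test_that("case_variant_lists uses carrier calls only", {
  calls <- tibble::tibble(
    chrom = "1", pos = c(1L, 1L, 2L, 2L), ref = "A", alt = "G",
    variant_id = variant_id("1", c(1L, 1L, 2L, 2L), "A", "G"),
    sample_id = c("S1", "S2", "S1", "S2"),
    dosage = c(1L, 0L, NA, 2L), gq = NA_integer_, dp = NA_integer_,
    rsid = NA_character_, gene = NA_character_, maf = NA_real_,
    genotype = c("het", "hom_ref", "missing", "hom_alt")
  )
  lst <- case_variant_lists(calls, c("S1", "S2"))
  expect_equal(lst$S1$pos, 1L)
  expect_equal(lst$S2$pos, 2L)
})

test_that("quality stratification applies GQ/DP thresholds over inspected samples", {
  calls <- tibble::tibble(
    chrom = "1", pos = rep(c(1L, 2L, 3L), each = 2), ref = "A", alt = "G",
    variant_id = variant_id("1", rep(c(1L, 2L, 3L), each = 2), "A", "G"),
    rsid = NA_character_, gene = NA_character_, maf = NA_real_,
    sample_id = rep(c("S1", "S2"), 3),
    genotype = "het", dosage = 1L,
    gq = c(99L, 99L, 5L, 99L, NA, 99L),
    dp = c(40L, 40L, 40L, 40L, 40L, 40L)
  )
  strat <- quality_stratify(calls, min_gq = 20, min_dp = 10)
  expect_equal(strat$quality_pass[order(strat$pos)], c(TRUE, FALSE, TRUE))
  # thresholds of zero pass everything
  all_pass <- quality_stratify(calls, min_gq = 0, min_dp = 0)
  expect_true(all(all_pass$quality_pass))
  # missing quality can be made failing
  strict <- quality_stratify(calls, missing_quality = "fail")
  expect_false(strict$quality_pass[strict$pos == 3])
})

test_that("integrate_candidates requires DE retention and pathway membership", {
  shared <- tibble::tibble(
    chrom = "1", pos = 1:3, ref = "A", alt = "G",
    variant_id = variant_id("1", 1:3, "A", "G"),
    rsid = "rs1", gene = c("GA", "GB", "GC"), maf = c(0.3, 0.001, 0.2)
  )
  de_retained <- tibble::tibble(gene = c("GA", "GB"), log2_ratio = c(1, 2),
    q = c(0.01, 0.02))
  pathways <- tibble::tibble(
    pathway = c("P1", "P1", "P2", "P3"),
    gene = c("GA", "GB", "GA", "GC"))
  enrichment <- tibble::tibble(pathway = c("P1", "P2", "P3"),
    p = c(0.001, 0.01, 0.5), significant = c(TRUE, TRUE, FALSE))
  cand <- integrate_candidates(shared, de_retained, enrichment, pathways)
  # GC not retained; GA in two significant pathways; GB rare flag from maf
  expect_equal(cand$gene, c("GA", "GB"))
  expect_equal(cand$n_pathways, c(2L, 1L))
  expect_equal(cand$pathways[[1]], c("P1", "P2"))
  expect_equal(cand$rare, c(FALSE, TRUE))
  # gene in no significant pathway emits no candidate
  enrichment2 <- dplyr::mutate(enrichment, significant = FALSE)
  expect_equal(nrow(integrate_candidates(shared, de_retained, enrichment2,
    pathways)), 0)
})

verification_fixture <- function(case_dosages, control_dosages) {
  n_case <- length(case_dosages)
  n_ctrl <- length(control_dosages)
  ids <- c(sprintf("P_%d", seq_len(n_case)), sprintf("C_%d", seq_len(n_ctrl)))
  samples <- tibble::tibble(
    sample_id = ids,
    phenotype = rep(c("case", "control"), c(n_case, n_ctrl)),
    cohort = rep(c("PED1", "HAPMAP"), c(n_case, n_ctrl)),
    role = "verification"
  )
  calls <- tibble::tibble(
    chrom = "1", pos = 1L, ref = "A", alt = "G",
    variant_id = variant_id("1", 1L, "A", "G"),
    rsid = NA_character_, gene = NA_character_, maf = NA_real_,
    sample_id = ids, dosage = c(case_dosages, control_dosages),
    genotype = NA_character_, gq = NA_integer_, dp = NA_integer_
  )
  list(calls = calls, samples = samples)
}

test_that("verification separates possible mutations from potential modifiers", {
  # 2 of 5 pedigree cases homozygous, none of 10 controls
  fx <- verification_fixture(c(2, 2, 1, 0, 0), rep(0, 10))
  v <- verify_in_cohorts(fx$calls, fx$samples, required_genotype = "hom_alt")
  expect_equal(v$verdict, "possible_putative_mutation")
  expect_equal(v$control_carriers, 0L)
  expect_equal(v$supporting_cohorts, "PED1")

  # carrier rule, present in cases and in 2 controls
  fx2 <- verification_fixture(c(1, 0, 0, 0, 0), c(2, 1, rep(0, 8)))
  v2 <- verify_in_cohorts(fx2$calls, fx2$samples, required_genotype = "carrier")
  expect_equal(v2$verdict, "potential_putative_effect_modifier")
  expect_equal(v2$control_carriers, 2L)

  # absent everywhere
  fx3 <- verification_fixture(rep(0, 5), rep(0, 10))
  v3 <- verify_in_cohorts(fx3$calls, fx3$samples)
  expect_equal(v3$verdict, "unsupported")

  # a mutation verdict never co-occurs with control carriers
  expect_true(all(!(v$verdict == "possible_putative_mutation" &
    v$control_carriers > 0)))

  empty <- fx$samples[0, ]
  expect_error(verify_in_cohorts(fx$calls, empty), "empty")
})

test_that("funnel counts follow the stage semantics and nested monotonicity", {
  all_v <- tibble::tibble(variant_id = sprintf("v%d", 1:10))
  shared <- tibble::tibble(
    variant_id = sprintf("v%d", 1:6),
    rsid = c("rs1", "rs2", "rs3", NA, "rs5", "rs6"),
    gene = c("GA", "GB", "GC", "GD", "ZZ", NA),
    maf = c(0.3, 0.005, 0.2, 0.001, 0.4, NA)
  )
  de_retained <- tibble::tibble(gene = c("GA", "GB", "GC", "GD"))
  pathways <- tibble::tibble(pathway = c("P1", "P1"), gene = c("GA", "GB"))
  enrichment <- tibble::tibble(pathway = "P1", significant = TRUE)
  fc <- funnel_counts(all_v, shared, de_retained, enrichment, pathways)
  expect_equal(fc$count, c(10L, 6L, 5L, 4L, 2L, 2L))
  nested <- fc$count[1:4]
  expect_true(all(diff(nested) <= 0))
  # empty intersection zeroes everything downstream
  fc0 <- funnel_counts(all_v, shared[0, ], de_retained, enrichment, pathways)
  expect_equal(fc0$count, c(10L, 0L, 0L, 0L, 0L, 0L))
  expect_s3_class(plot_funnel(fc), "ggplot")
})
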