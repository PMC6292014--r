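# The synthetic-cohort generator: determinism, Hardy-Weinberg structure, LD
# construction, the penetrance model and the DE/pathway plantings.

small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_cases = 30, n_controls = 30, pool_batch = 1000,
    include_funnel = FALSE,
    de = list(n_genes = 60, n_planted = 12, fold_change = 4, sigma = 0.35,
      n_lowdata = 3),
    pathways = list(n_sets = 5, set_size = 10, hub_membership = 2,
      de_fraction = 0.5), ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  c1 <- simulate_cohort(small_cfg(9))
  c2 <- simulate_cohort(small_cfg(9))
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$de, c2$de)
  expect_identical(c1$pathways, c2$pathways)
  expect_identical(c1$truth, c2$truth)
  # different seeds differ in genotypes but share the schema
  c3 <- simulate_cohort(small_cfg(10))
  expect_false(identical(c1$calls$dosage, c3$calls$dosage))
  expect_identical(names(c1$calls), names(c3$calls))
})

test_that("independent loci follow Hardy-Weinberg proportions", {
  cfg <- sim_config(seed = 3, include_funnel = FALSE, null_freq = 0.5)
  withr::with_seed(3, {
    plan <- omicsfunnel:::variant_plan(cfg)
    g <- simulate_genotypes(cfg, 10000, plan)
    v <- plan$variant_id[plan$name == "null_1"]
    props <- tabulate(g[, v] + 1, 3) / 10000
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
    expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se + 0.005))
  })
})

test_that("the LD pair is built from haplotypes hitting the target D'", {
  cfg <- sim_config(seed = 5, include_funnel = FALSE, ld_target = 1)
  withr::with_seed(5, {
    plan <- omicsfunnel:::variant_plan(cfg)
    g <- simulate_genotypes(cfg, 4000, plan)
    haps <- attr(g, "ld_haplotypes")
    expect_false(any(haps == 3)) # no recombinant aB class at D' = 1
  })
  expect_error(
    omicsfunnel:::ld_hap_freqs(0.4, 0.3, 1.5),
    "infeasible"
  )
})

test_that("a null penetrance model makes disease independent of genotype", {
  cfg <- sim_config(seed = 6, include_funnel = FALSE, mutation_effect = 1,
    interaction_effect = 1)
  withr::with_seed(6, {
    plan <- omicsfunnel:::variant_plan(cfg)
    g <- simulate_genotypes(cfg, 8000, plan)
    status <- assign_phenotypes(g, cfg, plan)
    # disease rate matches the baseline penetrance (3.5 binomial SE)
    expect_lt(abs(mean(status) - 0.1), 0.012)
    # and is independent of the mutation genotype
    mut <- plan$variant_id[plan$role == "mutation"]
    tab <- build_table(g[, mut], ifelse(status, "case", "control"), "carrier")
    expect_gt(chi2_independence(tab)$p.value, 0.001)
  })
})

test_that("balancing removes the modifier loci's marginal penetrance differences", {
  cfg <- sim_config(seed = 1)
  bal <- omicsfunnel:::solve_modifier_balance(cfg)
  grid <- expand.grid(gm = 0:2, ga = 0:2, gb = 0:2)
  pg <- stats::dbinom(grid$gm, 2, cfg$mutation_freq) *
    stats::dbinom(grid$ga, 2, cfg$modifier_freq[1]) *
    stats::dbinom(grid$gb, 2, cfg$modifier_freq[2])
  risk <- stats::plogis(stats::qlogis(cfg$penetrance) +
    log(cfg$mutation_effect) * (grid$gm == 2) +
    log(cfg$interaction_effect) * (grid$ga >= 1 & grid$gb >= 1) +
    bal$hA[grid$ga + 1] + bal$hB[grid$gb + 1])
  mA <- tapply(pg * risk, grid$ga, sum) / tapply(pg, grid$ga, sum)
  mB <- tapply(pg * risk, grid$gb, sum) / tapply(pg, grid$gb, sum)
  expect_lt(max(abs(mA - mA[1])), 1e-10)
  expect_lt(max(abs(mB - mB[1])), 1e-10)
  # the joint risk surface still carries the interaction
  expect_gt(max(risk) / min(risk), 2)
})

test_that("planted DE genes dominate the q < 0.05 set and statuses are set", {
  cfg <- small_cfg(11)
  out <- withr::with_seed(11, simulate_de_table(cfg))
  retained <- filter_de(out$de)
  expect_true(all(gene_planted <- out$planted %in% out$de$gene))
  expect_gt(mean(out$planted %in% retained$gene), 0.9)
  # few non-planted genes sneak in (BH at 5%)
  expect_lt(sum(!(retained$gene %in% out$planted)), 6)
  expect_equal(sum(out$de$status == "LOWDATA"), 3)
})

test_that("a flat fold change keeps the false-discovery proportion controlled", {
  cfg <- small_cfg(12)
  cfg$de$fold_change <- 1
  fdp <- withr::with_seed(12, {
    replicate(20, {
      out <- simulate_de_table(cfg)
      length(filter_de(out$de)$gene) # every call is false under the flat model
    })
  })
  # with no signal, BH keeps discoveries rare
  expect_lt(mean(fdp > 0), 0.3)
})

test_that("the pathway generator plants the hub and candidate memberships", {
  cfg <- small_cfg(13)
  out <- withr::with_seed(13, {
    de <- simulate_de_table(cfg)
    simulate_pathways(cfg, de$planted)
  })
  hub_sets <- unique(out$pathways$pathway[out$pathways$gene == out$hub_gene])
  expect_equal(sort(hub_sets), sort(out$enriched))
  expect_equal(length(hub_sets), cfg$pathways$hub_membership)
  sizes <- table(out$pathways$pathway)
  expect_true(all(sizes == cfg$pathways$set_size))
})

test_that("ascertainment fills the case and control quotas exactly", {
  cohort <- simulate_cohort(small_cfg(14))
  reps <- cohort$samples[cohort$samples$role == "replication", ]
  expect_equal(sum(reps$phenotype == "case"), 30)
  expect_equal(sum(reps$phenotype == "control"), 30)
  # an unreachable quota errors with the iteration budget
  hard <- small_cfg(15)
  hard$penetrance <- 0.001
  hard$max_batches <- 1L
  hard$n_cases <- 500
  expect_error(simulate_cohort(hard), "iteration budget")
})

test_that("emitted files validate against the readers without warnings", {
  dir <- tempfile()
  cohort <- emit_cohort(small_cfg(16), dir)
  expect_no_warning({
    samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
    read_vcf(file.path(dir, "cohort.vcf"), sample_sheet = samples)
    read_de_table(file.path(dir, "de_table.tsv"))
    read_gmt(file.path(dir, "pathways.gmt"))
  })
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$funnel$total, 6) # compact cohort: planted loci only
  # per-case VCFs list only carrier calls
  case1 <- read_vcf(file.path(dir, "cases", "DIS_CASE_1.vcf"))
  expect_true(all(case1$dosage >= 1))
})
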