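# Deterministic, seeded synthetic-cohort generator with planted ground truth.
#
# The generator emulates the statistical structure of a small integrative
# case-control study: a discovery RNA-seq arm (6 cases vs 4 controls) that
# yields per-case variant lists and a DE table; verification pedigrees plus
# population controls; and a larger replication case-control arm used for the
# chi-square association battery. Planted features: a penetrant recessive
# "mutation" locus, a pure-interaction effect-modifier pair (marginally
# balanced, see assign_phenotypes), a linkage-disequilibrium pair with a
# target D', a null locus, differential expression with a planted fold
# change, and pathway sets containing a planted hub gene.

gene_id <- function(i) sprintf("G%04d", i)

#' Configuration for the synthetic cohort generator
#'
#' Returns the full set of simulation parameters with defaults frozen to the
#' package's reference study conditions (see the methods vignette for the
#' power analysis behind them). All probabilities are in (0, 1) and odds
#' multipliers positive.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param n_cases,n_controls Replication (association) arm sizes.
#' @param penetrance Baseline disease probability for the reference genotype.
#' @param mutation_effect Odds multiplier for the mutation's required
#'   genotype.
#' @param mutation_genotype `"hom_alt"` (recessive, default) or `"carrier"`.
#' @param interaction_effect Odds multiplier applied only when both modifier
#'   loci are carriers.
#' @param balance_modifier_margins Solve per-locus compensating terms so each
#'   modifier locus has exactly flat marginal penetrance (a pure-epistasis
#'   model); on by default — without it, case-control ascertainment induces a
#'   direct marginal association at the modifier loci and they are no longer
#'   pure effect modifiers.
#' @param mutation_freq,modifier_freq,ld_freqs,null_freq Population alternate
#'   allele frequencies of the planted loci.
#' @param ld_target Target D' for the designated LD pair.
#' @param include_funnel Also generate the funnel filler variants (100
#'   variants total with planted stage memberships); turn off for compact
#'   association-only cohorts.
#' @param n_variants,n_shared,n_dbsnp,n_in_de,n_rare Funnel plantings: total
#'   variants, present-in-all-cases count, rsID-bearing count among shared,
#'   shared variants in DE genes, and rare (MAF < `rare_maf`) among those.
#' @param discovery Cases/controls in the discovery expression arm.
#' @param pedigrees,verification_controls Named sizes of the verification
#'   case cohorts and control pools.
#' @param de DE generator settings: `n_genes`, `n_planted`, `fold_change`,
#'   `sigma` (sd of log2 expression), `n_lowdata`.
#' @param pathways Pathway generator settings: `n_sets`, `set_size`,
#'   `hub_membership` (sets carrying the hub gene), `de_fraction` (planted-DE
#'   share of each enriched set).
#' @param rare_maf Rare-MAF threshold.
#' @param pool_batch,max_batches Rejection-sampling batch size and iteration
#'   budget for case-control ascertainment.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_cases = 500, n_controls = 500,
                       penetrance = 0.1,
                       mutation_effect = 6, mutation_genotype = c("hom_alt", "carrier"),
                       interaction_effect = 6,
                       balance_modifier_margins = TRUE,
                       mutation_freq = 0.5, modifier_freq = c(0.3, 0.3),
                       ld_freqs = c(0.4, 0.3), null_freq = 0.3,
                       ld_target = 1.0,
                       include_funnel = TRUE,
                       n_variants = 100, n_shared = 40, n_dbsnp = 38,
                       n_in_de = 12, n_rare = 3,
                       discovery = c(cases = 6, controls = 4),
                       pedigrees = c(PED1 = 3, PED2 = 5, PED3 = 5),
                       verification_controls = c(HAP_CEU = 5, HAP_CHB = 5, CTRL_IT = 1),
                       de = list(n_genes = 500, n_planted = 30, fold_change = 4,
                         sigma = 0.35, n_lowdata = 5),
                       pathways = list(n_sets = 10, set_size = 20,
                         hub_membership = 3, de_fraction = 0.5),
                       rare_maf = 0.01,
                       pool_batch = 5000, max_batches = 1000) {
  mutation_genotype <- match.arg(mutation_genotype)
  stopifnot(
    penetrance > 0, penetrance < 1,
    mutation_effect > 0, interaction_effect > 0,
    mutation_freq > 0, mutation_freq < 1,
    all(modifier_freq > 0), all(modifier_freq < 1),
    ld_target >= 0, ld_target <= 1,
    pathways$hub_membership <= pathways$n_sets
  )
  structure(
    list(
      seed = as.integer(seed), n_cases = n_cases, n_controls = n_controls,
      penetrance = penetrance, mutation_effect = mutation_effect,
      mutation_genotype = mutation_genotype,
      interaction_effect = interaction_effect,
      balance_modifier_margins = balance_modifier_margins,
      mutation_freq = mutation_freq, modifier_freq = modifier_freq,
      ld_freqs = ld_freqs, null_freq = null_freq, ld_target = ld_target,
      include_funnel = include_funnel,
      n_variants = n_variants, n_shared = n_shared, n_dbsnp = n_dbsnp,
      n_in_de = n_in_de, n_rare = n_rare,
      discovery = discovery, pedigrees = pedigrees,
      verification_controls = verification_controls,
      de = de, pathways = pathways, rare_maf = rare_maf,
      pool_batch = pool_batch, max_batches = max_batches
    ),
    class = "sim_config"
  )
}

#' Variant plan: identity, annotation and planted role of every simulated locus
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per simulated variant: key columns, `rsid`,
#'   `gene`, `maf`, planted `role` (mutation, modifier_pair_member,
#'   ld_partner, null), and the funnel plantings (`shared`, `rare`).
#' @export
variant_plan <- function(config) {
  planted <- tibble(
    name = c("mutation", "modifier_a", "modifier_b", "ld_a", "ld_b", "null_1"),
    role = c("mutation", "modifier_pair_member", "modifier_pair_member",
      "ld_partner", "ld_partner", "null"),
    freq = c(config$mutation_freq, config$modifier_freq, config$ld_freqs,
      config$null_freq),
    gene = gene_id(1:6),
    shared = TRUE, has_rsid = TRUE, rare = FALSE
  )
  if (!config$include_funnel) {
    plan <- planted
  } else {
    n_filler_de <- config$n_in_de - nrow(planted)
    n_shared_nonde <- config$n_shared - config$n_in_de
    n_nonshared <- config$n_variants - config$n_shared
    stopifnot(n_filler_de >= config$n_rare, n_shared_nonde >= 0, n_nonshared >= 0)
    filler_de <- tibble(
      name = sprintf("de_filler_%02d", seq_len(n_filler_de)),
      role = "null",
      freq = c(rep(0.005, config$n_rare), rep(0.2, n_filler_de - config$n_rare)),
      gene = gene_id(6 + seq_len(n_filler_de)),
      shared = TRUE, has_rsid = TRUE,
      rare = c(rep(TRUE, config$n_rare), rep(FALSE, n_filler_de - config$n_rare))
    )
    # variant-assigned non-DE genes come from a pool never used by the
    # pathway generator, so pathway membership of candidates is by design
    non_de_pool <- gene_id(201:(200 + n_shared_nonde + n_nonshared))
    missing_rsid <- c(rep(FALSE, max(0, n_shared_nonde - (config$n_shared - config$n_dbsnp))),
      rep(TRUE, config$n_shared - config$n_dbsnp))
    shared_nonde <- tibble(
      name = sprintf("shared_%02d", seq_len(n_shared_nonde)),
      role = "null",
      freq = rep(c(0.1, 0.2, 0.3, 0.4), length.out = n_shared_nonde),
      gene = non_de_pool[seq_len(n_shared_nonde)],
      shared = TRUE, has_rsid = !missing_rsid[seq_len(n_shared_nonde)],
      rare = FALSE
    )
    nonshared <- tibble(
      name = sprintf("private_%02d", seq_len(n_nonshared)),
      role = "null",
      freq = rep(c(0.05, 0.15, 0.25, 0.35), length.out = n_nonshared),
      gene = non_de_pool[n_shared_nonde + seq_len(n_nonshared)],
      shared = FALSE, has_rsid = TRUE, rare = FALSE
    )
    plan <- bind_rows(planted, filler_de, shared_nonde, nonshared)
  }
  n <- nrow(plan)
  plan$chrom <- "1"
  plan$pos <- 1000000L + 1000L * seq_len(n)
  plan$ref <- "A"
  plan$alt <- "G"
  plan$variant_id <- variant_id(plan$chrom, plan$pos, plan$ref, plan$alt)
  plan$rsid <- if_else(plan$has_rsid, sprintf("rs%d", 100000L + seq_len(n)),
    NA_character_)
  plan$maf <- if_else(plan$rare, plan$freq, pmin(plan$freq, 1 - plan$freq))
  plan
}

ld_hap_freqs <- function(pA, pB, d_prime) {
  d_max <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- d_prime * d_max
  haps <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
    (1 - pA) * (1 - pB) + D)
  if (any(haps < -1e-12)) {
    abort(sprintf(
      "Target D' %.3f infeasible for allele frequencies %.3f/%.3f (feasible D' <= %.3f).",
      d_prime, pA, pB, d_max / max(d_max, 1e-12)
    ))
  }
  pmax(haps, 0)
}

#' Simulate a genotype matrix under the configured variant plan
#'
#' Independent loci are drawn under Hardy-Weinberg equilibrium from their
#' allele frequencies; the designated LD pair is drawn by sampling two-locus
#' haplotypes constructed to have the target D' and pairing two haplotypes
#' per individual. The phased haplotypes of the LD pair are attached as the
#' `"ld_haplotypes"` attribute (the phased truth for EM recovery tests).
#'
#' @param config A [sim_config()].
#' @param n Number of individuals.
#' @param plan Optional precomputed variant plan (internal use).
#' @return Integer matrix `n x n_variants` of dosages, with variant ids as
#'   column names.
#' @export
simulate_genotypes <- function(config, n, plan = variant_plan(config)) {
  geno <- matrix(0L, nrow = n, ncol = nrow(plan),
    dimnames = list(NULL, plan$variant_id))
  ld_idx <- which(plan$role == "ld_partner")
  for (j in seq_len(nrow(plan))) {
    if (j %in% ld_idx) next
    geno[, j] <- rbinom(n, 2, plan$freq[j])
  }
  if (length(ld_idx) == 2) {
    haps <- ld_hap_freqs(plan$freq[ld_idx[1]], plan$freq[ld_idx[2]],
      config$ld_target)
    h1 <- sample.int(4, n, replace = TRUE, prob = haps)
    h2 <- sample.int(4, n, replace = TRUE, prob = haps)
    geno[, ld_idx[1]] <- HAP_A[h1] + HAP_A[h2]
    geno[, ld_idx[2]] <- HAP_B[h1] + HAP_B[h2]
    attr(geno, "ld_haplotypes") <- cbind(h1, h2)
  }
  geno
}

# Solve per-locus compensating logit terms so that both modifier loci have
# flat marginal penetrance, integrating over the full effect-locus grid
# (mutation x modifier A x modifier B).
solve_modifier_balance <- function(config) {
  if (!config$balance_modifier_margins) {
    return(list(hA = c(0, 0, 0), hB = c(0, 0, 0)))
  }
  grid <- expand.grid(gm = 0:2, ga = 0:2, gb = 0:2)
  pg <- dbinom(grid$gm, 2, config$mutation_freq) *
    dbinom(grid$ga, 2, config$modifier_freq[1]) *
    dbinom(grid$gb, 2, config$modifier_freq[2])
  mut_hit <- if (config$mutation_genotype == "hom_alt") grid$gm == 2 else grid$gm >= 1
  both <- grid$ga >= 1 & grid$gb >= 1
  hA <- hB <- c(0, 0, 0)
  for (i in seq_len(300)) {
    risk <- plogis(qlogis(config$penetrance) +
      log(config$mutation_effect) * mut_hit +
      log(config$interaction_effect) * both +
      hA[grid$ga + 1] + hB[grid$gb + 1])
    mA <- tapply(pg * risk, grid$ga, sum) / tapply(pg, grid$ga, sum)
    mB <- tapply(pg * risk, grid$gb, sum) / tapply(pg, grid$gb, sum)
    resid <- max(abs(qlogis(mA) - qlogis(mA[1])), abs(qlogis(mB) - qlogis(mB[1])))
    hA <- hA - (qlogis(mA) - qlogis(mA[1]))
    hB <- hB - (qlogis(mB) - qlogis(mB[1]))
    if (resid < 1e-12) break
  }
  list(hA = unname(hA), hB = unname(hB))
}

#' Assign disease status under the planted penetrance model
#'
#' Per-subject disease probability is logistic:
#' logit(penetrance) + log(mutation_effect) for the mutation's required
#' genotype + log(interaction_effect) when both modifier loci are carriers,
#' plus (by default) the marginal-balancing terms that keep each modifier
#' locus free of any direct genotype-disease association (see the methods
#' vignette). Disease status is then a Bernoulli draw per subject.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param config The [sim_config()].
#' @param plan Optional precomputed variant plan.
#' @return Logical vector: diseased or not, one per row of `genotypes`.
#' @export
assign_phenotypes <- function(genotypes, config, plan = variant_plan(config)) {
  mut <- genotypes[, plan$variant_id[plan$role == "mutation"][1]]
  mods <- plan$variant_id[plan$role == "modifier_pair_member"]
  ga <- genotypes[, mods[1]]
  gb <- genotypes[, mods[2]]
  mut_hit <- if (config$mutation_genotype == "hom_alt") mut == 2 else mut >= 1
  both <- ga >= 1 & gb >= 1
  bal <- solve_modifier_balance(config)
  lin <- qlogis(config$penetrance) +
    log(config$mutation_effect) * mut_hit +
    log(config$interaction_effect) * both +
    bal$hA[ga + 1] + bal$hB[gb + 1]
  rbinom(length(lin), 1, plogis(lin)) == 1
}

# draw a carrier dosage from HWE conditional on dosage >= 1
draw_carrier <- function(n, p) {
  pr <- c(2 * p * (1 - p), p^2)
  sample(1:2, n, replace = TRUE, prob = pr)
}

# Discovery-arm genotypes: shared variants are forced present (carrier) in
# every case; the mutation is homozygous-alt in every case; non-shared
# variants are guaranteed absent from at least one case.
simulate_discovery <- function(config, plan) {
  n_ca <- config$discovery[["cases"]]
  n_co <- config$discovery[["controls"]]
  ids <- c(sprintf("DIS_CASE_%d", seq_len(n_ca)), sprintf("DIS_CTRL_%d", seq_len(n_co)))
  geno <- matrix(0L, nrow = n_ca + n_co, ncol = nrow(plan),
    dimnames = list(ids, plan$variant_id))
  for (j in seq_len(nrow(plan))) {
    p <- plan$freq[j]
    g <- rbinom(n_ca + n_co, 2, p)
    if (plan$shared[j]) {
      if (plan$role[j] == "mutation") {
        g[seq_len(n_ca)] <- 2L
      } else {
        g[seq_len(n_ca)] <- draw_carrier(n_ca, p)
      }
    } else if (all(g[seq_len(n_ca)] >= 1)) {
      g[1] <- 0L
    }
    geno[, j] <- g
  }
  geno
}

# Verification-arm genotypes implementing the planted verification verdicts:
# mutation present (hom-alt in two members of the last pedigree) in cases and
# absent from every control; modifier and LD loci carried in pedigrees and in
# two controls each.
simulate_verification <- function(config, plan) {
  ped_ids <- unlist(purrr::imap(as.list(config$pedigrees), function(k, nm) {
    sprintf("%s_%d", nm, seq_len(k))
  }), use.names = FALSE)
  ctl_ids <- unlist(purrr::imap(as.list(config$verification_controls), function(k, nm) {
    sprintf("%s_%d", nm, seq_len(k))
  }), use.names = FALSE)
  ids <- c(ped_ids, ctl_ids)
  geno <- matrix(0L, nrow = length(ids), ncol = nrow(plan),
    dimnames = list(ids, plan$variant_id))
  n_ped <- length(ped_ids)
  last_ped <- names(config$pedigrees)[length(config$pedigrees)]
  last_members <- grep(paste0("^", last_ped, "_"), ids)
  for (j in seq_len(nrow(plan))) {
    role <- plan$role[j]
    if (role == "mutation") {
      g <- rep(0L, length(ids))
      g[seq_len(n_ped)] <- 1L
      g[last_members[1:2]] <- 2L
      g[(n_ped + 1):length(ids)] <- 0L
    } else if (role %in% c("modifier_pair_member", "ld_partner")) {
      g <- rep(0L, length(ids))
      first_two <- function(prefix) grep(paste0("^", prefix, "_"), ids)[1:2]
      for (nm in names(config$pedigrees)) g[first_two(nm)[1]] <- 1L
      g[n_ped + 1:2] <- 1L # two verification controls carry it
    } else {
      g <- rbinom(length(ids), 2, plan$freq[j])
    }
    geno[, j] <- g
  }
  geno
}

geno_to_calls <- function(geno, plan, with_quality = FALSE) {
  long <- tibble(
    sample_id = rep(rownames(geno), times = ncol(geno)),
    variant_id = rep(colnames(geno), each = nrow(geno)),
    dosage = as.integer(geno)
  )
  long <- left_join(long,
    plan[, c("variant_id", "chrom", "pos", "ref", "alt", "rsid", "gene", "maf")],
    by = "variant_id")
  long$genotype <- dosage_to_code(long$dosage)
  if (with_quality) {
    long$gq <- sample(60:99, nrow(long), replace = TRUE)
    long$dp <- sample(20:60, nrow(long), replace = TRUE)
  } else {
    long$gq <- NA_integer_
    long$dp <- NA_integer_
  }
  long[, c("chrom", "pos", "ref", "alt", "variant_id", "rsid", "gene", "maf",
    "sample_id", "genotype", "dosage", "gq", "dp")]
}

#' Simulate the differential-expression table
#'
#' Log-normal FPKMs: per-gene log2 baseline ~ N(5, 1), within-group noise
#' sd `sigma`; planted genes are shifted by log2(fold_change) in cases. The
#' per-gene test is a two-sample t-test on log2(FPKM + 1); q-values are BH.
#' The last `n_lowdata` genes are marked LOWDATA.
#'
#' @param config A [sim_config()].
#' @return A list: `de` (tibble in [read_de_table()] layout) and `planted`
#'   (character vector of planted gene names).
#' @export
simulate_de_table <- function(config) {
  de_cfg <- config$de
  if (de_cfg$n_planted > de_cfg$n_genes) {
    abort("`n_planted` cannot exceed `n_genes`.")
  }
  genes <- gene_id(seq_len(de_cfg$n_genes))
  planted <- genes[seq_len(de_cfg$n_planted)]
  n_ca <- config$discovery[["cases"]]
  n_co <- config$discovery[["controls"]]
  mu <- rnorm(de_cfg$n_genes, mean = 5, sd = 1)
  shift <- if_else(genes %in% planted, log2(de_cfg$fold_change), 0)
  case_mat <- matrix(rnorm(de_cfg$n_genes * n_ca, mu + shift, de_cfg$sigma),
    nrow = de_cfg$n_genes)
  ctrl_mat <- matrix(rnorm(de_cfg$n_genes * n_co, mu, de_cfg$sigma),
    nrow = de_cfg$n_genes)
  fpkm_case_mat <- 2^case_mat
  fpkm_ctrl_mat <- 2^ctrl_mat
  tt <- purrr::map(seq_len(de_cfg$n_genes), function(i) {
    # pooled-variance t: the generator's groups are homoscedastic by
    # construction, and Welch df can collapse at n = 6 vs 4
    t <- stats::t.test(log2(fpkm_case_mat[i, ] + 1), log2(fpkm_ctrl_mat[i, ] + 1),
      var.equal = TRUE)
    c(stat = unname(t$statistic), p = t$p.value)
  })
  stat <- purrr::map_dbl(tt, "stat")
  p <- purrr::map_dbl(tt, "p")
  fpkm_case <- rowMeans(fpkm_case_mat)
  fpkm_control <- rowMeans(fpkm_ctrl_mat)
  status <- rep("OK", de_cfg$n_genes)
  if (de_cfg$n_lowdata > 0) {
    status[(de_cfg$n_genes - de_cfg$n_lowdata + 1):de_cfg$n_genes] <- "LOWDATA"
  }
  de <- tibble(
    gene = genes,
    fpkm_case = fpkm_case,
    fpkm_control = fpkm_control,
    log2_ratio = log2_ratio(fpkm_case, fpkm_control),
    test_stat = stat,
    p = p,
    q = bh_adjust(p),
    status = status
  )
  list(de = de, planted = planted)
}

#' Simulate pathway gene sets with a planted hub
#'
#' The hub gene (the mutation's gene) is inserted into `hub_membership`
#' enriched sets; every enriched set also contains the other candidate genes
#' and is filled to `de_fraction` with planted DE genes, the remainder drawn
#' from a reserved non-DE pool. The remaining sets are null sets of non-DE
#' genes only.
#'
#' @param config A [sim_config()].
#' @param planted Planted DE gene names (from [simulate_de_table()]).
#' @return A list: `pathways` (long tibble), `enriched` (names of the planted
#'   enriched sets), `hub_gene`.
#' @export
simulate_pathways <- function(config, planted) {
  pw <- config$pathways
  hub <- gene_id(1)
  candidate_genes <- gene_id(1:5)
  fill_planted <- setdiff(intersect(planted, gene_id(13:30)), candidate_genes)
  reserved_nonde <- gene_id(31:200)
  n_planted_per_set <- max(length(candidate_genes),
    round(pw$de_fraction * pw$set_size))
  sets <- purrr::map(seq_len(pw$n_sets), function(k) {
    name <- sprintf("P%02d", k)
    if (k <= pw$hub_membership) {
      extra <- sample(fill_planted, n_planted_per_set - length(candidate_genes))
      genes <- c(candidate_genes, extra,
        sample(reserved_nonde, pw$set_size - n_planted_per_set))
    } else {
      genes <- sample(reserved_nonde, pw$set_size)
    }
    tibble(pathway = name, description = "synthetic gene set", gene = genes)
  })
  list(
    pathways = bind_rows(sets),
    enriched = sprintf("P%02d", seq_len(pw$hub_membership)),
    hub_gene = hub
  )
}

#' Simulate the full cohort with its ground-truth manifest
#'
#' Deterministically (given `config$seed`) generates the discovery,
#' verification and replication arms, the DE table and the pathway sets, and
#' assembles the ground truth: per-variant planted role, expected
#' classification and verification verdicts, planted DE genes and enriched
#' pathways, and the expected funnel counts (evaluated on the emitted data,
#' so BH-filter randomness is reflected exactly).
#'
#' Replication cases and controls are collected by rejection sampling
#' (case-control ascertainment): population batches are simulated and
#' diseased/healthy subjects accumulated until the quotas are met.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `calls`, `samples`, `de`,
#'   `pathways`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  withr::with_seed(config$seed, {
    plan <- variant_plan(config)

    # replication arm by ascertainment
    n_needed <- c(case = config$n_cases, control = config$n_controls)
    got_case <- got_ctrl <- NULL
    batches <- 0L
    while ((is.null(got_case) || nrow(got_case) < n_needed["case"]) ||
           (is.null(got_ctrl) || nrow(got_ctrl) < n_needed["control"])) {
      batches <- batches + 1L
      if (batches > config$max_batches) {
        abort(sprintf(
          "Case quota unreachable within the iteration budget (%d batches).",
          config$max_batches
        ))
      }
      geno <- simulate_genotypes(config, config$pool_batch, plan)
      status <- assign_phenotypes(geno, config, plan)
      got_case <- rbind(got_case, geno[status, , drop = FALSE])
      got_ctrl <- rbind(got_ctrl, geno[!status, , drop = FALSE])
    }
    rep_case <- got_case[seq_len(n_needed["case"]), , drop = FALSE]
    rep_ctrl <- got_ctrl[seq_len(n_needed["control"]), , drop = FALSE]
    rownames(rep_case) <- sprintf("REP_CASE_%03d", seq_len(nrow(rep_case)))
    rownames(rep_ctrl) <- sprintf("REP_CTRL_%03d", seq_len(nrow(rep_ctrl)))

    disc <- simulate_discovery(config, plan)
    ver <- simulate_verification(config, plan)

    samples <- bind_rows(
      tibble(sample_id = rownames(disc),
        phenotype = rep(c("case", "control"), config$discovery),
        cohort = "discovery", role = "discovery"),
      tibble(sample_id = rownames(ver),
        phenotype = if_else(grepl("^PED", rownames(ver)), "case", "control"),
        cohort = sub("_[0-9]+$", "", rownames(ver)),
        role = "verification"),
      tibble(sample_id = c(rownames(rep_case), rownames(rep_ctrl)),
        phenotype = rep(c("case", "control"),
          c(nrow(rep_case), nrow(rep_ctrl))),
        cohort = "replication", role = "replication")
    )

    calls <- bind_rows(
      geno_to_calls(disc, plan, with_quality = TRUE),
      geno_to_calls(ver, plan),
      geno_to_calls(rbind(rep_case, rep_ctrl), plan)
    )

    de_sim <- simulate_de_table(config)
    pw_sim <- simulate_pathways(config, de_sim$planted)

    # expected verdicts for the candidate variants (by planted role)
    mods <- plan$variant_id[plan$role == "modifier_pair_member"]
    truth_class <- tibble(
      variant_id = plan$variant_id[plan$role != "null" | plan$name == "null_1"],
      role = plan$role[plan$role != "null" | plan$name == "null_1"]
    ) |>
      mutate(expected_verdict = dplyr::case_when(
        .data$role == "mutation" ~ "putative_mutation",
        .data$role == "modifier_pair_member" ~ "putative_effect_modifier",
        TRUE ~ "unclassified"
      ),
      expected_partner = dplyr::case_when(
        .data$variant_id == mods[1] ~ mods[2],
        .data$variant_id == mods[2] ~ mods[1],
        TRUE ~ NA_character_
      ))

    truth_verify <- tibble(
      variant_id = plan$variant_id[plan$role %in%
        c("mutation", "modifier_pair_member", "ld_partner")],
      expected_verdict = if_else(
        plan$role[plan$role %in%
          c("mutation", "modifier_pair_member", "ld_partner")] == "mutation",
        "possible_putative_mutation", "potential_putative_effect_modifier")
    )

    # expected funnel, evaluated on the emitted DE table / pathway sets
    retained <- filter_de(de_sim$de)
    universe <- de_sim$de$gene[de_sim$de$status == "OK"]
    enr <- enrich_pathways(retained$gene, pw_sim$pathways, universe)
    shared_plan <- plan[plan$shared, , drop = FALSE]
    sig_genes <- unique(pw_sim$pathways$gene[
      pw_sim$pathways$pathway %in% enr$pathway[enr$significant]])
    in_de <- shared_plan[shared_plan$gene %in% retained$gene, , drop = FALSE]
    truth_funnel <- tibble(
      stage = FUNNEL_STAGES,
      count = as.integer(c(
        nrow(plan), nrow(shared_plan), sum(!is.na(shared_plan$rsid)),
        nrow(in_de),
        sum(!is.na(in_de$maf) & in_de$maf < config$rare_maf),
        sum(in_de$gene %in% sig_genes)
      ))
    )

    truth <- list(
      variant_roles = plan[, c("variant_id", "name", "role", "freq", "gene",
        "shared", "rare")],
      classification = truth_class,
      verification = truth_verify,
      planted_de_genes = de_sim$planted,
      retained_de_genes = retained$gene,
      enriched_pathways = pw_sim$enriched,
      hub_gene = pw_sim$hub_gene,
      funnel = truth_funnel,
      ld_pair = plan$variant_id[plan$role == "ld_partner"],
      ld_target = config$ld_target
    )

    structure(
      list(calls = calls, samples = samples, de = de_sim$de,
        pathways = pw_sim$pathways, truth = truth, config = config),
      class = "sim_cohort"
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (all samples), one per-case VCF under `cases/` for each
#' discovery case (non-reference calls only, as a variant caller would), the
#' sample sheet, the DE table, the GMT pathway file and the ground-truth
#' manifest `truth.json`. Re-reading the files through the package readers
#' reproduces the in-memory objects.
#'
#' @param config A [sim_config()] (or an already-simulated `sim_cohort`).
#' @param out_dir Output directory.
#' @return The `sim_cohort`, invisibly, with a `files` attribute listing the
#'   written paths.
#' @export
emit_cohort <- function(config, out_dir) {
  cohort <- if (inherits(config, "sim_cohort")) config else simulate_cohort(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    de = file.path(out_dir, "de_table.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_vcf(cohort$calls, files["vcf"])
  write_sample_sheet(cohort$samples, files["samples"])
  write_de_table(cohort$de, files["de"])
  write_gmt(cohort$pathways, files["gmt"])

  case_dir <- file.path(out_dir, "cases")
  if (!dir.exists(case_dir)) dir.create(case_dir)
  disc_cases <- cohort$samples$sample_id[
    cohort$samples$role == "discovery" & cohort$samples$phenotype == "case"]
  for (s in disc_cases) {
    per_case <- cohort$calls |>
      filter(.data$sample_id == s, !is.na(.data$dosage), .data$dosage >= 1)
    write_vcf(per_case, file.path(case_dir, paste0(s, ".vcf")))
  }
  files <- c(files, setNames(file.path(case_dir, paste0(disc_cases, ".vcf")),
    disc_cases))

  truth_json <- cohort$truth
  truth_json$funnel <- as.list(setNames(truth_json$funnel$count,
    truth_json$funnel$stage))
  writeLines(jsonlite::toJSON(truth_json, dataframe = "rows", auto_unbox = TRUE,
    digits = 10, pretty = TRUE, na = "null"), files[["truth"]])
  attr(cohort, "files") <- files
  invisible(cohort)
}
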