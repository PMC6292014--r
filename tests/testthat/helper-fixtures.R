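# Fixtures are built in code at test time; nothing binary ships with the
# package.

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

mini_vcf_header <- function(samples) {
  c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"MAF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
}

# compact association-arm cohort: planted mutation, balanced modifier pair,
# LD pair and a null locus, ascertained to n cases / n controls
simulate_association_arm <- function(seed, n_cases = 500, n_controls = 500,
                                     ...) {
  cfg <- sim_config(seed = seed, n_cases = n_cases, n_controls = n_controls,
    include_funnel = FALSE, ...)
  plan <- omicsfunnel:::variant_plan(cfg)
  withr::with_seed(cfg$seed, {
    got_case <- got_ctrl <- NULL
    for (i in 1:50) {
      geno <- simulate_genotypes(cfg, cfg$pool_batch, plan)
      status <- assign_phenotypes(geno, cfg, plan)
      got_case <- rbind(got_case, geno[status, , drop = FALSE])
      got_ctrl <- rbind(got_ctrl, geno[!status, , drop = FALSE])
      if (nrow(got_case) >= n_cases && nrow(got_ctrl) >= n_controls) break
    }
    geno <- rbind(got_case[seq_len(n_cases), , drop = FALSE],
      got_ctrl[seq_len(n_controls), , drop = FALSE])
  })
  ids <- sprintf("S%04d", seq_len(nrow(geno)))
  calls <- tibble::tibble(
    variant_id = rep(colnames(geno), each = nrow(geno)),
    sample_id = rep(ids, times = ncol(geno)),
    dosage = as.integer(geno)
  )
  samples <- tibble::tibble(
    sample_id = ids,
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    cohort = "replication", role = "replication"
  )
  list(calls = calls, samples = samples, plan = plan)
}

# independent brute-force seed-site scanner used as the oracle: builds the
# three literal site patterns with Biostrings and applies the precedence rule
# on match positions
brute_force_seed_scan <- function(mature_mirna, utr_seq) {
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  mir_dna <- chartr("Uu", "Tt", toupper(mature_mirna))
  utr <- chartr("Uu", "Tt", toupper(utr_seq))
  core <- rc(substr(mir_dna, 2, 7))
  m8 <- rc(substr(mir_dna, 8, 8))
  p8 <- paste0(m8, core, "A")
  p7m8 <- paste0(m8, core)
  p71a <- paste0(core, "A")
  find_all <- function(pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), utr, perl = TRUE)[[1]]
    if (hits[1] == -1) integer() else as.integer(hits)
  }
  s8 <- find_all(p8)
  s7m8 <- setdiff(find_all(p7m8), s8)
  s71a <- setdiff(find_all(p71a), s8 + 1L)
  out <- rbind(
    if (length(s8)) data.frame(site_type = "8mer", start = s8, end = s8 + 7L),
    if (length(s7m8)) data.frame(site_type = "7mer-m8", start = s7m8, end = s7m8 + 6L),
    if (length(s71a)) data.frame(site_type = "7mer-1A", start = s71a, end = s71a + 6L)
  )
  if (is.null(out)) {
    return(data.frame(site_type = character(), start = integer(), end = integer()))
  }
  out[order(out$start, out$site_type), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
  collapse = "")

# exact hypergeometric right tail by enumeration (the independent oracle)
enumerate_tail <- function(x, query, universe, set) {
  js <- x:min(set, query)
  sum(choose(query, js) * choose(universe - query, set - js)) / choose(universe, set)
}
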