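# Frequencies and the EM haplotype / linkage-disequilibrium estimator.

test_that("allele_frequency counts alt alleles over non-missing genotypes", {
  expect_equal(allele_frequency(c(2, 2, 2)), 1)
  expect_equal(allele_frequency(c(0, 1, 2)), 0.5)
  set.seed(8)
  g <- sample(c(0:2, NA), 200, replace = TRUE)
  expect_equal(allele_frequency(g),
    sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))))
  expect_error(allele_frequency(c(NA, NA)), "missing")
})

test_that("carrier_frequency reproduces the printed cohort frequencies", {
  expect_equal(round(carrier_frequency(39, 143), 6), 0.272727)
  expect_equal(round(carrier_frequency(37, 143), 6), 0.258741)
  expect_equal(carrier_frequency(0, 10), 0)
  expect_error(carrier_frequency(5, 0), "positive")
  expect_error(carrier_frequency(11, 10), "n_total")
})

test_that("ld_stats matches the closed-form derivations", {
  perfect <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r2, 1)

  # equilibrium: products of the margins
  eq <- ld_stats(c(0.35 * 0.2, 0.35 * 0.8, 0.65 * 0.2, 0.65 * 0.8))
  expect_equal(eq$D, 0, tolerance = 1e-12)
  expect_equal(eq$D_prime, 0)

  # hand evaluation at (0.4, 0.1, 0.1, 0.4): pA = pB = 0.5, D = 0.15,
  # D_max = 0.25 so D' = 0.6 and r2 = 0.15^2 / 0.0625 = 0.36
  mid <- ld_stats(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(mid$D, 0.15)
  expect_equal(mid$D_prime, 0.6)
  expect_equal(mid$r2, 0.36)

  mono <- ld_stats(c(0.5, 0.5, 0, 0))
  expect_true(is.na(mono$D_prime) && is.na(mono$r2))
  expect_true(mono$monomorphic)
  expect_error(ld_stats(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("EM resolves unambiguous cohorts by direct haplotype counting", {
  # no double heterozygotes: half hom-alt/hom-alt, half hom-ref/hom-ref
  fit <- em_haplotype_freqs(c(rep(2, 40), rep(0, 40)), c(rep(2, 40), rep(0, 40)))
  expect_equal(unname(fit$hap_freqs), c(0.5, 0, 0, 0.5))
  expect_equal(fit$D, 0.25)
  expect_equal(fit$D_prime, 1)
  expect_equal(fit$r2, 1)
})

test_that("EM stays at the symmetric point when every sample is a double het", {
  fit <- em_haplotype_freqs(rep(1, 30), rep(1, 30))
  expect_equal(fit$D, 0, tolerance = 1e-9)
  expect_equal(unname(fit$hap_freqs), rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and frequencies stay a simplex", {
  set.seed(11)
  for (i in 1:25) {
    a <- rbinom(120, 2, runif(1, 0.15, 0.85))
    b <- rbinom(120, 2, runif(1, 0.15, 0.85))
    if (allele_frequency(a) %in% c(0, 1) || allele_frequency(b) %in% c(0, 1)) next
    fit <- em_haplotype_freqs(a, b)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_true(all(fit$hap_freqs >= 0))
    expect_equal(sum(fit$hap_freqs), 1, tolerance = 1e-9)
    # |D| <= D_max and r2 <= 1
    if (!fit$monomorphic) {
      expect_lte(fit$D_prime, 1 + 1e-9)
      expect_lte(fit$r2, 1 + 1e-9)
    }
  }
})

test_that("EM recovers the phased simulation truth", {
  cfg <- sim_config(seed = 21, include_funnel = FALSE)
  withr::with_seed(21, {
    plan <- omicsfunnel:::variant_plan(cfg)
    g <- simulate_genotypes(cfg, 1500, plan)
    ld <- plan$variant_id[plan$role == "ld_partner"]
    haps <- attr(g, "ld_haplotypes")
    fit <- em_haplotype_freqs(g[, ld[1]], g[, ld[2]])
    truth <- tabulate(c(haps), nbins = 4) / (2 * nrow(g))
    # phase discarded yet frequencies match the phased truth within 2 SE
    se <- sqrt(truth * (1 - truth) / (2 * nrow(g)))
    expect_true(all(abs(unname(fit$hap_freqs) - truth) <= 2 * se + 1e-3))
    # target D' = 1 leaves no recombinant class, so the estimate is exact
    expect_equal(fit$D_prime, 1)
  })
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- em_haplotype_freqs(c(rep(2, 20), rep(0, 20)), c(rep(2, 20), rep(0, 20)))
  td <- generics::tidy(fit)
  expect_equal(td$haplotype, c("AB", "Ab", "aB", "ab"))
  expect_equal(sum(td$frequency), 1)
  gl <- generics::glance(fit)
  expect_equal(gl$D_prime, 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
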