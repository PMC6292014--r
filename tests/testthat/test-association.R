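# The chi-square engine, the table constructions and BH adjustment.

test_that("chi2_independence matches the hand-derived closed forms", {
  # 2x2 closed form N(ad-bc)^2 / (r1 r2 c1 c2) on [[5,0],[0,5]] = 10
  plain <- chi2_independence(matrix(c(5, 0, 0, 5), 2), yates = "off")
  expect_equal(plain$statistic, 10)
  expect_equal(plain$df, 1L)
  # Yates: each cell (2.5 - 0.5)^2 / 2.5 = 1.6, total 6.4
  yates <- chi2_independence(matrix(c(5, 0, 0, 5), 2), yates = "on")
  expect_equal(yates$statistic, 6.4)
  expect_true(yates$expected_warning) # expected cells are 2.5
})

test_that("perfectly proportional tables give statistic 0 and p 1 under Yates", {
  t0 <- chi2_independence(matrix(c(10, 10, 10, 10), 2), yates = "auto")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
  t1 <- chi2_independence(matrix(c(20, 10, 40, 20), 2), yates = "on")
  expect_equal(t1$statistic, 0)
})

test_that("the engine agrees with the reference implementation on random tables", {
  set.seed(2024)
  for (i in 1:200) {
    r <- sample(2:5, 1)
    cc <- sample(2:4, 1)
    m <- matrix(rpois(r * cc, lambda = sample(3:15, 1)) + 1, r, cc)
    ours_plain <- chi2_independence(m, yates = "off")
    ref_plain <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours_plain$statistic, unname(ref_plain$statistic), tolerance = 1e-12)
    expect_equal(ours_plain$p.value, ref_plain$p.value, tolerance = 1e-12)
    expect_equal(ours_plain$df, unname(ref_plain$parameter))
    ours_y <- chi2_independence(m, yates = "auto")
    ref_y <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(ours_y$statistic, unname(ref_y$statistic), tolerance = 1e-12)
  }
})

test_that("degenerate tables error naming the collapsed margin", {
  expect_error(chi2_independence(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
    "row margin")
  expect_error(chi2_independence(matrix(c(5, 0, 5, 0), 2, byrow = TRUE)),
    "column margin")
  expect_error(chi2_independence(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("chi2_gof implements the test for probabilities", {
  g0 <- chi2_gof(c(25, 25, 25, 25), rep(0.25, 4))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)
  g1 <- chi2_gof(c(30, 20), c(0.5, 0.5))
  expect_equal(g1$statistic, 2)
  expect_equal(g1$df, 1L)
  ref <- stats::chisq.test(c(30, 20), p = c(0.5, 0.5))
  expect_equal(g1$statistic, unname(ref$statistic))
  expect_equal(g1$p.value, ref$p.value)
  expect_error(chi2_gof(c(10), c(1)), "two categories")
  expect_error(chi2_gof(c(10, 5), c(0, 1)), "probability 0")
  expect_error(chi2_gof(c(10, 5), c(0.6, 0.6)), "sum to 1")
})

test_that("build_table produces the documented constructions", {
  dosage <- c(2, 2, 2, 1)
  phen <- c("case", "case", "case", "control")
  tg <- build_table(dosage, phen, "genotype")
  expect_equal(unname(tg), rbind(c(0L, 1L), c(3L, 0L)), ignore_attr = TRUE)
  expect_equal(rownames(tg), c("het", "hom_alt"))
  # stratum on the same data reproduces the spec's [[3,0],[0,1]] layout
  ts <- build_table(dosage, phen, "stratum", focus_genotype = "hom_alt")
  expect_equal(unname(ts), rbind(c(3L, 0L), c(0L, 1L)), ignore_attr = TRUE)
  tc <- build_table(c(0, 1, 2, 0), c("case", "case", "control", "control"), "carrier")
  expect_equal(unname(tc), matrix(c(1L, 1L, 1L, 1L), 2), ignore_attr = TRUE)
  expect_error(build_table(c(NA, NA), c("case", "control"), "carrier"),
    "non-missing")
  expect_error(build_table(dosage, phen, "stratum"), "focus_genotype")
})

test_that("table margins equal the genotype-class and phenotype tallies", {
  set.seed(5)
  for (i in 1:20) {
    n <- 60
    dosage <- sample(c(0:2, NA), n, replace = TRUE, prob = c(.4, .3, .2, .1))
    phen <- sample(c("case", "control"), n, replace = TRUE)
    tab <- build_table(dosage, phen, "genotype")
    keep <- !is.na(dosage)
    expect_equal(sum(tab), sum(keep))
    expect_equal(unname(colSums(tab)),
      unname(c(sum(phen[keep] == "case"), sum(phen[keep] == "control"))))
    cls <- table(factor(dosage_code <- c("hom_ref", "het", "hom_alt")[dosage[keep] + 1],
      levels = c("hom_ref", "het", "hom_alt")))
    expect_equal(unname(rowSums(tab)), unname(as.integer(cls[cls > 0])))
  }
})

test_that("build_joint_table captures dependence and irregular df", {
  # identical vectors give a diagonal table with a positive statistic
  g <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 0)
  tj <- build_joint_table(g, g)
  expect_true(all(tj[upper.tri(tj)] == 0) && all(tj[lower.tri(tj)] == 0))
  expect_gt(chi2_independence(tj, yates = "off")$statistic, 0)

  # 4 observed joint categories x 2 phenotypes -> df = 3
  ga <- c(0, 0, 1, 1, 0, 0, 1, 1)
  gb <- c(0, 1, 0, 1, 0, 1, 0, 1)
  ph <- rep(c("case", "control"), each = 4)
  t3 <- build_joint_table(ga, gb, ph)
  expect_equal(nrow(t3), 4)
  expect_equal(chi2_independence(t3, yates = "off")$df, 3L)
  expect_error(build_joint_table(c(NA, NA), c(1, NA)), "overlapping")
})

test_that("joint-table p-values are near-uniform under independence", {
  set.seed(7)
  ps <- replicate(300, {
    a <- rbinom(300, 2, 0.4)
    b <- rbinom(300, 2, 0.35)
    chi2_independence(build_joint_table(a, b), yates = "off")$p.value
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_adjust is the BH step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- sort(runif(20))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= -1e-12)) # monotone on sorted input
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("tidy and glance return one-row summaries", {
  tt <- chi2_independence(matrix(c(5, 1, 2, 6), 2), construction = "carrier")
  td <- generics::tidy(tt)
  expect_equal(nrow(td), 1)
  expect_equal(td$construction, "carrier")
  expect_equal(td$statistic, tt$statistic)
  expect_equal(generics::glance(tt)$p.value, tt$p.value)
})
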