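# DE significance filtering, the log2 ratio, and hypergeometric pathway
# over-representation (with the brute-force enumeration oracle).

make_de <- function(q, status = rep("OK", length(q))) {
  tibble::tibble(
    gene = sprintf("G%02d", seq_along(q)), fpkm_case = 2, fpkm_control = 1,
    log2_ratio = 1, test_stat = 1, p = q / 2, q = q, status = status
  )
}

test_that("filter_de applies the strict q threshold and the OK-status rule", {
  de <- make_de(c(0.013927, 0.05, 0.01), c("OK", "OK", "FAIL"))
  kept <- filter_de(de, q_max = 0.05)
  expect_equal(kept$gene, "G01") # q = 0.05 dropped (strict), FAIL dropped
  kept2 <- filter_de(de, q_max = 0.05, require_ok = FALSE)
  expect_equal(kept2$gene, c("G01", "G03"))
  expect_equal(nrow(filter_de(de[0, ], 0.05)), 0)
})

test_that("filter_de is monotone in the threshold", {
  set.seed(42)
  de <- make_de(runif(50))
  qs <- c(0.01, 0.05, 0.2, 0.8)
  for (i in seq_len(length(qs) - 1)) {
    a <- filter_de(de, qs[i])$gene
    b <- filter_de(de, qs[i + 1])$gene
    expect_true(all(a %in% b))
  }
})

test_that("log2_ratio handles finite, infinite and undefined cases", {
  expect_equal(log2_ratio(2, 1), 1)
  expect_equal(log2_ratio(5.2944, 0), Inf)
  expect_equal(log2_ratio_flag(5.2944, 0), "case_only")
  expect_equal(log2_ratio_flag(0, 3), "control_only")
  expect_true(is.nan(log2_ratio(0, 0)))
  expect_equal(log2_ratio_flag(0, 0), "undefined")
  expect_error(log2_ratio(-1, 2), "non-negative")
  # antisymmetry
  set.seed(1)
  a <- runif(20, 0.1, 50)
  b <- runif(20, 0.1, 50)
  expect_equal(log2_ratio(a, b), -log2_ratio(b, a))
})

test_that("enrichment p equals the exact hypergeometric tail by enumeration", {
  # the spec-style closed case: query of 5, pathway the same 5, universe 20
  uni <- sprintf("g%02d", 1:20)
  e <- enrich_pathways(uni[1:5], list(S = uni[1:5]), uni)
  expect_equal(e$p, 1 / choose(20, 5))

  # all instances with universe <= 30
  set.seed(99)
  for (rep in 1:60) {
    N <- sample(5:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    m <- sample(1:(N - 1), 1)
    k <- sample(1:N, 1)
    query <- sample(uni, m)
    set <- sample(uni, k)
    x <- length(intersect(query, set))
    e <- enrich_pathways(query, list(S = set), uni)
    expect_equal(e$p, enumerate_tail(x, m, N, k), tolerance = 1e-12)
    expect_equal(e$overlap, x)
  }
})

test_that("zero overlap gives p = 1 and non-significance", {
  uni <- sprintf("u%02d", 1:20)
  e <- enrich_pathways(uni[1:5], list(S = uni[10:14]), uni)
  expect_equal(e$p, 1)
  expect_false(e$significant)
  expect_equal(e$neg_log10_p, 0)
})

test_that("with fixed margins, increasing overlap never increases the tail p", {
  # construct query/set pairs with overlap x = 0..5 at fixed sizes
  N <- 25; m <- 8; k <- 6
  uni <- sprintf("u%02d", seq_len(N))
  ps <- sapply(0:min(m, k), function(x) {
    query <- uni[1:m]
    set <- c(uni[seq_len(x)], uni[(m + 1):(m + (k - x))])
    enrich_pathways(query, list(S = set), uni)$p
  })
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("results are sorted by p with name tie-break and genes outside the universe warn", {
  uni <- sprintf("u%02d", 1:20)
  sets <- list(B = uni[1:4], A = uni[5:8], Z = uni[1:4])
  e <- enrich_pathways(uni[1:4], sets, uni)
  expect_equal(e$pathway, c("B", "Z", "A")) # tie between B and Z by name
  expect_warning(enrich_pathways(c(uni[1], "NOT_THERE"), sets, uni),
    "outside the universe")
  expect_error(enrich_pathways(uni[1], sets, character(0)), "non-empty")
})

test_that("planted pathway enrichment crosses the -log10 p threshold", {
  # three sets sharing a planted hub-like gene, each loaded with query genes
  uni <- sprintf("u%03d", 1:200)
  query <- uni[1:20]
  sets <- list(
    P1 = c(uni[1:8], uni[101:112]),
    P2 = c(uni[1], uni[9:15], uni[113:124]),
    P3 = c(uni[1], uni[16:20], uni[2:4], uni[125:136])
  )
  e <- enrich_pathways(query, sets, uni)
  expect_true(all(e$significant))
  expect_true(all(e$neg_log10_p >= 1.3))
})
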