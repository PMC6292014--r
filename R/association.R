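# The chi-square test battery: Pearson independence tests (optionally with
# Yates' continuity correction), the goodness-of-fit "test for probabilities",
# and the contingency-table constructions used for genotype-disease and
# genotype-genotype association.

new_chi2_test <- function(statistic, df, p, method, observed, expected,
                          construction = NA_character_) {
  structure(
    list(
      statistic = statistic, df = df, p.value = p, method = method,
      observed = observed, expected = expected,
      expected_warning = any(expected < 5),
      construction = construction
    ),
    class = "chi2_test"
  )
}

#' @export
print.chi2_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$construction)) cat("construction:", x$construction, "\n")
  cat(sprintf("X-squared = %.6g, df = %d, p-value = %.6g\n",
    x$statistic, x$df, x$p.value))
  if (x$expected_warning) {
    cat("warning: at least one expected cell count is below 5\n")
  }
  invisible(x)
}

drop_empty_margins <- function(x) {
  x <- as.matrix(x)
  x[x == 0] <- 0 # normalise -0
  x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
}

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic on a two-way contingency table, with Yates'
#' continuity correction available for 2x2 tables. The per-cell correction is
#' clamped at |O - E| (i.e. c = min(0.5, |O - E|)), so perfectly proportional
#' tables give a statistic of exactly 0 rather than a negative deviation; this
#' matches the behaviour of the mainstream statistical environments. The
#' p-value is the upper tail of the chi-square distribution with
#' (r - 1)(c - 1) degrees of freedom. Rows and columns whose counts are all
#' zero are dropped before testing.
#'
#' @param x A numeric matrix or table of non-negative counts.
#' @param yates `"auto"` (correct 2x2 tables only; default), `"on"` or `"off"`.
#' @param construction Optional label describing how the table was built
#'   (carried into reports).
#' @return An object of class `chi2_test` with `statistic`, `df`, `p.value`,
#'   `observed`, `expected`, `expected_warning` (any expected count < 5) and
#'   `construction`. Use [generics::tidy()] / [generics::glance()] to get a
#'   tibble.
#' @export
#' @examples
#' chi2_independence(matrix(c(5, 0, 0, 5), 2), yates = "off") # X-squared = 10
#' chi2_independence(matrix(c(5, 0, 0, 5), 2), yates = "on") # X-squared = 6.4
chi2_independence <- function(x, yates = c("auto", "on", "off"),
                              construction = NA_character_) {
  yates <- match.arg(yates)
  x <- as.matrix(x)
  if (any(x < 0) || any(is.na(x))) abort("Counts must be non-negative and complete.")
  obs <- drop_empty_margins(x)
  if (nrow(obs) < 2) {
    abort("Degenerate table: fewer than two non-empty rows (a row margin is zero).")
  }
  if (ncol(obs) < 2) {
    abort("Degenerate table: fewer than two non-empty columns (a column margin is zero).")
  }
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  use_yates <- switch(yates,
    auto = all(dim(obs) == c(2, 2)),
    on = TRUE,
    off = FALSE
  )
  dev <- abs(obs - expected)
  if (use_yates) dev <- dev - pmin(0.5, dev)
  stat <- sum(dev^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  method <- if (use_yates) {
    "Pearson's Chi-squared test with Yates' continuity correction"
  } else {
    "Pearson's Chi-squared test"
  }
  new_chi2_test(stat, df, p, method, obs, expected, construction)
}

#' Chi-square goodness-of-fit test against stated probabilities
#'
#' The "test for probabilities": compares observed category counts with
#' expected counts N * p_i, statistic sum (O_i - N p_i)^2 / (N p_i) on k - 1
#' degrees of freedom.
#'
#' @param observed Non-negative integer counts.
#' @param expected_probs Probabilities summing to 1 (within 1e-6), same length
#'   as `observed`. A zero probability with a positive observed count is an
#'   error; categories with zero probability and zero count are dropped.
#' @param construction Optional label for reports.
#' @return A `chi2_test` object.
#' @export
#' @examples
#' chi2_gof(c(30, 20), c(0.5, 0.5)) # X-squared = 2, df = 1
chi2_gof <- function(observed, expected_probs, construction = NA_character_) {
  if (length(observed) != length(expected_probs)) {
    abort("`observed` and `expected_probs` must have the same length.")
  }
  if (any(observed < 0) || any(is.na(observed))) {
    abort("Observed counts must be non-negative and complete.")
  }
  if (abs(sum(expected_probs) - 1) > 1e-6) {
    abort("`expected_probs` must sum to 1.")
  }
  if (any(expected_probs < 0)) abort("`expected_probs` must be non-negative.")
  bad <- expected_probs == 0 & observed > 0
  if (any(bad)) {
    abort("A category with expected probability 0 has a positive observed count.")
  }
  keep <- expected_probs > 0
  observed <- observed[keep]
  expected_probs <- expected_probs[keep]
  if (length(observed) < 2) {
    abort("Goodness-of-fit needs at least two categories (df would be 0).")
  }
  expected <- sum(observed) * expected_probs
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_chi2_test(stat, df, p, "Chi-squared test for given probabilities",
    matrix(observed, nrow = 1), matrix(expected, nrow = 1), construction)
}

genotype_class <- function(dosage) {
  factor(dosage_to_code(dosage), levels = c("hom_ref", "het", "hom_alt"))
}

#' Build a genotype-by-disease contingency table
#'
#' Three constructions mirror how variant-disease association is usually
#' tabulated:
#' * `carrier`: 2x2, carrier (dosage >= 1) vs non-carrier by case/control;
#' * `genotype`: up-to-3x2 over the observed genotype classes;
#' * `stratum`: 2x2, a focus genotype vs all others, by case/control.
#'
#' Missing genotypes are excluded pairwise-complete; rows with all-zero counts
#' are dropped.
#'
#' @param dosage Integer alt-allele dosages (0/1/2, NA = missing).
#' @param phenotype Character or factor, `"case"`/`"control"`, aligned with
#'   `dosage`.
#' @param mode `"carrier"`, `"genotype"` or `"stratum"`.
#' @param focus_genotype Required for `mode = "stratum"`: one of `"hom_ref"`,
#'   `"het"`, `"hom_alt"`.
#' @return An integer matrix with named dimensions and a `construction`
#'   attribute.
#' @export
build_table <- function(dosage, phenotype,
                        mode = c("carrier", "genotype", "stratum"),
                        focus_genotype = NULL) {
  mode <- match.arg(mode)
  dosage <- check_dosage(dosage)
  phenotype <- as.character(phenotype)
  if (length(dosage) != length(phenotype)) {
    abort("`dosage` and `phenotype` must be aligned vectors.")
  }
  keep <- !is.na(dosage) & phenotype %in% c("case", "control")
  if (!any(keep)) abort("No non-missing genotypes to tabulate.")
  dosage <- dosage[keep]
  phen <- factor(phenotype[keep], levels = c("case", "control"))
  rows <- switch(mode,
    carrier = factor(if_else(dosage >= 1, "carrier", "non_carrier"),
      levels = c("carrier", "non_carrier")),
    genotype = genotype_class(dosage),
    stratum = {
      if (is.null(focus_genotype) || !(focus_genotype %in% GENOTYPE_CODES[1:3])) {
        abort("`mode = \"stratum\"` requires `focus_genotype` in hom_ref/het/hom_alt.")
      }
      lab <- c(paste0(focus_genotype), paste0("not_", focus_genotype))
      factor(if_else(dosage_to_code(dosage) == focus_genotype, lab[1], lab[2]),
        levels = lab)
    }
  )
  tab <- table(rows, phen)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  out <- matrix(as.integer(tab), nrow = nrow(tab),
    dimnames = dimnames(tab))
  attr(out, "construction") <- mode
  out
}

#' Build a joint two-variant contingency table
#'
#' Without phenotypes the table crosses the genotype classes of variant A with
#' those of variant B (a variant-variant dependence test). With phenotypes the
#' rows are the observed joint (A, B) genotype combinations and the columns
#' case/control; empty combinations are dropped, which reproduces the
#' irregular degrees of freedom seen in joint genotype-disease tests. Only
#' samples with non-missing genotypes at both variants are used.
#'
#' @param dosage_a,dosage_b Integer dosages over the same samples.
#' @param phenotype Optional case/control labels aligned with the dosages.
#' @return An integer matrix with a `construction` attribute (`joint2` or
#'   `joint3`).
#' @export
build_joint_table <- function(dosage_a, dosage_b, phenotype = NULL) {
  dosage_a <- check_dosage(dosage_a, "dosage_a")
  dosage_b <- check_dosage(dosage_b, "dosage_b")
  if (length(dosage_a) != length(dosage_b)) {
    abort("Genotype vectors must cover the same samples.")
  }
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  if (!is.null(phenotype)) {
    phenotype <- as.character(phenotype)
    keep <- keep & phenotype %in% c("case", "control")
  }
  if (!any(keep)) abort("No overlapping non-missing samples for the two variants.")
  a <- genotype_class(dosage_a[keep])
  b <- genotype_class(dosage_b[keep])
  if (is.null(phenotype)) {
    tab <- table(a, b)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    construction <- "joint2"
  } else {
    phen <- factor(phenotype[keep], levels = c("case", "control"))
    combo <- factor(paste(as.character(a), as.character(b), sep = "|"))
    tab <- table(combo, phen)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    construction <- "joint3"
  }
  out <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  attr(out, "construction") <- construction
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (the q-value used by the DE
#' significance filter), delegated to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted values, monotone, each >= its raw p and <= 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  check_probability(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

# --- broom-style methods -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chi-square test
#' @param x A `chi2_test` object.
#' @param ... Unused.
#' @return One-row tibble: statistic, df, p.value, method, construction,
#'   expected_warning.
#' @method tidy chi2_test
#' @export
tidy.chi2_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    method = x$method, construction = x$construction,
    expected_warning = x$expected_warning
  )
}

#' @rdname tidy.chi2_test
#' @method glance chi2_test
#' @export
glance.chi2_test <- function(x, ...) tidy(x)
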