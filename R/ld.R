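# Allele and carrier frequencies, EM haplotype-frequency estimation from
# unphased two-locus genotypes, and the D / D' / r^2 linkage-disequilibrium
# statistics.

#' Alternate-allele frequency from dosages
#'
#' @param dosage Integer dosages (0/1/2, NA = missing); at least one
#'   non-missing value required.
#' @return Frequency in [0, 1]: sum of dosages over twice the number of
#'   non-missing genotypes.
#' @export
#' @examples
#' allele_frequency(c(0, 1, 2))
allele_frequency <- function(dosage) {
  dosage <- check_dosage(dosage)
  n <- sum(!is.na(dosage))
  if (n == 0) abort("All genotypes are missing.")
  sum(dosage, na.rm = TRUE) / (2 * n)
}

#' Carrier frequency
#'
#' @param n_carriers Number of subjects carrying the variant (dosage >= 1).
#' @param n_total Total subjects; must be positive.
#' @return `n_carriers / n_total`.
#' @export
#' @examples
#' carrier_frequency(39, 143) # 0.272727
carrier_frequency <- function(n_carriers, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive.")
  if (any(n_carriers < 0) || any(n_carriers > n_total)) {
    abort("`n_carriers` must lie in [0, n_total].")
  }
  n_carriers / n_total
}

HAP_LABELS <- c("AB", "Ab", "aB", "ab")
# alt-allele content of each haplotype at locus A and locus B
HAP_A <- c(1L, 1L, 0L, 0L)
HAP_B <- c(1L, 0L, 1L, 0L)

# P(genotype cell) under random union of gametes, as a 3x3 matrix [gA+1, gB+1]
geno_probs_from_haps <- function(p) {
  probs <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      ga <- HAP_A[i] + HAP_A[j]
      gb <- HAP_B[i] + HAP_B[j]
      probs[ga + 1, gb + 1] <- probs[ga + 1, gb + 1] + p[i] * p[j]
    }
  }
  probs
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' `D = f(AB) f(ab) - f(Ab) f(aB)`; `D' = |D| / D_max` with
#' `D_max = min(p_A q_b, p_a q_B)` for positive D and
#' `min(p_A q_B, p_a q_b)` otherwise (capital letters denote the alternate
#' alleles); `r^2 = D^2 / (p_A p_a q_B q_b)`. When either locus is
#' monomorphic, `D_prime` and `r2` are undefined (NA), not 0, so degenerate
#' cohorts stay visible.
#'
#' @param hap_freqs Numeric vector of the four haplotype frequencies in the
#'   order AB, Ab, aB, ab (sum 1 within 1e-6).
#' @return A one-row tibble with `D`, `D_prime`, `r2`, `p_A`, `p_B`,
#'   `monomorphic`.
#' @export
#' @examples
#' ld_stats(c(0.5, 0, 0, 0.5)) # perfect coupling: D' = 1, r2 = 1
ld_stats <- function(hap_freqs) {
  if (length(hap_freqs) != 4 || any(hap_freqs < 0)) {
    abort("`hap_freqs` must be four non-negative frequencies (AB, Ab, aB, ab).")
  }
  if (abs(sum(hap_freqs) - 1) > 1e-6) {
    abort("Haplotype frequencies must sum to 1.")
  }
  fAB <- hap_freqs[1]; fAb <- hap_freqs[2]; faB <- hap_freqs[3]; fab <- hap_freqs[4]
  pA <- fAB + fAb; pB <- fAB + faB
  D <- fAB * fab - fAb * faB
  mono <- min(pA, 1 - pA, pB, 1 - pB) <= 0
  if (mono) {
    d_prime <- NA_real_
    r2 <- NA_real_
  } else {
    d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
    d_prime <- if (D == 0) 0 else abs(D) / d_max
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  tibble(D = D, D_prime = d_prime, r2 = r2, p_A = pA, p_B = pB,
    monomorphic = mono)
}

#' EM haplotype-frequency estimation and LD for a variant pair
#'
#' Maximum-likelihood haplotype frequencies from unphased two-locus genotypes
#' via expectation-maximisation over the double-heterozygote phase ambiguity.
#' The chain starts from linkage-equilibrium frequencies (products of allele
#' frequencies), which is deterministic and leaves the estimator at the
#' symmetric point when the data are phase-uninformative. The log-likelihood
#' is non-decreasing across iterations; iteration stops when the largest
#' frequency change drops below `tol` or at `max_iter`.
#'
#' @param dosage_a,dosage_b Integer dosages over the same samples; only
#'   pairwise-complete samples are used, and at least two are required.
#' @param tol Convergence tolerance on haplotype frequencies (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `ld_fit`: `hap_freqs` (named AB/Ab/aB/ab), `D`,
#'   `D_prime`, `r2`, `n`, `n_iterations`, `loglik`, `loglik_trace`,
#'   `monomorphic`. `tidy()`/`glance()` return tibbles; `autoplot()` draws the
#'   haplotype frequencies.
#' @export
em_haplotype_freqs <- function(dosage_a, dosage_b, tol = 1e-8, max_iter = 1000) {
  if (tol <= 0) abort("`tol` must be positive.")
  dosage_a <- check_dosage(dosage_a, "dosage_a")
  dosage_b <- check_dosage(dosage_b, "dosage_b")
  if (length(dosage_a) != length(dosage_b)) {
    abort("Genotype vectors must cover the same samples.")
  }
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[keep]
  b <- dosage_b[keep]
  n <- length(a)
  if (n < 2) abort("Fewer than two informative (pairwise-complete) samples.")

  counts <- matrix(0, 3, 3)
  for (i in seq_len(n)) counts[a[i] + 1, b[i] + 1] <- counts[a[i] + 1, b[i] + 1] + 1

  pA <- sum(a) / (2 * n)
  pB <- sum(b) / (2 * n)
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))

  loglik_of <- function(p) {
    probs <- geno_probs_from_haps(p)
    sum(counts[counts > 0] * log(probs[counts > 0]))
  }

  # Haplotype counts contributed by unambiguous genotype cells: each
  # individual carries two gametes whose allele content is fixed unless the
  # genotype is the double heterozygote (1,1).
  base_counts <- numeric(4)
  for (ga in 0:2) {
    for (gb in 0:2) {
      ncell <- counts[ga + 1, gb + 1]
      if (ncell == 0 || (ga == 1 && gb == 1)) next
      # gametes: locus A contributes (ga split as sorted pair), same for B;
      # for non-double-het cells the pairing is unique.
      a_all <- if (ga == 0) c(0, 0) else if (ga == 2) c(1, 1) else c(0, 1)
      b_all <- if (gb == 0) c(0, 0) else if (gb == 2) c(1, 1) else c(0, 1)
      if (ga == 1) {
        # one haplotype carries the alt A allele; B alleles are homozygous
        h1 <- which(HAP_A == 1 & HAP_B == b_all[1]); h2 <- which(HAP_A == 0 & HAP_B == b_all[2])
      } else if (gb == 1) {
        h1 <- which(HAP_B == 1 & HAP_A == a_all[1]); h2 <- which(HAP_B == 0 & HAP_A == a_all[2])
      } else {
        h1 <- which(HAP_A == a_all[1] & HAP_B == b_all[1]); h2 <- h1
      }
      base_counts[h1] <- base_counts[h1] + ncell
      base_counts[h2] <- base_counts[h2] + ncell
    }
  }
  n_dh <- counts[2, 2]

  ll <- loglik_of(p)
  trace <- ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    h <- base_counts
    if (n_dh > 0) {
      cis <- p[1] * p[4] # AB/ab
      trans <- p[2] * p[3] # Ab/aB
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      h[c(1, 4)] <- h[c(1, 4)] + n_dh * w
      h[c(2, 3)] <- h[c(2, 3)] + n_dh * (1 - w)
    }
    p_new <- h / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    ll <- loglik_of(p)
    trace <- c(trace, ll)
    if (delta < tol || iter >= max_iter) break
  }

  stats_row <- ld_stats(p)
  structure(
    list(
      hap_freqs = setNames(p, HAP_LABELS),
      D = stats_row$D, D_prime = stats_row$D_prime, r2 = stats_row$r2,
      p_A = stats_row$p_A, p_B = stats_row$p_B,
      monomorphic = stats_row$monomorphic,
      n = n, n_iterations = iter, loglik = ll, loglik_trace = trace
    ),
    class = "ld_fit"
  )
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("EM haplotype frequencies (n =", x$n, "pairs,", x$n_iterations,
    "iterations)\n")
  print(round(x$hap_freqs, 6))
  cat(sprintf("D = %.6g, D' = %s, r2 = %s\n", x$D,
    ifelse(is.na(x$D_prime), "undefined", sprintf("%.6g", x$D_prime)),
    ifelse(is.na(x$r2), "undefined", sprintf("%.6g", x$r2))))
  invisible(x)
}

#' Tidy an EM linkage-disequilibrium fit
#' @param x An `ld_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per haplotype with its estimated frequency.
#'   `glance()`: one row with D, D', r2, n, iterations and final
#'   log-likelihood.
#' @method tidy ld_fit
#' @export
tidy.ld_fit <- function(x, ...) {
  tibble(haplotype = HAP_LABELS, frequency = unname(x$hap_freqs))
}

#' @rdname tidy.ld_fit
#' @method glance ld_fit
#' @export
glance.ld_fit <- function(x, ...) {
  tibble(
    D = x$D, D_prime = x$D_prime, r2 = x$r2, p_A = x$p_A, p_B = x$p_B,
    n = x$n, n_iterations = x$n_iterations, loglik = x$loglik,
    monomorphic = x$monomorphic
  )
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.ld_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$haplotype, y = .data$frequency)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = NULL, y = "estimated frequency",
      subtitle = sprintf("D = %.3g, D' = %s, r2 = %s", object$D,
        ifelse(is.na(object$D_prime), "undef.", sprintf("%.3g", object$D_prime)),
        ifelse(is.na(object$r2), "undef.", sprintf("%.3g", object$r2)))
    ) +
    ggplot2::theme_minimal()
}
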