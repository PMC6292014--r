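# Differential-expression significance filtering and the log2 expression ratio.

#' Filter a DE table to significant genes
#'
#' A gene is retained iff its BH-adjusted q-value is strictly below `q_max`
#' and (when `require_ok`) the test status is `OK`; LOWDATA, HIDATA and FAIL
#' rows carry no trustworthy test. The full DE record is kept so effect
#' direction can be reported downstream.
#'
#' @param de DE tibble (see [read_de_table()]).
#' @param q_max Strict upper bound on q; default 0.05.
#' @param require_ok Require status `OK` (default TRUE).
#' @return The retained subset of `de`.
#' @export
#' @examples
#' de <- tibble::tibble(gene = c("ECHS1", "X"), fpkm_case = c(10, 1),
#'   fpkm_control = c(3, 1), log2_ratio = c(1.63, 0), test_stat = c(3, 0),
#'   p = c(0.00135, 0.9), q = c(0.013927, 0.95), status = c("OK", "OK"))
#' filter_de(de)
filter_de <- function(de, q_max = 0.05, require_ok = TRUE) {
  if (q_max <= 0 || q_max >= 1) abort("`q_max` must lie in (0, 1).")
  if (nrow(de) == 0) return(de)
  keep <- !is.na(de$q) & de$q < q_max
  if (require_ok) keep <- keep & de$status == "OK"
  de[keep, , drop = FALSE]
}

#' Log2 expression ratio of case over control FPKM
#'
#' Vectorised log2(case/control). A zero control FPKM with positive case FPKM
#' gives +Inf (case-only expression); the mirrored situation gives -Inf; both
#' zero is undefined (NaN). See [log2_ratio_flag()] for the labels.
#'
#' @param fpkm_case,fpkm_control Non-negative FPKM values.
#' @return Numeric vector, possibly containing +/-Inf and NaN.
#' @export
#' @examples
#' log2_ratio(2, 1)
#' log2_ratio(5.2944, 0) # case-only expression
log2_ratio <- function(fpkm_case, fpkm_control) {
  if (any(fpkm_case < 0, na.rm = TRUE) || any(fpkm_control < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative.")
  }
  log2(fpkm_case / fpkm_control)
}

#' Label the degenerate cases of the log2 expression ratio
#'
#' @inheritParams log2_ratio
#' @return Character vector: `"finite"`, `"case_only"` (control FPKM 0),
#'   `"control_only"` (case FPKM 0) or `"undefined"` (both 0).
#' @export
log2_ratio_flag <- function(fpkm_case, fpkm_control) {
  if (any(fpkm_case < 0, na.rm = TRUE) || any(fpkm_control < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative.")
  }
  dplyr::case_when(
    fpkm_case == 0 & fpkm_control == 0 ~ "undefined",
    fpkm_control == 0 ~ "case_only",
    fpkm_case == 0 ~ "control_only",
    TRUE ~ "finite"
  )
}
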