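#' Efficiency-corrected relative quantification (Pfaffl method)
#'
#' Computes, per record, the expression ratio
#' `E_target^(Ct_control - Ct_sample) / E_ref^(Ct_control - Ct_sample)`
#' where E is the primer-pair amplification efficiency (2 = perfect
#' doubling) and Ct values come from the target and reference-gene
#' reactions. With both efficiencies at 2 this reduces to the classic
#' 2^(-ddCt) form. The log10 ratio is returned alongside for comparison
#' with array log10 fold changes.
#'
#' @param records data.frame with columns E_target, ct_target_control,
#'   ct_target_sample, E_ref, ct_ref_control, ct_ref_sample (extra columns
#'   pass through).
#' @return `records` with added `ratio` and `log10_ratio` columns.
#' @export
pfaffl_ratio <- function(records) {
  need <- c("E_target", "ct_target_control", "ct_target_sample",
            "E_ref", "ct_ref_control", "ct_ref_sample")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(records$E_target <= 1 | records$E_ref <= 1))
    stopf("amplification efficiencies must exceed 1")
  if (any(records$E_target > 2 | records$E_ref > 2))
    stopf("amplification efficiencies cannot exceed 2 (perfect doubling)")
  if (any(records[, grep("^ct_", names(records))] <= 0))
    stopf("Ct values must be positive")
  ratio <- records$E_target^(records$ct_target_control - records$ct_target_sample) /
    records$E_ref^(records$ct_ref_control - records$ct_ref_sample)
  records$ratio <- ratio
  records$log10_ratio <- log10(ratio)
  records
}

#' Array vs qPCR concordance report
#'
#' Pairs array and qPCR log10 fold changes per gene/condition and reports
#' how often the two platforms agree on the mode of differential expression
#' at a fold threshold. Under the default rule a pair is same-mode when both
#' platforms call the same direction at >= `fold`, or both fall below the
#' threshold; with `strict = TRUE` only pairs where both platforms reach the
#' threshold with the same sign count (sub-threshold pairs are discordant).
#' Pearson correlation of the paired log10 values is reported alongside.
#'
#' @param array_log10fc,qpcr_log10fc paired numeric vectors.
#' @param fold fold threshold for calling a direction.
#' @param strict same-mode convention (see above).
#' @return list: n, n_same, fraction, pearson.
#' @export
concordance <- function(array_log10fc, qpcr_log10fc, fold = 2, strict = FALSE) {
  ok <- is.finite(array_log10fc) & is.finite(qpcr_log10fc)
  a <- array_log10fc[ok]; q <- qpcr_log10fc[ok]
  if (length(a) < 2) stopf("need at least 2 paired observations")
  th <- log10(fold)
  mode_of <- function(v) ifelse(v >= th, "up", ifelse(v <= -th, "down", "none"))
  ma <- mode_of(a); mq <- mode_of(q)
  same <- if (strict) ma == mq & ma != "none" else ma == mq
  list(n = length(a), n_same = sum(same), fraction = mean(same),
       pearson = stats::cor(a, q))
}
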