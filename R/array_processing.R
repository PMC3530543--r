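#' Quality-control filtering of probe-level spots
#'
#' Drops every spot flagged bad, removes control probes from gene-level
#' analysis (they still count toward each array's QC denominator), and
#' excludes entire arrays whose bad-feature fraction reaches the standard
#' facility threshold of 1%.
#'
#' @param probes probe table (see [read_probe_table()] for the dialect).
#' @return list with `probes` (filtered table) and `reports` (one row per
#'   array: array_id, n_features, n_bad, bad_fraction, pass).
#' @export
qc_filter <- function(probes) {
  if (nrow(probes) == 0) stopf("probe table is empty")
  by_array <- split(probes$flag, probes$array_id)
  reports <- data.frame(
    array_id = names(by_array),
    n_features = vapply(by_array, length, 0L),
    n_bad = vapply(by_array, function(f) sum(f == "bad"), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  reports$bad_fraction <- reports$n_bad / reports$n_features
  reports$pass <- reports$bad_fraction < 0.01
  failed <- reports$array_id[!reports$pass]
  if (length(failed))
    warning(sprintf("array(s) excluded for >=1%% bad features: %s",
                    paste(failed, collapse = ", ")), call. = FALSE)
  keep <- probes$flag == "ok" & !(probes$array_id %in% failed)
  list(probes = probes[keep, , drop = FALSE], reports = reports)
}

#' Intensity-dependent (Lowess) ratio normalization
#'
#' Per array, computes M = log10(cy5/cy3) and A = 0.5 log10(cy5 * cy3), fits
#' a robust locally weighted regression of M on A (tricube weights,
#' `iter` robustness iterations) and returns the residual M' = M - fit(A) as
#' the normalized log10 ratio in a new `ratio_log10` column. This removes
#' smooth intensity-dependent dye bias while leaving gene-level fold changes
#' intact. Arrays with fewer than 10 usable spots are passed through
#' unnormalized with a warning.
#'
#' @param probes QC-filtered probe table (flag == "ok" rows).
#' @param span lowess smoother span (fraction of points in each window).
#' @param iter robustness iterations.
#' @return probe table with an added `ratio_log10` column.
#' @export
lowess_normalize <- function(probes, span = 0.3, iter = 3L) {
  if (any(probes$cy5 <= 0 | probes$cy3 <= 0))
    stopf("intensities must be positive; run qc_filter() first")
  M <- log10(probes$cy5 / probes$cy3)
  A <- 0.5 * log10(probes$cy5 * probes$cy3)
  out <- M
  for (aid in unique(probes$array_id)) {
    i <- which(probes$array_id == aid)
    if (length(i) < 10) {
      warning(sprintf("array %s has <10 features; normalization skipped", aid),
              call. = FALSE)
      next
    }
    fit <- stats::lowess(A[i], M[i], f = span, iter = iter)
    out[i] <- M[i] - stats::approx(fit$x, fit$y, xout = A[i], rule = 2,
                                   ties = "ordered")$y
  }
  probes$ratio_log10 <- out
  probes
}

#' Aggregate replicate spots into a gene x condition matrix
#'
#' For each (gene, tissue, dpa, strand) the replicate log10 ratios are
#' averaged -- the arithmetic mean of logs, i.e. the log10 of the
#' geometric-mean ratio -- with their standard deviation (geometric SD, log10
#' scale) and replicate count. Where a gene is probed on both strands the
#' strand record with the larger |mean| is retained as the gene value.
#' Genes with no usable replicate in a condition are missing (`NA`) there.
#'
#' @param probes normalized probe table; if `ratio_log10` is absent the raw
#'   log10(cy5/cy3) is used.
#' @return a [regen_expr()].
#' @export
aggregate_replicates <- function(probes) {
  if (nrow(probes) == 0) stopf("probe table is empty")
  probes <- probes[probes$flag == "ok", , drop = FALSE]
  ratio <- if ("ratio_log10" %in% names(probes)) probes$ratio_log10
           else log10(probes$cy5 / probes$cy3)
  key <- interaction(probes$gene_id, probes$tissue, probes$dpa, probes$strand,
                     drop = TRUE, sep = "\r")
  mu <- tapply(ratio, key, mean)
  sdv <- tapply(ratio, key, stats::sd)
  nr <- tapply(ratio, key, length)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  agg <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    tissue = vapply(parts, `[`, "", 2L),
    dpa = as.numeric(vapply(parts, `[`, "", 3L)),
    strand = vapply(parts, `[`, "", 4L),
    value = as.numeric(mu), sd = as.numeric(sdv), n_rep = as.integer(nr),
    stringsAsFactors = FALSE
  )
  agg$sd[is.na(agg$sd)] <- 0  # single replicate
  # strand resolution: keep the record with larger |value| per gene/condition
  o <- order(agg$gene_id, agg$tissue, agg$dpa, -abs(agg$value))
  agg <- agg[o, ]
  agg <- agg[!duplicated(agg[, c("gene_id", "tissue", "dpa")]), ]

  # condition ordering: tissue order of first appearance, then dpa
  tis <- unique(probes$tissue)
  conds <- unique(agg[, c("tissue", "dpa")])
  conds <- conds[order(match(conds$tissue, tis), conds$dpa), ]
  labels <- condition_label(conds$tissue, conds$dpa)
  gene_ids <- sort(unique(agg$gene_id))

  shape <- function(col, fill) {
    m <- matrix(fill, length(gene_ids), length(labels),
                dimnames = list(gene_ids, labels))
    m[cbind(match(agg$gene_id, gene_ids),
            match(condition_label(agg$tissue, agg$dpa), labels))] <- agg[[col]]
    m
  }
  regen_expr(shape("value", NA_real_), shape("sd", NA_real_),
             shape("n_rep", 0L), conds)
}

#' Replicate-intensity coefficient of variation summary
#'
#' Measures, per gene, the relative standard deviation (SD / mean) of
#' replicate spot intensities within each (condition, channel), averaged
#' over conditions and channels, plus the across-gene average. This is the
#' array-fidelity summary: with well-behaved hybridizations the average sits
#' in the few-percent range.
#'
#' @param probes probe table (flag == "ok" rows are used).
#' @return list with `per_gene` (gene_id, rel_sd, n_conditions) and
#'   `average` (across-gene mean relative SD).
#' @export
replicate_cv_summary <- function(probes) {
  probes <- probes[probes$flag == "ok", , drop = FALSE]
  key <- interaction(probes$gene_id, probes$tissue, probes$dpa,
                     drop = TRUE, sep = "\r")
  rel <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / mean(x)
  r5 <- tapply(probes$cy5, key, rel)
  r3 <- tapply(probes$cy3, key, rel)
  gene <- vapply(strsplit(names(r5), "\r", fixed = TRUE), `[`, "", 1L)
  per_cond <- rowMeans(cbind(as.numeric(r5), as.numeric(r3)), na.rm = TRUE)
  mu <- tapply(per_cond, gene, mean, na.rm = TRUE)
  nn <- tapply(!is.na(per_cond), gene, sum)
  per_gene <- data.frame(gene_id = names(mu), rel_sd = as.numeric(mu),
                         n_conditions = as.integer(nn), row.names = NULL,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene, average = mean(per_gene$rel_sd, na.rm = TRUE))
}
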