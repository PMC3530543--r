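# Fold-change tier boundaries (log10 scale), inclusive at each threshold.
.TIERS <- c(t1p5 = log10(1.5), t2 = log10(2), t5 = log10(5), t10 = 1)

.tier_of <- function(magnitude) {
  out <- rep("none", length(magnitude))
  for (nm in names(.TIERS)) out[magnitude >= .TIERS[[nm]]] <- nm
  out
}

#' Tiered fold-change differential-expression calls
#'
#' One call per non-missing (gene, tissue, dpa): the direction (up/down/none)
#' and the highest fold-change tier attained, with inclusive boundaries --
#' a log10 value of exactly log10(2) is a 2-fold call. Direction is `none`
#' below 1.5-fold. Tiers nest: every t10 call is also at least 5-fold, and
#' so on down.
#'
#' @param x a [regen_expr()] of log10 fold changes vs day 0.
#' @return data.frame of calls: gene_id, tissue, dpa, direction, tier,
#'   magnitude.
#' @export
call_differential <- function(x) {
  stopifnot(inherits(x, "regen_expr"))
  v <- x$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  if (any(!is.finite(v[idx]))) {
    warning("non-finite expression values skipped", call. = FALSE)
    idx <- idx[is.finite(v[idx]), , drop = FALSE]
  }
  val <- v[idx]
  mag <- abs(val)
  calls <- data.frame(
    gene_id = rownames(v)[idx[, 1]],
    tissue = x$conditions$tissue[idx[, 2]],
    dpa = x$conditions$dpa[idx[, 2]],
    direction = ifelse(mag < .TIERS[["t1p5"]], "none",
                       ifelse(val > 0, "up", "down")),
    tier = .tier_of(mag),
    magnitude = mag,
    stringsAsFactors = FALSE
  )
  calls[order(calls$gene_id, match(calls$tissue, unique(x$conditions$tissue)),
              calls$dpa), ]
}

#' Study-wide differential-expression summary counts
#'
#' For each fold threshold, counts genes up- or down-regulated by at least
#' that factor in at least one tissue at one time point (categories are
#' entire and inclusive: the 2-fold column contains the 5- and 10-fold
#' genes). A gene whose direction changes over the time course counts in
#' both the up and down columns. Percentages divide by the number of assayed
#' genes.
#'
#' @param calls output of [call_differential()].
#' @param thresholds fold thresholds to summarize at.
#' @param total denominator for percentages; defaults to the number of
#'   distinct genes in `calls` (genes with at least one valid measurement).
#' @return data.frame: threshold, n_up, pct_up, n_down, pct_down, with the
#'   denominator in attribute `total`.
#' @export
summarize_counts <- function(calls, thresholds = c(2, 5, 10), total = NULL) {
  if (is.null(total)) total <- length(unique(calls$gene_id))
  res <- do.call(rbind, lapply(thresholds, function(th) {
    hit <- calls$magnitude >= log10(th)
    up <- unique(calls$gene_id[hit & calls$direction == "up"])
    dn <- unique(calls$gene_id[hit & calls$direction == "down"])
    data.frame(threshold = th, n_up = length(up),
               pct_up = 100 * length(up) / total,
               n_down = length(dn), pct_down = 100 * length(dn) / total)
  }))
  attr(res, "total") <- total
  res
}

#' Count of genes differentially expressed anywhere
#'
#' Number of genes whose |log10 fold change| reaches `log10(fold)` in at
#' least one tissue at one time point.
#'
#' @param calls output of [call_differential()].
#' @param fold fold threshold.
#' @export
n_differential <- function(calls, fold = 2) {
  length(unique(calls$gene_id[calls$magnitude >= log10(fold)]))
}

#' Select genes in a fold-change band
#'
#' Genes whose maximum |log10 fold| over all conditions lies in
#' `[log10(low), log10(high))`, or `[log10(low), Inf)` when `high` is NULL.
#' The half-open upper bound keeps the 1.5--2-fold band disjoint from the
#' >=2-fold set.
#'
#' @param x a [regen_expr()].
#' @param low lower fold bound (>= 1).
#' @param high upper fold bound, or NULL for unbounded.
#' @return character vector of gene ids.
#' @export
band_select <- function(x, low, high = NULL) {
  if (low < 1) stopf("'low' must be >= 1")
  if (!is.null(high) && high <= low) stopf("'high' must exceed 'low'")
  mx <- apply(abs(x$values), 1, max, na.rm = TRUE)
  mx[!is.finite(mx)] <- NA
  keep <- !is.na(mx) & mx >= log10(low)
  if (!is.null(high)) keep <- keep & mx < log10(high)
  rownames(x$values)[keep]
}

#' Per-condition up/down counts
#'
#' Distribution of up- and down-regulated genes per (tissue, dpa) at a fold
#' threshold -- the per-time-point companion of [summarize_counts()].
#'
#' @param calls output of [call_differential()].
#' @param fold fold threshold.
#' @return data.frame: tissue, dpa, n_up, n_down.
#' @export
per_tissue_counts <- function(calls, fold = 2) {
  hit <- calls[calls$magnitude >= log10(fold) & calls$direction != "none", ]
  key <- unique(calls[, c("tissue", "dpa")])
  key <- key[order(key$tissue, key$dpa), ]
  key$n_up <- mapply(function(ti, t)
    sum(hit$tissue == ti & hit$dpa == t & hit$direction == "up"),
    key$tissue, key$dpa)
  key$n_down <- mapply(function(ti, t)
    sum(hit$tissue == ti & hit$dpa == t & hit$direction == "down"),
    key$tissue, key$dpa)
  rownames(key) <- NULL
  key
}

#' Direction/tier profile of one gene in one tissue
#'
#' The set of fold-change tiers a gene attains in each direction over a
#' tissue's time course -- the machine form of an arrowhead summary, where a
#' gene can show both up- and down-arrowheads if its direction changes over
#' time.
#'
#' @param x a [regen_expr()].
#' @param gene gene identifier.
#' @param tissue tissue code.
#' @return list with character vectors `up` and `down` of tiers attained.
#' @export
direction_profile <- function(x, gene, tissue) {
  if (!gene %in% rownames(x$values)) stopf("unknown gene '%s'", gene)
  v <- x$values[gene, x$conditions$tissue == tissue]
  v <- v[!is.na(v)]
  tiers_hit <- function(vals) {
    if (length(vals) == 0) return(character())
    m <- max(abs(vals))
    names(.TIERS)[.TIERS <= m]
  }
  list(up = tiers_hit(v[v >= .TIERS[["t1p5"]]]),
       down = tiers_hit(-v[v <= -.TIERS[["t1p5"]]]))
}
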