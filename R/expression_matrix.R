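#' Gene-by-condition expression container
#'
#' Holds aggregated log10 fold changes (regenerating vs day-0 intact tissue)
#' for each gene under each (tissue, dpa) condition, together with the
#' replicate-level standard deviation (log10 scale) and replicate count from
#' which each value was derived. Conditions never include dpa = 0: every
#' hybridization is a competitive two-channel measurement against the matched
#' intact tissue, so day 0 is the implicit denominator.
#'
#' @param values numeric matrix, genes in rows, conditions in columns; column
#'   names follow the `"tissue:dpa"` convention.
#' @param sd matrix of log10-scale standard deviations, same shape as
#'   `values` (may be `NA` where unavailable, e.g. pre-aggregated input).
#' @param n_rep integer matrix of replicate counts, same shape as `values`.
#' @param conditions optional data.frame with columns `tissue` and `dpa`; if
#'   omitted it is parsed from `colnames(values)`.
#'
#' @return An object of class `regen_expr`.
#' @export
regen_expr <- function(values, sd = NULL, n_rep = NULL, conditions = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stopf("'values' must have condition column names (\"tissue:dpa\")")
  if (is.null(rownames(values)))
    stopf("'values' must have gene row names")
  if (is.null(conditions)) conditions <- split_condition(colnames(values))
  if (any(conditions$dpa == 0, na.rm = TRUE))
    stopf("conditions must exclude dpa = 0 (ratios are relative to day 0)")
  if (is.null(sd)) {
    sd <- matrix(NA_real_, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (is.null(n_rep)) {
    n_rep <- matrix(1L, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  sd <- as.matrix(sd); n_rep <- as.matrix(n_rep)
  stopifnot(identical(dim(sd), dim(values)), identical(dim(n_rep), dim(values)))
  if (any(sd < 0, na.rm = TRUE)) stopf("'sd' must be non-negative")
  structure(
    list(values = values, sd = sd, n_rep = n_rep, conditions = conditions),
    class = "regen_expr"
  )
}

#' @export
print.regen_expr <- function(x, ...) {
  tis <- unique(x$conditions$tissue)
  cat(sprintf(
    "regen_expr: %d genes x %d conditions (%d tissues: %s)\n",
    nrow(x$values), ncol(x$values), length(tis), paste(tis, collapse = ", ")
  ))
  nm <- sum(is.na(x$values))
  if (nm > 0) cat(sprintf("  %d missing values\n", nm))
  cat("  log10 fold-change range:",
      sprintf("[%.3f, %.3f]\n", min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.regen_expr <- function(x, ...) x$values

#' @export
dim.regen_expr <- function(x) dim(x$values)

#' Genes of an expression container
#' @param x a `regen_expr` object.
#' @return Character vector of gene identifiers.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.regen_expr <- function(x) rownames(x$values)

#' Subset a regen_expr by genes and/or conditions
#' @param x a `regen_expr`.
#' @param i gene index (names, logical or integer).
#' @param j condition index.
#' @param ... unused.
#' @export
`[.regen_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  regen_expr(
    x$values[i, j, drop = FALSE],
    x$sd[i, j, drop = FALSE],
    x$n_rep[i, j, drop = FALSE]
  )
}

#' Write / read an aggregated expression matrix as TSV
#'
#' The value matrix is written genes-in-rows with a `gene_id` first column and
#' `"tissue:dpa"` condition columns; companion `<path>.sd.tsv` and
#' `<path>.n.tsv` files carry the dispersion and replicate counts. A plain
#' pre-aggregated matrix TSV (no companions) can also be read back, which is
#' the ingestion route for externally aggregated data.
#'
#' @param x a `regen_expr`.
#' @param path output TSV path for the value matrix.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns a `regen_expr`.
#' @export
write_expression_matrix <- function(x, path) {
  write_mat <- function(m, p) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(x$values, path)
  write_mat(x$sd, paste0(path, ".sd.tsv"))
  write_mat(x$n_rep, paste0(path, ".n.tsv"))
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  read_mat <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(df)) stopf("matrix TSV must have a gene_id column")
    m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
    rownames(m) <- df$gene_id
    storage.mode(m) <- "double"
    m
  }
  v <- read_mat(path)
  sdp <- paste0(path, ".sd.tsv"); np <- paste0(path, ".n.tsv")
  sd <- if (file.exists(sdp)) read_mat(sdp) else NULL
  n <- if (file.exists(np)) read_mat(np) else NULL
  regen_expr(v, sd, n)
}
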