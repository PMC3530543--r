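#' EASE score: penalized hypergeometric upper tail
#'
#' A conservative variant of the Fisher exact enrichment p-value in which one
#' gene is removed from the list-term overlap before taking the upper tail:
#' with N background genes, K of them in the term and a list of n genes
#' overlapping the term in k, the score is P(X >= k - 1) for
#' X ~ Hypergeometric(N, K, n). Overlaps of 0 or 1 score 1.0, and the score
#' is always at least the unpenalized Fisher upper tail P(X >= k).
#'
#' @param k overlap count (list genes in the term).
#' @param n list size.
#' @param K term size in the background.
#' @param N background size.
#' @return probability in (0, 1]. Vectorized over its arguments.
#' @export
ease_score <- function(k, n, K, N) {
  r <- cbind(k, n, K, N)
  k <- r[, 1]; n <- r[, 2]; K <- r[, 3]; N <- r[, 4]
  if (any(k < 0 | n < 0 | K < 0 | N < 1 | k > pmin(n, K) | n > N | K > N))
    stopf("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  p <- rep(1, length(k))
  i <- k > 1
  # P(X >= k-1) = 1 - P(X <= k-2)
  p[i] <- stats::phyper(k[i] - 2, K[i], N[i] - K[i], n[i], lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Read / write GMT term-set files
#'
#' One term per line: term_id, description, then member genes, tab-separated.
#' The description field carries the term name and, optionally, a category
#' after a `|` (e.g. `"sarcomere|cell_component"`).
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of terms, each a list with `name`,
#'   `category`, `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("parse error in %s: line %d has fewer than 3 fields", path, i)
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    list(name = desc[1],
         category = if (length(desc) > 1) desc[2] else "other",
         genes = unique(f[-(1:2)]))
  })
  names(terms) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  terms
}

#' @rdname read_gmt
#' @param terms named list of term records (as returned by `read_gmt` or
#'   [simulate_term_sets()]).
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    t <- terms[[id]]
    paste(c(id, paste0(t$name, "|", t$category), t$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.norm_ids <- function(x) toupper(trimws(x))

#' Term enrichment of a gene list
#'
#' Scores every term with at least one list overlap by [ease_score()]
#' against the supplied background, sorted by score. A term is flagged
#' significant when the overlap is at least `min_overlap` genes and the EASE
#' score is at most `max_p` (defaults: >= 2 genes, <= 0.01). Gene IDs are
#' case-normalized; list genes absent from the background are dropped with a
#' message.
#'
#' @param gene_list character vector of gene ids.
#' @param term_sets named list of terms (see [read_gmt()]) or a plain named
#'   list of gene-id vectors.
#' @param background background gene ids (the assayed, annotated universe).
#' @param min_overlap,max_p significance rule.
#' @return data.frame: term_id, term_name, category, k, n, K, N, ease_p,
#'   significant, genes (comma-separated overlap).
#' @export
enrich <- function(gene_list, term_sets, background,
                   min_overlap = 2, max_p = 0.01) {
  if (length(background) == 0) stopf("empty background")
  background <- unique(.norm_ids(background))
  gene_list <- unique(.norm_ids(gene_list))
  dropped <- setdiff(gene_list, background)
  if (length(dropped))
    message(length(dropped), " list gene(s) absent from background dropped")
  gene_list <- intersect(gene_list, background)
  n <- length(gene_list); N <- length(background)
  rows <- lapply(names(term_sets), function(id) {
    t <- term_sets[[id]]
    g <- if (is.list(t)) t$genes else t
    g <- intersect(unique(.norm_ids(g)), background)
    ov <- intersect(gene_list, g)
    if (length(ov) == 0) return(NULL)
    data.frame(
      term_id = id,
      term_name = if (is.list(t) && !is.null(t$name)) t$name else id,
      category = if (is.list(t) && !is.null(t$category)) t$category else "other",
      k = length(ov), n = n, K = length(g), N = N,
      ease_p = ease_score(length(ov), n, length(g), N),
      genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), ease_p = numeric(),
                      significant = logical(), genes = character()))
  res$significant <- res$k >= min_overlap & res$ease_p <= max_p
  res <- res[order(res$ease_p, res$term_id), ]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "category", "k", "n", "K", "N",
          "ease_p", "significant", "genes")]
}

#' Remove redundant enriched terms
#'
#' Greedy scan of results sorted by score: a term is kept unless its overlap
#' gene set has Jaccard similarity of at least `jaccard_threshold` with a
#' term already kept -- the automated form of omitting essentially identical
#' terms with entirely or significantly overlapping member genes.
#'
#' @param results output of [enrich()] (sorted by ease_p).
#' @param jaccard_threshold similarity above which a term is redundant.
#' @return filtered results data.frame.
#' @export
deduplicate_terms <- function(results, jaccard_threshold = 0.75) {
  if (nrow(results) == 0) return(results)
  sets <- strsplit(results$genes, ",", fixed = TRUE)
  keep <- logical(nrow(results))
  kept_sets <- list()
  for (i in seq_len(nrow(results))) {
    red <- any(vapply(kept_sets, function(s) {
      length(intersect(s, sets[[i]])) / length(union(s, sets[[i]]))
    }, 0) >= jaccard_threshold)
    if (!red) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1]] <- sets[[i]]
    }
  }
  out <- results[keep, ]
  rownames(out) <- NULL
  out
}

#' Split differential calls into up and down gene lists
#'
#' Genes up-regulated by at least `fold` in any condition go to the up list;
#' down analogously. A gene whose direction changes over the time course
#' appears in both.
#'
#' @param calls output of [call_differential()].
#' @param fold fold threshold (5 by default, the enrichment input rule).
#' @return list with character vectors `up` and `down`.
#' @export
direction_split <- function(calls, fold = 5) {
  hit <- calls$magnitude >= log10(fold)
  list(up = sort(unique(calls$gene_id[hit & calls$direction == "up"])),
       down = sort(unique(calls$gene_id[hit & calls$direction == "down"])))
}
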