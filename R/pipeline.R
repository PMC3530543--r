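#' Pipeline configuration
#'
#' Collects every stage parameter with its default: the 2/5/10-fold summary
#' tiers, the 1.5--2 and >=10 clustering bands, the 5-fold heatmap bound, 30
#' RadViz anchors per class with the appendage ({FL, HL, T}) and internal
#' organ ({SC, B, H}) class schemes, the EASE significance rule (overlap >= 2
#' and score <= 0.01) on >=5-fold gene lists, and the display alignment of
#' the heart's own time grid onto the shared one (3 -> 3, 7 -> 6, 14 -> 12).
#'
#' @param sim a [sim_config()] used when `input` is NULL.
#' @param input optional path to a probe-table TSV (or a probe data.frame)
#'   to analyse instead of simulating.
#' @param out_dir output directory for stage artifacts; NULL for none.
#' @param span lowess span.
#' @param summary_folds fold thresholds for the summary table.
#' @param cluster_bands list of `c(low, high)` fold bands (NA = unbounded)
#'   to cluster on.
#' @param heatmap_bound heatmap clipping bound (fold).
#' @param n_per_class RadViz anchors per class.
#' @param radviz_schemes named list of tissue-class groupings.
#' @param enrich_fold fold threshold feeding the enrichment gene lists.
#' @param ease_max_p,min_overlap EASE significance rule.
#' @param jaccard_threshold redundancy threshold for term deduplication.
#' @param heart_align display alignment map for heart dpa.
#' @param run_qpcr whether to run the simulated qPCR concordance stage.
#' @param seed pipeline seed (also seeds `sim` unless one was supplied).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input = NULL, out_dir = NULL,
                            span = 0.3,
                            summary_folds = c(2, 5, 10),
                            cluster_bands = list(c(2, NA), c(10, NA), c(1.5, 2)),
                            heatmap_bound = 5,
                            n_per_class = 30,
                            radviz_schemes = list(
                              appendages = c("FL", "HL", "T"),
                              organs = c("SC", "B", "H")
                            ),
                            enrich_fold = 5,
                            ease_max_p = 0.01, min_overlap = 2,
                            jaccard_threshold = 0.75,
                            heart_align = c("3" = 3, "7" = 6, "14" = 12),
                            run_qpcr = TRUE,
                            seed = 1L) {
  if (is.null(sim) && is.null(input)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full regeneration-analysis pipeline
#'
#' Executes simulate/ingest, QC and Lowess normalization, replicate
#' aggregation, tiered differential-expression calling with the summary
#' table, hierarchical condition clustering on each configured fold band
#' (with self-sorting scores and Newick export), the clipped heatmap, RadViz
#' classification for each class scheme, EASE enrichment of the up- and
#' down-regulated gene lists, and (on simulated input) qPCR concordance.
#' All stage outputs are returned; when `out_dir` is set they are also
#' written as TSV/JSON together with a manifest recording every parameter
#' and the seed, which suffices to reproduce the run.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config)
  dir_out <- config$out_dir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(dir_out))
      utils::write.table(df, file.path(dir_out, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## ingest ------------------------------------------------------------------
  sim <- NULL
  probes <- .stage("input", {
    if (!is.null(config$input)) {
      if (is.character(config$input)) read_probe_table(config$input)
      else config$input
    } else {
      sim <- simulate_probe_data(config$sim)
      out$truth <- sim$truth
      sim$probes
    }
  })
  if (!is.null(sim)) out$truth <- sim$truth

  ## QC + normalize + aggregate ---------------------------------------------
  qc <- .stage("qc", qc_filter(probes))
  out$qc <- qc$reports
  save_tsv(qc$reports, "qc_report.tsv")
  norm <- .stage("normalize", lowess_normalize(qc$probes, span = config$span))
  xmat <- .stage("aggregate", aggregate_replicates(norm))
  out$expression <- xmat
  if (!is.null(dir_out))
    write_expression_matrix(xmat, file.path(dir_out, "expression.tsv"))

  ## differential expression --------------------------------------------------
  calls <- .stage("diffexpr", call_differential(xmat))
  out$calls <- calls
  save_tsv(calls, "diff_calls.tsv")
  out$summary <- summarize_counts(calls, thresholds = config$summary_folds)
  save_tsv(out$summary, "summary_counts.tsv")
  out$per_tissue <- per_tissue_counts(calls)
  save_tsv(out$per_tissue, "per_tissue_counts.tsv")

  ## clustering over fold bands ----------------------------------------------
  tissue_of <- xmat$conditions$tissue
  names(tissue_of) <- colnames(xmat$values)
  out$clustering <- .stage("clustering", lapply(config$cluster_bands, function(b) {
    genes_in <- band_select(xmat, b[1], if (is.na(b[2])) NULL else b[2])
    if (length(genes_in) < 2) return(NULL)
    dend <- cluster_conditions(xmat, genes_in)
    score <- self_sorting_score(dend, tissue_of,
                                k = length(unique(tissue_of)))
    nm <- if (is.na(b[2])) sprintf("ge%g", b[1]) else sprintf("%g-%g", b[1], b[2])
    if (!is.null(dir_out))
      write_newick(dend, file.path(dir_out, sprintf("dendrogram_%s.nwk", nm)))
    list(band = b, n_genes = length(genes_in), dendrogram = dend, score = score)
  }))

  ## heatmap ------------------------------------------------------------------
  out$heatmap <- .stage("heatmap", {
    de_genes <- band_select(xmat, 2)
    if (length(de_genes) >= 2) {
      gd <- cluster_genes(xmat[de_genes, ])
      cd <- cluster_conditions(xmat, de_genes)
      hm <- heatmap_export(xmat[de_genes, ],
                           gene_order = gd$labels[gd$order],
                           condition_order = cd$labels[cd$order],
                           fold_bound = config$heatmap_bound)
      if (!is.null(dir_out)) write_heatmap(hm, file.path(dir_out, "heatmap.tsv"))
      hm
    }
  })

  ## RadViz per class scheme ---------------------------------------------------
  out$radviz <- .stage("radviz", lapply(config$radviz_schemes, function(tis) {
    keep <- xmat$conditions$tissue %in% tis
    if (sum(keep) < 2 * length(tis)) return(NULL)
    sub <- xmat[, keep]
    model <- radviz(sub, sub$conditions$tissue, n_per_class = config$n_per_class)
    model
  }))
  if (!is.null(dir_out)) {
    for (nm in names(out$radviz)) {
      m <- out$radviz[[nm]]
      if (is.null(m)) next
      save_tsv(m$anchors, sprintf("radviz_%s_anchors.tsv", nm))
      save_tsv(m$points, sprintf("radviz_%s_points.tsv", nm))
    }
  }

  ## enrichment ----------------------------------------------------------------
  out$enrichment <- .stage("enrichment", {
    lists <- direction_split(calls, fold = config$enrich_fold)
    background <- genes(xmat)
    # stage-offset seed: keeps term membership independent of the draws that
    # assigned gene programs under the same pipeline seed
    terms <- if (!is.null(out$truth))
      simulate_term_sets(background, out$truth, seed = config$seed + 101L)
    else simulate_term_sets(background, seed = config$seed + 101L)
    res <- lapply(lists, function(gl) {
      if (length(gl) == 0) return(NULL)
      deduplicate_terms(
        enrich(gl, terms, background,
               min_overlap = config$min_overlap, max_p = config$ease_max_p),
        config$jaccard_threshold
      )
    })
    for (dir in names(res))
      if (!is.null(res[[dir]]))
        save_tsv(res[[dir]], sprintf("enrichment_%s.tsv", dir))
    res
  })

  ## qPCR concordance (simulated input only) -----------------------------------
  if (config$run_qpcr && !is.null(out$truth)) {
    out$qpcr <- .stage("qpcr", {
      rec <- simulate_qpcr(out$truth, seed = config$seed + 202L)
      rec <- pfaffl_ratio(rec)
      # pair against the measured array values where present
      lab <- condition_label(rec$tissue, rec$dpa)
      have <- lab %in% colnames(xmat$values)
      arr <- ifelse(have,
                    xmat$values[cbind(match(rec$gene_id, genes(xmat)),
                                      match(lab, colnames(xmat$values)))],
                    NA_real_)
      rep <- concordance(arr, rec$log10_ratio, fold = 2)
      save_tsv(rec, "qpcr_records.tsv")
      list(records = rec, report = rep)
    })
  }

  ## manifest ------------------------------------------------------------------
  if (!is.null(dir_out)) {
    manifest <- config
    manifest$out_dir <- NULL  # a path, not a run parameter
    manifest$input <- if (is.character(config$input)) config$input
                      else if (!is.null(config$input)) "<in-memory probe table>"
    class(manifest) <- NULL
    if (!is.null(manifest$sim)) class(manifest$sim) <- NULL
    jsonlite::write_json(manifest, file.path(dir_out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  if (is.null(dir_out)) out else invisible(out)
}

#' Align heart time points onto the shared display grid
#'
#' The heart is sampled on its own grid (3, 7, 14 dpa); for cross-tissue
#' displays its points are aligned with the other tissues at 3, 6 and 12 dpa.
#'
#' @param conditions data.frame with tissue and dpa columns.
#' @param map named alignment vector (names = heart dpa as character).
#' @return `conditions` with an added `display_dpa` column.
#' @export
align_heart_dpa <- function(conditions, map = c("3" = 3, "7" = 6, "14" = 12)) {
  conditions$display_dpa <- conditions$dpa
  h <- conditions$tissue == "H" & as.character(conditions$dpa) %in% names(map)
  conditions$display_dpa[h] <- map[as.character(conditions$dpa[h])]
  conditions
}
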