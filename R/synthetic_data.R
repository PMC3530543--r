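#' Simulation configuration for probe-level two-channel array data
#'
#' Builds and validates the parameter set for [simulate_probe_data()]. The
#' defaults describe the study conditions the generator emulates: six
#' regenerating newt tissues measured against matched intact (day 0) tissue on
#' custom two-channel arrays, with limbs, tail and brain sampled at 1, 3, 6,
#' 12 and 21 days postamputation (dpa), spinal cord at 1, 6, 12 and 21 dpa and
#' heart at 3, 7 and 14 dpa on a second array design; 1,860 assayed genes each
#' printed 7--23 times per array; replicate spot noise of 2--3% of signal; a
#' small fraction of bad features; and 1,417 control probes per array.
#'
#' @param n_genes number of assayed genes.
#' @param tissues tissue codes; defaults to FL (forelimb), HL (hindlimb),
#'   T (tail), SC (spinal cord), B (brain after spinal cord transection),
#'   H (heart).
#' @param time_grid named list mapping tissue code to its dpa grid.
#' @param replicates_range integer interval `[low, high]` for per-gene
#'   replicate printings.
#' @param frac_conserved fraction of genes carrying the conserved
#'   (cross-tissue) regeneration program.
#' @param frac_tissue_specific fraction of genes differentially expressed in
#'   exactly one tissue.
#' @param effect_log10_range interval of |true log10 fold change| at the peak
#'   time point for signature genes.
#' @param replicate_cv target relative standard deviation of replicate spot
#'   intensities (per channel).
#' @param dye_bias_coeffs polynomial coefficients (constant first) of the
#'   intensity-dependent dye-bias curve, evaluated in scaled mean
#'   log-intensity; the default plants a visible curvature for Lowess
#'   normalization to remove. Set to `0` for bias-free data.
#' @param bad_feature_rate probability that a spot is corrupted and flagged
#'   bad.
#' @param n_control_probes control spots per array.
#' @param frac_inverted fraction of genes additionally probed on the
#'   complementary ("inverted") strand.
#' @param baseline_range intensity range for the log-uniform day-0 baseline.
#' @param seed integer RNG seed; identical configs give byte-identical data.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1860,
                       tissues = c("FL", "HL", "T", "SC", "B", "H"),
                       time_grid = NULL,
                       replicates_range = c(7L, 23L),
                       frac_conserved = 0.10,
                       frac_tissue_specific = 0.30,
                       effect_log10_range = c(log10(2), log10(20)),
                       replicate_cv = 0.025,
                       dye_bias_coeffs = c(0.05, 0.08, -0.03),
                       bad_feature_rate = 0.001,
                       n_control_probes = 1417L,
                       frac_inverted = 0.025,
                       baseline_range = c(10^2.5, 10^4.5),
                       seed = 1L) {
  if (is.null(time_grid)) {
    time_grid <- list(
      FL = c(1, 3, 6, 12, 21), HL = c(1, 3, 6, 12, 21),
      T = c(1, 3, 6, 12, 21), B = c(1, 3, 6, 12, 21),
      SC = c(1, 6, 12, 21), H = c(3, 7, 14)
    )[tissues]
    names(time_grid) <- tissues
  }
  if (length(tissues) == 0L) stopf("'tissues' must be nonempty")
  if (!all(tissues %in% names(time_grid)))
    stopf("'time_grid' must name every tissue")
  if (any(!vapply(time_grid[tissues], length, 0L)))
    stopf("every tissue needs a nonempty time grid")
  if (any(unlist(time_grid) <= 0)) stopf("time grids are dpa > 0")
  check_proportion(frac_conserved, "frac_conserved")
  check_proportion(frac_tissue_specific, "frac_tissue_specific")
  check_proportion(bad_feature_rate, "bad_feature_rate")
  check_proportion(frac_inverted, "frac_inverted")
  if (frac_conserved + frac_tissue_specific > 1)
    stopf("frac_conserved + frac_tissue_specific must be <= 1")
  if (length(replicates_range) != 2L || replicates_range[1] > replicates_range[2] ||
      replicates_range[1] < 1)
    stopf("'replicates_range' must be an interval [low, high] with low >= 1")
  if (replicate_cv <= 0 || replicate_cv >= 1) stopf("'replicate_cv' must be in (0, 1)")
  if (diff(effect_log10_range) < 0 || effect_log10_range[1] <= 0)
    stopf("'effect_log10_range' must be a positive interval")
  structure(list(
    n_genes = as.integer(n_genes), tissues = tissues, time_grid = time_grid,
    replicates_range = as.integer(replicates_range),
    frac_conserved = frac_conserved, frac_tissue_specific = frac_tissue_specific,
    effect_log10_range = effect_log10_range, replicate_cv = replicate_cv,
    dye_bias_coeffs = dye_bias_coeffs, bad_feature_rate = bad_feature_rate,
    n_control_probes = as.integer(n_control_probes),
    frac_inverted = frac_inverted, baseline_range = baseline_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Temporal activation profile: a Gaussian-in-log-time bump peaking at 1 on a
# persistent baseline, so a signature gene stays induced (or repressed)
# throughout the sampled window and reaches its full magnitude at the peak
# time. The floor reflects that regeneration programs, once switched on,
# remain active over the first three weeks rather than firing at one
# time point.
.time_profile <- function(dpa, peak, width = 0.8, floor = 0.6) {
  floor + (1 - floor) * exp(-((log(dpa) - log(peak))^2) / (2 * width^2))
}

# dye bias in log10 units as a polynomial in scaled baseline log-intensity
.dye_bias <- function(log10_intensity, coeffs, baseline_range) {
  ctr <- mean(log10(baseline_range))
  half <- diff(log10(baseline_range)) / 2
  x <- (log10_intensity - ctr) / max(half, .Machine$double.eps)
  b <- 0
  for (j in seq_along(coeffs)) b <- b + coeffs[j] * x^(j - 1)
  b
}

#' Generate a probe-level dataset with planted ground truth
#'
#' Simulates every replicate spot of every gene on every hybridization
#' (one two-channel array per tissue/dpa condition, competing regenerating
#' tissue in the Cy5 channel against intact day-0 tissue in Cy3). Genes are
#' partitioned into a conserved regeneration program active in all tissues, a
#' tissue-specific program active in exactly one tissue, and null genes. A
#' signature gene's true log10 fold change follows a smooth activation bump
#' over the tissue's time grid, reaching its drawn peak magnitude (at least
#' 2-fold) at a randomly chosen grid point. Channel intensities are
#' `cy3 = baseline x noise` and `cy5 = baseline x 10^lfc x 10^bias(A) x
#' noise`, with independent multiplicative log-normal noise per channel whose
#' relative SD is `replicate_cv`, so the Cy5:Cy3 ratio carries the planted
#' fold change distorted by the intensity-dependent dye bias that Lowess
#' normalization is meant to remove. Bad features are corrupted and flagged;
#' control probes carry a `control` flag; a configurable subset of genes is
#' probed on both strands.
#'
#' @param config a [sim_config()].
#' @return A list of class `regen_sim` with elements `probes` (one row per
#'   replicate spot: probe_id, gene_id, tissue, dpa, array_id, cy5, cy3,
#'   flag, strand) and `truth` (gene_id, program, tissue, dpa, true_log10_fc).
#' @export
simulate_probe_data <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must come from sim_config()")
  with_seed(config$seed, {
    n <- config$n_genes
    gene_ids <- sprintf("Nvg%05d", seq_len(n))

    ## --- program labels and per-gene effects -------------------------------
    n_cons <- round(config$frac_conserved * n)
    n_ts <- round(config$frac_tissue_specific * n)
    program <- rep("null", n)
    idx <- sample.int(n, n_cons + n_ts)
    cons_idx <- idx[seq_len(n_cons)]
    ts_idx <- idx[seq_len(n_ts) + n_cons]
    program[cons_idx] <- "conserved"
    ts_tissue <- sample(config$tissues, n_ts, replace = TRUE)
    program[ts_idx] <- paste0("tissue_specific:", ts_tissue)

    effect <- runif(n, config$effect_log10_range[1], config$effect_log10_range[2]) *
      sample(c(-1, 1), n, replace = TRUE)
    effect[program == "null"] <- 0

    ## --- truth: per (gene, tissue, dpa) planted log10 fold -----------------
    cond <- do.call(rbind, lapply(config$tissues, function(ti) {
      data.frame(tissue = ti, dpa = config$time_grid[[ti]])
    }))
    truth <- do.call(rbind, lapply(seq_len(nrow(cond)), function(ci) {
      ti <- cond$tissue[ci]; t <- cond$dpa[ci]
      lfc <- numeric(n)
      grid <- config$time_grid[[ti]]
      # peak time and cross-tissue magnitude jitter drawn once per (gene, tissue)
      # below, seeded deterministically through the single stream
      data.frame(gene_id = gene_ids, program = program, tissue = ti, dpa = t,
                 true_log10_fc = lfc)
    }))
    # fill planted effects with one peak-time / jitter draw per gene x tissue
    for (ti in config$tissues) {
      grid <- config$time_grid[[ti]]
      peak <- sample(grid, n, replace = TRUE)
      jitter <- runif(n, 0.9, 1.1)
      active <- program == "conserved" | program == paste0("tissue_specific:", ti)
      mag <- abs(effect) * jitter
      # invariant: an active signature gene reaches at least 2-fold at its peak
      mag <- pmax(mag, log10(2))
      for (t in grid) {
        rows <- truth$tissue == ti & truth$dpa == t
        prof <- .time_profile(t, peak)
        truth$true_log10_fc[rows] <- ifelse(active, sign(effect) * mag * prof, 0)
      }
    }

    ## --- probe scaffold ----------------------------------------------------
    n_rep <- sample(seq(config$replicates_range[1], config$replicates_range[2]),
                    n, replace = TRUE)
    baseline <- 10^runif(n, log10(config$baseline_range[1]),
                         log10(config$baseline_range[2]))
    inv_idx <- sample.int(n, round(config$frac_inverted * n))
    n_rep_inv <- sample(seq(config$replicates_range[1], config$replicates_range[2]),
                        length(inv_idx), replace = TRUE)

    spot_gene <- c(rep(seq_len(n), n_rep), rep(inv_idx, n_rep_inv))
    spot_strand <- rep(c("plain", "inverted"), c(sum(n_rep), sum(n_rep_inv)))
    rep_no <- c(
      unlist(lapply(n_rep, seq_len), use.names = FALSE),
      unlist(lapply(n_rep_inv, seq_len), use.names = FALSE)
    )
    probe_id <- sprintf("%s%s_r%02d", gene_ids[spot_gene],
                        ifelse(spot_strand == "inverted", "i", ""), rep_no)
    n_spots <- length(spot_gene)

    sdlog <- sqrt(log(1 + config$replicate_cv^2))  # exact log-normal relative SD

    per_array <- lapply(seq_len(nrow(cond)), function(ci) {
      ti <- cond$tissue[ci]; t <- cond$dpa[ci]
      design <- if (ti == "H") "B" else "A"
      array_id <- sprintf("%s_%s_%g", design, ti, t)
      lfc_gene <- truth$true_log10_fc[truth$tissue == ti & truth$dpa == t]
      lfc <- lfc_gene[spot_gene]
      base <- baseline[spot_gene]
      bias <- .dye_bias(log10(base), config$dye_bias_coeffs, config$baseline_range)
      cy3 <- base * exp(rnorm(n_spots, -sdlog^2 / 2, sdlog))
      cy5 <- base * 10^(lfc + bias) * exp(rnorm(n_spots, -sdlog^2 / 2, sdlog))
      flag <- ifelse(runif(n_spots) < config$bad_feature_rate, "bad", "ok")
      bad <- flag == "bad"
      if (any(bad)) {  # corrupted spots: junk intensities, still positive
        cy5[bad] <- cy5[bad] * 10^runif(sum(bad), -2, 2)
        cy3[bad] <- cy3[bad] * 10^runif(sum(bad), -2, 2)
      }
      spots <- data.frame(
        probe_id = probe_id, gene_id = gene_ids[spot_gene], tissue = ti, dpa = t,
        array_id = array_id, cy5 = cy5, cy3 = cy3, flag = flag,
        strand = spot_strand, stringsAsFactors = FALSE
      )
      if (config$n_control_probes > 0L) {
        nc <- config$n_control_probes
        cbase <- 10^runif(nc, 2.5, 3.5)
        ctl <- data.frame(
          probe_id = sprintf("CTRL%04d", seq_len(nc)),
          gene_id = sprintf("CTRL%04d", seq_len(nc)),
          tissue = ti, dpa = t, array_id = array_id,
          cy5 = cbase * exp(rnorm(nc, -sdlog^2 / 2, sdlog)),
          cy3 = cbase * exp(rnorm(nc, -sdlog^2 / 2, sdlog)),
          flag = "control", strand = "plain", stringsAsFactors = FALSE
        )
        spots <- rbind(spots, ctl)
      }
      spots
    })
    probes <- do.call(rbind, per_array)
    rownames(probes) <- NULL
    structure(list(probes = probes, truth = truth, config = config),
              class = "regen_sim")
  })
}

#' @export
print.regen_sim <- function(x, ...) {
  cat(sprintf("regen_sim: %d spots, %d genes, %d arrays\n",
              nrow(x$probes), x$config$n_genes,
              length(unique(x$probes$array_id))))
  cat("  programs:", paste(sprintf("%s=%d", names(tb <- table(sub(":.*", "", x$truth$program[!duplicated(x$truth$gene_id)]))), tb), collapse = ", "), "\n")
  invisible(x)
}

.PROBE_COLS <- c("probe_id", "gene_id", "tissue", "dpa", "array_id",
                 "cy5", "cy3", "flag", "strand")

#' Write / read a probe-level spot table as TSV
#'
#' Lossless round trip of the probe table dialect (columns probe_id, gene_id,
#' tissue, dpa, array_id, cy5, cy3, flag, strand). Reading validates the
#' header and reports the 1-based data line number of any malformed row.
#'
#' @param probes probe table data.frame (e.g. `simulate_probe_data()$probes`).
#' @param path TSV file path.
#' @export
write_probe_table <- function(probes, path) {
  miss <- setdiff(.PROBE_COLS, names(probes))
  if (length(miss)) stopf("probe table lacks columns: %s", paste(miss, collapse = ", "))
  utils::write.table(probes[, .PROBE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(.PROBE_COLS, names(df))
  if (length(miss))
    stopf("probe table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  for (col in c("dpa", "cy5", "cy3")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) == 0) bad <- which(is.na(v))
    if (length(bad))
      stopf("parse error in %s: non-numeric '%s' at data line %d",
            path, col, bad[1])
    df[[col]] <- v
  }
  bad_flag <- which(!df$flag %in% c("ok", "bad", "control"))
  if (length(bad_flag))
    stopf("parse error in %s: invalid flag at data line %d", path, bad_flag[1])
  df
}

#' Generate synthetic term-to-gene annotation sets
#'
#' Builds a GMT-style collection of term sets over the assayed genes for
#' exercising enrichment analysis without an external ontology. Random terms
#' draw members uniformly; if planted programs are supplied via `truth`,
#' additional terms are enriched for conserved-program and per-tissue genes,
#' giving the enrichment stage real structure to find.
#'
#' @param gene_ids background gene identifiers.
#' @param truth optional truth table from [simulate_probe_data()].
#' @param n_terms number of random terms.
#' @param term_size_range size interval for random terms.
#' @param seed RNG seed.
#' @return Named list of terms; each element is a list with `name`,
#'   `category` and `genes`.
#' @export
simulate_term_sets <- function(gene_ids, truth = NULL, n_terms = 50,
                               term_size_range = c(10, 80), seed = 1L) {
  with_seed(seed, {
    cats <- c("cell_component", "biological_process", "molecular_function")
    terms <- lapply(seq_len(n_terms), function(i) {
      sz <- sample(seq(term_size_range[1], min(term_size_range[2], length(gene_ids))), 1)
      list(name = sprintf("random process %d", i),
           category = sample(cats, 1),
           genes = sample(gene_ids, sz))
    })
    names(terms) <- sprintf("TERM%04d", seq_len(n_terms))
    if (!is.null(truth)) {
      prog <- truth$program[!duplicated(truth$gene_id)]
      ids <- truth$gene_id[!duplicated(truth$gene_id)]
      cons <- ids[prog == "conserved"]
      if (length(cons) >= 5) {
        sz <- min(length(cons), 60)
        terms[["PLANT_CONS"]] <- list(
          name = "conserved regeneration program", category = "biological_process",
          genes = sample(cons, sz)
        )
      }
      for (ti in unique(sub("^tissue_specific:", "", grep("^tissue_specific:", prog, value = TRUE)))) {
        tsg <- ids[prog == paste0("tissue_specific:", ti)]
        if (length(tsg) >= 5) {
          terms[[paste0("PLANT_", ti)]] <- list(
            name = sprintf("%s-specific program", ti), category = "biological_process",
            genes = sample(tsg, min(length(tsg), 60))
          )
        }
      }
    }
    terms
  })
}

#' Simulate qRT-PCR validation records from planted truth
#'
#' Emits one Pfaffl-style record per requested (gene, tissue, dpa): primer
#' efficiencies drawn in `efficiency_range`, a stable reference gene, and
#' cycle thresholds constructed so the efficiency-corrected ratio equals the
#' planted fold change perturbed by log10-scale measurement noise. The
#' matched array-side value is reported as `compression x true_log10_fc`,
#' letting callers emulate the narrower dynamic range of array ratios
#' relative to qPCR.
#'
#' @param truth truth table from [simulate_probe_data()].
#' @param gene_ids genes to validate (default: up to 13 signature genes).
#' @param dpa time point to validate at (default 3).
#' @param tissues tissues to validate in.
#' @param efficiency_range interval for amplification efficiencies.
#' @param noise_sd log10-scale SD of qPCR measurement noise.
#' @param compression multiplicative compression applied to the reported
#'   array-side log10 value (1 = none).
#' @param seed RNG seed.
#' @return data.frame of qPCR records plus `array_log10fc` and
#'   `true_log10fc` columns.
#' @export
simulate_qpcr <- function(truth, gene_ids = NULL, dpa = 3,
                          tissues = c("FL", "HL", "T", "H"),
                          efficiency_range = c(1.85, 2.0),
                          noise_sd = 0.15, compression = 1, seed = 1L) {
  with_seed(seed, {
    sub <- truth[truth$tissue %in% tissues & truth$dpa == dpa, ]
    if (is.null(gene_ids)) {
      sig <- unique(sub$gene_id[sub$program != "null"])
      gene_ids <- utils::head(sig, 13)
    }
    sub <- sub[sub$gene_id %in% gene_ids, ]
    if (nrow(sub) == 0) stopf("no (gene, tissue, dpa) rows to validate")
    n <- nrow(sub)
    E_t <- runif(n, efficiency_range[1], efficiency_range[2])
    E_r <- 2.0
    target_lfc <- sub$true_log10_fc + rnorm(n, 0, noise_sd)
    # choose Ct values so that E_t^(ct_control - ct_sample) = 10^target_lfc
    ct_tc <- runif(n, 22, 28)
    ct_ts <- ct_tc - target_lfc * log(10) / log(E_t)
    data.frame(
      gene_id = sub$gene_id, tissue = sub$tissue, dpa = sub$dpa,
      E_target = E_t, ct_target_control = ct_tc, ct_target_sample = ct_ts,
      reference = "hat1", E_ref = E_r,
      ct_ref_control = 20, ct_ref_sample = 20,
      true_log10fc = sub$true_log10_fc,
      array_log10fc = compression * sub$true_log10_fc,
      stringsAsFactors = FALSE
    )
  })
}
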