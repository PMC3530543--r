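# regenarray

Multi-tissue regeneration expression analysis for two-channel microarray
time courses.

Some salamanders regenerate amputated limbs, tails, spinal cord, brain
tissue and heart muscle without scarring. A classic way to look for the gene
programs behind this is a custom two-channel (Cy5/Cy3) microarray screen:
RNA from regenerating tissue at 1–21 days postamputation (dpa) is
competitively hybridized against RNA from the matched intact (day 0) tissue,
so each spot measures a relative expression ratio. `regenarray` implements
the full downstream analysis for such a screen as a tested R pipeline:

- **Probe-level simulation** with planted ground truth: six tissues on their
  own sampling grids (heart on a separate array design), 7–23 replicate
  printings per gene, ~2–3% replicate intensity noise, an
  intensity-dependent dye bias, control probes, rare bad features, and gene
  programs that are either conserved across tissues, tissue-specific, or
  null.
- **Array processing**: spot QC (arrays with ≥1% bad features are dropped),
  Lowess normalization of M = log10(Cy5/Cy3) against
  A = ½·log10(Cy5·Cy3), and replicate aggregation by the geometric mean —
  the gene value is the arithmetic mean of replicate log10 ratios, with its
  standard deviation and replicate count.
- **Tiered differential expression**: inclusive fold-change tiers at ≥1.5,
  ≥2, ≥5 and ≥10-fold per gene/tissue/time, summary tables with both
  directions counted (a gene that switches direction counts in both), and
  half-open fold bands for downstream displays.
- **Hierarchical clustering** of tissue/time conditions on Euclidean
  distance with a quantitative self-sorting score (cluster purity and
  adjusted Rand index against tissue labels), heatmap export clipped to a
  5-fold color bound, and Newick dendrogram export.
- **Class-discriminant RadViz**: per class, genes are scored by a Welch
  t statistic (class vs rest, Bonferroni-reported) on min-max-normalized
  values; the top 30 per class anchor a circle divided into paired +/−
  sectors, and samples settle at the spring-force equilibrium
  `u = Σ k_j S_j / Σ k_j`, where the spring constant `k` is the normalized
  expression value (Hooke's law, f = k·d).
- **EASE-score enrichment**: the conservative variant of the Fisher exact
  test that removes one gene from the list–term overlap,
  `P(X ≥ k−1)` for `X ~ Hypergeom(N, K, n)`, with the ≥2-overlap and
  p ≤ 0.01 significance rule, GMT input and greedy Jaccard redundancy
  removal.
- **qRT-PCR concordance** via the Pfaffl efficiency-corrected ratio
  `E_target^ΔCt(target) / E_ref^ΔCt(reference)` and a same-mode
  (up vs down at ≥2-fold) agreement report against the array values.

## Worked example

```r
library(regenarray)

cfg <- pipeline_config(sim = sim_config(n_genes = 300, seed = 1), seed = 1)
res <- run_pipeline(cfg)

print(res$expression)
#> regen_expr: 300 genes x 27 conditions (6 tissues: FL, HL, T, SC, B, H)
#>   log10 fold-change range: [-1.364, 1.313]

print(res$summary)
#>   threshold n_up    pct_up n_down  pct_down
#> 1         2   65 21.666667     54 18.000000
#> 2         5   33 11.000000     34 11.333333
#> 3        10   17  5.666667     13  4.333333

print(res$radviz$appendages)
#> radviz: 90 anchors (FL=30, HL=30, T=30), 15 samples
#>   own-centroid fraction 1.00, mean silhouette 0.83

b <- res$clustering[[1]]  # the >= 2-fold band
#> self-sorting on the >=2-fold band (119 genes): purity 1.00, ARI 1.00

res$qpcr$report
#> qPCR concordance: 48/52 same mode (92%), r = 0.96

head(res$enrichment$up[, c("term_id", "term_name", "k", "K", "ease_p")], 2)
#>      term_id                      term_name k  K      ease_p
#> 1    PLANT_H             H-specific program 6 12 0.005388621
#> 2 PLANT_CONS conserved regeneration program 8 30 0.032487070
```

Reading the output: 65 of 300 genes are up-regulated at least 2-fold in at
least one tissue at one time point (21.7% of the assayed genes), counts
shrink monotonically at the 5- and 10-fold tiers, the 27 tissue/time
conditions cluster perfectly by tissue of origin on the ≥2-fold gene set,
the RadViz projection places every appendage sample nearest its own class
centroid, and 48 of 52 simulated qPCR validations agree with the array on
the mode of differential expression. The enrichment stage ranks the planted
program terms ahead of the random ones.

Real data enters either as a probe-level TSV (`read_probe_table()`,
columns `probe_id, gene_id, tissue, dpa, array_id, cy5, cy3, flag, strand`)
or as a pre-aggregated log10 ratio matrix (`read_expression_matrix()`, one
`"tissue:dpa"` column per condition).

## Package layout

- `R/synthetic_data.R` — generator, truth tables, term-set and qPCR simulators
- `R/array_processing.R` — QC, Lowess normalization, replicate aggregation
- `R/diffexpr.R` — tier calls, summary counts, fold bands, direction profiles
- `R/clustering.R` — condition/gene dendrograms, self-sorting score, heatmap
- `R/radviz.R` — feature selection, anchor layout, projection, separation
- `R/enrichment.R` — EASE score, GMT I/O, enrichment, redundancy removal
- `R/qpcr.R` — Pfaffl ratios and concordance
- `R/pipeline.R` — `run_pipeline()` orchestration with manifest output

See `vignettes/regeneration-analysis.Rmd` for the methods account.
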