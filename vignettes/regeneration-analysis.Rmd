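---
title: "Methods: multi-tissue regeneration expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue regeneration expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenarray)
```

# The measurement model

Every hybridization in this design is a two-channel competitive measurement:
RNA from a regenerating tissue at some number of days postamputation (dpa)
is labelled Cy5 and hybridized against Cy3-labelled RNA from the matched
intact (day 0) tissue on the same array. A spot therefore measures a
*relative* expression ratio, and day 0 never appears as a condition of its
own — it is the denominator of every ratio. Six tissues are measured on
their own sampling grids: forelimb, hindlimb, tail and brain at 1, 3, 6, 12
and 21 dpa, spinal cord at 1, 6, 12 and 21 dpa, and heart at 3, 7 and 14
dpa on a second array design (the generator marks heart arrays with a
distinct design prefix but does not model probe-content differences between
the two designs). For cross-tissue displays the heart grid is aligned onto
the shared one as 3 → 3, 7 → 6, 14 → 12 (`align_heart_dpa()`).

Each gene is printed many times per array (7–23 replicate spots), which is
what makes the downstream fold-change analysis usable without biological
replicates per condition: the replicate printings pin down the technical
variance. The study design this emulates pools several animals per time
point into one hybridization, so per-condition *biological* variance is not
identifiable from these data; the generator exposes technical replication
only, and nothing downstream pretends otherwise.

# The synthetic-data generator

`simulate_probe_data(sim_config())` emulates the statistical structure the
analysis assumes, with planted ground truth so every downstream stage can be
scored against known answers.

**Gene programs.** Genes are partitioned into a *conserved* program (default
10%), active in every tissue; *tissue-specific* programs (default 30%,
spread uniformly over tissues), active in exactly one tissue; and null genes
(true log10 fold change 0 everywhere). Signature genes draw a peak |log10
fold| uniformly from `effect_log10_range` (default log10 2 to log10 20) with
a random sign, jittered per tissue by ±10% but floored at log10 2, so every
active gene is at least 2-fold at its peak in every tissue where its program
runs.

**Temporal profile.** An active gene follows a Gaussian-in-log-time bump
that peaks (value 1) at a grid point drawn per gene and tissue, riding on a
persistent baseline of 0.6: `p(t) = 0.6 + 0.4·exp(−(log t − log t_peak)² /
2·0.8²)`. The floor encodes the biology this emulates — regeneration
programs, once induced, stay active across the first three weeks rather than
firing at a single time point — and it is what makes tissue identity visible
at *every* sampled time. An earlier all-bump profile (no floor) collapses
early time points of all tissues toward zero and makes conditions cluster by
time rather than tissue, which is not the structure the analysis is meant to
find. Conserved genes draw their peak time independently per tissue: the
program is shared, but each tissue runs it on its own schedule, which is
exactly why condition clustering can separate tissues even though most
signature genes are common to all of them.

**Intensities and noise.** Each gene has a day-0 baseline intensity drawn
log-uniformly over `baseline_range` (default 10^2.5–10^4.5). A spot's
channels are

```
cy3 = baseline · ε₃          cy5 = baseline · 10^lfc · 10^bias(A) · ε₅
```

with ε₃, ε₅ independent multiplicative log-normal factors whose relative SD
is `replicate_cv` (default 0.025, matching the reported 2–3% replicate
fidelity of the platform). Giving *each channel* its own noise factor makes
the measured per-channel replicate relative SD equal `replicate_cv`, which
is the quantity `replicate_cv_summary()` measures; the noise on the
*ratio* is then the quotient of the two factors, with log-scale SD √2 times
the per-channel value. The log-normal mean is offset by −σ²/2 so the
expected intensity is the baseline itself.

**Dye bias.** `bias(A)` is a polynomial (default mildly curved, coefficients
`c(0.05, 0.08, −0.03)`) in the scaled baseline log-intensity. It gives
Lowess normalization something real and smooth to remove; setting
`dye_bias_coeffs = 0` produces bias-free data for calibration tests.

**Artifacts.** Bad features occur at `bad_feature_rate` (default 0.1%) and
get junk intensities; each array also carries `n_control_probes` control
spots (default 1,417) with ratio ≈ 1. A small fraction of genes (default
2.5%) is probed on the complementary ("inverted") strand as a second,
independently noisy replicate set mapped to the same gene.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-sequence effects, spatial array artifacts,
print-tip structure, background signal, saturation at the scanner, and any
biological replicate variance. Real arrays also do not come with ground
truth; the recovery and self-sorting guarantees quantified here are
statements about data *with* the assumed structure, not about any particular
real dataset.

# Array processing

`qc_filter()` drops bad spots, removes control probes from gene-level work
(they still count in each array's QC denominator), and excludes any array
whose bad fraction reaches 1% — the standard facility rejection threshold.

`lowess_normalize()` computes M = log10(cy5/cy3) and
A = ½·log10(cy5·cy3) per array and subtracts a robust locally weighted
regression of M on A. The smoother is `stats::lowess` with span 0.3 and 3
robustness iterations — common two-channel practice; the span is exposed
because the right value depends on spot density. Arrays with fewer than 10
usable spots are passed through raw with a warning rather than fit with a
meaningless curve. Normalization is global (whole-array), not per
print-tip: the probe table carries no print-tip coordinates, and the
generator plants only global intensity-dependent bias.

`aggregate_replicates()` averages replicate log10 ratios per gene and
condition — arithmetically on the log scale, which is the log of the
geometric-mean ratio — and records the log10-scale (geometric) SD and the
replicate count. The SD is kept on the log scale because the mean is; a
linear-scale SD would not pair with a geometric mean. Plain and
inverted-strand records for the same gene are aggregated separately and the
record with the larger |mean| is retained: the strands are independent
probes of the same transcript, and the stronger signal is taken as the
better hybridization. This reconciliation rule is a package decision — the
two-strand design is documented for the platform, but not how the strands
were combined. Genes with no usable replicate in a condition are missing
there and are simply excluded from that condition's calls.

# Differential expression

Calls are pure fold-change tiers, not significance tests — with 7–23
technical replicates at 2–3% noise, the standard error of a gene's log10
ratio is far below the smallest tier, so thresholding is the appropriate
instrument and no multiple-testing machinery is applied at this stage.
Boundaries are inclusive (`magnitude ≥ log10(2)` is a 2-fold call) at 1.5,
2, 5 and 10-fold; direction is `none` below 1.5-fold. Summary counts are
"entire, inclusive": the ≥2-fold column contains the ≥5- and ≥10-fold genes,
and a gene that changes direction over the time course counts in both the
up and down columns. Percentages divide by the number of assayed genes
(genes with at least one valid measurement) by default, with the denominator
configurable. For the between-2-and-5-fold fraction both denominators are of
interest — of all assayed genes or of the differentially expressed subset —
and `summarize_counts()` output makes either a one-line computation, so the
package does not privilege one. Fold bands for display subsets are half-open
at the top (`[1.5, 2)`), keeping the low band disjoint from the ≥2-fold set.

# Clustering and self-sorting

`cluster_conditions()` clusters condition vectors (features = selected
genes) under Euclidean distance. Missing values are imputed as 0 before the
distance computation: on this scale 0 means "no change", the least
informative value, which neither attracts nor repels any pair. Linkage
defaults to complete — the default of the R clustering stack this kind of
display is built with — and `single`, `average` and `ward` are available,
since the linkage is genuinely unspecified territory. Items are sorted
lexicographically by label before clustering so distance ties resolve the
same way on every run.

"Tissue self-sorting" — the observation that conditions group by tissue of
origin, whatever the time point — is quantified rather than eyeballed:
`self_sorting_score()` cuts the tree at k clusters and reports cluster
purity and the adjusted Rand index against the tissue labels. ARI comes
from `mclust`; purity is computed in-package. The heatmap contract is the
clipped matrix plus a color-scale description (±log10 of the fold bound,
default 5-fold; green–black–red, piecewise-linear): the exact palette is
presentation, the clipping and scale are the contract.

# Class-discriminant RadViz

The projection answers: *which genes best tell the labelled tissue classes
apart, and how cleanly do the samples separate when only those genes act?*

Feature scores are Welch (unequal-variance) two-sample t statistics of each
gene's min-max-normalized values, class vs all other conditions. The
normalized scale is used for the sector ratio too — class mean divided by
the sum of the other classes' means — because raw log10 means can be
negative, which makes a ratio criterion ill-defined; on the [0, 1] scale
the ratio is always meaningful. No hard t or p cutoff is imposed: genes are
ranked by |t| within class and the top `n_per_class` (default 30) kept,
with the Bonferroni-adjusted p (multiplied by the gene count, capped at 1)
reported for transparency. A gene may anchor only one class; when several
classes select it, it stays where its |t| is largest and the next-ranked
gene is promoted for the losers. Zero-variance genes score t = 0 and are
never selected.

The display circle has 2·n_classes equal sectors, each class's − sector
diametrically opposite its + sector; within a sector, anchors sit at
uniformly spaced angles with half-gap margins, ordered by rank from the
arc's counterclockwise start. Samples are placed at the equilibrium of
spring forces f = k·d toward the anchors, which has the closed form
u = Σ k_j S_j / Σ k_j — the k-weighted centroid of the anchor positions.
The closed form holds whether the force acts on distance or squared
distance; the package adopts it directly and the test suite checks it
against an iterative force-balance minimizer. It follows immediately that
the projection is invariant to scaling all of a sample's spring constants
by a positive factor, and that every point lies in the convex hull of its
anchors. A sample with all-zero springs is placed at the origin.
`separation_report()` turns the picture into numbers: own-centroid
fraction and mean silhouette width (via `cluster`), with a degenerate flag
(silhouette reported as 0) when all points coincide.

# Enrichment

The EASE score is the one-gene-penalized hypergeometric upper tail:
`P(X ≥ k − 1)` for `X ~ Hypergeom(N, K, n)`, 1.0 for overlaps of 0 or 1.
Removing one overlap gene before taking the tail makes the score strictly
more conservative than the Fisher exact upper tail and, in particular,
refuses to call single-gene overlaps significant no matter how small the
term. Significance uses the conventional rule: overlap ≥ 2 and score
≤ 0.01. The statistic is local — any term-to-gene mapping in GMT form is
accepted, with no ontology-graph propagation (annotations are taken as
given, FAT-style flattened input). The background defaults to the assayed
gene universe supplied by the caller; published analyses of this kind often
ran against a whole-genome background of a model species, so externally
published term lists are structural templates rather than exactly
reproducible targets. Redundant terms (near-identical overlap gene sets)
are removed by a greedy scan keeping each term unless its overlap has
Jaccard ≥ 0.75 with an already-kept term; 0.75 operationalizes
"significantly overlapping" and is exposed.

# qPCR concordance

`pfaffl_ratio()` implements efficiency-corrected relative quantification:
ratio = E_target^ΔCt(target) / E_ref^ΔCt(reference) with ΔCt = control −
sample, normalized to a stable reference gene. Efficiencies are inputs in
(1, 2] — their derivation from dilution series is upstream wet-lab work.
`concordance()` reports the fraction of gene/condition pairs where array
and qPCR agree on the mode of differential expression at ≥2-fold. The
default convention counts a pair where both platforms stay below threshold
as concordant; `strict = TRUE` requires both to reach the threshold with
the same sign, because the convention behind any published "same mode"
count is rarely stated. Pearson correlation of the paired log10 values is
reported alongside, since "overall correlation" can mean either quantity.
The qPCR simulator can compress the array-side values (`compression < 1`)
to emulate the narrower dynamic range arrays show relative to qPCR.

# Numerical choices and degenerate inputs

- Tier boundaries are inclusive; fold bands half-open at the top.
- Lowess: span 0.3, tricube weights, 3 robustness iterations; < 10 spots →
  raw values with a warning.
- Constant genes normalize to spring constant 0.5 (neutral) and score t = 0.
- Σk = 0 projects to the origin; all-coincident projections flag the
  silhouette as degenerate and report 0.
- Distance ties in clustering break by lexicographic label order.
- Single-condition clustering returns a one-leaf stub rather than an error.
- EASE inputs are validated (0 ≤ k ≤ min(n, K), n ≤ N, K ≤ N); inconsistent
  tables are errors, not silent 1.0s.
- All seeds flow through a save/restore wrapper so library calls never
  disturb the caller's RNG stream; pipeline stages draw from offset seeds so
  that, e.g., synthetic term membership is independent of the program
  assignment drawn from the same pipeline seed.

# Problem sizes used in the checks

The shipped test-and-acceptance workloads run the full default study
geometry (1,860 genes, six tissues, 27 hybridizations, 1,417 control probes
per array) once for end-to-end recovery, and smaller geometries (80–300
genes, two to six tissues) for the per-module properties and oracle
comparisons, which keeps each property readable and the whole suite quick
while exercising every code path at realistic replicate counts and noise.

# Known limitations

- Fold-change calling carries no error model; it inherits its validity from
  the replicate-rich array design, and would be the wrong tool for designs
  with few replicates.
- The strand-reconciliation rule (larger |mean|) and the concordance
  convention are package decisions where the field's practice varies; both
  are configurable or documented above.
- Purity/ARI depend on the cut count k; the pipeline uses k = number of
  tissues, which is the honest default but not an optimum.
- The generator's noise is purely multiplicative and spot-independent; real
  arrays show spatially correlated artifacts that QC must catch upstream.
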