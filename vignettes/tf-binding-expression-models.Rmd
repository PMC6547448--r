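---
title: "Modeling transcript levels from quantitative TF binding signal"
author: "tfmars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcript levels from quantitative TF binding signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfmars)
```

## The modeling problem

Chromatin immunoprecipitation with exonuclease trimming (ChIP-exo) measures
transcription-factor (TF) binding genome-wide with high resolution and low
background. When the same cellular states are also profiled by RNA-seq, one
can ask a quantitative question: how much of the variation in transcript
levels across genes is explained by how much each TF binds each promoter?

`tfmars` implements that framework end to end for condition-resolved
studies (for example, yeast chemostat cultures held at one growth rate
across distinct metabolic regimes):

1. **Quantify binding.** Per-base coverage tracks (WIG) are averaged over
   biological replicates and summarized per gene promoter. Three
   representations are supported: the summed signal of SNR-thresholded
   peaks, coverage sums in ±50 bp windows around peaks, and the plain sum
   of coverage over the whole promoter window (TSS −500 to +500 by
   default). The promoter sum deliberately keeps weak binding events that
   a peak caller would discard; with a low-background assay those events
   carry real regulatory information, and the package's representation
   comparison makes the difference measurable.
2. **Quantify expression.** Gene read counts are filtered (≥ 1 read in
   every sample), converted to FPKM
   (count × 10⁹ / (library size × gene length)), and replicate-averaged
   per condition. FPKM on the natural scale is the regression response.
3. **Model.** Transcript levels are regressed on binding with multivariate
   adaptive regression splines (MARS),
   *Y* = β₀ + Σₖ βₖ Bₖ(x) + ε, where each basis term Bₖ is either a TF's
   binding signal or a hinge max(0, x − t) / max(0, t − x). A hinge knot
   is interpretable as a binding threshold below which the TF has no
   predicted effect; a retained pair of opposite hinges whose upper arm is
   flat describes saturation.
4. **Interrogate.** On top of fitted models the package computes signed TF
   importance, binding collinearity with substitution testing,
   additive-versus-multiplicative interaction scans, promoter-segment and
   region-extension regressions, coordinated-trio detection, and
   BIC-selected k-means clustering of normalized expression with
   hypergeometric gene-set enrichment.

## The MARS engine

The engine is written from scratch in this package (forward pass, backward
pass, cross-validated stabilization) because it *is* the core method; the
surrounding steps (k-means, hypergeometric tests, BH adjustment, OLS
solving) use base R's stats machinery.

**Forward pass.** Starting from the intercept, the candidate set at each
step is every not-yet-included linear term plus a reflected hinge pair at
every admissible knot of every variable; the addition with the largest RSS
reduction wins. Knots are restricted to observed data values (not a grid)
with at least `endspan` observations strictly between the knot and each
data extreme — the default `endspan = 100` suppresses boundary knots that
would let a hinge chase a handful of extreme-binding genes. The pass stops
at `maxTerms` (default min(21, n/10)) or when the relative RSS improvement
drops below 1e-6. Ties break deterministically: lowest variable index,
linear before hinge, lowest knot. Internally a hinge pair is scored
through the identity span{1, h⁺, h⁻} = span{1, x, h⁺}, which lets all
candidate knots of a variable be evaluated with one set of matrix
projections.

**Backward pass.** Sub-models are scored by generalized cross-validation,
GCV = (RSS/n) / (1 − C/n)², with complexity
C = #coefficients + `penalty` × #knots and `penalty = 2` (the additive-model
convention; a hinge pair at one knot costs one knot); the intercept-only
model is always a candidate. Up to 10 terms the pruner refits *every*
subset and returns the exact GCV minimum (at most 1024 small OLS refits —
cheap at these sizes, and greedy deletion demonstrably misses the optimum
by a few percent on a handful per hundred random instances); above that
the classical greedy backward deletion path is used. The test suite
verifies the exact-minimum property against an independent enumeration
oracle.

**Cross-validated stabilization (`cvSelect`).** The exact protocol behind
"selection with cross-validation" is a design decision of this package: a
MARS model is fitted on every fold-complement of a repeated k-fold split
(default 10 folds × 5 repeats); a TF is retained when it appears in more
than half of the fits, and keeps its hinge form only when a hinge on that
TF also appears in more than half (knot = median of the fold knots). The
retained structure is then refitted on all data — and that final refit is
itself GCV-pruned, so cross-validation *proposes* structure but never
forces it into the final model: borderline structure that full-data GCV
rejects is still dropped. All knobs (`folds`, `repeats`, `retainFrac`) are
exposed.

**Importance.** The relative importance of a selected TF is the increase
in model GCV when all of that TF's terms are deleted (with refit), floored
at zero and normalized to sum to 1 — one interpretable number per TF in
[0, 1]. The signed importance score multiplies this by the model R² and by
the sign of the TF's net effect (+1 activation, −1 repression), where the
net effect weights each term's coefficient by its average basis slope (the
signed fraction of observations on a hinge's active side).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| promoter window | (500, 500) bp | inclusive window around the TSS; 1001 bases |
| `minSnr` | 2 | peaks kept when signal/local noise strictly exceeds this |
| `endspan` | 100 obs | boundary-knot suppression in the forward pass |
| `penalty` | 2 | GCV cost per knot |
| `maxTerms` | min(21, n/10) | forward-pass cap |
| `folds` × `repeats` | 10 × 5 | cross-validation plan |
| `retainFrac` | 0.5 | strict retention threshold for TFs and hinges |
| min count | 1 read | detection filter in every sample |
| cluster k | BIC over 2..30 | spherical-Gaussian BIC, best-of-restarts k-means |

## Coordinates, windows and numerical choices

* Coordinates are 1-based and inclusive throughout (the WIG convention), so
  the ±500 promoter window spans 1001 bases.
* Promoter windows are strand-mirrored by default ("upstream" is
  biologically 5′ of a minus-strand gene); `mirror = FALSE` reproduces
  strand-agnostic processing. Published pipelines do not always state
  which convention they used, so both are supported.
* The naive peak caller is a stand-in for an event-calling algorithm
  (event callers proper are out of scope): local maxima of lightly
  smoothed coverage, local noise = median raw coverage in a 2 kb flanking
  window, snr = signal/noise, strict threshold. Its `minSignal` floor
  exists because a Poisson background has median 0, which would otherwise
  make every single-read maximum an infinite-SNR peak; the floor is off by
  default and set explicitly by the pipeline.
* Library size for FPKM is the plain column sum of retained counts (no
  TMM); the count filter is applied before the library size is computed.
* OLS uses QR decomposition, falling back to the minimum-norm SVD solution
  (with a warning) on rank-deficient designs. Forward-pass additions skip
  exactly collinear columns, so pruning always operates on a full-rank
  basis.
* Pearson significance uses the product-moment t transform
  t = r√((n−2)/(1−r²)).
* BIC for choosing k is the full spherical equal-variance Gaussian-mixture
  criterion (−2 lnL + p·log n with the multinomial assignment term
  Σ nᵢ log(nᵢ/n) and p = (k−1) + k·d + 1). The simpler textbook form
  n·d·log(WCSS/(n·d)) + k·d·log(n) is available as `formula = "simple"`,
  but its per-cluster penalty (d·log n) is an order of magnitude below the
  likelihood gain of spuriously splitting a Gaussian cluster, so on
  mixture data it drifts to the top of the k range; the assignment term is
  what makes the criterion consistent — for a single spherical blob the
  split gain and the entropy penalty cancel exactly and the parameter
  count drives k to the bottom of the range.
* Interaction scans test the raw (uncentered) product of binding signals,
  matching the "multiplication of TF signals" reading; a centering flag
  exists for diagnostics. The improvement ratio
  (ΔR² + R²_add)/R²_add is scale-invariant.
* The trio detector partitions genes by 2-means on jointly standardized
  (3 binding + 1 expression) profiles; the published analyses this
  reconstructs show two groups but do not name a grouping procedure.
* Enrichment uses the clustered genes as the background universe and
  adjusts BH across the full cluster × set grid (stricter than per-cluster
  adjustment).

## The synthetic-data generator: what it emulates, what it does not

The generator exists so every stage has an input with known ground truth.
Its stated world:

* **Binding marginals** are log-normal (meanlog 2, sdlog 1) — promoter
  read-count sums are heavy-tailed and non-negative. The real empirical
  distribution of promoter sums is not published; log-normal is an
  assumption and both parameters are configurable.
* **Collinear TF pairs** are induced by a Gaussian copula on the log
  scale. The target ρ is the Pearson correlation *of the binding values*,
  so the latent normal correlation is calibrated analytically
  (ρ_latent = log(1 + ρ(e^{σ²} − 1))/σ²); without this calibration a
  latent 0.9 would surface as an observed ≈0.85. Correlations outside the
  attainable range for log-normal margins are rejected.
* **Effects** on expression are linear, hinge, or saturating per TF, plus
  an optional multiplicative pair, with additive Gaussian noise on the
  FPKM scale — the simplest model consistent with fitting FPKM by OLS.
* **Counts** invert the FPKM formula at a fixed library size of 10⁷ with
  gene lengths uniform in [500, 5000] bp. The response is rescaled once
  per condition so the pseudo-counts of detected genes sum exactly to the
  library size; this makes the counts → filter → FPKM path recover the
  generator's response to 1e-9 (a pure rescaling: R², correlations and
  knots are unaffected). RNA replicates are identical — all expression
  noise lives in the response.
* **Coverage tracks** are rectangular read pileups of known height/width
  at fixed per-gene offsets over per-base Poisson background, so
  noise-free promoter sums have closed-form values.

Not emulated, deliberately: exonuclease footprint shape, nucleosome
occupancy, motif content, fragment-length distributions, overdispersed
count noise. A green test on this generator therefore establishes that the
*statistical machinery* behaves as specified (recovers planted structure,
controls false structure), not that any particular biological claim holds
on real data.

Demo-scale defaults (200 genes, 8 TFs, 2 conditions, intercept 50, noise
SD 15 ≈ 20% of the response SD, background 0.2 reads/bp, 1200 bp gene
spacing) were chosen once as a desk-scale caricature of a ~850-gene
metabolic gene set and are not revisited by tests.

## Design choices where the design was open

* **Final refit in `cvSelect` is GCV-pruned.** With the retained structure
  refitted by plain OLS, structure that recurs across (90%-overlapping)
  folds but is not supported by whole-data GCV would persist; pruning the
  refit keeps the pure-noise behavior clean. This is the package's
  choice; the cross-validation scheme itself (10 × 5, strict 0.5
  retention, median knot) is likewise a reconstruction, with every knob
  exposed.
* **Hinges are penalized, linear terms are cheap.** GCV charges `penalty`
  per knot and nothing extra for a linear coefficient — the standard MARS
  accounting. Consequently spurious *hinge* structure is rare while a
  marginal *linear* term costs only one coefficient; the cross-validated
  retention threshold is what keeps marginal linear terms out of final
  models.
* **Substitution testing** removes one selected TF at a time (no
  combinatorial subsets) and asks whether a significantly correlated,
  previously unselected TF enters the refitted selection.
* **Peaks annotate to at most one gene** (nearest TSS within 500 bp,
  lexicographic tie-break) for determinism.
* **Representation comparison** uses the same selection machinery
  (linear-only MARS) for all non-spline representations, so comparisons
  differ only in the data.
* **Config files are JSON** — plain-text, round-trip exact, and a JSON
  parser is a package import anyway.

## Known limitations

* The promoter-sum representation cannot distinguish co-bound TFs from
  overlapping footprints; collinearity diagnostics flag, but cannot
  resolve, such pairs.
* GCV-based selection is calibrated for n in the hundreds; for very small
  gene groups (clusters under ~10 genes) fitting is refused rather than
  reported.
* The naive peak caller is adequate for rectangular synthetic pileups and
  for plumbing real tracks through the pipeline, but it is not an event
  caller; SNR thresholds near 2 on real data should be treated as
  qualitative.
* Importance signs summarize a monotone net effect; genuinely
  non-monotone fits (opposite-sign hinge arms) reduce to the dominant
  direction with a warning.

## A minimal session

```{r demo, eval = FALSE}
demo <- makeDemo(seed = 7, dir = "demo")
run <- runPipeline(demo$config)

# per-condition model and importance
model <- jsonlite::read_json(file.path("demo/results", "model_glucose.json"),
                             simplifyVector = TRUE)
model$selected_tfs
model$r2
```

The `scripts/acceptance.R` entry point regenerates the demo bundle from a
seed, runs this pipeline end to end, and writes a JSON summary; the
testthat suite holds the quantitative checks (oracle equivalences,
planted-structure recovery rates, determinism).
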