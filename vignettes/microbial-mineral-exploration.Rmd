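---
title: "Methods: microbial indicator species for mineral exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbial indicator species for mineral exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoindicate)
```

## The problem

Buried ore bodies — here, diamondiferous kimberlite pipes concealed under
meters to tens of meters of glacial till — leave only subtle traces at the
surface. Classical exploration geochemistry looks for pathfinder elements
(Cr, Ni, Nb, Mg for kimberlite) mechanically smeared down-ice from the
deposit by past glaciation, which vectors *toward* a source but rarely
outlines it. Soil microbial communities offer a complementary signal:
community members respond to the altered mineral substrate directly above
the deposit, so 16S rRNA amplicon profiles can carry a spatially *coincident*
fingerprint of buried mineralization.

`geoindicate` implements the analysis chain that turns OTU count tables into
exploration maps:

1. derive **indicator species** from a controlled amendment experiment
   (soils incubated with ground ore) and/or directly from a field survey;
2. **curate and transfer** laboratory indicators to a field site;
3. sum the indicators' mean-normalized relative abundances into a per-station
   **anomaly score**, classified into ordinal intervals for mapping;
4. benchmark against the equivalent **pathfinder-element** surface; and
5. challenge the whole pipeline with a **label-randomization null**.

## Indicator-species analysis

For a two-class design (control vs amended soils in the laboratory;
background vs above-kimberlite soils in the field) each OTU is screened with
a tie-corrected Kruskal–Wallis test on its within-sample relative abundances
(`kw_alpha`, default 0.05). Survivors are scored with a LEfSe-style
bootstrapped linear-discriminant effect size: abundances are scaled to parts
per million, and for each of `n_bootstrap` (default 30) resamples — two
thirds of each class, drawn with replacement — a one-dimensional linear
discriminant is fit and the log10 absolute difference of the projected class
means recorded, floored at `1e-30` to keep degenerate zero-difference
resamples finite. The mean across bootstraps is the LDA score; records with
score `> lda_threshold` (default 2, i.e. a consistent class difference of
roughly 100 ppm or more) are reported, labelled `enriched` or `depleted` by
which class holds the larger mean. For a single feature the discriminant
axis is the feature itself, so the score reduces to the log10 mean
difference on the ppm scale — the scale on which LEfSe scores are
conventionally interpreted.

Two-class only: the subclass (within-class Wilcoxon) stage of the original
LEfSe scheme is omitted because these designs have no subclasses. This is a
documented limitation, not a configuration option.

**Known property — false discoveries at the effect-size gate.** The LDA
threshold filters *small* effects, not *noisy* ones: any OTU abundant enough
that its chance between-class difference exceeds ~100 ppm (roughly, relative
abundance above ~5×10⁻⁴) will pass the score gate whenever it passes the
Kruskal–Wallis gate, and the rank test is exactly calibrated — 5% of null
features pass at `kw_alpha = 0.05`. With thousands of OTUs and tens of
samples the significant set therefore contains a non-trivial fraction of
abundant bystanders (our planted-recovery suite measures an FDR around
20–25% under ~22% replicate noise, at essentially 100% sensitivity for
factor-50 effects). This mirrors published critiques of LEfSe's error
control. Downstream stages are designed to tolerate it: curation requires a
positive field response ratio, and mean-normalization bounds any single
variable's influence on the summed surface.

## Curation, transfer, and anomaly surfaces

Enriched laboratory indicators are curated for field use by three rules:
mean raw count above `min_mean_count` (default 1 read/sample) in the
incubation, presence in the field table, and a positive field **response
ratio** — the percent excess of the on-deposit mean over the off-deposit
mean, `(mean(on)/mean(off) − 1) × 100`, a ratio of means (a mean of
per-sample ratios would require a pairing that does not exist). Field-derived
indicator sets are not curated further. Sets are combined as a union by OTU
id, enriched direction only, retaining per-source provenance; conflicting
directions resolve to enriched with a warning, since exploration targets are
positive anomalies.

Cross-site transfer matches OTUs by id, which presumes the tables were built
against a shared OTU definition (closed-reference or pooled clustering). The
synthetic generators guarantee this; real use must ensure it.

The anomaly surface divides each variable (an indicator's relative
abundance, or an element concentration in its native units) by its mean over
all survey samples and sums per sample. Divide-by-mean keeps zeros at zero
and preserves the non-negativity that makes the sum interpretable as
enrichment; z-scoring was rejected because negative contributions would let
depleted background cancel anomalies. After normalization every variable has
mean exactly 1, so the summed score has mean equal to the number of
variables — a conservation law the tests assert to 1e-12. Anomaly classes
are assigned from empirical quantiles of the summed score
(`quantile_breaks`, default 0.5/0.75/0.9/0.95/0.98): a deterministic,
documented stand-in for the analyst-picked inflection points of
probability-plot thresholding in exploration software. No attempt is made to
match any particular map's class boundaries. Surfaces export as GeoJSON
point features with CSV twins; coordinates are projected planar meters
(local grids), never latitude/longitude.

## Diversity and clustering

Filtering removes OTUs with fewer than `min_total_reads_per_otu` (default 2)
reads summed over all samples. Rarefaction subsamples each sample without
replacement to exactly `rarefaction_depth` reads (default 16365, the
subsample-to-lowest-coverage convention); shallower samples are dropped, not
scaled. Alpha diversity reports observed OTUs, Chao1 and inverse Simpson.
Chao1 defaults to the bias-corrected form
`S_obs + F1(F1−1)/(2(F2+1))` (the form mothur and vegan compute); the
classical `S_obs + F1²/(2F2)` is available by flag and falls back to the
bias-corrected expression when no doubletons exist. Diversity is computed on
rarefied counts while indicator analysis uses unrarefied relative
abundances: richness comparisons need equal depth, effect sizes should not
discard reads. Both choices are logged. Whether Chao1 is better computed
from filtered or rarefied data is genuinely ambiguous in practice; both
paths are supported and rarefied input is the default.

Community clustering uses Euclidean distances on relative abundances
(raw-count mode by flag; proportions remove depth artifacts) and UPGMA
(unweighted pair-group average linkage), giving an ultrametric tree whose
merge heights are average between-cluster distances. The cluster count `k`
for the composition summary is user-chosen, defaulting to the largest gap in
merge heights; published analyses pick `k` by eye and state no criterion.
Cluster summaries report the fraction of on-deposit vs background members
per cluster.

## The synthetic generators

The generators exist so that every downstream stage can be tested against
known ground truth without sequencing data. They emulate the statistical
structure the analysis relies on — not raw reads, chimeras, sequencing
error, or covariates like pH.

**Community model.** Expected abundances follow a deterministic lognormal
rank-abundance curve (`sdlog = 2` over 2000 OTUs: a few taxa at several
percent, a long tail, >3 orders of magnitude of range). The bottom 30% of
the curve sits below ~0.6 expected reads at the default 25000-read depth —
the "rare biosphere" below practical detection. Counts are gamma-Poisson
(negative binomial) with dispersion 0.05 (~22% CV for abundant taxa) for
replicate jars of homogenized soil; field simulations use 0.3, reflecting
spatial soil heterogeneity. These noise levels were fixed as part of the
model design, from what replicate amplicon data typically show.

**Amendment response.** Responders default to the 65 shallowest rare-tail
OTUs with enrichment factors log-spaced 200–3000; decliners to the 310 most
abundant taxa with factors 0.05–0.5. These synthetic conventions are
calibrated to the share arithmetic of strong amendment responses: a
collectively sub-percent set of near-detection taxa blooming to a dominant
community share while the formerly dominant bulk collapses to a few percent.
Because sequencing depth is fixed, the bloom starves the detection-marginal
tail of reads, which is what makes observed richness and Chao1 *decline*
under amendment — the directional property the diversity tests assert.
Effects interpolate linearly in log-factor from no effect at the first
timepoint to full effect at the last (default sampling days 0/15/55/85), the
simplest monotone ingrowth.

**Field surveys.** Stations form a regular grid (default 10×10 at 50 m)
with a compact deposit footprint near the center. The only microbial
treatment effect is the responder enrichment (`indicator_effect`, default
30) at on-deposit stations — field anomalies are a subtle species-level
signal on an otherwise homogeneous community. Geochemistry is a per-element
background (Cr 15 ppm, Ni 7 ppm, Nb 2 ppm, Mg 0.24 wt% — typical background
soils for this terrain) plus a plume: a double-exponential along the
ice-flow azimuth (default 290°, decay length 200 m) peaked 75 m *down-ice*
of each footprint station, with a 100 m Gaussian cross-axis width, times
lognormal noise (sdlog 0.4). The plume maximum therefore sits strictly
down-ice while the microbial signal sits on top of the deposit — the spatial
contrast between the two survey types that the end-to-end tests check.

**What passing tests do not show.** The generators draw independent counts
per station and per jar; real soils have spatial autocorrelation, surficial-
material covariates, compositional correlations among taxa, and OTU-calling
artifacts. Recovery rates measured here are therefore upper bounds on field
performance, and the pipeline's behavior under mis-matched OTU definitions
across sites is untested by construction.

## Randomization null

To ask whether "predictive" indicators could arise by chance, the training
site's on/off labels are permuted (group sizes preserved — only the labels
are randomized), the indicator analysis re-run, and the enriched set's
mean-normalized summed abundance transferred to the test site, where its
response ratio is computed; ten replicates by default. Genuine indicator
sets give large positive transfer ratios; permuted ones scatter around
zero. The scatter is not perfectly symmetric: chance indicator sets are
dominated by abundant bystander taxa, and wherever a real responder bloom
exists on-deposit it *dilutes* those bystanders there, tipping chance
transfers mildly negative. The calibration test therefore checks sign
balance at the 1% binomial level rather than asserting exact symmetry.

## Numerical and degenerate-input conventions

* All readers reject rather than coerce; errors name the offending
  row/column/cell. Counts are integers; proportions are always derived.
* Kruskal–Wallis on an all-tied feature is undefined; p = 1 by convention.
* The LDA bootstrap floors |Δ| at 1e-30 before log10; ties in UPGMA break
  deterministically (lowest index); rarefaction, both simulators, the LDA
  bootstrap and the randomization null are bit-reproducible under a fixed
  seed (replicate seeds derive affinely from the run seed, kept below 2³¹).
* Zero-mean variables are dropped from anomaly surfaces with a warning;
  zero-total samples are an error wherever proportions are needed.
* Every stage logs one structured record (stage, dimensions, parameters,
  seed) to the run log; the pipeline manifest checksums every output, so a
  rerun with the same config and seed can be verified bit-for-bit.

## Problem sizes used by the test suite

The statistical suites run at sizes chosen to finish in minutes while
keeping the assertions sharp: planted-recovery at 2000 OTUs and 10 samples
per arm over 10 seeds; type-I control at 800 OTUs; null-transfer calibration
at 800 OTUs on an 8×8 grid (10 seeds × 10 permutations); the end-to-end
transfer chain at the generator defaults over 10 seeds; Kruskal–Wallis
uniformity at 1000 features with 20 samples per class (where the rank
statistic is effectively continuous against the KS reference); UPGMA checked
against a brute-force O(n³) agglomerator at up to 8 samples, where
exhaustive comparison is cheap.
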