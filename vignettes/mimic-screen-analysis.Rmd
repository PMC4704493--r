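---
title: "Analyzing miRNA mimic toxicity screens with mimicscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing miRNA mimic toxicity screens with mimicscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicscreen)
```

## The problem

Gain-of-function miRNA mimic screens transfect a library of synthetic
miRNA duplexes, one per well, into each cell line of a panel and read
out viability (a luminescence endpoint) several days later. The
scientific questions downstream are: which mimics are selectively
toxic, and to which lines ("private" versus "public" vulnerabilities);
which mimics and lines share phenotype structure; which predicted
target genes actually mediate a mimic's toxicity; and whether the
corresponding endogenous miRNAs carry prognostic signal in patient
cohorts. `mimicscreen` implements this entire analysis chain against
plain delimited tables, plus seeded generators that emulate a
genome-scale screen so every stage can be exercised and validated
without external data.

## From raw luminescence to hits

**Row-median normalization.** Liquid-handling and edge artifacts are
row-structured on multi-well plates. Each well is divided by the median
of its plate row (`normalize_row_median()`), after which every row has
median exactly 1. This removes any per-row multiplicative gain — the
normalized values are invariant to rescaling a row by any positive
constant. Rows whose median is zero are refused rather than silently
producing infinities. An optional per-plate median centering
(`batch_center = TRUE`) is available for unbalanced layouts; for full
plates the row step already pins the plate median.

**Replicate aggregation.** Transfections are run in biological
triplicate. `aggregate_replicates()` averages wells within a replicate
(relevant only for multi-well reagents such as the negative control),
then reports the mean and the sample standard deviation (divisor
n−1) across replicate means, together with the count of contributing
replicates. A mimic present in a single replicate gets a mean but a
missing SD — missing values are flagged, never fabricated.

**z-scores.** Mean viabilities are standardized to
z = (x − mean)/SD within a scoping population
(`compute_zscores()`). The default scope is *per cell line over all
mimics screened in that line*, which is what makes a z of −2 mean the
same thing in a sensitive and a resistant line and hence makes hit
calls comparable across the panel; a per-plate scope is available
where plate-level standardization is preferred. Sample SD is used
throughout. Standardization is invariant to positive affine transforms
of a line's viability vector.

**Hit calling.** A (mimic, line) cell is a hit when z ≤ −2
(`call_hits()`). The boundary is inclusive — a z of exactly −2 counts —
and configurable. Hits are summarized by the number of responsive lines
per mimic (`responsiveness_summary()`): hits in only 1–2 lines are
"private", and the fraction of private hits is the screen's headline
selectivity statistic. Because mimic libraries assembled from
successive database releases contain redundant reagents,
`collapse_unique_mature()` also counts hits at the level of distinct
mature sequences.

**Variance decomposition.** `variance_profile()` computes three SD
distributions — per mimic across the panel (total phenotypic
variation), within seed family per line (mimics sharing a seed should
act alike), and within replicate (technical noise) — and fits a
Gaussian kernel density to each (Silverman bandwidth, 512-point grid
spanning the data ± 4 bandwidths; degenerate all-equal inputs take a
tiny bandwidth so the mass concentrates at the common value). In a
well-behaved screen the replicate and family distributions sit well
below the across-panel distribution.

## Affinity propagation clustering

Phenotype structure is delineated with affinity propagation (AP), which
selects exemplar data points by message passing on a pairwise
similarity matrix; the cluster count emerges from the data rather than
being pre-specified. `build_similarity()` supports negative Euclidean
distance (the default for z-score profiles) and Pearson correlation
used directly as the similarity. The diagonal "preference" defaults to
the median of the off-diagonal similarities, the standard data-driven
choice; quantile and explicit preferences are exposed because more
negative preferences yield fewer exemplars.

The updates iterated by `ap_cluster()` are, with s(i,k) the similarity
and all messages starting at zero:

* responsibility: r(i,k) ← s(i,k) − max_{k′≠k} { a(i,k′) + s(i,k′) }
* availability (i ≠ k): a(i,k) ← min{ 0, r(k,k) + Σ_{i′∉{i,k}} max(0, r(i′,k)) }
* self-availability: a(k,k) ← Σ_{i′≠k} max(0, r(i′,k))

damped as `new ← λ·old + (1−λ)·update` with λ = 0.9 by default
(stability over speed; `max_iter = 1000`, exemplar set stable for 50
consecutive iterations to converge). Exemplars are the points with
r(k,k) + a(k,k) > 0; after convergence a single clean assignment pass
maps every item to its most similar exemplar, exemplars to themselves,
with deterministic lowest-index tie-breaks.

Two numerical choices matter in practice:

* **Degeneracy breaking.** Exactly symmetric configurations (for
  example two identical points under the median preference) pin the
  exemplar evidence at exactly zero — an unstable equilibrium the
  damped dynamics never leave. `ap_cluster()` therefore perturbs the
  similarities by a tiny deterministic jitter (10⁻⁹ of the similarity
  range, from a fixed internal stream). This is the same device
  reference AP implementations use with random noise, made
  deterministic so identical inputs give bit-identical clusterings; it
  is invariant under translating all similarities.
* **Fully degenerate inputs.** If the messages reach a numerical fixed
  point with no positive exemplar evidence (all items identical), the
  configuration is treated as a single cluster exemplified by the
  lowest-index item. If `max_iter` is exhausted with no exemplar and no
  fixed point, a convergence error carrying the final message state is
  raised.

`hierarchical_ap()` re-clusters the exemplars — their original feature
vectors, not cluster means — and repeats until one cluster remains or
no further merging occurs; composed memberships at every level are
returned and can be exported to GraphML (`export_cluster_network()`)
for Cytoscape. On small instances the resulting partition coincides
with exhaustive search over exemplar subsets maximizing net similarity
(the objective AP approximately maximizes), which is how the
implementation is validated. When comparing a hierarchy against an
external partition of known size, we read off the level whose cluster
count is closest to that size — the hierarchical analogue of cutting a
dendrogram at matching granularity.

## Enrichment, context scores, and phenocopy

**Hypergeometric overlap.** `hypergeom_overlap()` computes the exact
upper-tail probability P(X ≥ k) of the observed intersection of two
sets within a declared universe — no normal approximation, one-sided in
the enrichment direction, validated against explicit combinatorial
enumeration. For target enrichment the universe is the *expressed*
genes; expression is a caller-supplied flag, since detection rules are
platform-specific. No multiple-testing correction is applied inside
these operations (a Benjamini–Hochberg utility, `bh_adjust()`, is
provided for callers running many tests).

**Context-score response.** `context_score_curve()` bins expressed
predicted targets by total context score (more negative = stronger
predicted repression) and estimates, per bin, the probability of at
least a 2-fold expression decrease (log2 ratio ≤ −1; both the fold
threshold and the bin edges, default 0/−0.1/−0.2/−0.3/−0.4/−∞, are
configurable). Empty bins are reported as undefined, not zero.

**Dual-pool phenocopy.** To nominate targets that mediate a mimic's
toxicity, `phenocopy_screen()` applies the two-stage filter: keep genes
whose depletion was active in the index line (relative viability
strictly below 0.5 in the genome-wide screen), then nominate those
whose siRNA toxicity profile across the panel correlates positively
with the mimic profile — Pearson r > 0 *and* r² > 0.35, with **both**
independent reagent pools. The sign requirement is explicit: a strongly
anti-correlated gene has a large r² but is not a phenocopy. Both
inequalities are strict. Genes with constant profiles have undefined
correlations and are excluded with a logged reason. The result is
invariant to cell-line ordering and to positive affine rescaling of any
profile, and equals the intersection of the two per-pool nomination
sets by construction.

## Survival validation

Expression–survival association is tested with the percentile
cutoff-scan procedure: split the cohort 2/3 training, 1/3 validation
(`split_cohort()`, seeded); in training, dichotomize at every integer
expression percentile from the 25th to the 75th ("high" = strictly
above the quantile value, quantiles by inclusive linear interpolation)
and keep the cutoffs whose log-rank p is below 0.05
(`cutoff_scan()`); then confirm each kept cutoff — as an *absolute*
expression value — on the held-out cohort (`validate_cutoff()`), which
also reports per-group Kaplan–Meier median survivals. When several
cutoffs validate, all are reported and the minimum-training-p one is
flagged primary.

Kaplan–Meier estimation and the log-rank statistic are standard, and
`km_curve()`/`logrank_test()` delegate to the survival package
(`survfit`/`survdiff`), wrapped to this package's conventions: events
precede censorings at tied times, median survival is the smallest time
with S(t) ≤ 0.5 (undefined if never reached), and with no censoring
the curve equals the empirical survival function exactly.

The training scan involves ~51 correlated tests and its selection rate
on null data is therefore well above the nominal 5%; this multiplicity
is deliberately *not* corrected — the held-out validation is the
control, and the package's tests measure both facts (inflated training
selection, nominal-rate validation) rather than hiding them.

## The synthetic screen generator

`simulate_screen()` generates raw plates under

```
lum = baseline × row effect × batch effect × (1 − planted effect) × phenotype × noise
```

with multiplicative lognormal terms throughout — luminescence readouts
are positive and their noise scales with signal, so a lognormal model
is the natural choice. The defaults emulate a genome-scale screen: 400
mimics × 16 lines in triplicate on 8 × 12 plates (11 library wells plus
one negative-control well per row; leftover wells on the last plate
hold extra controls so the grid stays rectangular), row effect sdlog
0.1, batch effect sdlog 0.1, and per-well replicate noise sdlog 0.02 —
about a 2% CV, the reproducibility a well-optimized luminescence
endpoint achieves.

The planted biology has three layers:

* **Hit architecture.** 108 of the 400 mimics are sensitive: 60
  responsive in exactly 1 line, 26 in 2, and 22 spread over 3–9 lines —
  i.e. ~27% of the library scores in at least one line, ~80% of those
  hits are private, and no mimic tops 9 lines. Planted effects reduce
  fractional viability by 0.4–0.7, a strong-hit regime.
* **Seed families.** Mimics are grouped into seed families (by
  default ~250 singletons, 45 pairs, 20 triples, with 14 pairs sharing
  an identical mature sequence to emulate library redundancy across
  database releases); family members share a latent phenotype with
  intra-family correlation ρ = 0.8, so the within-family SD
  distribution sits below the across-panel one.
* **Line clusters.** The 16 lines belong to 5 latent response clusters
  that shape both a shared phenotype component (sdlog 0.05 against an
  idiosyncratic 0.03) and where multi-line hits land (a hit's
  responsive lines are drawn inside a home cluster, spilling into a
  neighbor only when the requested count exceeds it). This is what
  makes line clustering recoverable from the z matrix.

Every generator is a pure function of (config, seed): repeat calls are
bit-identical and the session RNG is left untouched. Ground truth
(effect matrix, family map, line clusters, duplication map) is returned
alongside the data so every pipeline stage can be scored.

`simulate_survival_cohort()` draws exponential survival with the hazard
multiplied by the configured ratio above an expression percentile, plus
independent exponential censoring. `simulate_expression_response()`
assigns context scores to predicted targets and knocks genes down with
a score-dependent rate (default 41% at scores ≤ −0.2, 15% above, 5%
background).

`simulate_phenocopy_panel()` plants the requested correlation as the
*exact sample correlation*: the planted gene's pool profiles mix the
mimic profile with an orthogonalized noise vector (Gram–Schmidt), one
independent noise vector per pool. At the default 13-line panel the
sampling distribution of r around 0.8 is wide enough that a
stochastically planted correlation would fail the r² > 0.35 rule in a
non-trivial fraction of panels; planting the realized correlation makes
"the generator planted r = 0.8" literally true in every panel, which is
the property the recovery checks are about. Null genes are ordinary
independent noise, so the false-positive behavior of the rule is still
exercised stochastically.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: transfection-efficiency differences
between lines, edge-well evaporation gradients (effects are
row-structured only), assay saturation, mimics with partial effects
just at the hit boundary, correlated censoring or cohort batch
structure, and any sequence-level determination of targeting (families
are phenotype-correlated by construction, not through seed matching).

## Problem sizes and numerical conventions

The validation suite runs the default 400 × 16 × 3 screen once and
reuses it across checks; clustering oracles use exhaustive search on
instances of up to 8 items (255 exemplar subsets); hypergeometric
enumeration covers every configuration with universes up to 12;
survival calibration uses 2000 null cohorts (n = 200), cutoff-scan
recovery 200 cohorts (n = 300, hazard ratio 3 at the 60th percentile),
and phenocopy recovery 200 panels. These sizes put all the binomial
acceptance bands well inside their targets while keeping the whole
suite in the low minutes on one core.

Conventions collected in one place: sample SD (n−1) everywhere;
hit and copy-number boundaries inclusive (z = −2 is a hit, depth ratio
1.5 a gain, 0.5 a loss); quantiles by R's default inclusive linear
interpolation (type 7); "high" expression strictly above the cutoff;
events before censorings at ties; missing values written as `NA` and
read back as missing; all tie-breaks lowest-index or lexicographic;
`round(fraction × n)` genes kept by the variance filter; TSV (UTF-8,
"." decimal) as the default dialect with CSV via a flag.

## Limitations

* AP is O(n²) per iteration in memory and time; the implementation is
  dense and intended for panels and libraries up to a few thousand
  items, not for sparse or streaming use.
* The cutoff-scan reports what it measures: an uncorrected scan plus
  held-out confirmation. It is not a substitute for a pre-registered
  cutoff or a Cox model over the continuous covariate (Cox modeling is
  out of scope).
* `top_variant_filter()` ranks by variance on the scale it is given;
  log-transform first if that is the scale variability is meaningful
  on.
* Reading the field's binary formats (IDAT, BAM) and producing
  per-gene expression or depth ratios is upstream of this package; it
  consumes the resulting tables only.
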