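# mimicscreen

Analysis of genome-scale **miRNA mimic toxicity screens** across cancer
cell-line panels, for functional genomicists working from plate-level
viability readouts to biological interpretation.

A mimic screen transfects a library of synthetic miRNA duplexes — one
per well — into every cell line of a panel and measures viability by a
luminescence endpoint. `mimicscreen` covers the full analysis chain:

* **Screen processing** — per-row median normalization of raw
  luminescence (each well divided by its plate-row median), replicate
  aggregation (mean and sample SD over triplicates), standardization to
  z-scores per cell line, z = (x − x̄)/s, and hit calling at z ≤ −2,
  with responsiveness summaries (private hits = toxic in only 1–2
  lines) and seed-family variance decomposition.
* **Affinity propagation clustering** — implemented from the
  message-passing updates
  r(i,k) ← s(i,k) − max<sub>k′≠k</sub>{a(i,k′) + s(i,k′)},
  a(i,k) ← min{0, r(k,k) + Σ<sub>i′∉{i,k}</sub> max(0, r(i′,k))},
  a(k,k) ← Σ<sub>i′≠k</sub> max(0, r(i′,k)),
  with damping, a data-driven (median) preference, and hierarchical
  re-clustering of exemplars; GraphML export for Cytoscape.
* **Enrichment and target inference** — exact hypergeometric
  upper-tail overlap P(X ≥ k), context-score response curves
  (probability of ≥2-fold knockdown per score bin), and the dual-pool
  siRNA **phenocopy** filter (activity in the index line, then Pearson
  r > 0 with r² > 0.35 against the mimic's toxicity profile in *both*
  reagent pools).
* **Survival validation** — Kaplan–Meier curves and log-rank tests
  (via the survival package) inside a percentile **cutoff scan**:
  2/3–1/3 train/validation split, every integer percentile from the
  25th to the 75th tried in training, significant cutoffs confirmed on
  the held-out cohort.
* **Synthetic data** — seeded generators for the whole stack: a
  400-mimic × 16-line triplicate plate screen with row/batch effects,
  seed-family-correlated phenotypes and planted private/public
  sensitivities; survival cohorts with threshold-dependent hazards;
  phenocopy panels; context-score-dependent expression responses. All
  pure functions of (config, seed), returning ground truth for
  validation.

## Worked example

```r
library(mimicscreen)

sim    <- simulate_screen(screen_sim_config(), seed = 1)
plates <- lapply(sim$plates, normalize_row_median)
agg    <- aggregate_replicates(plates)
z      <- compute_zscores(agg$mean)
z
#> <zscore_matrix> 400 mimics x 16 cell lines
#>   z range: [-6.499, 2.286] | mean viability attached

hits <- call_hits(z, threshold = -2)
rs   <- responsiveness_summary(hits)
rs$n_hit_mimics                          # 108 mimics hit >= 1 line
collapse_unique_mature(hits, sim$annotations)  # 107 unique mature sequences
round(rs$fraction_private, 3)            # 0.796 toxic in only 1-2 lines
rs$max_lines                             # no mimic toxic in more than 9

h <- hierarchical_ap(t(unclass(z)))      # cluster the 16 lines
h
#> <cluster_hierarchy> 16 items | 3 level(s) | clusters: 5 -> 2 -> 1
adjusted_rand_index(h$membership[, 1], sim$truth$line_clusters)
#> [1] 1
```

The screen's 108 hits, ~80% of them private, and the recovery of all 5
planted cell-line response clusters are read straight off the z matrix.
Set overlaps use the exact hypergeometric tail:

```r
uni <- sprintf("g%02d", 1:10)
hypergeom_overlap(uni[1:5], c(uni[1:3], uni[6]), uni)
#> <overlap_result> overlap 3 (sets 5 & 4 of universe 10) | p = 0.2619
```

and a miRNA–survival association is validated by cutoff scan:

```r
csim <- simulate_survival_cohort(
  survival_sim_config(n_patients = 450, hazard_ratio = 3,
                      threshold_percentile = 60), seed = 7)
sp   <- split_cohort(csim$cohort, seed = 7)
scan <- cutoff_scan(sp$training)
scan
#> <cutoff_scan_result> 51 candidate(s) | 51 selected at alpha 0.05 | best at percentile 61
best <- scan$candidates[which.min(scan$candidates$p), ]
validate_cutoff(sp$validation, best$cutoff_value)[c("p", "median_low", "median_high")]
#> $p           6.74e-11
#> $median_low  17.1       # months, low-expression arm
#> $median_high 5.06       # months, high-expression (3x hazard) arm
```

The planted 60th-percentile effect is found at the 61st, and the
held-out cohort confirms it with the two arms' Kaplan–Meier medians
straddling the planted hazard ratio.

A file-based orchestration of the same stages (with run manifests) is
available through `run_stage()`/`run_pipeline()` and the thin CLI
wrapper in `inst/scripts/run-pipeline.R`; the methods vignette
(`vignettes/mimic-screen-analysis.Rmd`) documents the model,
parameters, numerical conventions, and what the synthetic generator
does and does not emulate.

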