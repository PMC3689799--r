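# incompatscan

Analysis pipeline for time-course expression data from fungal **heterokaryon
incompatibility** experiments. When hyphae of incompatible *het* genotypes
fuse, a programmed cell-death reaction is triggered; in a thermosensitive
self-incompatible (SI) strain the reaction can be switched on by a
temperature shift and followed over time against a wild-type control. This
package implements the downstream computational analysis of such an
experiment — and a synthetic-data generator with planted ground truth, so the
whole pipeline is testable without any external download.

**Who it is for:** anyone analyzing a two-condition expression time course
(SI vs control, several time points, replicated) who needs regulation calls,
profile clustering, category enrichment, and — the distinctive part —
statistics for the *genomic clustering* of coregulated genes.

## The statistics at its core

* **Signed fold change** — FC = R for ratio R > 1, FC = −1/R for R < 1,
  where R is the linear-scale ratio of mean intensities at time t vs T0
  within a strain.
* **Moderated t** — per-gene pooled variance s² (df d) shrunk toward a
  moment-matched prior (s0², d0): s̃² = (d0·s0² + d·s²)/(d0 + d), t
  referred to d0 + d df; Benjamini–Hochberg FDR per time point. A gene is
  UP/DOWN when |FC| ≥ 2 with adjusted P < 0.001 in the SI strain and never
  in the control; detection flags add ISP (expressed only during the
  reaction) and SILENCED calls.
* **Robust clusters** — intersection of UPGMA and 12-class k-means
  partitions of signed log2|FC| profiles under correlation distance
  1 − r; cells with ≥ 10 members are robust.
* **Enrichment** — two-tailed Fisher exact tests; enrichment factor
  (k/K)/(n/G) for a size-K category with k members in a size-n regulated
  set over G genes.
* **Run-length null model** — expected windows of n adjacent regulated
  genes c_n = f^n·g, corrected to maximal-run counts
  N_n = c_n − Σ_{m>n}(m−n+1)·N_m, validated by Monte-Carlo simulation and
  an exact enumeration oracle; plus chromosome-level Fisher enrichment and
  30-gene sliding-window density scans.

## Worked example

```r
library(incompatscan)

spec <- synthetic_spec(seed = 42)          # the stated world: 10,556 genes,
tr   <- generate_truth(spec)               # 7 chromosomes, planted islands,
ds   <- generate_expression(tr$gene_map, tr$truth, spec)   # 4 replicates

cfg <- analysis_config(rng_seed = 42, detection_floor = 5)
de  <- call_genes(ds, cfg)
summarize_kinetics(de, cfg)$status_counts
#>        UP      DOWN       ISP  SILENCED UNCHANGED
#>      2101      2425       116         3      5911
```

2101 UP plus 116 ISP genes ≈ the planted 21% up-regulated fraction; the 3
SILENCED genes are exactly the planted count. Runs of adjacent up-regulated
genes versus the random-placement null:

```r
sets <- regulated_sets(de)                  # ISP counts as up, SILENCED as down
rs   <- detect_runs(tr$gene_map, sets$up)
run_null_table(rs, sum(tr$gene_map$chromosome != "UNPLACED"), cfg)[1:6, ]
#>   n observed         c_n N_n_analytic N_n_simulated
#> 1 2      264 459.3250914  286.5070127        282.45
#> 2 3       42  96.5581417   60.2287688         60.85
#> 3 4       16  20.2982047   12.6611372         13.05
#> 4 5        2   4.2670365    2.6615918          2.40
#> 5 6        1   0.8970055    0.5595130          0.30
#> 6 7        2   0.1885662    0.1176194          0.05
```

Observed counts track the null for short runs, but two runs of exactly 7
appear where ~0.1 are expected — planted islands; further down the table the
planted islands of 10 and 8 show up as runs of 11 and 9, each extended by a
chance neighbor. The analytic N_n and the
20-set simulation agree, the model's own validation. The null's headline
number at the study's scale:

```r
100 * expected_fraction_in_runs(2231/10556, 10556, min_size = 4)
#> [1] 3.177669   # "3% expected in a random distribution"
```

Chromosome enrichment on this island-free-background world is flat, as it
should be (uniform placement):

```r
chromosome_enrichment(tr$gene_map, sets$up)[, c("chromosome", "enrichment", "p_value")]
#>   chromosome enrichment p_value
#> 1          I      0.997   0.955
#> 2         II      0.946   0.239
#> ...
```

`run_pipeline(ds, tr$gene_map, cfg, out_dir = "out")` runs every stage
(differential calls → clustering → enrichment → genomic distribution →
optional cross-species overlap) and writes the stage tables plus a JSON
summary; `incompat_scan()` exposes the same as a CLI
(`inst/cli/incompat-scan run --config cfg.json`).

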