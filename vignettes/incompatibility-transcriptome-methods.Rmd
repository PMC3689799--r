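---
title: "Methods: analyzing the transcriptional response to heterokaryon incompatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing the transcriptional response to heterokaryon incompatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incompatscan)
```

## The experimental system and the analysis problem

Heterokaryon incompatibility is a programmed cell-death reaction of
filamentous fungi, triggered when hyphae of genetically incompatible
(*het*-locus) individuals fuse. In a self-incompatible (SI) strain carrying
two incompatible alleles in one nucleus, the reaction is thermosensitive:
suppressed at 32°C, triggered by a shift to 26°C. This gives a controllable
induction experiment: expression is profiled in the SI strain and a
wild-type control before the shift (T0) and at 0.5, 1, 2, 3 and 4 h after,
with four biological replicates per point, on arrays probing ~10,500 genes.

This package implements the downstream analysis of such a time course:
differential-expression calls, robust profile clustering, annotation
enrichment, and — the distinctive part — statistics for the *genomic
distribution* of the regulated genes (runs of adjacent coregulated genes,
chromosome-level enrichment, sliding-window island detection), plus a
synthetic-data generator with planted ground truth so that every stage is
testable without the original arrays.

## Differential expression

For each strain separately, each post-shift time point is compared with that
strain's T0. Ratios are computed on the linear intensity scale (log2 values
are exponentiated before averaging replicates), then mapped to signed fold
changes: FC = R when R > 1 and FC = −1/R when R < 1, so down-regulation
reads as a negative factor. R = 1 maps to FC = 1 (the convention covers a
boundary the formula leaves open).

Significance uses a moderated two-sample t-statistic on the log2 scale. The
per-gene pooled variance s² (residual df d) is shrunk toward a global prior
(s0², d0):

  s̃² = (d0·s0² + d·s²)/(d0 + d),

with p-values from a t distribution on d0 + d degrees of freedom. The prior
is estimated across genes by moment matching under the standard hierarchical
model s² ~ s0²·F(d, d0): the squared coefficient of variation of the
observed s² satisfies CV² = 2(d + d0 − 2)/(d(d0 − 4)), which is solved for
d0; s0² = mean(s²)(d0 − 2)/d0. When the spread of the observed variances is
no wider than sampling alone allows, d0 is taken as infinite and the prior
collapses onto the mean variance. With d0 = 0 the statistic is exactly the
classical pooled t (a property the tests exploit); the suite also verifies
agreement with limma's empirical-Bayes t when limma's own prior is supplied.

P-values are adjusted by the Benjamini–Hochberg step-up rule *per time
point across genes* (the adjustment family is a design choice; the source
analysis does not state one). A gene is called UP or DOWN when |FC| ≥ 2 with
adjusted P < 0.001 at some time point in the SI strain **and** the control
strain never meets the same criterion (the control veto, operationalized as
the mirrored criterion since the original phrasing — "no differential
expression was detected in wild-type control" — names no thresholds). The
threshold is applied inclusively (|FC| ≥ 2), following the more inclusive of
the two phrasings in the source.

Two further statuses come from detection flags rather than fold changes. A
measurement is *detected* when its log2 intensity strictly exceeds a
detection floor (by default the 5th percentile of control-strain
intensities; the original detection rule is unstated, so this is an explicit
stand-in). **ISP** (incompatibility-specific): undetected in all SI T0
replicates, detected in at least half the SI replicates at some later time,
and not differential in the control. **SILENCED**: detected at SI T0 and
undetected in every SI replicate from some time point onward. ISP genes
count as up-regulated, SILENCED as down-regulated, in all downstream set
statistics.

## Profile clustering

Genes with max |FC| > 4 in the up-regulated set are clustered by time-course
*shape*: the feature vector is the signed log2 fold change at each of the
five post-shift times (log scale chosen because induction magnitudes span
two orders of magnitude), and the metric is correlation distance
1 − r. Two independent partitions are computed — UPGMA (average-linkage)
hierarchical clustering, and k-means with 12 classes on row-standardized
profiles (on standardized rows, squared Euclidean distance is monotone in
correlation distance; the centroid update is the standardized mean, a
medoid-like minimizer of summed correlation distance). The hierarchical tree
is cut at the class count (2–15) maximizing mean silhouette width, since the
original cut rule is unstated and its headline cluster count was a data
outcome, not a parameter. The *robust clusters* are the cells of the
intersection of the two partitions with at least 10 members (the smallest
published cluster had 12–13); everything else is reported unclassified.
k-means uses 50 seeded restarts; empty classes are allowed to stay empty
during Lloyd iterations, which is what lets a noise-free 8-archetype input
be recovered exactly even with k = 12.

## Enrichment statistics

All enrichment P-values are two-tailed Fisher exact tests, computed by
minimum-likelihood summation of the hypergeometric distribution (the sum of
the probabilities of all tables no more probable than the observed one).
The enrichment factor for a category of size K with k members in a regulated
set of size n over a universe of G genes is (k/K)/(n/G) — symmetric in the
roles of category and set. The universe for annotation enrichment is all
probed genes; for chromosome-level enrichment it is placed genes only (the
convention that reproduces the published per-chromosome factors, whose
totals sum to 10,394 rather than 10,556). The secretome classifier labels
secreted proteins, small (< 250 aa, strict) extracellular proteins, and
cysteine-rich ones (> 3.5% or > 6% cysteine over the full annotated length —
whether the signal peptide is excluded is unstated in the source, so it is
included). Printed enrichment factors are matched at ±0.01 because at least
one published value (2.24 for 19/40 against 2231/10556, exactly 2.2475)
reflects truncation rather than rounding.

## The run-length null model

The central bespoke statistic asks whether regulated genes cluster in
chromosomal gene order more than chance allows. Observed *maximal runs* of
same-direction regulated genes are counted per chromosome (runs never span
chromosomes; unplaced genes are excluded). The null treats the genome as a
single concatenated sequence of g genes with regulated fraction f. The
expected number of *windows* of n consecutive regulated genes is

  c_n = f^n · g,

and expected counts of *maximal runs of exactly n* follow by removing runs
embedded in longer ones, descending from n = nmax (default 10, the largest
cluster modeled):

  N_nmax = c_nmax;  N_n = c_n − Σ_{m>n} (m − n + 1)·N_m,

because a run of m contains m − n + 1 windows of size n. The expected
fraction of regulated genes lying in runs of ≥ s is Σ_{n≥s} n·N_n/(f·g).
Two deliberate approximations are retained from the source procedure: the
null ignores chromosome junctions (at most 6 junction artifacts among
~10,400 genes), and c_n = f^n·g is a Bernoulli-style formula although the
regulated set is drawn without replacement. Both are covered by the
validation criterion the source itself used: a Monte-Carlo simulation (20
sets of m distinct positions drawn uniformly from 1..g, maximal runs of
consecutive integers counted and averaged) agrees with the analytic N_n
within ±10% for run sizes 2–4. An exhaustive-enumeration oracle
(`enumerate_exact_run_counts`, all C(g, m) placements for small g) anchors
the simulation in the tests, and for f ≤ ~0.2 the recursion agrees within 1%
with the stationary closed form N_n → g·f^n·(1 − f)².

Sliding-window density scans (default 30-gene windows, step 1 — the step is
unstated in the source) locate the islands chromosome by chromosome;
chromosome-level enrichment uses the Fisher machinery above with the
placed-gene universe.

## Cross-species overlap

Overlap between two species' regulated sets is computed over one-to-one
ortholog pairs only (genes without orthologs are excluded). Association is
tested by the two-tailed Fisher exact test on the 2×2 pair table — the
source reports significance without naming a test, so the hypergeometric
upper tail is reported alongside. `top_k_concordance` ranks one species'
genes by fold change, restricts to the pair universe, and reports the
fraction of the top k whose ortholog is regulated in the other species.

## The synthetic world

`synthetic_spec()` defaults state the emulated world: g = 10,556 genes;
placed chromosome sizes (2557, 1569, 1208, 1119, 1447, 1277, 1217) with the
162-gene remainder unplaced; regulated fractions f_up = 0.21, f_down = 0.23;
four planted up-regulated islands of lengths 10, 8, 7, 7; eight archetype
induction shapes with log2 amplitudes uniform on [1.5, 5.5] (all planted
effects clear the |FC| ≥ 2 threshold, with a tail of strong inductions, as
observed); replicate noise sd 0.25 on the log2 scale with 4 replicates;
116 isp and 3 silenced genes; baseline intensities Normal(10, 1.5) over a
detection floor of 5.

Design choices worth knowing:

* **Archetype shapes** are the generator's own parameterization of the eight
  qualitative families (early transient, early sustained, lagged plateau,
  late rise, two peaked-then-return, two peaked-then-decline). They were
  designed so no pair exceeds Pearson r = 0.88: with five time points,
  shapes of the form (x, 1, 1, 1, 1) are collinear after standardization and
  a perfectly flat profile has no defined correlation, so a
  correlation-metric clustering could never separate them — identifiability
  is a property of the stated world, fixed a priori.
* **Silenced genes are exactly the planted count**: baselines of
  down-regulated non-silenced genes are clamped high enough that the bottom
  of their trajectory stays above the detection floor. Without this, strong
  repressions on low baselines would cross the floor and masquerade as
  silencing.
* **Categories** are planted by stratified allocation (membership
  probability rr-fold higher for up-regulated genes), which hits the target
  relative risk by construction; sequential weighted sampling without
  replacement attenuates it.
* **isp genes** sit 2 log2 units below the floor at SI T0 and in the
  control, and ramp from the floor toward their baseline along their
  archetype, so their peak is always detected.

What the generator does *not* emulate: spot-level artifacts, dye bias,
probe cross-hybridization, correlated noise between replicates, and any
relationship between annotation categories and genomic position. A green
end-to-end test therefore establishes that the statistics recover planted
structure under idealized two-color noise — not that they would be robust
to array-specific systematics, which the upstream normalization is assumed
to have removed.

## Numerical conventions and edge cases

* FC at R = 1 exactly is 1; ratios must be positive (a domain error
  otherwise).
* Fisher two-sided summation uses a (1 + 1e-7) slack on the
  minimum-likelihood comparison, the standard guard against ties lost to
  floating-point noise.
* Step-up FDR adjustment is order-equivariant and idempotent on plateau
  sequences, but *not* idempotent in general — re-adjusting an adjusted
  vector can only inflate non-plateau values; the tests assert the property
  where it actually holds.
* Correlation distances are clipped at 0 from below after matrix
  computation to absorb floating-point negatives; zero-variance profiles
  raise a typed degenerate-profile error rather than producing NaN.
* All randomness flows from one seed; stage seeds are derived by a fixed
  affine map kept inside 32-bit range. Re-running any stage with the same
  config and inputs reproduces outputs byte-for-byte.

## Known limitations

* The published gene lists and the exact eight cluster memberships are not
  reproducible without the original deposited arrays; tests validate the
  machinery on printed counts and planted truth instead.
* The moderated-t flavor approximates the cited (undocumented) analysis
  software; the per-time adjustment family and the detection rule are
  explicit stand-ins for unstated choices.
* The run-length null model inherits the source's concatenated-genome and
  with-replacement approximations; both are validated only within the ±10%
  envelope at the study's scale.
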