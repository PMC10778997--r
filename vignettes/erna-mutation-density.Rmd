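---
title: "Methods: mutation density and strand asymmetry around eRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation density and strand asymmetry around eRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ernadens)
```

This vignette records the statistical model, the conventions, and the
numerical design decisions behind `ernadens`. It is the reference for *why*
the code does what it does; the function documentation covers *what* each
call does.

## 1. Model and quantities

### Substitution categories and forms

Every single-base substitution is collapsed onto one of six
pyrimidine-reference **categories** — C>A, C>G, C>T, T>A, T>C, T>G — by
reverse-complementing purine-reference records (G>T becomes C>A, and so
on). Each category retains two strand-resolved **forms**: the
pyrimidine-reference form as observed, and the purine-reference form
(`classify_sbs()`, `sbs_forms()`). Categories are the unit of burden and
density analysis; the pair of forms is the unit of strand-bias analysis.
Records with non-ACGT alleles or `ref == alt` are rejected at
classification time; the reader (`read_mutations()`) drops non-SBS records
up front and reports the tally. Duplicate records (same donor, position,
alleles) are **kept**: the catalog is taken at face value, and
deduplication is the caller's decision, not the package's.

### The MPKM burden

For one donor, one category, and one merged region of $M$ megabases,

$$\mathrm{MPKM} = \frac{C}{M \cdot f \cdot K}$$

with $C$ the in-region count, $K$ the donor's genome-wide category count in
kilos, and $f$ the composition factor: $0.2$ for C-rooted categories, $0.3$
for T-rooted ones. These defaults reflect the approximate genome-wide base
composition (each of C/G at roughly 20%, A/T at roughly 30%);
`composition_factors()` can recompute them from an actual reference
sequence when one is available. The **combined** all-category row uses
$f = 0.25$ — the value that makes the combined MPKM a plain per-mutable-base
rate when the category mix is balanced, and the midpoint of the two
category-level factors.

`region_size()` measures $M$ on the *merged* (union) intervals, so
overlapping input intervals are not double-counted; consistently,
`count_region_mutations()` counts **membership** (a mutation inside two
overlapping intervals counts once), not multiplicity.

### Coordinates

Mutation positions are 1-based (ICGC convention); intervals are 0-based
half-open (BED convention). The two meet at exactly one conversion point,
`as_granges()`, so off-by-one reasoning lives in one place. Chromosome
names are normalized (leading `chr` stripped, case folded, `M` → `MT`).
Anchors on an interval $[s, e)$ are `start` $= s$, `end` $= e - 1$ (the
last base inside), and `midpoint` $= \lfloor (s + e - 1)/2 \rfloor$ — the
floor keeps the midpoint on an actual base and makes it exact for
odd-length intervals.

## 2. Density profiling

`bin_counts()` tallies mutations into a fixed grid around each focal
point: the default grid spans $\pm 2000$ bp in 100 bp bins (40 bins;
`bin_grid(6000, 100)` gives the extended 120-bin view). The offset of a
mutation at 1-based position $p$ from a focal point at $q$ is
$d = (p - 1) - q$; the window is half-open, $d \in [-\mathrm{flank},
+\mathrm{flank})$, and the bin index is $\lfloor (d + \mathrm{flank}) /
\mathrm{width} \rfloor$. Counting is **per occurrence**: a mutation within
the flank of two focal points contributes to both profiles. This is the
natural convention for an average profile over loci ("what does the
neighborhood of a locus look like"), and it is what makes the conservation
property used in the tests hold exactly: the total binned count equals the
number of (mutation, focal point) co-occurring pairs.

Bin counts are normalized to MPKM against the cohort's genome-wide total:
for a bin with count $c$ over $n$ focal points,

$$\mathrm{MPKM}_{\mathrm{bin}} = \frac{c}{(n \cdot w / 10^6) \cdot f \cdot
(T / 1000)}$$

with $w$ the bin width and $T$ the cohort-wide mutation total
(`normalize_mpkm()`).

## 3. Inference

### Poisson peak/dip detection

The local background rate for a category is estimated from an annulus
$|d| \in [5000, 50000)$ bp around the focal points: with $n_{bg}$
mutations in the annulus, $\lambda_{bg} = n_{bg} \cdot w / (2 \cdot
45000)$ per bin per focal-point side, scaled by the number of points. The
inner radius keeps the estimate clear of the signal region itself; the
outer radius keeps it local enough to track regional rate variation. An
empty annulus falls back to a pseudo-count of $0.5$ and is flagged.

`detect_peak_dip()` evaluates only the two extreme bins: the maximum-count
bin against the upper tail ($P(X \ge x_{max})$, computed as
`ppois(x - 1, lambda, lower.tail = FALSE)`) and the minimum-count bin
against the lower tail ($P(X \le x_{min})$ via `ppois`). Ties between
equally extreme bins break toward the focal point. The nominal threshold
is $\alpha = 10^{-5}$, chosen for a scan that examines extreme order
statistics rather than a prespecified bin — the tests in this package
calibrate the resulting procedure's actual error rate on simulated null
cohorts rather than relying on the nominal level being exact.

### Strand-bias testing

For each category and each region — left flank ($d < 0$), right flank
($d \ge 0$), whole window — `strand_bias_test()` runs a two-sided
**paired Wilcoxon signed-rank test** of per-bin MPKM, pyrimidine form
versus purine form. Zero differences are dropped (standard signed-rank
convention); with no informative bins the test is vacuous and reports
$p = 1$. With $n \le 25$ informative bins the exact distribution is
requested; above that, the normal approximation with continuity
correction. One behavior inherited from `stats::wilcox.test()` is
documented rather than overridden: when tied *magnitudes* are present, the
exact path is unavailable and the implementation silently falls back to
the normal approximation even for small $n$. Binned counts produce ties
readily (differences are proportional to integer count differences), so
small-sample $p$-values on real profiles are often approximate; this is
the field-standard behavior and is left intact.

`strand_bias_scan()` runs all $6 \times 3 = 18$ tests and applies
Benjamini–Hochberg adjustment **pooled across the full set of 18**, not
per region: the scan is one family of hypotheses, and pooling gives a
single coherent FDR statement over it.

### Interval-set comparison

`pairwise_overlap()` reports the **asymmetric** overlap proportion: entry
$(i, j)$ is the fraction of set $i$'s merged bases that fall inside set
$j$, which is generally different from $(j, i)$ — both directions are
informative when the sets differ in total size, so both are reported,
along with the means over ordered and unordered pairs as attributes.
Empty sets yield `NA` rows rather than a silent 0.

## 4. The cohort simulator

`synth_config()` + `simulate_cohort()` generate a cohort with known,
controllable structure; every random quantity derives from the single
`seed` field (sub-generators offset it deterministically, so the
reference, intervals, and mutations are individually reproducible).

The generative model, in order:

1. **Reference** (optional): i.i.d. bases at a specified `gc_fraction`
   (default 0.4) per chromosome (default one chromosome of 3 Mb).
2. **Intervals**: `n_ernas` (default 40) non-overlapping intervals with
   lengths uniform on `erna_length` (default 500–1999 bp, inside the
   under-2 kb eRNA proxy), placed uniformly at least `margin` (default
   50 kb) from chromosome ends so background annuli never truncate.
3. **Donor totals**: log-normal with median `donor_total_median` (default
   3000) and log-scale sigma 0.4 — heavy-tailed donor loads, as observed
   in real cohorts.
4. **Positions**: a two-component mixture. The background component is
   uniform over the chromosome (rejection-sampled out of affected zones);
   the effect component places mass under **triangular kernels** —
   compact-support, linearly decaying — centered on interval midpoints
   (a multiplicative depletion of depth `dip_depth` and half-width
   `dip_halfwidth`) and boundaries (a multiplicative excess of height
   `peak_height`, half-width `peak_halfwidth`). Triangular kernels were
   chosen over Gaussians for exact compact support: outside the stated
   half-width the intensity is *exactly* flat, which makes background-rate
   oracles exact in tests.
5. **Categories**: i.i.d. from `category_weights`; the default weights
   are the reference donor's genome-wide spectrum, normalized —
   (0.195, 0.172, 0.258, 0.133, 0.169, 0.073).
6. **Forms**: each mutation is assigned the pyrimidine form with
   probability 0.5, except within `strand_window` (default 2000 bp) of an
   interval midpoint, where the probability is $0.5 + \beta/2$ downstream
   (offset $\ge 0$) and $0.5 - \beta/2$ upstream, with
   $\beta$ = `strand_beta`. The asymmetry is confined to a window around
   the midpoint rather than switching exactly at interval boundaries: the
   analysis reads strand bias in midpoint-anchored flank windows, so the
   generator injects the effect in the same geometry the detector
   measures — a deliberate simplification over modeling
   transcription-tract boundaries.
7. `harmonize_reference()` optionally patches the reference so every
   mutation's reference allele matches the sequence.

`generate_null_batch()` derives per-replicate seeds from the master config
and returns *configs* (with all effect parameters zeroed), not
materialized cohorts, so multi-hundred-replicate null studies stay
memory-flat.

### Generator scope

The simulator is a calibration instrument, not a genome model: no
trinucleotide context, no replication timing or expression covariates, no
indels or multi-allelic sites, no clustered hypermutation, independence
across mutations. It is sufficient to verify that the detectors find what
was injected and stay quiet when nothing was — which is all the package's
tests ask of it.

## 5. Problem sizes used in the simulation studies

The test suite calibrates error rates at three fixed study conditions,
chosen once from power analysis before the studies were run:

* **Null / type I error**: the `synth_config()` defaults (1 chromosome of
  3 Mb, 40 intervals, 25 donors, median load 3000), 500 replicates; the
  pooled strand-bias rejection rate at $p < 0.05$ must lie in a binomial
  band around the nominal level.
* **Strand-bias power**: 8 Mb, 150 intervals, median load 9000,
  $\beta = 0.3$ (a 65/35 form split), 200 replicates; the downstream C>T
  test must reject (after FDR) in at least 90%. The load was sized so the
  downstream flank holds enough mutations for the test to be informative.
* **Dip recovery**: 3.5 Mb, 60 intervals, median load 5000, 50% depletion
  over the central 400 bp, 200 replicates; the dip must be called within
  200 bp of the midpoint in at least 95%, with at most 1% spurious calls
  on matched null cohorts.

## 6. What the tests do and do not establish

The suite verifies the arithmetic (closed-form oracles, full sign-
enumeration of the signed-rank distribution, brute-force interval
counting), the conventions (coordinate round-trips, conservation,
invariances), the published worked example, and the error calibration of
the inferential machinery on synthetic cohorts. It does **not** compute or
assert any empirical biological result: no claim about real eRNA loci,
real cohorts, or real mutational processes is tested, because no real
data ships with the package. The single empirical anchor is the reference
donor's published tally table, used as a fixed worked example of the
burden formula.
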