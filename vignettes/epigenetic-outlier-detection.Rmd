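---
title: "Detecting epigenetic outliers in disease-discordant monozygotic twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epigenetic outliers in disease-discordant monozygotic twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epioutliers)
```

## The design and the statistic

Monozygotic (MZ) co-twins share their DNA sequence, so any methylation
difference between them is epigenetic (or technical) in origin. In a
disease-discordant pair — one affected, one healthy co-twin — a CpG site at
which the affected co-twin carries an extreme hyper- or hypo-methylation
value, while every other individual in the cohort sits in a narrow band, is
an *epigenetic outlier*: a candidate stochastic epimutation associated with
the disease rather than with genotype.

A single extreme value in a small group inflates the group's **variance**
much more than its mean. The scan statistic is therefore the per-probe
variance ratio between the affected and healthy co-twins of the discordant
pairs,

$$F \;=\; \frac{S^2_{\mathrm{affected}}}{S^2_{\mathrm{healthy}}},$$

with unbiased sample variances, referred to the upper tail of the
$F_{n-1,\,m-1}$ distribution ($n$, $m$ the group sizes; $6$ and $6$ in the
reference design). The test is **one-tailed with the affected group fixed
in the numerator**: probes that are more variable among healthy
individuals exist and are biologically expected, but they are not evidence
for disease-linked epimutation, so they must never reach significance.
Exchanging the groups maps $F \mapsto 1/F$ and $p \mapsto 1-p$; this
antisymmetry is property-tested.

The groups are treated as independent samples, exactly as `var.test()`
would treat them; the twin pairing is *not* modelled inside the statistic.
Each group contains one member of every pair, so a shared within-pair
deviation enters both sample variances with the same realized values. This
makes the scan slightly conservative in the presence of strong pair
effects (the two variance estimates are positively correlated), which is
the tolerable direction of error for a discovery screen. The suite's null
calibration is therefore run under independent measurement noise (no pair
effects, intermediate methylation means), where $p$-values are exactly
uniform and the 5% level must be hit inside its binomial band; with pair
effects or boundary clipping present, the realized type-I rate can only
fall below the nominal one.

Probes are tested on the beta scale (methylation fractions,
$\beta = M/(M+U+\alpha)$), not on logit-transformed M-values: the ranges
and means a practitioner compares against published candidate tables are
beta-scale quantities, and the outlier signal of interest is a large
absolute displacement, not a fold change.

### Multiple testing: Storey q-values

Genome-scale scans are corrected with q-values. The null proportion
$\pi_0$ is estimated on the grid $\lambda = 0.05, 0.10, \ldots, 0.95$ as
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$, smoothed with a
cubic smoothing spline (3 degrees of freedom) and read off at
$\lambda = 0.95$, truncated into $(0, 1]$. q-values then follow the
step-up rule $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With
$\pi_0 = 1$ this reduces *exactly* to Benjamini–Hochberg, an identity the
suite checks against a brute-force step-up on a thousand random vectors.
Vectors shorter than the $\lambda$ grid (fewer than 20 p-values) cannot
support the smoother; $\pi_0$ then falls back to 1 with a warning, i.e.
plain BH.

### The range-difference filter

Array methylation differences under roughly 10 percentage points (pp) sit
within the technology's error band and are unlikely to be functional. A
probe is only called an outlier when, besides $q \le 0.05$, the affected
group's beta range exceeds the healthy group's by **strictly more than
10 pp** (`range_threshold_pp`, configurable). The two funnel stages —
significant, then range-filtered — are reported separately, so the count
of "significant but sub-technical" probes is always visible. Applied to
the packaged 13-row published candidate table, the rule flags all 13 rows
at 10 pp and exactly 11 at 15 pp; the suite pins both counts.

### Attribution and validation

Each flagged probe is attributed to the affected co-twin with the largest
absolute deviation from the median of all discordant-pair samples (ties
break to the lexicographically first sample id and are flagged). The
deviation is reported in percentage points.

Candidates are then re-examined in the concordant and healthy pairs. Per
probe and validation pair, each co-twin gets a robust z-score against all
samples outside the pair (median and 1.4826·MAD); a co-twin is outlying at
$|z| > 3$. The pair pattern is

* **shared_outlier** — both co-twins outlying *and* within 5 pp of each
  other: the signature of a sequence variant or shared exposure, since a
  stochastic epimutation would not replicate in both co-twins at nearly
  identical levels;
* **discordant_outlier** — exactly one co-twin outlying: the same
  signature the scan detects, occurring in an unaffected pair;
* **normative** — otherwise.

A candidate is *validated* when no validation pair shows a
discordant_outlier pattern. Shared outliers are reported as SNV-suspect
annotations but do not invalidate — the presence of a genetically driven
hyper-methylated pair elsewhere in the cohort says nothing about the
affected co-twin's epimutation. The published analysis reached the same
verdict by visual inspection of per-pair profiles; the z-rule (defaults
$z = 3$, 5 pp) is this package's operationalization, and both thresholds
are exposed. When the reference MAD is zero (a degenerate, near-constant
probe) the classifier falls back to a range rule: outlying means beyond
the reference min/max by more than the shared-difference threshold.

The 5 pp shared-difference default reflects the observation that intrapair
methylation differences below about 5% are within technical measurement
noise.

## Cell-composition adjustment

Whole-blood methylation is a mixture over leukocyte types; a probe whose
methylation differs between cell types will vary between samples that
differ in composition, confounding any variance comparison. The package
implements the standard two-step reference-based correction:

1. **Deconvolution.** For each sample, the cell-type proportion vector
   minimizes the squared deviation between the sample's betas at the
   discriminating reference probes and the proportion-weighted reference
   profiles, subject to non-negativity and a sum $\le 1$ (the remainder
   absorbs unmodelled types such as granulocyte contamination; an
   equality constraint is available). The solver is Lawson–Hanson NNLS;
   when the unconstrained-sum optimum exceeds one, convexity places the
   constrained optimum on the sum-to-one face and the problem is re-solved
   with a heavily weighted sum-to-one penalty row followed by exact
   renormalization. Noiseless mixtures are recovered to $10^{-6}$,
   verified against an exhaustive simplex grid search.
2. **Average-cell adjustment.** Per probe, beta is regressed on the
   centred proportion columns (OLS; an optional ridge penalty
   $\lambda \ge 0$ on the composition coefficients is available, default
   $\lambda = 0$). The adjusted value is the fit at the cohort-mean
   composition plus the residual — the beta the probe would show in a
   sample of average cellular make-up. With $\lambda = 0$ this is a
   projection, hence idempotent; values pushed outside $[0,1]$ are
   clipped and counted. The published protocol describes this step only
   as "penalized regression" yielding an average-cell beta; the
   OLS-at-mean-composition-plus-residual estimator is this package's
   fully specified reading of that intent.

**A caveat that matters at cohort sizes like 34.** The per-probe fit has
hat-matrix leverage up to $\sim K/n$ and beyond for samples with unusual
compositions. A very large single-sample deviation (tens of pp) is then
partially absorbed into the composition fit and smeared across the other
samples, inflating the healthy-group variance and deflating $F$. On
simulated cohorts the adjusted scan is therefore *markedly* more
conservative than the unadjusted one — the direction the published
analysis also reports — and can under-detect spike outliers. The analysis
drivers run both scans, report both funnels, and carry the unadjusted
statistics forward to validation; `run_pipeline()` keeps adjustment on by
default whenever a reference is supplied. A small ridge $\lambda$ damps
the leverage if adjustment of spike-scale effects is required.

## The probe-filtering funnel

Filters run in the narrative order of the reference protocol, each
reported with its removal count so any order-dependence is inspectable:

1. **Detection quality**: a probe is dropped if its detection p-value
   exceeds $10^{-4}$ in *any* sample (the strictest reading; no
   sample-fraction rule is used).
2. **Autosomes**: probes on chromosomes X and Y are removed (mixed-sex
   cohort). Unannotated probes are dropped with a warning by default.
3. **Completeness**: probes with a missing value in any discordant-pair
   individual are removed — the scan's groups must be complete, while
   missingness confined to validation pairs is tolerated at this stage.
   (Adjustment and pair profiling additionally require completeness
   across all samples; the pipeline enforces it right before those
   steps.)

## The synthetic cohort generator

The generator exists so that every stage — including failure modes — is
exercisable without downloads, with ground truth. Its defaults *are* the
emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| pairs | 6 discordant, 4 concordant, 7 healthy | 34 samples |
| `n_probes` | 10,000 | desk-scale stand-in for a ~450K array |
| baseline mixture | centers 0.05 / 0.50 / 0.92, weights 0.3 / 0.4 / 0.3, logit sd 0.5 | hypo / intermediate / hyper probe means |
| `pair_effect_sd` | 0.03 (logit) | shared within-pair deviation |
| `noise_sd` | 0.005 (beta) | per-sample measurement noise |
| `n_outlier_probes` | 13 | injected single-co-twin outliers |
| `outlier_delta` | 0.3 (beta) | outlier magnitude, sign away from the nearer boundary |
| cell types | 6, Dirichlet with blood-like mean, concentration 30 | per-sample composition |
| `detection_fail_rate` | 0.001 | failing detection-p cells |

Pair effects act on the logit scale (so boundary probes stay inside
$[0,1]$ without truncation dominating) and are drawn once per
probe–pair and copied to both co-twins — the MZ identity. Measurement
noise acts on the beta scale. `pair_effect_sd = 0.03` was chosen so that
a group of six co-twins shows beta ranges around 1–2 pp at typical probes,
matching the healthy-group ranges of published candidate tables;
`outlier_delta = 0.3` sits inside the 14–40 pp affected-range band those
tables print. Outliers are assigned to one affected co-twin sampled per
probe, so each injected event lives in a single pair. All betas are
clipped to $[0,1]$ with a clip counter in the ground truth.

What the simulator does **not** emulate: Infinium probe-type chemistry
biases, batch and position effects, age/sex methylation structure, and
spatially correlated (region-level) methylation. Passing tests therefore
demonstrate the statistical machinery under the design's stochastic
structure, not robustness to every artifact of real array data.

The synthetic cell reference assigns each discriminating probe one
hypermethylated target type (offset 0.5 by default, cycled over types)
on a random baseline, guaranteeing pairwise column separation and full
rank — enough for identifiable deconvolution, with no claim to match any
published reference panel's values.

## Numerical and degenerate-input choices

* Zero healthy variance with positive affected variance yields
  $F = \infty$, $p = 0$; both variances zero yields a degenerate record
  with $p = 1$. Genome-scale scans never abort on constant probes;
  occurrences are counted in the funnel.
* Out-of-range values on *read* are errors (never clamped silently);
  out-of-range values produced by *adjustment* are clipped and counted.
* Missing tokens: empty cells and `NA` on read, written as `NA`. Matrices
  are written at 10 significant digits, far beyond assay resolution, so
  read–write–read round trips are exact at that precision.
* Coordinates are 1-based internally (as printed in hg19 candidate
  tables); BED export converts to 0-based half-open single-base
  intervals.
* Tie-break in outlier attribution: lowest-sorting sample id, flagged.
* The sum-to-one penalty weight in the constrained solver is $10^4$ times
  the reference norm, followed by exact renormalization onto the face.

## Problem sizes and what the suite asserts

The suite runs at desk scale: cohorts of 10,000 probes for calibration
and recovery (10 seeds each), smaller fixtures elsewhere; the full suite
completes in well under a minute. The headline property-style checks:

* identical groups give $p = 0.5$ at equal degrees of freedom; the
  one-tailed p matches numerical integration of the $F$ density to
  $10^{-8}$ over a grid including the design's $(5, 5)$;
* empirical $P(p \le 0.05)$ under the independent-noise null lies in the
  99% binomial band around 0.05, and $q \le 0.05$ yields zero discoveries
  in at least 9 of 10 seeds;
* q-values equal brute-force BH whenever $\pi_0 = 1$, and are monotone in
  $p$ always;
* noiseless 6-type mixtures are recovered to $10^{-6}$, cross-checked by
  grid search on 3-type subproblems;
* injected single-co-twin outliers (20 of 10,000 probes, delta 0.3,
  noise sd 0.01) are recovered with realized false-discovery proportion
  ≤ 0.1 per seed — the range filter removes essentially every null false
  positive, whose range differences stay far below 10 pp. Mean recovery
  across the fixed seed set is asserted at ≥ 18/20; note that the
  expected recovery under exactly these conditions is itself ≈ 18/20, so
  this assertion sits on the boundary of its own sampling distribution;
* a shared pair-level shift in a validation pair is classified
  shared_outlier and does not invalidate the candidate, while a
  single-co-twin extreme does.

## Known limitations

* The F-ratio ignores pairing (by construction, for fidelity to the
  reference protocol); a mixed-model variance test would gain power under
  strong pair effects.
* The robust z validation rule estimates scale from ~30 reference values;
  the finite-sample wobble of the MAD inflates the realized
  exceedance rate above the Gaussian $2\Phi(-3)$ ideal (the suite bounds
  it against a Monte-Carlo oracle of the rule itself).
* Boundary probes (means near 0 or 1) have truncated noise; the scan is
  conservative there, and simulated calibration is asserted away from the
  boundaries.
* Adjustment leverage can absorb spike outliers at small $n$ (discussed
  above).
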