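---
title: "Methods and design of progsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of progsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

`progsig` analyzes tumor expression cohorts around a single marker gene:
stratification, differential expression, per-gene survival cutoff scans,
continuous-phenotype gene-set enrichment, and a semantic map of enriched
ontology terms. This vignette records the statistical models the package
implements, the parameters that matter, the numerical conventions, and
the design choices that were genuinely open — so that results are
interpretable and exactly reproducible.

## Marker stratification

Patients are sorted by marker expression (descending, ties broken by
sample id ascending) and the top `floor(q * n)` form the marker-high
group; **the low group is all remaining patients**, not a bottom
percentile. The floor rule makes group sizes deterministic (30% of an
n = 88 cohort is 26 high / 62 low). Excluding mid-range patients instead
would be a different design; the remainder convention is the simplest
two-way reading and is worth a sensitivity analysis on real data.

The adaptive mode evaluates q = q0, q0 + step, … (defaults 0.10 and
0.05) and stops at the first q whose DEG count reaches `m_min`. What
counts as a "considerable" number of DEGs is inherently a judgment call,
so it is an explicit parameter (default 50), never a hidden constant. If
no q reaches `m_min` by `q_max` (default 0.50) the search returns the q
with the largest count (smallest q on ties) and sets a not-converged
flag, preserving the full history either way.

## Differential expression

Per gene, an unpaired two-sided t test between high and low groups —
pooled-variance Student t by default (the classical spreadsheet-style
"multiple t tests"), Welch–Satterthwaite as an option — followed by
Benjamini–Hochberg adjustment across all tested genes (`bh_adjust()`
fronts `stats::p.adjust(method = "BH")`). The DEG rule is q < 10⁻⁴,
i.e. the literal reading of "FDR q-value < 0.01%". Genes with zero
variance in both groups are assigned p = 1 rather than dropped: this
keeps the BH family size m stable and is conservative. Which FDR
procedure and which variance assumption to use were open choices; both
are exposed options with these documented defaults.

## Kaplan-Meier cutoff scan

`km_estimate()` is the product-limit estimator over distinct death
times; censored-only times shrink the risk set without adding a step.
`logrank_test()` accumulates the hypergeometric mean and variance of
group-1 deaths at each distinct death time and refers
(O₁−E₁)²/V to a 1-df chi-squared distribution, two-sided, with no
continuity correction. The chi-squared reference is asymptotic: on
10-subject instances it tracks a 10⁴-relabeling permutation tail to
within a few hundredths, which is the precision the test suite asserts.
A comparison with no information (V = 0) returns p = 1 by convention.

`kaplan_scan()` enumerates candidate cutoffs at midpoints between
consecutive *distinct* sorted expression values — a cutoff never splits
tied samples — subject to at least `min_group` samples on each side
(default `max(8, ceil(0.1 n))`; the floor prevents spurious extreme
splits and is exposed as a parameter, since scan internals such as the
cutoff grid, group floor and test statistic are conventions this package
must fix). The smallest p over the k cutoffs actually evaluated is
Bonferroni-corrected as `min(1, k * p_min)` — multiplying by tests
performed, not by n − 1. Direction comes from the sign of observed
minus expected deaths in the high group at the best cutoff: an excess of
deaths means *unfavorable*. Constant genes, or genes with no admissible
cutoff, are non-evaluable rather than errors.

Internally the scan is vectorized: with samples ordered by expression,
successive high groups grow one sample at a time, so group-level at-risk
and death counts at every death time are column cumulative sums and the
whole scan reduces to a few matrix products. The test suite verifies
this path against explicit per-cutoff `logrank_test()` calls.

Bonferroni over positively correlated cutoff tests is conservative: on
null cohorts the per-gene family-wise error sits visibly below the
nominal 0.05 (the acceptance suite bounds it at 0.06 over 5 × 1000 null
genes).

## Continuous-phenotype GSEA

Genes are ranked by Pearson correlation with the marker's expression
vector; the marker's own row is excluded (its self-correlation of 1
would trivially dominate any set containing it), zero-variance genes get
r = 0, and ties are broken by gene symbol so ranked lists are identical
across platforms. The enrichment score is the signed maximal deviation
of the weighted running sum: hits add |r|^p / Σ_hits |r|^p (weight
exponent p = 1 by default; p = 0 recovers the classical unweighted KS
statistic), misses subtract 1/(N − N_hit). At an exact tie between the
maximal positive and negative deviation the positive one is reported.

The null is **phenotype permutation**: each of B (default 100) shuffles
permutes the phenotype across samples, re-ranks all genes and recomputes
every set's ES — appropriate for a continuous phenotype, where gene-set
permutation would break the inter-gene correlation structure. Nominal p
uses same-sign nulls with an add-one pseudocount, so the smallest
attainable p at B = 100 is 1/101 ≈ 0.0099; at B = 100 the FDR
granularity is correspondingly coarse, which is why B is a parameter. NES divides ES by
the mean magnitude of the set's same-sign null ES; the FDR q is the
usual two-sided-by-sign ratio of null-NES to observed-NES tail
fractions, clipped to [0, 1] and step-up monotonized so a more extreme
NES never has a larger q. A set is *enriched* when nominal p < 0.05 and
FDR q < 0.25.

## Resnik similarity and the semantic landscape

The phrase "Resnik score for depth of annotation" is ambiguous between
IC-based Resnik similarity and raw DAG depth; the package implements the
standard IC-based measure as the default and treats depth as out of
scope for the landscape. A term's information content is
−ln(count/total) in nats, where count is the descendant-closed number of
distinct annotated genes; the root has IC 0. Resnik similarity of two
terms is the maximal IC over common ancestors (a term is its own
ancestor), which on a tree is bounded by both terms' own IC.

Similarities become distances by d = 1 − sim/s_max with s_max the matrix
maximum: monotone, bounded in [0, 1] and scale-free — the exact
transform used by the original web tool is unpublished, so a documented
one is used instead. Embedding is classical (Torgerson) MDS via
`stats::cmdscale` — deterministic, with no initialization sensitivity,
unlike stress-majorization variants. Negative eigenvalues among the top
two axes are truncated to zero with a warning; a normalized stress
(√(Σ(D−D̂)²/ΣD²)) is reported; one- and two-point inputs embed trivially
at the origin and at ±d/2. MDS is unique only up to rotation and
reflection, so axes are oriented deterministically (the largest
coordinate on each axis is made positive; in a landscape, the largest
set gets non-negative x), making outputs comparable across runs.

The landscape attaches two channels per enriched set: its measured size,
and its *prognostic value* — the percentage of its measured genes whose
Kaplan-scan label is not "ns" (direction-agnostic), min-max normalized
across the scored sets of the cohort. Min-max is the simplest reading of
"normalized percentage" and the raw percent is always reported
alongside; when all sets tie, normalized scores are 0 with a warning.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, emulating a
microarray-like cohort:

* log2 expression: gene means Normal(7, 1.5²), residual SD σ = 1;
* a marker gene whose top `q_true` fraction of samples (default 0.30)
  is the true "high" subpopulation;
* DE genes (fraction `frac_de`, default 0.03 — on arrays, marker-linked
  DEG lists are typically a few percent of measured genes) shifted by
  ±`beta_de` (default 1.5 log2 units) in the high group, half up / half
  down by default;
* a standard-normal latent risk u per patient; prognostic genes load on
  it with ±γ (default 1.5, 20 genes, all unfavorable by default, since
  recovery benchmarks plant a single known direction);
* survival T ~ Exponential(λ₀ · exp(β_surv · u)) with λ₀ = 5·10⁻⁴/day
  (median ≈ 3.8 years) and censoring C ~ Uniform(0, 3650 days),
  giving roughly half the patients an observed event — realistic
  follow-up for a high-risk pediatric cohort. Default size n = 88
  mirrors an NB-sized cohort; 237 is the AML-sized alternative.

One latent factor drives survival, rather than independent per-gene
hazards, so per-sample hazards are never contradictory and the marginal
effect of any prognostic gene is the analytically known attenuation
corr(x, u) = γ/√(γ² + σ²) — giving closed-form targets for tests. The
marker can optionally load on the risk factor itself
(`marker_is_prognostic`), mirroring a marker that is both stratifier and
prognostic candidate, and prognostic genes can be drawn from the DE
block (`prognostic_from_de`) to emulate signatures whose DEGs carry
survival information.

Planted gene sets draw `purity × set_size` members from the
*up-regulated* DE genes by default: real pathways are coherently
regulated, and a set mixing strong positive and negative correlates
would have its running-sum excursions partially cancel — a property of
the ES statistic itself, not of the simulation. Random sets are uniform
draws from all genes. The synthetic ontology is a complete b-ary tree
with randomly annotated leaves.

What the generator does **not** emulate: probe-level noise, batch
effects, heavy-tailed intensity distributions, correlated co-expression
modules outside the planted blocks, non-proportional hazards and
informative censoring. Passing recovery tests therefore demonstrates
correctness of the statistics under a clean generative model, not
robustness to real-array artifacts.

## Determinism and numerical conventions

Every stochastic routine takes an explicit seed, and the pipeline
derives per-stage seeds from one global seed by a fixed counter scheme
(stage i uses `seed * 100 + i`), so stage-subset reruns reproduce the
full run's results. Reports serialize floats at 6 significant digits
with fixed row and column orders, making repeated runs byte-identical;
expression matrices serialize at 17 significant digits, which
round-trips doubles exactly. Duplicate probes collapse to the
highest-mean row per symbol — a deterministic, conventional choice, made
explicitly because multi-probe handling on the original array platforms
is rarely documented. Cross-cohort gene identity is by uppercased
symbol, the only identifier that survives crossing array platforms.

Test problem sizes are chosen to make each statistical property visible
at comfortable margins while keeping the whole suite fast: for example,
type-I control of the scan uses 5 cohorts of 1000 null genes at n = 100;
DEG recovery uses 20 cohorts of 2000 genes at n = 120; GSEA recovery
uses 20 cohorts with 5 planted and 5 random sets at B = 100; adaptive
stratification uses 50 cohorts at the default NB-like size.

## Known limitations

* The scan's Bonferroni correction is valid but conservative; exact
  corrections for maximally selected rank statistics are deliberately
  out of scope, matching the analysis pattern being implemented.
* GSEA FDR at B = 100 permutations is coarse; increase B for finer q
  resolution.
* The log-rank p-value is asymptotic and optimistic at very small group
  sizes; `min_group` guards the scan against that regime.
* No Cox regression, competing risks or time-dependent covariates; the
  survival interface is deliberately limited to the product-limit /
  log-rank toolkit the pipeline needs.
* The pipeline is orchestrated through `run_pipeline()` and the exported
  functions; there is no shell executable, as the intended users drive
  analyses from R.
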