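---
title: "Variable-threshold rare-variant burden testing with permutation adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-threshold rare-variant burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtburden)
```

## The problem

Single-gene sequencing screens of extreme phenotypes ask whether rare,
likely-deleterious coding variants are collectively more common in
cases than in controls. Individually each variant is too rare to test,
so the variants are *collapsed*: an individual either carries at least
one qualifying variant or does not (dominant model), and the carrier
counts form a 2×2 table tested exactly. The motivating design is a
screen of a candidate obesity gene — a scaffolding protein of the
Raf–MEK–ERK pathway whose C-terminal kinase domain harbours most of
the functionally damaging missense changes — in about two thousand
severely obese cases and fifteen hundred population controls, with a
replication arm and a combined analysis.

## Qualification

A variant qualifies when three filters pass:

* **functional class** — frameshift, nonsense or missense by default;
  synonymous and other changes are excluded. The class is an input
  annotation, not computed here.
* **protein region** — optionally, the variant's residue position
  (1-based on the 950-aa isoform) must fall inside a named interval,
  inclusive on both ends. The shipped example regions file places the
  kinase domain at residues 634–938; this interval is user-supplied
  annotation chosen to span the kinase-domain mutation cluster
  (P662L … S904L) and should be treated as approximate — domain
  boundaries are not part of the method.
* **sample MAF** — the alternate-allele count over `2N` chromosomes of
  the analysed sample must be strictly below the threshold (a variant
  sitting exactly at the threshold is excluded). MAFs are always
  recomputed on the sample actually being tested: original,
  replication, merged, or a BMI-filtered subset.

The MAF reference population is a genuinely open design choice: the
pooled analysed sample or its control arm. The package defaults to
**pooled** because pooled frequencies are invariant under case/control
relabeling, which lets the permutation step reuse the qualifying sets
and keeps the permutation test exact; `controls_only` is available,
in which case qualification is recomputed inside every permutation.

## The test

For each threshold `t` of the ladder (default 0.005, 0.001, 0.0005,
strictly decreasing) the qualifying set is collapsed into a 2×2 table
and tested with the exact two-sided Fisher test. The p-value follows
the minimum-likelihood convention: the sum of hypergeometric point
probabilities (computed with `stats::dhyper`) of all tables no more
probable than the observed one, with a relative tolerance of 1e-7 on
the comparison so that mathematically tied tables are counted as tied
despite floating-point noise. A threshold with no qualifying variants
yields the degenerate table and p = 1.

The **variable-threshold statistic** is the smallest per-threshold
p-value, with ties broken toward the largest threshold. It is not a
valid p-value — the best threshold was chosen after seeing the data —
so it is calibrated by permutation: `B` uniform relabelings of
case/control status (preserving both arm sizes, drawn within the
analysed individual set, i.e. after any BMI exclusion), the full scan
recomputed for each, and

`adjusted_p = (1 + #{permuted min_p ≤ observed min_p}) / (1 + B)`.

Including the observed labeling and counting ties as extreme makes the
estimator valid (never anti-conservative) with floor `1/(B + 1)`. All
permutations derive from the single configured seed, so results are
bit-reproducible.

Under the dominant model a carrier of several qualifying variants, or
of a homozygous genotype, counts once. The additive model counts
alleles instead (heterozygote 1, homozygote 2, summed over qualifying
variants) against a margin of `2N` alleles per arm; the same Fisher
test is applied to the allele table. With an extreme number of multi-variant
carriers the summed allele count could exceed the `2N` margin; the
package raises an error in that (biologically implausible) case rather
than producing a negative cell.

## Subset and merged analyses

The control arm can be restricted to normal-weight controls, dropping
controls with BMI above 30 kg/m² — overweight controls (25–30) remain,
and controls with missing BMI are dropped because the condition cannot
be verified; the cutoff is configurable. Two cohorts with disjoint
individuals merge into a combined sample; variants colliding on id
must agree on position and class, and all MAFs are recomputed on the
union by the qualification step itself.

## The simulator

`simulate_cohort()` draws independent sites (no linkage
disequilibrium — appropriate for rare variants in unrelated
individuals, and the test ignores LD anyway). Control genotypes follow
Hardy–Weinberg equilibrium at the site's baseline frequency `q`;
cases use the enriched frequency solving
`q'/(1-q') = OR × q/(1-q)`, i.e. a constant allele-scale odds ratio
across sites — the simplest generative model consistent with a
carrier-level Fisher analysis. Defaults emulate the motivating study:
2,101 cases vs 1,536 controls, 30 sites, odds ratio 2 (≈ twofold
carrier contrast), and a baseline MAF spectrum given by a point
mixture (2×10⁻⁴, 5×10⁻⁴, 10⁻³, 5×10⁻³ with weights 0.60, 0.20, 0.15,
0.05). The mixture reconciles two requirements that a uniform spectrum
cannot satisfy together: sites must straddle all three thresholds of
the ladder, while the aggregate carrier rate stays at the few-percent
level typical of rare-variant screens. Controls receive a truncated
normal BMI (mean 26, sd 4, bounds 15–45) and cases an obese-range BMI
so the normal-weight subset path is exercisable.

What the simulator does **not** emulate: population stratification,
relatedness, sequencing/calling error, per-class effect heterogeneity
and recurrent-site mutation processes. Passing calibration and power
checks on simulated data therefore validates the statistical machinery
under exchangeability, not robustness to those real-data features.

`make_paper_fixture()` is different in kind: a deterministic cohort
reproducing the published *marginal* counts of the motivating screen —
45 of 2,101 cases and 16 of 1,536 controls carrying, 27 case-observed
and 7 control-observed variants, one case homozygous for two variants,
14 of the carriers among the 1,353 normal-weight controls — with a
synthetic carrier layout, since the per-variant table of the screen is
not reproduced. It exercises every pipeline stage with realistic
sparsity.

## Numerical and design choices

* Two-sidedness: the minimum-likelihood convention, the dominant
  convention in genetics software (`stats::fisher.test` uses the same
  rule and serves as an independent cross-check in the test suite; the
  implementation enumerates the hypergeometric support directly and is
  verified against a log-binomial brute-force oracle for every table
  with N ≤ 60).
* Hypergeometric masses come from `dhyper`, which works in log space
  internally; tables at cohort scale (N ≈ 5,000) are exact.
* Permutation tie handling: `≤` with a 1e-12 relative guard — the
  conservative choice.
* Degenerate inputs: empty case or control arms, empty MAF reference
  sets and unknown variant ids raise errors before any computation;
  zero-carrier scans return `min_p = 1` and `adjusted_p = 1`.
* Seeds: one integer seed per analysis drives all permutations; the
  calibration study derives per-replicate seeds deterministically from
  a master seed.

## Calibration, power, and a known limitation

The packaged calibration study (`calibration_study()`) measures the
empirical size and power of the adjusted test. At the scaled design
used throughout the tests — 200 cases / 200 controls, 20 sites, B =
200, chosen to keep a thousand-replicate study in the tens of seconds
on one CPU — the power curve at 500/500 rises from the null level
through ≈ 0.23 (odds ratio 2) and ≈ 0.84 (4) to ≈ 0.99 (8).

The empirical null size at α = 0.05, however, is well below nominal
(≈ 0.01–0.02). This is a structural property, not a defect: with
rare sites at small N the expected number of carriers is in the single
digits, many null draws cannot attain p ≤ 0.05 at all, and the
tie-inclusive `(r+1)/(B+1)` estimator adds further conservatism. The
same machinery reaches size ≈ 0.044 when the statistic is nearly
continuous (common variants, single threshold), and the Monte-Carlo
adjusted p matches exhaustive enumeration of all label assignments on
small cohorts exactly. Users should expect the adjusted test to be
*valid but conservative* on sparse carrier data; conservatism shrinks
as cohorts grow toward the thousands-of-individuals scale of the
motivating study.

## Limitations

* No covariate adjustment, kinship correction, or variance-component
  (SKAT-type) tests — the design assumes unrelated individuals.
* Protein-level coordinates only; no transcript liftover between
  isoforms, no nucleotide/strand handling.
* Functional classes and deleteriousness predictions are pass-through
  inputs, never computed.
* The additive-model allele table treats alleles as exchangeable
  units, which is an approximation when individuals carry multiple
  variants.
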