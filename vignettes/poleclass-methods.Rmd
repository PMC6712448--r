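---
title: "Methods: classifying POLE-driven ultramutated colorectal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying POLE-driven ultramutated colorectal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poleclass)
```

## The problem

A small fraction of colorectal cancers carry somatic mutations in the
exonuclease (proofreading) domain of DNA polymerase epsilon (*POLE*).
Proofreading failure produces an *ultramutated* phenotype: thousands of
nonsynonymous SNVs with a characteristic substitution spectrum dominated by
C>A transversions and nearly devoid of C>G. Recognizing these tumors
matters because their enormous neoantigen load makes them plausible
responders to immune-checkpoint blockade, like mismatch-repair-deficient
(MMR-D) hypermutators. This package implements the standard cohort
analysis: QC filtering of somatic calls, a three-way classification,
POLE-domain annotation, signature refitting, and the cohort-level
statistics used to compare the resulting groups.

## Filtering model

Somatic callers on amplicon-based exome platforms produce characteristic
artifacts. Six per-variant criteria are applied; a call is discarded when
it fulfils **at least one**:

| # | criterion | threshold |
|---|-----------|-----------|
| 1 | caller quality score | < 60 |
| 2 | depth of coverage | < 20 |
| 3 | variant reads on one strand only | exactly one strand count is 0 |
| 4 | average clipped read length | < 100 |
| 5 | variant at read end (`avg_pos_as_fraction`) | < 0.05 |
| 6 | site on a user-supplied false-positive blacklist | set membership |

Numerical choices: every comparison is **strict** — a variant exactly at a
threshold passes. Criterion 3 treats a call with zero reads on both strands
as degenerate and fails it. A variant whose metric is missing passes that
criterion with a warning by default (`strict_missing = TRUE` flips the
policy); the metrics are caller-produced, so absence usually means the
caller did not emit the field, not that the variant is suspect. The
blacklist content is inherently site-local and is consumed as user input.
Filtering is per-variant, hence idempotent and order-independent, and a
larger blacklist can only shrink the kept set — all three properties are
tested.

## Classification model

Two statistics per tumor: the nonsynonymous SNV count $n$ and the
six-class pyrimidine-normalized spectrum (each substitution expressed with
a C or T reference; G>T becomes C>A, and so on). The rules, with strict
inequalities throughout:

* $n \le 500$: **nonhypermutator**;
* $n > 500$ and $f_{C>A} > 0.20$ and $f_{C>G} < 0.03$: **POLE category**;
* otherwise: **common-hypermutator**.

Exactly one label is always produced; a hypermutator with no usable SNVs
for the spectrum (possible only with a non-SNV-driven count definition)
falls through to common-hypermutator. The count threshold, the two
fraction thresholds, the domain bounds and the hotspot set all live in
`classification_thresholds()` / `run_config()` rather than being
hard-coded, because the hypermutator definition is not standardized across
studies.

**Spectrum denominator.** Whether the 20%/3% fractions should be computed
over all filtered SNVs or nonsynonymous SNVs only is genuinely open; using
all SNVs maximizes the count behind the fractions and matches common
practice, so it is the default, with `spectrum_set = "nonsynonymous"`
available as a switch.

**Mutations/Mb.** The callable exome footprint depends on capture design
and coverage and has no defensible universal default, so `footprint_mb` is
mandatory configuration. The burden is simply `count / footprint_mb`.

**POLE annotation.** Protein changes are parsed from
`<refAA><residue><altAA|*>` (optional `p.` prefix); compound entries split
on commas. The exonuclease domain is residues 86–427 inclusive; hotspot
residues are 286, 297, 367, 411 (P286R, S297Y, F367C, V411L). Annotation
is by residue arithmetic only — pathogenicity prediction is out of scope.

## Signature refitting

The refit expresses a normalized 96-context catalog $m$ as a convex
combination $Pw$ of reference signature columns: minimize
$\lVert m - Pw \rVert^2$ subject to $w \ge 0$, $\sum w = 1$. The
constrained fit solves nonnegative least squares on a system augmented
with a heavily weighted sum-to-one row (weight 100), then renormalizes —
the residual of that soft constraint is negligible at this weight, and the
approach keeps the solver a single deterministic NNLS call.

Signature selection is greedy forward selection: starting from the empty
set, add the signature whose inclusion most reduces the reconstruction
error; stop when the relative improvement falls below `rel_tol = 1e-3`.
After fitting, exposures below `cutoff = 0.06` are discarded and the kept
weights renormalized — the cutoff mirrors the widely used refitting
default and suppresses spurious small exposures. Catalogs with fewer than
`min_mutations = 50` mutations are refused: sparse catalogs make the
decomposition unstable, and only heavily mutated tumors are meaningfully
decomposed. No per-context trinucleotide-frequency renormalization is
applied by default (the reference matrix is assumed to be on the same
footprint as the catalogs).

The tests exercise an identity case (single-signature catalogs recover
weight 1 within 0.02), two-signature mixtures (recovered within 0.05 at
5,000 mutations), scale invariance, and agreement of the greedy selection
with an exhaustive subset search (same constrained fit, same size-wise
stopping rule) on at least 95% of random mixtures.

## Cohort statistics

**Fisher's exact test** (2×2, two-sided) uses the minimum-likelihood
convention: the p-value sums the hypergeometric probabilities of all
tables with the observed margins whose point probability does not exceed
the observed one, with a `1e-7` relative tie tolerance. This is the
convention that reproduces the published three-group comparison p-values
from their printed counts, and it matches full same-margin enumeration
exactly (a tested property).

**Mann-Whitney U** is computed from midranks. For `min(n, m) <= 8` with no
ties the exact null distribution is used; otherwise the normal
approximation with tie correction and a 0.5 continuity correction. The
familiar closed form for fully separated triples, 2/C(6,3) = 0.1, is a
fixed test point, and the approximation is checked against the exact
distribution and a permutation oracle.

**Expression.** Raw intensities are log2-transformed and normalized by
subtracting each sample's 75th percentile (so per-sample scale factors
cancel and the normalized 75th percentile is 0 by construction); the
per-patient fold change is tumor minus matched normal on the log2 scale.
Group comparisons are pairwise Mann-Whitney tests without multiplicity
adjustment, matching the exploratory-analysis convention of the source
study design. Log base 2 is the microarray convention; the choice only
shifts fold changes by a constant factor.

**The comparison table** dichotomizes pT as Tis–T2 vs T3–T4 and pStage as
0–II vs III–IV, reports counts with percentages to one decimal, medians
with ranges for age and size, and p-values to three decimals for the
POLE-category group against each other group.

## What the synthetic cohort emulates

`cohort_spec()` defaults describe a large surgical CRC cohort:

* **Prevalence** 0.926 / 0.063 / 0.011 (nonhypermutator /
  common-hypermutator / POLE category).
* **Counts.** Class-conditional log-normals, truncated so each latent
  class satisfies its own count rule: nonhypermutators median 65 on
  [1, 500] — chosen so the cohort-wide *mixture* median lands at 71, the
  headline cohort value; common-hypermutators median ≈1,200 on
  [501, 3,500]; POLE category median ≈3,400 on [1,698, 9,515], the
  observed ultramutator range. About 70% of simulated SNVs are
  nonsynonymous (`nonsyn_fraction`), a free parameter: the true
  total-to-nonsynonymous ratio is not reported for such cohorts.
* **Spectra.** C>T-rich backgrounds for nonhypermutators and
  common-hypermutators (C>A 0.08; C>G 0.05–0.06); POLE-category tumors
  draw C>A from (0.25, 0.50) and C>G from (0.005, 0.02) per tumor, so
  they satisfy the classification rule by construction and
  misclassification can arise only from multinomial noise near the
  thresholds.
* **QC noise.** Decoy variants engineered to fail each criterion at
  configurable per-criterion rates (2% each for criteria 1–5, 1% for the
  blacklist). Decoys for the blacklist criterion are placed on a reserved
  stratum of genome positions (positions divisible by 7) so a blacklisted
  site can never collide with a genuine simulated mutation elsewhere in
  the cohort; with that, the post-filter variant set equals the clean set
  exactly, which is what makes ≥99% end-to-end label recovery a meaningful
  test of the filters and classifier rather than of collision luck.
* **Clinical covariates.** Class-conditional distributions reproducing the
  published group contrasts: POLE-category patients younger (mean 46 vs
  66/68) and predominantly men (90% vs 58.6%/50.9%); common-hypermutators
  right-sided (71.9%) and more often poorly differentiated; sizes, stage
  and invasion rates from the published margins.
* **Expression.** Per-gene log2 fold changes N(shift, 1): shift +1.5 for
  PD-L1 and PD-1 in both hypermutator classes, +1.5 for CD8A in the POLE
  category only, 0 for CTLA-4. The published figures report significance
  only, not effect sizes, so the shifts are free parameters chosen once to
  make the qualitative pattern detectable at realistic group sizes
  (829/53/10): at +1.5 the smallest comparison (n = 10 vs 829) has
  rank-test power well above 99%, so the joint pattern emerges in ≥90% of
  seeds with margin.
* **POLE mutations.** Each POLE-category tumor carries one hotspot change
  (P286R with probability 0.7, else S297Y/F367C/V411L); out-of-domain
  passenger changes are sprinkled into other classes at low rates.

A note on the "null gene": a criterion of the form "CTLA-4 is
non-significant in every comparison in ≥90% of cohorts" cannot exceed
$0.95^k$ for $k$ null tests at $\alpha = 0.05$ purely from the type-I
rate, so CTLA-4 non-significance is scored per comparison (each at its
nominal ≥90% rate) rather than jointly.

**What it does not emulate.** Indels, copy number, genome composition and
linkage (positions are uniform over a 100 kb random genome), realistic
trinucleotide-context structure *within* the six substitution classes
(flank contexts are approximately uniform, so simulated tumor catalogs are
not mixtures of the packaged signature shapes — signature-recovery tests
therefore sample catalogs from explicit signature mixtures), sequencing
reads, tumor purity, or any germline variation. Passing tests demonstrate
that the pipeline's logic is correct under the stated statistical
structure, not that the generator reproduces real Ion-Proton exome data.

## Problem sizes and determinism

The test suite and the acceptance script use a 1,000-tumor cohort for
end-to-end recovery (~350k simulated variants), 100 catalogs of 5,000
mutations for signature recovery, 500 random tables for the Fisher
enumeration cross-check, and 100 simulated expression cohorts at group
sizes 829/53/10 for the significance-pattern rate — sizes at which the
binomial/multinomial error bands in the assertions are comfortably
resolved. Every stochastic step is seeded; `simulate_cohort()` is a pure
function of its spec (including the seed) and restores the caller's RNG
state. The packaged reference genome and the synthetic 96×4 signature
matrix are fixed deterministic objects.

## Known limitations

* The six QC criteria consume caller annotations; the package never
  recomputes them from reads (BAM processing is upstream).
* The classification thresholds are the source study's; the hypermutator
  definition varies across the literature, which is why all thresholds are
  configuration.
* Exact Fisher enumeration is over 2×2 tables only; larger tables are out
  of scope.
* The refit is a greedy decomposition against *fixed* signatures; it does
  not extract signatures de novo and inherits the usual non-identifiability
  caveats when reference columns are nearly collinear.
* MMR status is consumed as a categorical covariate (immunohistochemistry
  is upstream); survival analysis is out of scope for lack of follow-up
  structure in the emulated design.
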