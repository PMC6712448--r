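# poleclass

Somatic-mutation analysis of colorectal cancer (CRC) cohorts centered on
tumors with DNA polymerase epsilon (*POLE*) proofreading deficiency — the
rare, ultramutated subset whose recognition matters clinically because these
tumors are strong candidates for immune-checkpoint blockade.

The package is aimed at cancer genomics analysts who receive per-tumor
somatic variant calls (VCF or tab-separated tables with caller QC
annotations) and want a tested, reproducible implementation of the standard
downstream analysis:

1. **False-positive filtering.** A somatic call is discarded when it fulfils
   at least one of six criteria: quality score < 60; depth of coverage < 20;
   variant reads on one strand only; average clipped read length < 100;
   variant at a read end (`avg_pos_as_fraction` < 0.05); or membership on a
   site blacklist of recurrent artifacts. All comparisons are strict, and
   every verdict carries its reason codes.
2. **Three-way tumor classification.** With *n* the tumor's nonsynonymous
   SNV count and *f*(C>A), *f*(C>G) the pyrimidine-normalized substitution
   fractions:
   - *n* ≤ 500 → **nonhypermutator**;
   - *n* > 500 and *f*(C>A) > 0.20 and *f*(C>G) < 0.03 → **POLE category**
     (the ultramutated, proofreading-deficient phenotype);
   - otherwise → **common-hypermutator** (typically mismatch-repair
     deficient, C>T-rich).
3. **POLE annotation.** Protein changes (e.g. `P286R`, `Q196*`) are parsed
   and flagged for membership in the exonuclease (proofreading) domain
   (residues 86–427) and for the recurrent pathogenic hotspots at residues
   286, 297, 367 and 411.
4. **Signature refitting.** A tumor's 96-trinucleotide-context catalog
   **m** (normalized to fractions) is decomposed over fixed reference
   signatures P as **m** ≈ P**w** with **w** ≥ 0, Σw = 1, by forward
   selection: signatures are added greedily while the relative reduction in
   the sum-of-squares reconstruction error exceeds 1e-3, and exposures
   below a cutoff (default 0.06) are discarded and the rest renormalized.
5. **Cohort statistics.** Two-sided Fisher's exact test (minimum-likelihood
   convention, exact hypergeometric mass), Mann-Whitney U (midranks, exact
   for small untied samples, tie- and continuity-corrected normal
   approximation otherwise), 75th-percentile log2 expression normalization
   with per-patient tumor/normal fold changes, and a publication-style
   three-group clinicopathological comparison table.
6. **Synthetic cohorts.** A generator that reproduces the statistical
   structure of a large surgical CRC cohort (92.6% / 6.3% / 1.1% class
   prevalence, class-conditional SNV counts, spectra, clinical covariates,
   immune-gene expression shifts, QC decoys and a blacklist), so the whole
   pipeline is testable end to end without patient data.

## Worked example

```r
library(poleclass)

# simulate a 300-tumor cohort, filter it and classify every tumor
sim  <- simulate_cohort(cohort_spec(n_tumors = 300, seed = 11))
verd <- apply_fp_filters(sim$variants, sim$blacklist)
filter_summary(verd)[c("kept", "n")]
#> $kept [1] 85229    $n [1] 94472

prof <- build_tumor_profiles(kept_variants(verd), footprint_mb = 45)
table(prof$label)
#> common_hypermutator     nonhypermutator       pole_category
#>                  10                 285                   5
```

85,229 of 94,472 simulated calls survive the six filters (the generator
plants decoys that each filter should remove), and the cohort splits into
the three classes at roughly the expected prevalences. The top of the
hypermutator table shows the POLE-category signature — high C>A, very low
C>G:

```r
hyper <- prof[prof$label != "nonhypermutator",
              c("tumor_id", "nonsyn_snv_count", "frac_C.A", "frac_C.G", "label")]
head(hyper[order(-hyper$nonsyn_snv_count), ], 5)
#>     tumor_id nonsyn_snv_count frac_C.A frac_C.G         label
#> 140    T0140             4910    0.392  0.00784 pole_category
#> 194    T0194             4606    0.327  0.01778 pole_category
#> 216    T0216             3550    0.466  0.01696 pole_category
#> 241    T0241             2954    0.309  0.00735 pole_category
#> 123    T0123             2412    0.305  0.01886 pole_category
```

Exposure refitting recovers a planted 0.7 / 0.3 signature mixture from a
5,000-mutation catalog:

```r
sigs <- synthetic_signature_matrix()
set.seed(5)
mix   <- 0.7 * sigs$weights[, "Sig.POLE"] + 0.3 * sigs$weights[, "Sig.MMR"]
cat96 <- setNames(as.numeric(rmultinom(1, 5000, mix)), context_labels_96())
refit_exposures(cat96, sigs)
#> exposure_vector (reconstruction SSE 0.0001922)
#> Sig.POLE  Sig.MMR
#>   0.6975   0.3025
```

And the exact statistics behave as advertised: a male/female 2×2 of
494/349 nonhypermutators vs 9/1 POLE-category tumors gives the two-sided
Fisher p

```r
fisher_exact_2x2(494, 9, 349, 1)$p_value
#> [1] 0.05424  (0.054 at 3 decimals)

mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> $U [1] 0   $p_value [1] 0.1   (exact: 2 / choose(6, 3))
```

A full run (filter → classify → signatures → comparison → manifest) is one
call: `run_pipeline(run_config(variants, out_dir, footprint_mb = 45, ...))`.
A thin command-line front end with `simulate` / `filter` / `classify` /
`signatures` / `compare` / `run` subcommands ships in
`inst/scripts/poleclass.R`.

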