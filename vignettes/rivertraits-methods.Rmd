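---
title: "Methods: trait-based community analysis across river biotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based community analysis across river biotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivertraits)
```

This vignette documents the statistical models the package implements, the
choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Study structure

The package targets a paired-reach biotope-sampling design: each restored
river reach is paired with an upstream non-restored (control) reach; within
every reach, each visually dominant biotope (a distinct in-channel habitat
patch type) is sampled with replicate kick samples, one per patch. A
biotope counts as *dominant* in a reach only when it provided at least
`min_patches` (default 3) replicate samples there; rarer biotopes are
excluded by `filter_dominant_biotopes()` before any statistics are run.
Organic biotopes (macroalgae and submerged macrophytes of a fine-leaved
*Ranunculus* type and a broad-leaved *Sparganium* type) occur in both
reach types; bare mineralogical biotopes (gravel, sand, gravel-in-sand)
are characteristic of restored reaches. The packaged vocabulary
(`dominant_biotopes()`) holds these six categories.

## Fuzzy-coded trait processing

Trait information is fuzzy-coded: each taxon holds an integer affinity
(0 = none up to 3 or 5 = strong, depending on the information available
for that grouping feature) for every trait modality. The packaged schema
(`default_trait_schema()`) has 13 grouping features and 76 modalities,
eleven features describing biological traits and two describing ecological
preferences (substrate and velocity). The processing chain is:

1. **Filter** the taxon list (`filter_taxa()`), e.g. to the regional fauna
   and the taxa actually observed.
2. **Standardize** affinities to unit sum within each grouping feature
   (`standardize_affinities()`), which gives every taxon equal weight and
   makes the mixed 0–3 / 0–5 scoring scales irrelevant — the reason no
   rescaling of raw scores is needed or performed.
3. **Aggregate** to the working taxonomic rank (`aggregate_to_rank()`) as
   the unweighted arithmetic mean of member profiles, then re-standardize.
   The mean is unweighted because the aggregation expresses taxonomic
   equivalence, not abundance.
4. **Weight** by ln(x + 1)-transformed abundances
   (`build_trait_abundance_array()`); a taxon absent from a sample
   (ln 1 = 0) contributes nothing.
5. **Sum and re-standardize** per sample and grouping feature
   (`community_trait_profile()`), giving community-weighted trait
   profiles. Algebraically this is the ln-abundance-weighted mean of the
   member taxa's standardized profiles, which the tests verify against a
   brute-force loop.

**All-zero feature blocks.** A taxon with no affinity information in a
grouping feature keeps an all-zero block, flagged rather than imputed
uniform: it contributes nothing at step 5, and the final
re-standardization absorbs the missing mass. This is the natural reading
of "standardizing to account for taxa expressing zero affinity scores":
imputing a uniform profile would invent information.

**Step-5 ambiguity.** "Standardizing to account for between-reach
abundances" could mean renormalizing per sample (chosen) or dividing by a
reach-level total. Per-sample renormalization keeps every sample a unit
composition per feature, which is what distance-based comparisons of
*composition* require, so it is used throughout; there is no reach-total
option.

**Converse mismatches.** Taxa present in samples but absent from the trait
database are dropped from trait analyses with a warning naming them; there
is no affinity information to use. Requested taxa absent from the trait
table likewise warn rather than fail.

## Distances and ordination

Abundances are ln(x + 1)-transformed (natural log) before every taxonomic
analysis, for comparability with the trait weighting. Bray–Curtis
dissimilarity is used for both compositions; trait profiles enter as-is
(each row sums to the number of non-flagged grouping features).
Bray–Curtis is a semi-metric, so the principal coordinates analysis
(`pcoa()`) retains negative eigenvalues: axes with eigenvalue
λ < −tol carry "imaginary" coordinates scaled by √(−λ). The tolerance for
classifying zero eigenvalues is `1e-10 × max|λ|` (floating-point rank
deficiency). No Lingoes or Cailliez correction is applied, because the
dispersion analysis corrects squared distances with the imaginary axes
explicitly and a constant-shift correction would distort that.

## Permutational inference

**Blocked PERMANOVA.** The one-factor decomposition uses
SS_total = N⁻¹ Σ_{i<j} d²ᵢⱼ and SS_within = Σ_g n_g⁻¹ Σ_{i<j∈g} d²ᵢⱼ, with
pseudo-F = (SS_between/(a−1)) / (SS_within/(N−a)). On Euclidean distances
of univariate data this is exactly the classical one-way ANOVA F, which
the tests assert to 1e−10. The "nested / blocking factor" design is
implemented as restricted permutation: group labels are shuffled
independently within each block (site pair), never across blocks. This
matches the blocking semantics of the standard distance-based software
rather than a nested sums-of-squares decomposition, which would estimate a
different quantity. When the number of distinct within-block relabelings
is at most 10,000 the null is enumerated exhaustively and
p = count/total (observed labeling included); otherwise
p = (1 + count)/(1 + n_perm), the standard bias-avoiding estimator. A
block containing a single group is legal but unshuffleable and triggers a
warning. One structural fact worth knowing: flipping the labels in *every*
block reproduces the same bipartition and therefore the same F, so the
observed statistic is always tied at least once and the smallest
attainable exact p is 2/(number of relabelings).

**Multivariate dispersion.** Each sample's squared distance to its group
centroid is the squared Euclidean distance on the real PCoA axes minus the
squared distance on the imaginary axes. Strongly non-Euclidean inputs can
make this marginally negative; such values are clamped to zero with a
warning. Group centroids (not spatial medians) are used, without
small-sample bias adjustment, and significance comes from a classical
one-way ANOVA on the distances, with r² = SS_group/SS_total from that
ANOVA; a label-permutation test is available (`permutation_test = TRUE`)
but off by default since the ANOVA is the primary stated test.

**SIMPER.** The contribution of variable *i* to the dissimilarity of a
between-group sample pair is |x_ij − x_ik| / Σ_m (x_mj + x_mk); averaging
over all between-group pairs gives contributions that sum *exactly* to the
mean between-group Bray–Curtis dissimilarity (asserted to 1e−10).
Per-variable p-values permute group labels and count permuted average
contributions ≥ observed, with the (1 + count)/(1 + n_perm) estimator —
the permutation criterion is stated explicitly because published usage is
often vague on it. With more than two groups all pairwise contrasts run.

**IndVal.** For item *i* and combination C of groups:
A = Σ_{g∈C} ā_g / Σ_all ā_g with ā_g the within-group mean (the
"group-equalized" form, so unequal group sizes do not bias specificity),
and B = the fraction of samples in C where the item is present
(value > 0). The statistic is √(A·B), maximized over all non-empty
*proper* subsets of groups — the full set is excluded because an item
indicating every group indicates nothing. Specificity uses abundance-based
A for trait matrices too (community weight, not presence). Significance
permutes sample memberships and compares the permuted maximum statistic to
the observed best, (1 + count)/(1 + n_perm). Ties in the maximization are
broken toward the first combination in size-then-lexicographic order.
IndVal and SIMPER p-values are reported unadjusted; pass the tables to
`p.adjust()` for a Holm correction if desired.

**Seeds.** Every permutation routine requires an explicit seed; nothing
falls back to the global RNG state silently, and the pipeline derives
per-stage child seeds deterministically from its master seed.

## Diversity and contrasts

Alpha diversity is the inverse Simpson index D = 1/Σp², the effective
number of equally common categories — appropriate for trait profiles,
whose category count is fixed by the schema and whose modalities are not
independent. Taxonomic alpha diversity is computed on the
ln(x + 1)-transformed abundances, consistent with the global
transformation; trait alpha diversity on the per-sample profile
renormalized to unit sum across all traits (a per-feature option would be
a trivial extension; overall diversity is the default because the schema
fixes per-feature totals at one). Beta diversity is the multivariate
dispersion with biotope as the grouping factor, fit on the pooled
ordination of all samples (per-reach ordinations would make distances
incomparable across reaches). Diversity–biotope contrasts use a one-way
ANOVA with Tukey HSD at family-wise α = 0.05; residual diagnostics
(Shapiro–Wilk p, max/min per-group residual spread ratio) are reported,
not enforced, mirroring the graphical checks an analyst would make.

## The synthetic-data generator

No field data accompany this methodology, so the generator is the test
bed. It emulates: the paired design (default 3 site pairs), the biotope
asymmetry (3 organic biotopes in both reach types, 3 mineralogical only in
restored reaches), 3 replicates per biotope, and family-level taxa
(default 40). Counts are negative-binomial on a log link — field counts
are overdispersed — with log-mean

    base_t + affinity_{t, biotope} + delta·[restored] + eps_s ,
    eps_s ~ N(0, sd_sample · (phi if restored else 1))

Defaults: `base_mean = log(8)`, `base_sd = 1` (a right-skewed
family-abundance distribution), `affinity_sd = 0.8` (biotopes hold
clearly distinct communities), `sd_sample = 0.4` (about ±50% total
abundance variation between replicate kicks), `negbin_size = 5` (moderate
overdispersion), `delta = 0`, `phi = 1` (no restoration effect unless
asked for). The dispersion effect multiplies the *sample-level* random
effect rather than the negative-binomial size because it must act on
community-level heterogeneity — the quantity the dispersion analysis
measures — not on per-count noise. The trait database generator assigns
taxa to affinity-template "syndromes" (default 5) so that trait structure
is correlated across taxa, as in real databases. The realized parameters
are stored in `truth` for recovery tests.

The default layout gives 27 control / 54 restored samples; a real survey
of this kind reported 24/45 because per-reach biotope inventories were
uneven, which the uniform default cannot reproduce exactly — the design is
fully parameterizable per reach count, biotope lists and replicates.

What the generator does **not** emulate: taxon drift between paired
reaches, spatial autocorrelation among patches, zero-inflation beyond the
negative binomial, trait–abundance covariance (trait syndromes are
independent of the abundance model), and any hydraulic or water-quality
structure. Passing tests therefore show that the statistical machinery
recovers known effects under a plausible count model — not that real
restoration effects of a given size would be detected in the field.

## Calibration conditions used by the tests

The type-I-error check runs the blocked PERMANOVA on 200 null datasets
(organic-only design, `delta = 0`, `phi = 1`, `affinity_sd = 0`,
199 permutations each) and requires the rejection rate at α = 0.05 to
fall in [0.02, 0.09]. The null configuration removes *all* structured
effects so that reach labels are genuinely exchangeable within blocks:
this validates the permutation machinery itself. With biotope effects
present, the balanced assignment of biotopes to both reach types makes
free within-block relabeling conservative — a property of the design, not
of the code — so it is deliberately not the calibration condition. The
dispersion-recovery check uses the same layout with `phi = 3` over 100
datasets (restored mean distance-to-centroid must exceed control in ≥90%
of them, and the dispersion ANOVA must reject more often than under
`phi = 1`). Problem sizes throughout the test suite (54–81 samples, 40
taxa, 199–999 permutations, 100–200 replicate datasets) are chosen as the
smallest at which these frequency properties are stable.

## Known limitations

- Single-factor PERMANOVA only: no interactions, no distance-based RDA.
- Bray–Curtis and inverse Simpson only; other dissimilarities and
  diversity indices (Shannon, FD metrics) are out of scope.
- SIMPER's heuristic character is inherited: large contributions flag
  high-variance variables, not necessarily discriminating ones.
- The IndVal permutation test loses power when indicator signal is spread
  over many samples of a large combination; this matches the reference
  implementation's behavior.
- The generator's ground truth is a stand-in structure; it licenses
  software validation, not ecological inference.
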