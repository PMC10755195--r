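---
title: "Models and methods behind germDiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind germDiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

germDiv analyses SNP-array genotypes of allotetraploid crop germplasm
collections — the motivating case is cultivated peanut (*Arachis
hypogaea*), a selfing allotetraploid whose breeding collections mix
the two subspecies (*fastigiata*, *hypogaea*) and three market types
(Spanish, Valencia, Virginia). This vignette explains the models the
package implements, the parameters that matter, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Genotype model and marker QC

Genotypes are biallelic calls coded `0/1/2` (reference homozygote,
heterozygote, alternate homozygote) with `-1` as the missing sentinel —
an integer code rather than `NA` so matrices stay exact under equality
tests and VCF round trips. Allele dosage is `call/2`.

An allotetraploid SNP array carries features that interrogate
homeologous loci in **both** subgenomes. When the two subgenomes are
fixed for different alleles, every individual yields signal from both
alleles and is called heterozygous, even though each subgenome is
homozygous. In a selfing crop, true residual heterozygosity is rare, so
these collapsed features stand out: their heterozygote rate is far
above the few-percent background, and only two genotype classes appear
(the spurious "heterozygote" plus one homozygote). `applyQC()`
implements the rule:

* het rate ≤ threshold (default 0.05) → **keep**;
* het rate > threshold with two observed classes, one heterozygous
  (`{0,1}` or `{1,2}`) → **recode**: the heterozygous class becomes the
  *absent* homozygote class, reflecting the polymorphism of the single
  variable subgenome;
* het rate > threshold with all three classes → **discard**.

The threshold comparison is strict above (`>`) by a literal reading of
"more than". Missing calls enter neither the rate denominator nor the
class census, so missingness cannot inflate class counts. Monomorphic
markers are kept (polymorphism filtering is assumed upstream of the
genotype calls); a marker whose only observed class is the heterozygote
is the fully collapsed degenerate case and is recoded (the target
homozygote is then conventionally the alternate). A two-class marker
with both classes homozygous cannot reach the high-het branch (its het
rate is 0), so the branch needs no such case.

## Supervised market-type assignment (DAPC)

Breeder-provided passport data are sparse and error-prone, so market
types are assigned genetically, calibrated on reference accessions
whose three phenotype descriptors are mutually congruent: pod shapes of
the fastigiata group (Fastigiata, Vulgaris, Peruviana) + flowers on the
main axis + Spanish or Valencia pod type ⇒ Spanish/Valencia; pod
shapes of the hypogaea group (Hypogaea, Hirsuta) + no main-axis
flowers + Virginia pod type ⇒ Virginia. Everything else is dropped as
incongruent (`buildCalibrationSet()`).

`fitDapc()` is discriminant analysis of principal components:

1. per-marker mean imputation of missing calls, centering by marker
   means (calls are left unscaled — the markers share a scale already,
   and scaling by marker SD would up-weight near-monomorphic markers);
2. PCA; the retained axis count defaults to the smallest number
   explaining ≥ 90% of variance, capped at a third of the training
   size — the usual guard against discriminant overfitting when
   markers far outnumber samples;
3. within each market type, k-means (default k = 3, 20 restarts,
   seeded; restarted with a fresh seed if a subgroup degenerates below
   2 members) subdivides the type in PC space, giving subgroups such
   as `Spanish.1..3` that absorb within-type structure;
4. linear discriminant axes from the between/within scatter
   eigenproblem on the PC scores with subgroups as the grouping
   factor, scaled so the pooled within-group covariance is the
   identity.

Because of that scaling, posteriors are Gaussian with identity
covariance and equal priors: `posterior(g) ∝ exp(-d_g^2/2)` over
subgroup centroids, normalised with a log-sum-exp guard. The formula is
oracle-tested against closed-form Bayes on a one-dimensional toy and
against an independent LDA implementation. `assignFinal()` applies the
0.8 membership threshold and an explicit subgroup exclusion list
(subgroups poorly separated on the leading discriminant axes — a call
made by inspecting the discriminant plane of the calibration fit, so it
is exposed as configuration rather than automated). An
accession is `unassigned` when its best posterior is below threshold or
its best subgroup is excluded; Spanish/Valencia map to subspecies
*fastigiata*, Virginia to *hypogaea*. `removeCalibrationOutliers()`
prunes calibration accessions misclassified under self-prediction, the
operational reading of the reference-set cleanup; it refuses to drop
more than half the set, which would signal a mis-specified model.

Open choices resolved here: the calibration/validation split is
unstratified by default (a `stratify` flag exists); DAPC runs on
centered, unscaled calls; reported percentages round half up to the
printed precision, the convention under which an accuracy of 92.8%
prints as 93%.

## Admixture model (Gibbs sampler)

`gibbsFit()` implements the standard admixture model for unlinked
biallelic markers: individual `i` has ancestry proportions `q_i` over
`K` clusters, cluster `k` has allele frequencies `p_k`, each allele
copy draws a cluster of origin `z` from `q_i` and its allele from
`p_z`. The sampler alternates: categorical draws of `z` for both copies
of every non-missing call; `P | Z ~ Beta(λ + alt, λ + ref)` with the
uniform prior `λ = 1` (independent-frequency model — the correlated
prior adds a dependence the stability-based K rule does not need, and
the independent model is the more testable null); `Q | Z ~
Dirichlet(α + counts)`; and a Metropolis step for the symmetric
concentration `α` (log-normal proposal, SD 0.3, bounded in (0, 10),
initialised at 1). Estimates are posterior means over thinned
post-burn-in samples (thinning 10), and the observed-data
log-likelihood is stored at each thinning point as a convergence
diagnostic. Missing calls contribute nothing anywhere.

Defaults are desk-scale — burn-in 2,000 and 5,000 retained sweeps —
sized so that a full multi-K stability scan completes on a laptop while
leaving production-scale chains (e.g. burn-in 50,000 with 100,000
retained sweeps) one argument away. The acceptance checks use
burn-in 1,000 / 3,000 sweeps for ancestry recovery on a 150 × 300
instance and 300/900-sweep chains for the K scan — sizes at which, on
such instances, the recovery error and the stability ranking have
stabilised.

**Label switching and K selection.** Cluster labels are arbitrary per
run. `alignRuns()` greedily matches Q columns to a reference run by
column correlation, scores pairs as `1 − mean|Q_a − Q_b|`, takes the
medoid run, and reports stability as the fraction of runs whose
similarity to the medoid reaches 0.95. A composite breeders' collection
is not a sample from a structured natural population, so
likelihood-based K criteria are off the table; the number of clusters
retained is the most *reproducible* one. One refinement proved
necessary: the thresholded fraction saturates at 1.0 for every K with a
single dominant posterior mode — in particular K *below* the true
cluster count, where every run merges the same populations — so "most
stable, ties to the smaller K" degenerates to "smallest K in range".
`selectKByStability()` therefore breaks exact stability ties by the
continuous mean similarity to the medoid, and only then by the smaller
K. `assignStructureGroups()` applies the 0.8 membership rule, sending
everything below it to an `Admixed` group.

## Distances, trees, related clusters, PCA, He

* **Allele-sharing distance**: mean per-allele difference
  `|call_i − call_j| / 2` over markers non-missing in both samples
  (pairwise-complete); 0 for identical genotypes, 1 for opposite
  homozygotes throughout.
* **Modified Rogers distance**: Euclidean distance on dosages scaled
  to `[0, 1]`, `sqrt(Σ (x_i − x_j)^2 / m')`; for biallelic loci the
  classical two-allele form collapses to this expression exactly.
  Both are metrics; triangle-inequality and brute-force-loop oracles
  cover them. Pairs with no shared markers error by default (`"na"`
  policy available).
* **Ward tree**: agglomeration under Ward's criterion in its
  squared-distance (ward.D2) form, checked at small n against a naive
  Lance–Williams implementation; newick export with heights from the
  merge trace.
* **Related clusters**: `cutRelatedClusters()` cuts the tree at a
  height and keeps groups of ≥ 10 members (the operational definition
  of "closely related material"). An absolute cut height is only
  meaningful on one dataset's distance scale; since this package's
  distances are proportions, the default cut is instead the 0.02
  quantile of pairwise distances, which tracks the data's scale (an
  absolute `height` remains available). The quantile default
  presumes related material is a small share of all pairs (as in a
  1,000-line collection with a few clusters of 10–20); when near
  duplicates dominate a small matrix, pass an explicit height. Note
  ward.D2 merge heights are not bounded by within-cluster distances, so
  an aggressively low quantile can split a genuine cluster; the
  minimum-size filter then governs what survives.
* **PCA with supplementary individuals**: PCA is fitted on active
  samples only (centering and mean imputation from the active set),
  and the remaining members of each related cluster are projected with
  the stored centering and loadings — near-duplicates otherwise
  dominate the leading axes.
* **Expected heterozygosity**: per biallelic marker
  `He = 1 − (p² + q²)` with `p` the alternate-dosage frequency over
  non-missing calls; the summary is the mean over markers with any
  data. `programDiversityReport()` stratifies He per breeding program
  over all genotypes, the "no-related" subset (one representative per
  related cluster — the member with least missing data, ties to the
  lexicographically first id), and the no-related subset within each
  subspecies, with empty strata reported as missing, never zero.

## Core collection

The construction follows the three-step design: breeders nominate
lines (fixed entries); `dedupNominations()` prunes near-duplicates by
a greedy scan in nomination order (default threshold 0.05 Modified
Rogers — the manual tree inspection it automates had no numeric
threshold, and 0.05 sits an order of magnitude below typical
between-line distances); `optimizeCore()` then fills the remaining
slots to the target size by maximising the **average
entry-to-nearest-entry distance** `AN = mean_i min_{j≠i} d(i, j)`
under Modified Rogers distance. The search is greedy furthest-point
initialisation followed by steepest-ascent single swaps with seeded
restarts — deliberately simpler than the parallel-tempering engine of
dedicated core-selection software, with the identical objective; on
small instances it is oracle-tested against exhaustive enumeration,
and fixed entries are never swapped out. Ties between equally good
swaps resolve by scan order under the run's seed. `composeCoreReport()`
tabulates per-program composition with both raw and half-up-rounded
percentages, since printed shares on rounding boundaries are otherwise
unreproducible.

## Synthetic collections

`simulateCollection()` generates the structure every stage assumes,
so the whole pipeline is testable without any external download:

* ancestral frequencies `U(0.05, 0.95)`; population frequencies from
  the Balding–Nichols model `Beta(p(1−F)/F, (1−p)(1−F)/F)` — the
  natural companion of the admixture model, with `F` the
  differentiation knob (defaults 0.15–0.35, a realistic range between
  crop market-type gene pools; `F = 0` returns the ancestral
  frequencies exactly, `F = 1` is rejected);
* ancestry rows: a configurable share of admixed individuals drawn
  `Dirichlet(α)`, the rest near-pure with one component ≥ 0.95,
  reproducing the pure/admixed dichotomy the 0.8 threshold acts on;
* genotypes with an inbreeding coefficient `selfing` (default 0.95):
  `P(het) = 2θ(1−θ)(1−F_is)` with homozygotes absorbing the rest,
  since breeding lines of an autogamous crop are near-fully inbred and
  background heterozygosity must sit well below the 5% QC threshold;
  `selfing = 0` recovers the plain `Binomial(2, θ)` draw, used by the
  tests whose subject is Hardy–Weinberg behaviour itself;
* injected subgenome-collapsed markers (calls redrawn from `{0,1}` or
  `{1,2}` with a heterozygote share of 0.2–0.8), injected clusters of
  near-identical lines (founder copies with per-call mutation to a
  uniform random code), missing calls, duplicated display names, and
  phenotype records congruent with the true market type for a
  configurable fraction.

Everything is deterministic under the config seed. The generator does
**not** simulate linkage (markers are independent), pedigrees, allele
drop-out or array intensity artefacts; passing tests on it therefore
demonstrate the algorithms' correctness under the stated model, not
robustness to every pathology of real array data.

## Numerical and degenerate-input choices

Allele frequencies are clamped to `(1e-9, 1 − 1e-9)` inside the
sampler (`(1e-6, …)` in the generator) so likelihoods stay finite;
posterior normalisation subtracts the row maximum before
exponentiating; the discriminant eigenproblem whitens within-class
scatter through an eigendecomposition that drops components below
`1e-8` of the largest eigenvalue, which also handles rank-deficient
training sets; correlation-based run alignment falls back to negative
mean absolute difference for zero-variance ancestry columns (K = 1);
all-missing markers are discarded by QC and excluded from He means;
`dist`-grid ties (distances are rational with small denominators) can
make agglomeration order-dependent, which is why the permutation
invariance test varies per-pair denominators through missingness.

## Pipeline

`runPipeline()` sequences QC → classification → structure → diversity
→ core selection from one configuration (R list or YAML), writes every
table as CSV, trees as newick, filtered genotypes as VCF, and a JSON
manifest recording inputs, parameters, seeds and package version.
Stage toggles skip stages; failures abort naming the stage, retaining
artifacts already written; reruns under the same configuration are
byte-identical. `runDemo()` generates a small synthetic collection,
runs everything at desk scale and prints the headline tables. Problem
sizes in the test-suite and acceptance runs (collections of 60–200
samples × 80–500 markers, chains of a few thousand sweeps) are the
package's own desk-scale choices; every one of them is a config knob.
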