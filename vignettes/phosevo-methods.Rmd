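---
title: "phosevo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosevo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package's statistics are defined, why the
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design choices that were genuinely open.

## Coordinates and alphabets

All protein positions are 1-based and inclusive; alignment columns are
1-based. Sequences use the 20 canonical amino-acid letters plus `X`;
`X` never counts as identical to anything, including another `X`, in
any identity computation. Gaps are `-` and occur only in alignment
rows, never in proteome sequences.

## Window similarity and conserved-site calls

A site window is the phospho-acceptor plus `flank = 5` residues up- and
downstream: nominal length 11. Two windows are compared position-wise,
anchored at their centers, and the similarity is the identical-position
count divided by the **nominal** length 11 — not by the overlap. Three
consequences, all deliberate:

* a truncated window (site near a terminus) can never reach 1.0:
  missing context is evidence of non-comparability, and a constant
  denominator keeps scores comparable across sites;
* an ortholog gapped at the acceptor column contributes similarity 0 to
  the site's average rather than being dropped — absence is the
  strongest non-conservation signal, and dropping it would inflate
  averages;
* two windows identical at 10 of 11 positions score 10/11 ≈ 0.909,
  displayed as 0.9 at one decimal; all comparisons are done unrounded
  and rounding happens only at display time.

A site's average similarity is the arithmetic mean of
reference-versus-ortholog window similarities over the orthologs
present in its group; with zero orthologs it is undefined and the site
is excluded from conserved summaries. A site is *conserved* when its
average similarity is strictly greater than 0.5. An alternative
all-species-pairs mean is available (`comparison = "allpairs"`), but
reference-versus-each averaging is the default because per-species site
pages compare the reference site against each ortholog.

Cross-species acceptor status is classified per ortholog:
`identical_acceptor[_observed_both]`, `acceptor_class_changed` for
S↔T substitutions, `acceptor_lost` otherwise, `gap` for a gapped
target. Under the default strict mode Y↔S/T counts as `acceptor_lost`,
because tyrosine kinases are mechanistically distinct from Ser/Thr
kinases; `mode = "broad"` treats any change within {S,T,Y} as a class
change instead.

## Integration

Proteomes are consolidated per species to distinct sequences; the
representative of a duplicate set is the lexicographically smallest
protein id (deterministic and stable across runs). Peptide-supported
site records are re-anchored by exact substring search against the
consolidated proteome *of the record's own species* — cross-species
matching would systematically mis-assign peptides from conserved
regions to orthologs. Peptides matching more than one location are kept
and flagged `ambiguous`; downstream analyses exclude ambiguous records
by default. Merging catalogs unions sources per
`(species, protein, position, PTM type)` key, errors on residue
disagreements, and is invariant to input order. In the overlap table
the `"All"` row counts distinct keys supported by at least 2 and at
least 3 sources — the union-row reading that reproduces the monotone
structure of a per-source overlap table; this is an interpretation, not
a fact about any external dataset.

## Propensity model

Kinase context is summarised by a bank of 40 sparse log-odds PSSMs over
window offsets −5…+5 (30 ST motifs: proline-directed, basophilic,
acidophilic, hydrophobic-directed; 10 Y motifs), shipped as the
versioned fixture `inst/extdata/pssm_bank_v1.tsv` and rebuilt
bit-identically by `default_pssm_bank()`. The bank is a configurable
stand-in for an external kinase-specificity predictor: the shapes are
kinase-biology archetypes, not fitted to any real kinome. Feature *k*
of a window is the sum of motif *k*'s weights over the window's
residues; truncated/gapped/`X` positions contribute 0.

The classifier is a linear maximum-margin model trained per species and
acceptor class (S and T pooled; Y separate; training samples capped at
2000 for ST and 800 for Y, drawn uniformly without replacement and
reproducible from a seed). Features are standardised on the training
set; zero-variance features get scale 1 and therefore zero influence.
Optimisation is full-batch subgradient descent on the L2-regularised
hinge loss with λ = 10⁻³, 500 iterations and step 1/(λt), with three
convergence/imbalance safeguards, all deterministic:

* classes are cost-balanced (each class contributes total weight 1/2 to
  the loss, the SVM cost-factor idiom) so an abundant negative class
  cannot dominate;
* iterates are projected onto the ball of radius 1/√λ;
* the returned weights are the average over the second half of the
  iterations — the bare final iterate of a 1/(λt) schedule oscillates
  and does not converge at these iteration counts.

The bias is carried as an augmented always-1 feature and regularised
with the rest; the slight bias shrinkage is immaterial after
calibration. Margins are mapped to [0, 1] by a two-parameter logistic
fit with Platt's soft targets (which keeps the fit finite on separable
data). Sites observed by MS are pinned to propensity exactly 1,
irrespective of the model. Negative-set contamination — unobserved but
genuinely phosphorylated acceptors in the negative sample — is
acknowledged and left uncorrected.

Decile calibration curves are formed from **unique score quantiles**:
the sparse features give many windows literally identical minimal
scores, and rank-based deciles would split that atom arbitrarily into
bins whose true fractions are equal, so ties never straddle a bin
boundary.

## False-negative rate

Benchmark sites must have every species present and ungapped, all six
windows untruncated, `X`-free and pairwise 100% identical, and must be
observed in at least two species. The FNR of a species is the fraction
of benchmark sites missing from its data; "its data" means the merged
multi-source catalog for the reference species and the single source
elsewhere, mirroring the asymmetry of a reference species with several
datasets. A Wilson 95% score interval accompanies each point estimate.
Because selection conditions on ≥ 2 detections, the naive estimate is
slightly below 1 − sensitivity; recovery tests therefore compare
against the conditional expectation computed by enumerating all 2⁶
detection patterns, not against 1 − s itself.

## Exact Fisher test

`fisher_exact_two_sided()` implements the probability-mass rule: the
p-value is the sum of hypergeometric probabilities, at fixed margins,
of all tables at most as probable as the observed one, with the
customary 10⁻⁷ relative tolerance for floating-point ties (analytic
ties computed along different factorial paths differ in the last ulp;
a strict comparison would misclassify them). A table with a zero margin
admits no alternative configurations and returns p = 1. The odds ratio
is the sample cross-product ratio, `Inf` over a zero denominator. No
multiple-testing correction is applied across species by default, since
per-species raw p-values are reported side by side; `p.adjust` can be
applied by the caller.

In the site-level conservation comparison, control acceptors are drawn
from the same proteins as the phosphosites and matched to their S/T/Y
composition to avoid composition confounding (switchable off — the
matching is this package's addition). Sites whose protein has no
ortholog in the target species, or with a gap at the site, count as
"not conserved": ortholog absence is evidence, consistent with the
gap-at-acceptor rule above.

## Disease-variant proximity

A site is proximal to a variant when they lie on the same protein
within an inclusive 10-residue distance (the site's own position is
distance 0). Sites on proteins without any annotated variant stay in
denominators — absence of variants is informative. The headline
enrichment compares the ≥ cutoff identity stratum against the
below-cutoff stratum (not against all acceptors), with cutoff 0.8 by
default.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
not fly biology:

* **Tree.** Six species on a fixed pectinate tree with the reference
  species near the root (terminal substitution probabilities
  0.05/0.24/0.53/0.66/0.75/0.82 along the ladder, internal edges 0.04).
  Two design targets set these values: the neutral mean window identity
  across the five orthologs sits near 0.38, so the conserved >0.5 call
  has contrast in both directions and all identity bins 0.2–1.0 are
  populated; and the reference species retains ≈ 80% of ancestral
  residues, so planted kinase context survives in the species whose
  sites are scored. Branch lengths are configuration, not biology
  claims.
* **Sites.** 60% of families are phosphoproteins. Their ancestor
  acceptors are planted as *functional* (rate 0.05 per acceptor;
  substitution within ±5 reduced ×0.02 — strong purifying selection —
  and truly phosphorylated in every species retaining the acceptor
  class) or *labile* (rate 0.10; motif context but no protection;
  active per species with probability 0.4). Both classes draw their
  flanks from the bank tilted by exp(3 × weight) — 3 log-odds of
  planted motif strength. The two-class design separates what the
  conservation analyses recover (functional vs not) from what the
  propensity model learns (motif context, carried by *all* true sites).
* **Detection.** The reference species has four sources with
  sensitivities 0.45/0.40/0.35/0.30 (merged coverage ≈ 0.85, i.e. a
  ≈ 15% reference FNR); the other species have single sources at
  0.50/0.40/0.35/0.30/0.25 (FNRs ≈ 0.5–0.75). No false positives by
  default (`fp_rate` exists for robustness work). Detected records
  carry true 7–25-mer peptides so remapping is exercised end to end.
* **Variants.** Placed per residue on the comparator species at rate
  0.01, multiplied by 2 within 10 residues of a conserved functional
  site; realised near/far rates are recorded as attributes.
* **Orthology.** Non-reference species are retained per family at
  probabilities 0.95–0.80, with a 3× odds boost for phosphoprotein
  families (the planted protein-level conservation effect); retained
  members get DIOPT-like scores 3–15.
* **Indels.** Evolution is gap-free by default so alignment columns
  equal ancestor coordinates and the column-map oracles are exact. A
  deletion-only indel mode (per-site start rate, geometric lengths)
  punches recorded gaps into leaf rows for robustness tests;
  insertions are not modelled.

What the generator does **not** emulate: realistic codon-level
evolution or selection, MS spectra and localisation error,
correlated detection across related peptides, isoforms, kinase–substrate
assignment, or real kinome motif frequencies. Green recovery tests
therefore show that the pipeline recovers planted effects of realistic
shape and size under controlled noise — not that any biological claim
about real proteomes is reproduced.

All generator stages are reproducible from the config seed; detection,
variant and retention layers can be re-drawn independently of the
(expensive) sequence layer, which is how the null-distribution and
power checks run hundreds of replicates cheaply.

## Reference problem sizes

The test and acceptance runs use sizes chosen to make the recovery
estimates stable: 500 families for the propensity, conservation,
enrichment and integration checks (≈ 2900 proteins, ≈ 150 000 ST
windows); 900 families for the FNR recovery so the benchmark set
exceeds 500 sites at the planted sensitivities {0.9, 0.6, 0.3} × 2
species, averaged over 10 detection replicates; 50 variant replicates
for enrichment power and 200 for the null type-I rate; all 270 724
2×2 tables with n ≤ 48 for the Fisher enumeration. The `analysis/`
drivers use 150 families as a compact narrative scale.

## Known limitations

* The PSSM bank is an archetype stand-in; propensity scores are
  calibrated probabilities under the synthetic motif model, not
  predictions transferable to real kinomes.
* One representative isoform per gene per species (the longest, ties to
  the smallest id) keeps groups single-rowed per species; multi-isoform
  site summaries are out of scope.
* The FNR estimator inherits the benchmark-selection bias discussed
  above; it is quantified by the conditional oracle in the tests but
  not corrected in the reported point estimate.
* Protein-level conservation comparisons do not adjust for expression
  or abundance confounding.
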