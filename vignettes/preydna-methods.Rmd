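---
title: "Methods: decontamination and diet statistics in preydna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decontamination and diet statistics in preydna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preydna)
```

## The problem

Fecal-DNA metabarcoding infers a predator's diet by amplifying a marker
gene (here COI) from prey DNA surviving digestion, sequencing it, and
classifying the denoised amplicon sequence variants (ASVs). The raw
ASV-by-sample count matrix is not a diet: it mixes true prey reads with
reagent contamination, reads misassigned between samples during
demultiplexing of dual-indexed libraries (tag-jumping / index cross-talk),
unreliable taxonomic assignments, and stochastic amplification dropout.
`preydna` implements a filtering cascade calibrated by the controls a
well-designed experiment carries — extraction/PCR blanks, technical
replicates, and a mock community of known composition — and the statistics
used to compare presence/absence diets between groups of individuals.

Only presence/absence is analyzed. Read abundances depend on taxon-specific
amplification efficiency and biomass conversion that the experiment does
not calibrate, so the pipeline deliberately never interprets relative read
abundance beyond detection thresholds.

## The cascade and its parameters

The canonical stage order is fixed and enforced by `run_cascade()`; the
stages do not commute and each is a pointwise non-increasing map on counts
(merging across primer sets excepted).

**Negative-control filter.** The per-ASV removal threshold is the *maximum*
count of that ASV over all negative controls, and specimen cells are zeroed
when *at or below* it. The underlying rule ("below the read count of any
negative control") is ambiguous between min and max; max is the
conservative anti-contamination reading, and ties are removed because a
count equal to a blank's count cannot be distinguished from contamination.
Mock and blank columns are left untouched: the mock must retain its stray
reads because they are the signal the tag-jump estimator measures.

**Taxonomy resolution.** Classifier confidences (e.g. SINTAX posteriors)
are thresholded per rank — species 0.45, genus 0.40, family 0.30, order
0.20 by default — as an acceptance ladder: an ASV failing at species is
demoted to genus, and so on; failing order discards it. A per-rank ladder
(rather than all-or-nothing) follows from having one threshold per rank.
Thresholds are configurable through `filter_config()` but must be
monotone (species ≥ genus ≥ family ≥ order) and in (0, 1).

**Replicate consistency** operates after ASV collapse, at taxon level: a
taxon is removed from a sample unless both technical replicates produced
reads. Operating at taxon level (not ASV level) matches the intent of
removing *prey taxa* unsupported by both replicates, and is more permissive
only in the harmless case where different ASVs of one taxon appear in the
two replicates.

**Tag-jump estimation and filtering.** The mock community has known
composition, so non-mock reads in mock samples must have jumped in from
other samples. The estimated rate is pooled over both replicates of a
primer set and applied per primer set: within each sample, cells strictly
below `rate × (sample read total at this stage)` are zeroed. Two choices
deserve note: the strict `<` boundary (a cell exactly at the threshold
survives) and the use of the *current-stage* column total, since the
description does not pin down which total is meant; the choice is recorded
in the cascade report so a sensitivity audit can recompute with raw totals.
Whether tag-jump filtering precedes or follows non-target removal is also
under-determined; the cascade follows the narrative order (after
non-target removal), and since both filters only zero cells, the order
affects at most the column totals entering the threshold.

**Merging and exclusions.** The primer sets are merged by taxon union with
counts summed; because only presence is consumed downstream, any merge
preserving the support OR is equivalent. Mock taxa and configured exclusion
taxa are then dropped. The default exclusion is *Arrenurus reflexus*, a
parasitic water mite whose reads in the emulated system plausibly reflect
parasite contamination (or grooming) rather than predation; excluding it
changes which specimens retain any detection at all, which is why exclusion
happens before presence conversion. Specimens left with no detected taxon
are dropped from the presence matrix with a logged list.

## Statistical methods

**Prevalence.** Detection counts `k` out of `n` individuals get exact
Clopper–Pearson intervals via the Beta-quantile form. The denominator
convention matters when some collected individuals yield no usable reads:
`prevalence_table()` defaults to the analyzed specimens but accepts
explicit denominators (e.g. all collected individuals), and records which
was used. The reference table this package validates against uses the
collected denominators (152/103/49), which reproduce its printed
arithmetic exactly.

**Fisher and Holm.** Two-sided Fisher p-values sum hypergeometric point
probabilities not exceeding the observed table's (minimum-likelihood rule,
the convention of mainstream software, and the one that reproduces the
reference p-values 0.02 and 0.039). Holm–Bonferroni is the step-down
adjustment with enforced monotonicity; it is uniformly no larger than
Bonferroni and no smaller than the raw p-values, both asserted as test
properties.

**Richness.** Mann–Whitney uses the tie-corrected normal approximation
without continuity correction, because presence/absence richness is
heavily tied; an exact enumeration method exists for validation. At 6–8
observations per group the approximation sits within about 0.10 of the
exact p (worse below that), which the tests document rather than hide.
BCa bootstrap intervals use the usual bias term from the bootstrap
distribution and jackknife-skewness acceleration; constant input returns a
zero-width interval, and a degenerate bias term falls back to the
percentile interval.

**Community comparisons.** Presence/absence Bray–Curtis
`(A + B − 2J)/(A + B)` (the Sørensen dissimilarity) feeds a one-way
PERMANOVA: pseudo-F from the squared-distance decomposition, free
permutation of group labels (a single-factor design needs no strata), and
the add-one estimator `p = (#{F* ≥ F} + 1)/(B + 1)` so p is never zero.
The dispersion-homogeneity companion embeds the distance matrix by
principal coordinates, keeps negative-eigenvalue axes separate (binary
Bray–Curtis is non-Euclidean, so they occur), computes distances to group
centroids with negative-axis contributions subtracted in the squared
distance and floored at zero, and reports both the parametric F p-value
and a label-permutation p-value. The bootstrap resampling unit for the
mean dissimilarity is the specimen, not the pair: duplicated specimens in
a resample legitimately contribute zero distances.

**Accumulation and the assemblage test.** Expected sample-based rarefaction
uses the hypergeometric closed form; the random-ordering ensemble
(`accumulation_ensemble()`) exists for display and converges to the closed
form, which the tests verify. The assemblage randomization test compares
each group's expected curve with the pooled curve at 1..n_g samples,
summing *absolute* gaps (signed gaps could cancel), and builds the null by
reassigning specimens to groups of the same sizes. Using analytic curves
inside the permutation loop (rather than re-randomized accumulations) makes
the statistic deterministic given the data and much faster; the source
method's exact area variant is not pinned down publicly, so this variant is
committed and documented rather than inferred. One consequence: when the
two groups are literal copies of one specimen set the statistic is still
positive (group curves use fewer samples than the pooled curve), but the
test correctly fails to reject because the null reshuffles reproduce the
same structure.

## The synthetic world

`simulate_experiment()` generates what the emulated experiment would have
produced, with known ground truth. Defaults state the world once:

- 103 females, 49 males; 150-taxon prey pool; per-taxon detection
  probabilities are sorted Beta(0.5, 9.5) draws (mean 0.05, few common and
  many rare taxa), with a built-in default sex effect in four taxa.
- Two primer channels ("Leray", "ANML") observe the same true diets with
  channel-specific detection (p = 0.9, shared between replicates) and
  independent per-replicate dropout (p = 0.1).
- Read counts are negative-binomial (size 1) around a 10,000-read depth
  with Gamma-weighted within-sample composition. No abundance law is
  calibrated by the emulated study (it never uses relative abundance), so
  the family is configurable and nothing downstream depends on it.
- Tag-jumping moves each read to a uniformly random other sample of its
  dataset with probability 0.005 (the order of the rates the emulated
  study estimated, 0.52%/0.82%); reads are conserved. Because a jumped
  read lands in the mock with probability 1/(N−1), the mock-based
  estimator recovers `rate × T_spec/((N−1) × D_mock)` where `T_spec` is
  the realized specimen read total and `D_mock` the mock depth — a few
  percent of structural thinning at full design size (more in tiny test
  worlds where some specimens carry no active taxa), which the recovery
  tests condition on explicitly rather than hide in a widened tolerance.
- Four negative controls receive Poisson(0.5) stray reads per prey ASV;
  eight reagent-contaminant taxa (non-arthropod) hit specimens and blanks
  alike at Poisson(25), which is what makes the negative-control filter
  effective against them. Contaminants are not seeded into the mock, so
  the cross-talk estimator stays unbiased; a real mock shares reagents,
  and a real estimate would absorb that contamination into the rate.
- The six mock taxa are the insects of the emulated study's mock
  community; the predator leaks Poisson(0.5) reads per specimen (blocking
  primers "work"); six spurious ASVs carry confidences below every
  threshold.
- Classifier confidences are a monotone chain (coarse ≥ fine) with 70% of
  prey ASVs resolvable at species level; real data may violate
  monotonicity and is accepted with a warning.

One deliberate deviation from a strict generation-order reading: replicate
dropout is applied when each replicate's clean reads are drawn (both
replicates independently thinned) rather than as a post-hoc thinning of
replicate 2 — distributionally equivalent for everything downstream and
closer to the stated meaning ("a truly present taxon yields zero reads in
one replicate").

What a green test does *not* establish: the generator has no sequence-level
errors, chimeras, PCR bias, primer-specific amplification efficiencies, or
phylogenetically structured prevalence; recovery results on it bound only
the cascade's behaviour under the stated noise model.

## Numerical choices and degenerate inputs

- All permutation p-values use the add-one estimator; resolution is
  1/(B+1).
- All stochastic routines take a seed and restore the caller's RNG state;
  one master seed derives per-stage sub-streams, so a run manifest
  reproduces a run bit-for-bit.
- `bray_curtis_presence` errors on two empty diets (0/0); empty specimens
  never reach it because presence-matrix construction drops them.
- PCoA axes with |eigenvalue| below `1e-8 × max|eigenvalue|` are treated
  as null; squared centroid distances are floored at 0 before the square
  root.
- Fisher's minimum-likelihood rule compares point probabilities with a
  `1 + 1e-7` relative tolerance so floating-point noise cannot break ties.
- The cascade on an all-zero specimen matrix returns an empty presence
  matrix without error; a dataset with no mock reads makes the tag-jump
  estimator fail loudly rather than return 0.

## Scaled-down checks

Monte-Carlo validations run at reduced sizes to stay inside a small CI
budget: type-I error of PERMANOVA and the assemblage test at 200 null
worlds with 99/59 permutations (binomial 95% band around 0.05), BCa
coverage at 200 simulations with B = 600, and the Mann–Whitney
approximation audit at 25 parameter draws. The bands used are stated in
the tests; enlarging the simulations tightens, never changes, the
conclusions.

## Known limitations

- The pipeline consumes post-denoising matrices; primer trimming, DADA2
  denoising, chimera removal and classifier execution are upstream and out
  of scope, as is richness extrapolation (pool estimators do not converge
  on data like these) and any abundance-aware diet quantification.
- The tag-jump model (uniform per-read misassignment) matches the
  estimator's assumption; real cross-talk is structured by index pairs.
- The assemblage-test area statistic is one committed variant of a method
  whose published description admits several.
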