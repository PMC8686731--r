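# preydna

Diet analysis from fecal-DNA metabarcoding, for molecular ecologists
comparing the diets of groups of individual predators (sexes, age classes,
populations) from COI amplicon data.

Metabarcoding a predator's feces yields a matrix of read counts per
amplicon sequence variant (ASV) per sample — contaminated by reagent DNA,
index cross-talk ("tag-jumping"), and unreliable taxonomic assignments.
`preydna` implements a mock-community-calibrated decontamination cascade
that turns those raw matrices into defensible per-individual prey
presence/absence, plus the statistics used to compare diets between groups.

## The cascade

For each primer set with two technical replicates, in order:

1. **Negative-control filter** — for each ASV, specimen counts at or below
   the maximum count observed in any extraction blank / PCR negative are
   zeroed.
2. **Taxonomy resolution** — each ASV is assigned at the deepest rank whose
   classifier confidence reaches its threshold (species ≥ 0.45, genus
   ≥ 0.40, family ≥ 0.30, order ≥ 0.20 by default), demoting rank by rank;
   below the order threshold the ASV is discarded.
3. **ASV collapse** — reads of ASVs resolved to the same taxon are summed
   per sample.
4. **Replicate consistency** — a (taxon, sample) detection is kept only if
   both technical replicates produced reads; kept cells carry summed reads.
5. **Non-target removal** — taxa outside the target phylum (default
   Arthropoda) are dropped.
6. **Tag-jump filter** — the cross-talk rate is estimated per primer set as
   (non-mock reads in mock samples) / (total mock reads); any cell below
   that proportion of its sample's read total is zeroed.
7. **Merge** of the primer sets (taxon union, counts summed), removal of
   mock and excluded taxa (e.g. a parasite that is not genuine prey), and
   conversion to presence/absence.

## The statistics

With the binary taxa × specimen matrix and per-specimen group labels:

- prevalence per taxon with exact Clopper–Pearson intervals
  (`qbeta(α/2, k, n−k+1)` / `qbeta(1−α/2, k+1, n−k)`), overall and per
  group, at a caller-chosen denominator convention;
- two-sided Fisher exact tests (minimum-likelihood rule) per taxon with
  Holm–Bonferroni control;
- diet richness per specimen, Mann–Whitney tests (tie-corrected normal
  approximation, with exact enumeration available), BCa bootstrap CIs;
- presence/absence Bray–Curtis dissimilarity `d = (A + B − 2J)/(A + B)`,
  one-way PERMANOVA (pseudo-F, label permutation, add-one p), and a
  PERMDISP-style multivariate dispersion homogeneity test;
- exact sample-based rarefaction
  `E[S(m)] = Σᵢ (1 − C(n−nᵢ, m)/C(n, m))`, random-ordering accumulation
  ensembles, and an assemblage randomization test comparing group
  accumulation curves against the pooled curve.

A synthetic-experiment generator (`simulate_experiment()`) emulates the
full design — two primer sets, two replicates, blanks, a six-taxon mock,
heavy-tailed prevalences, overdispersed reads, tag-jumping — with known
ground truth, so every stage has a parameter-recovery test.

## Worked example

```r
library(preydna)
cfg <- sim_config(n_female = 40, n_male = 25, n_taxa = 60, seed = 7)
sim <- simulate_experiment(cfg)
res <- run_cascade(sim$datasets, sim$taxonomy, sim$meta, filter_config())
print(res$report)
#> <prey_cascade_report>
#>  primer_set                        stage   reads taxa
#>       Leray                        input 1347667  106
#>       Leray      negative_control_filter 1321856  106
#>       Leray             collapse_to_taxa 1319513   86
#>       Leray replicate_consistency_filter 1025043   86
#>       Leray             remove_nontarget 1023914   78
#>       Leray              tag_jump_filter 1023792   78
#>       ...
#> tag-jump rate: Leray=0.4331%, ANML=0.3885%
#> final: 40 taxa x 63 specimens; 2 specimen(s) dropped
```

Read totals shrink monotonically through the per-primer stages, and the
estimated tag-jump rates recover the simulated 0.5% cross-talk. Downstream:

```r
pm <- res$presence
d  <- pairwise_distances(pm)
permanova(d, n_perm = 999, seed = 1)
#> PERMANOVA: statistic(1,61) = 2.137, R2 = 0.0338, p = 0.026 (999 permutations)
assemblage_ecotest(pm, iterations = 200, seed = 2)
#> assemblage randomization (accumulation curves): statistic(1,63) = 50.91,
#>   p = 0.602 (200 permutations)
mean_dissimilarity(d, B = 1000, seed = 3)
#> mean Bray-Curtis dissimilarity 0.905 (95% BCa CI 0.898-0.921)
```

The default simulation plants a sex effect in four taxa, and PERMANOVA
detects it (p = 0.026); the assemblage test, which asks the coarser
question of whether both sexes draw from one prey pool, does not reject
(p = 0.60). Individual diets are highly dissimilar (mean presence/absence
Bray–Curtis 0.905), matching what fecal metabarcoding of generalist
predators typically shows.

## Command line

```sh
exec/preydna simulate --out data/ --seed 7
exec/preydna clean --in data/ --out cleaned/
exec/preydna all --simulate --seed 7 --out run/
```

Subcommands: `simulate`, `clean`, `prevalence`, `community`, `all`; config
via YAML (`--config run.yaml`); exit codes 0 / 2 (validation) / 3 (runtime).

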