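Package: preydna
Title: Metabarcoding Diet Analysis from Fecal DNA with Mock-Community
    Calibrated Decontamination
Version: 0.1.0
Authors@R:
    person("preydna", "developers", email = "preydna@example.org",
           role = c("aut", "cre"))
Description: Tools for COI amplicon metabarcoding diet analysis of predator
    feces. Implements a mock-community-calibrated decontamination cascade
    that turns raw ASV-by-sample read-count matrices into per-individual
    prey presence/absence (negative-control filtering, rank-threshold
    taxonomy resolution, ASV collapse, technical-replicate consistency
    filtering, non-target removal, tag-jump estimation and filtering, and
    primer-set merging), plus the diet statistics used to compare groups of
    individuals: exact binomial (Clopper-Pearson) prevalence intervals,
    two-sided Fisher tests with Holm-Bonferroni control, diet richness with
    Mann-Whitney tests and BCa bootstrap intervals, presence/absence
    Bray-Curtis dissimilarities, permutation MANOVA, multivariate dispersion
    homogeneity, sample-based rarefaction, and an accumulation-curve
    assemblage randomization test. Includes a synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
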