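test_that("negative-control filter zeroes specimen cells at or below the max blank count", {
  meta <- toy_meta()
  counts <- rbind(
    ASV1 = c(F1 = 4, F2 = 5, M1 = 80, NEG1 = 2, NEG2 = 5, MOCK = 0),
    ASV2 = c(F1 = 1, F2 = 7, M1 = 3, NEG1 = 0, NEG2 = 0, MOCK = 0))
  out <- negative_control_filter(toy_read_matrix(counts), meta)
  expect_identical(unname(unwrap(out)["ASV1", c("F1", "F2", "M1")]),
                   c(0L, 0L, 80L))
  # all-zero blanks leave the matrix unchanged
  expect_identical(unname(unwrap(out)["ASV2", c("F1", "F2", "M1")]),
                   c(1L, 7L, 3L))
  # blanks and mock columns are untouched
  expect_identical(unwrap(out)[, c("NEG1", "NEG2", "MOCK")],
                   unwrap(toy_read_matrix(counts))[, c("NEG1", "NEG2",
                                                       "MOCK")])
  # without negatives: warning and pass-through
  meta_nn <- toy_meta(negs = character())
  m <- toy_read_matrix(counts[, c("F1", "F2", "M1", "MOCK")])
  expect_warning(out2 <- negative_control_filter(m, meta_nn), "no-op|no neg")
  expect_identical(unwrap(out2), unwrap(m))
})

test_that("taxonomy resolution walks the rank ladder with the stated thresholds", {
  mk <- function(s, g, f, o, labels = c("Sp", "Ge", "Fa", "Or")) {
    data.frame(asv_id = "A1", species = labels[1], genus = labels[2],
               family = labels[3], order = labels[4], phylum = "Arthropoda",
               kingdom = "Animalia", species_conf = s, genus_conf = g,
               family_conf = f, order_conf = o, phylum_conf = max(o, 0.9),
               kingdom_conf = 1, is_mock = FALSE, stringsAsFactors = FALSE)
  }
  # some ladder fixtures are deliberately non-monotone; that raises the
  # documented accept-with-warning, which is not under test here
  res <- function(...) resolve_taxonomy(
    suppressWarnings(taxonomy_table(mk(...))), filter_config())
  r <- res(0.50, 0.60, 0.70, 0.90)
  expect_identical(c(r$rank, r$label), c("species", "Sp"))
  # all four thresholds just violated -> discard
  r <- res(0.44, 0.39, 0.29, 0.19)
  expect_identical(r$rank, "DISCARD")
  r <- res(0.10, 0.45, 0.80, 0.90)
  expect_identical(c(r$rank, r$label), c("genus", "Ge"))
  # boundary: confidence equal to the threshold is accepted
  r <- res(0.45, 0.40, 0.30, 0.20)
  expect_identical(r$rank, "species")
  # missing label at an accepted rank demotes further
  r <- res(0.90, 0.90, 0.90, 0.90, labels = c("", "", "Fa", "Or"))
  expect_identical(c(r$rank, r$label), c("family", "Fa"))
})

test_that("ASV collapse sums reads per resolved taxon and conserves totals", {
  meta <- toy_meta()
  counts <- rbind(ASV1 = c(F1 = 3, F2 = 0, M1 = 2, NEG1 = 0, NEG2 = 0,
                           MOCK = 0),
                  ASV2 = c(F1 = 4, F2 = 1, M1 = 0, NEG1 = 0, NEG2 = 0,
                           MOCK = 0),
                  ASV3 = c(F1 = 9, F2 = 9, M1 = 9, NEG1 = 0, NEG2 = 0,
                           MOCK = 0))
  resolution <- data.frame(
    asv_id = c("ASV1", "ASV2", "ASV3"),
    rank = c("species", "species", "DISCARD"),
    label = c("Aa bb", "Aa bb", ""), stringsAsFactors = FALSE)
  t1 <- collapse_to_taxa(toy_read_matrix(counts), resolution, meta)
  expect_identical(dim(unwrap(t1)), c(1L, 3L))
  expect_identical(unname(unwrap(t1)[1, ]), c(7L, 1L, 2L))
  # conservation: column sums equal those of retained ASVs
  expect_identical(colSums(unwrap(t1)),
                   colSums(counts[1:2, c("F1", "F2", "M1")]))

  # injective resolution is a row-relabeling
  res2 <- data.frame(asv_id = c("ASV1", "ASV2", "ASV3"),
                     rank = "species",
                     label = c("T1", "T2", "T3"), stringsAsFactors = FALSE)
  t2 <- collapse_to_taxa(toy_read_matrix(counts), res2, meta)
  expect_equal(unname(unwrap(t2)[order(attr(t2, "taxa")$label), ]),
               unname(counts[, c("F1", "F2", "M1")]))
})

test_that("replicate consistency keeps only detections seen in both replicates", {
  meta <- toy_meta()
  mk <- function(v, rep_i) {
    counts <- matrix(v, nrow = 2, byrow = TRUE,
                     dimnames = list(c("ASV1", "ASV2"),
                                     c("F1", "F2", "M1", "NEG1", "NEG2",
                                       "MOCK")))
    res <- data.frame(asv_id = c("ASV1", "ASV2"), rank = "species",
                      label = c("T1", "T2"), stringsAsFactors = FALSE)
    collapse_to_taxa(toy_read_matrix(counts, rep_i = rep_i), res, meta)
  }
  r1 <- mk(c(10, 10, 0, 0, 0, 0,
             5, 0, 7, 0, 0, 0), 1)
  r2 <- mk(c(0, 1, 4, 0, 0, 0,
             5, 0, 7, 0, 0, 0), 2)
  out <- replicate_consistency_filter(r1, r2)
  expect_identical(unname(unwrap(out)["species|T1", ]), c(0L, 11L, 0L))
  expect_identical(unname(unwrap(out)["species|T2", ]), c(10L, 0L, 14L))
  # identical replicates double the counts with identical support
  out2 <- replicate_consistency_filter(r1, r1)
  expect_identical(unwrap(out2), unwrap(r1) * 2L)
})

test_that("non-target removal keeps the target phylum and reports fractions", {
  sim <- simulate_experiment(small_sim_config())
  res <- resolve_taxonomy(sim$taxonomy, filter_config())
  tbl <- collapse_to_taxa(sim$datasets[[1]], res, sim$meta)
  out <- remove_nontarget(tbl, sim$taxonomy, filter_config())
  phyla <- preydna:::taxon_phylum(out, sim$taxonomy)
  expect_true(all(phyla == "Arthropoda"))
  expect_true(any(grepl("Conta", attr(out, "removed_taxa"))))
  expect_equal(attr(out, "removed_fraction"), 1 - sum(out) / sum(tbl))
  # an all-arthropod table passes unchanged
  again <- remove_nontarget(out, sim$taxonomy, filter_config())
  expect_identical(unwrap(again), unwrap(out))
})

test_that("tag-jump estimator reproduces the reference arithmetic", {
  ref <- reference_mock_reads()
  leray <- ref[ref$primer_set == "Leray", ]
  meta <- toy_meta()
  counts <- rbind(
    ASV_M = c(F1 = 0, F2 = 0, M1 = 0, NEG1 = 0, NEG2 = 0,
              MOCK = leray$total_mock_reads - leray$non_mock_reads),
    ASV_X = c(F1 = 100, F2 = 0, M1 = 0, NEG1 = 0, NEG2 = 0,
              MOCK = leray$non_mock_reads))
  tax <- taxonomy_table(data.frame(
    asv_id = c("ASV_M", "ASV_X"), species = c("Mockus mockus", "Prey prey"),
    genus = "", family = "", order = "", phylum = "Arthropoda",
    kingdom = "Animalia", species_conf = 1, genus_conf = 1, family_conf = 1,
    order_conf = 1, phylum_conf = 1, kingdom_conf = 1,
    is_mock = c(TRUE, FALSE), stringsAsFactors = FALSE))
  rate <- estimate_tag_jump_rate(toy_read_matrix(counts), meta, tax)
  expect_equal(as.numeric(rate), leray$non_mock_reads / leray$total_mock_reads)
  expect_equal(round(100 * as.numeric(rate), 2), 0.52)

  # a pure mock sample gives rate 0; an empty mock errors
  counts2 <- counts; counts2["ASV_X", "MOCK"] <- 0
  expect_equal(as.numeric(estimate_tag_jump_rate(
    toy_read_matrix(counts2), meta, tax)), 0)
  counts3 <- counts; counts3[, "MOCK"] <- 0
  expect_error(estimate_tag_jump_rate(toy_read_matrix(counts3), meta, tax),
               class = "preydna_validation_error")
})

test_that("tag-jump filter uses a strict-less rule on per-column proportions", {
  counts <- matrix(c(9, 10, 981), ncol = 1,
                   dimnames = list(c("t1", "t2", "t3"), "S1"))
  out <- tag_jump_filter(counts, 0.01)  # threshold = 10
  expect_equal(unname(out[, 1]), c(0, 10, 981))
  expect_equal(tag_jump_filter(counts, 0), counts)
})

test_that("merging primer sets unions taxa and ORs presence", {
  mk <- function(labels, counts, primer) {
    taxon_table(matrix(counts, nrow = length(labels), byrow = TRUE,
                       dimnames = list(NULL, c("F1", "M1"))),
                data.frame(rank = "species", label = labels),
                provenance = primer)
  }
  a <- mk(c("T1", "T2"), c(5, 0, 2, 3), "P1")
  b <- mk(c("T2", "T3"), c(1, 0, 0, 9), "P2")
  out <- merge_primer_sets(a, b)
  expect_setequal(rownames(out), c("species|T1", "species|T2", "species|T3"))
  expect_identical(unname(unwrap(out)["species|T1", ]), c(5L, 0L))
  expect_identical(unname(unwrap(out)["species|T2", ]), c(3L, 3L))
  expect_identical(sort(attr(out, "provenance")), c("P1", "P2"))
  pa <- unwrap(out) > 0
  expect_identical(pa[rownames(out), ],
                   (preydna:::align_tables(a, b)$a > 0 |
                      preydna:::align_tables(a, b)$b > 0)[rownames(out), ])
  # merging a table with itself doubles counts, same support
  self <- merge_primer_sets(a, a)
  expect_identical(unwrap(self)[rownames(a), ], unwrap(a) * 2L)
})

test_that("excluded and mock taxa are dropped; presence conversion drops empty specimens", {
  tt <- taxon_table(
    matrix(c(4, 0, 0, 0, 3, 0, 0, 0, 7), nrow = 3, byrow = TRUE,
           dimnames = list(NULL, c("F1", "F2", "M1"))),
    data.frame(rank = "species",
               label = c("Arrenurus reflexus", "Prey one", "Prey two")))
  out <- remove_excluded_taxa(tt, filter_config())
  expect_false("species|Arrenurus reflexus" %in% rownames(out))
  expect_identical(nrow(unwrap(out)), 2L)
  # empty exclusion list is the identity
  out2 <- remove_excluded_taxa(tt, filter_config(exclusion_taxa = character()))
  expect_identical(unwrap(out2), unwrap(tt))
  # excluding everything warns
  expect_warning(remove_excluded_taxa(
    tt, filter_config(exclusion_taxa = c("Arrenurus reflexus", "Prey one",
                                         "Prey two"))), "all taxa")

  # F1 was positive only for the excluded mite -> dropped from presence
  sex <- c(F1 = "female", F2 = "female", M1 = "male")
  expect_message(pm <- to_presence(out, sex), "F1")
  expect_identical(colnames(pm), c("F2", "M1"))
  expect_identical(unname(unwrap(pm)[, "M1"]), c(0L, 1L))
  # idempotence on binary data
  pm2 <- suppressMessages(to_presence(
    taxon_table(unwrap(pm), attr(out, "taxa")), sex))
  expect_identical(unwrap(pm2), unwrap(pm))
})

test_that("noise-free cascade recovers the ground truth exactly", {
  sim <- simulate_experiment(clean_sim_config())
  res <- run_cascade(sim$datasets, sim$taxonomy, sim$meta, filter_config())
  pm <- res$presence
  truth <- sim$truth$presence
  # recovered taxa are named by their species key
  rec_taxa <- sub("^species\\|", "", rownames(pm))
  expect_true(all(rec_taxa %in% rownames(truth)))
  # no false positives anywhere, and exact equality on the detected taxa
  for (i in seq_along(rec_taxa))
    expect_identical(unname(unwrap(pm)[i, ]),
                     unname(truth[rec_taxa[i], colnames(pm)]))
  # every true detection of a detected taxon in a retained specimen is found
  expect_identical(sum(unwrap(pm)), sum(truth[rec_taxa, colnames(pm)]))
})

test_that("cascade report read totals are non-increasing pre-merge", {
  sim <- simulate_experiment(small_sim_config())
  res <- run_cascade(sim$datasets, sim$taxonomy, sim$meta, filter_config())
  st <- res$report$stages
  for (p in unique(st$primer_set[st$primer_set != "combined"])) {
    reads <- st$reads[st$primer_set == p]
    expect_true(all(diff(reads) <= 0), label = p)
  }
  expect_true(all(res$report$tag_jump_rate > 0))
})

test_that("cascade of an all-zero matrix yields an empty presence matrix", {
  meta <- toy_meta(primer_sets = "P1")
  zero <- matrix(0L, 2, 6,
                 dimnames = list(c("ASV1", "ASV2"),
                                 c("F1", "F2", "M1", "NEG1", "NEG2",
                                   "MOCK")))
  zero[1, "MOCK"] <- 10L  # estimator needs mock reads
  tax <- taxonomy_table(data.frame(
    asv_id = c("ASV1", "ASV2"), species = c("Mock sp", "Prey sp"),
    genus = "", family = "", order = "", phylum = "Arthropoda",
    kingdom = "Animalia", species_conf = 1, genus_conf = 1, family_conf = 1,
    order_conf = 1, phylum_conf = 1, kingdom_conf = 1,
    is_mock = c(TRUE, FALSE), stringsAsFactors = FALSE))
  datasets <- list(P1_1 = toy_read_matrix(zero, rep_i = 1),
                   P1_2 = toy_read_matrix(zero, rep_i = 2))
  res <- run_cascade(datasets, tax, meta, filter_config())
  expect_identical(ncol(res$presence), 0L)
  expect_identical(nrow(res$presence), 0L)
})

test_that("negative filter removes contaminants more than it costs true prey", {
  sim <- simulate_experiment(small_sim_config(seed = 55))
  m <- sim$datasets[["Leray_1"]]
  out <- negative_control_filter(m, sim$meta)
  contam <- grepl("^ASV_CONT", rownames(m))
  spec_cols <- colnames(m)[preydna:::sample_roles(m, sim$meta) == "specimen"]
  before <- unwrap(m)[, spec_cols]
  after <- unwrap(out)[, spec_cols]
  # specificity: fraction of contaminant cells removed
  removed_contam <- sum(before[contam, ] > 0 & after[contam, ] == 0) /
    max(1, sum(before[contam, ] > 0))
  # sensitivity loss: fraction of abundant true-prey cells removed
  prey <- grepl("^ASV[0-9]", rownames(m))
  abundant <- before[prey, ] >= 50
  lost_prey <- sum(abundant & after[prey, ] == 0) / max(1, sum(abundant))
  expect_gt(removed_contam, lost_prey)
  expect_gt(removed_contam, 0.5)
})

test_that("tag-jump filter removes stray cells at a higher rate than true cells", {
  sim <- simulate_experiment(small_sim_config(seed = 77,
                                              tag_jump_rate = 0.01))
  res <- resolve_taxonomy(sim$taxonomy, filter_config())
  tbl <- collapse_to_taxa(sim$datasets[["Leray_1"]], res, sim$meta)
  rate <- estimate_tag_jump_rate(sim$datasets[c("Leray_1", "Leray_2")],
                                 sim$meta, sim$taxonomy)
  out <- tag_jump_filter(tbl, as.numeric(rate))
  # ground-truth presence of the collapsed species-level taxa
  labels <- attr(tbl, "taxa")$label
  known <- labels %in% rownames(sim$truth$presence)
  truth <- sim$truth$presence[labels[known], colnames(tbl), drop = FALSE]
  before <- unwrap(tbl)[known, , drop = FALSE]
  after <- unwrap(out)[known, , drop = FALSE]
  stray_cells <- before > 0 & truth == 0
  true_cells <- before > 0 & truth == 1
  frac_stray_removed <- sum(after[stray_cells] == 0) / max(1, sum(stray_cells))
  frac_true_removed <- sum(after[true_cells] == 0) / max(1, sum(true_cells))
  expect_gt(frac_stray_removed, frac_true_removed)
})

test_that("tag-jump estimator error shrinks with mock depth", {
  err_at_depth <- function(depth, seed) {
    sim <- simulate_experiment(small_sim_config(
      reads_per_sample = depth, seed = seed))
    est <- estimate_tag_jump_rate(sim$datasets, sim$meta, sim$taxonomy)
    # compare to the expectation conditioned on realized specimen totals,
    # so only sampling error remains
    abs(as.numeric(est) - expected_mock_stray(sim, 0.005)$rate)
  }
  shallow <- mean(vapply(1:6, function(s) err_at_depth(400, 400 + s), 0))
  deep <- mean(vapply(1:6, function(s) err_at_depth(8000, 400 + s), 0))
  expect_lt(deep, shallow)
})
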