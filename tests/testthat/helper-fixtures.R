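# Shared fixtures: everything is built in code at test time.

unwrap <- function(x) preydna:::unwrap(x)

small_sim_config <- function(seed = 101, n_female = 25, n_male = 15,
                             n_taxa = 40, reads_per_sample = 3000, ...) {
  sim_config(n_female = n_female, n_male = n_male, n_taxa = n_taxa,
             reads_per_sample = reads_per_sample, seed = seed, ...)
}

# A noise-free world: no contamination, no tag-jumping, no dropout, full
# detection, everything resolvable to species, mild overdispersion.
clean_sim_config <- function(seed = 202, ...) {
  sim_config(n_female = 12, n_male = 8, n_taxa = 20,
             reads_per_sample = 5000, overdispersion = 10,
             tag_jump_rate = 0, negative_contamination_mean = 0,
             replicate_dropout = 0, detection_prob = 1,
             predator_read_mean = 0, n_contaminant_taxa = 0,
             n_spurious_asvs = 0, prob_species_resolution = 1,
             max_asvs_per_taxon = 1, seed = seed, ...)
}

# Expected mock stray-read fraction for a simulated experiment, conditioned
# on realized specimen read totals: each read jumps with probability `rate`
# and lands in the mock column with probability 1/(N-1), so
# E[strays] = rate * T_spec / (N-1); the binomial SD follows from that.
expected_mock_stray <- function(sim, rate) {
  t_spec <- total_mock <- 0
  for (m in sim$datasets) {
    roles <- preydna:::sample_roles(m, sim$meta)
    t_spec <- t_spec + sum(unwrap(m)[, roles == "specimen", drop = FALSE])
    total_mock <- total_mock + sum(unwrap(m)[, roles == "mock", drop = FALSE])
  }
  n_cols <- ncol(sim$datasets[[1]])
  strays <- rate * t_spec / (n_cols - 1)
  list(rate = strays / total_mock, sd = sqrt(strays) / total_mock)
}

toy_meta <- function(spec = c(F1 = "female", F2 = "female", M1 = "male"),
                     negs = c("NEG1", "NEG2"), mock = "MOCK",
                     primer_sets = c("P1"), replicates = 1:2) {
  ids <- c(names(spec), negs, mock)
  base <- data.frame(
    sample_id = ids,
    role = rep(c("specimen", "negative_control", "mock"),
               c(length(spec), length(negs), length(mock))),
    sex = c(unname(spec), rep(NA_character_, length(negs) + length(mock))),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(primer_sets, function(p)
    do.call(rbind, lapply(replicates, function(r)
      cbind(base, primer_set = p, replicate = r)))))
  sample_metadata(out)
}

toy_read_matrix <- function(counts, primer = "P1", rep_i = 1) {
  read_matrix(counts, primer_set = primer, replicate = rep_i)
}

# Random binary presence matrix with sexes, guaranteed no empty specimens.
random_presence <- function(n_taxa = 12, n_f = 6, n_m = 5, p = 0.3,
                            seed = 1) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(n_taxa * (n_f + n_m), 1, p), n_taxa,
                  dimnames = list(sprintf("t%02d", 1:n_taxa),
                                  c(sprintf("F%02d", seq_len(n_f)),
                                    sprintf("M%02d", seq_len(n_m)))))
      if (all(colSums(m) > 0)) break
    }
    presence_matrix(m, setNames(rep(c("female", "male"), c(n_f, n_m)),
                                colnames(m)))
  })
}
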