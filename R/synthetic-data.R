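# Synthetic fecal-metabarcoding experiment generator.
#
# Emulates the structure of a two-primer (Leray/ANML), two-replicate COI
# diet study: sex-structured multi-prey diets with few common and many rare
# taxa, overdispersed read counts, near-zero predator carry-through
# (blocking primers), reagent contaminants shared between specimens and
# blanks, per-read tag-jumping (index cross-talk), a six-taxon mock
# community per primer set, and classifier confidences with a configurable
# resolution law.  Every run carries its ground truth so downstream stages
# have parameter-recovery tests.

#' Configuration for a synthetic metabarcoding experiment
#'
#' Defaults mirror the emulated study design: 103 female and 49 male
#' specimens, a 150-taxon prey pool with heavy-tailed prevalences (sorted
#' Beta(0.5, 9.5) draws, mean 0.05), two primer sets with two technical
#' replicates each, four negative controls, one mock sample per dataset, and
#' a 0.5% tag-jump rate (the order of the rates estimated per primer set in
#' the emulated study, 0.52%/0.82%).
#'
#' @param n_female,n_male Specimen counts per sex.
#' @param n_taxa Prey pool size.
#' @param prevalence_shape Beta shape pair for per-taxon detection
#'   probabilities, sorted decreasing (few common, many rare taxa).
#' @param sex_effect_taxa Named list `taxon -> c(female, male)` prevalence
#'   pairs overriding the shared law; `NULL` uses a built-in default of four
#'   contrasting taxa; use `list()` for a fully null (no sex effect) world.
#' @param reads_per_sample Mean sequencing depth per sample per dataset.
#' @param overdispersion Negative-binomial size parameter for per-taxon read
#'   counts (smaller = more overdispersed).
#' @param tag_jump_rate Probability that a read is misassigned to a
#'   uniformly random other sample of the same dataset.
#' @param negative_contamination_mean Expected stray reads per prey ASV in
#'   each negative control.
#' @param n_negative_controls Negative-control samples per dataset.
#' @param mock_taxa Labels of the mock-community taxa (6 by default).
#' @param mock_orders Taxonomic order of each mock taxon.
#' @param replicate_dropout Probability that a truly present taxon yields
#'   zero reads in one technical replicate.
#' @param detection_prob Per-primer-channel probability that a present taxon
#'   is amplifiable at all (shared by both replicates of that primer set).
#' @param predator_read_mean Mean predator reads per specimen (blocking
#'   primers keep this near zero).
#' @param n_contaminant_taxa,contaminant_read_mean Reagent-borne non-target
#'   (non-arthropod) taxa present in specimens and blanks alike.
#' @param n_spurious_asvs,spurious_read_mean Unclassifiable ASVs (confidence
#'   below every rank threshold) carrying a trickle of specimen reads.
#' @param prob_species_resolution Probability an ASV's confidences support
#'   species-level assignment; otherwise it resolves at a coarser rank.
#' @param max_asvs_per_taxon Taxa are represented by 1..this many ASVs.
#' @param primer_sets Dataset labels.
#' @param seed Master seed; all randomness flows through sub-streams derived
#'   from it.
#' @return A `"prey_sim_config"` list.
#' @export
sim_config <- function(n_female = 103, n_male = 49, n_taxa = 150,
                       prevalence_shape = c(0.5, 9.5),
                       sex_effect_taxa = NULL,
                       reads_per_sample = 10000,
                       overdispersion = 1,
                       tag_jump_rate = 0.005,
                       negative_contamination_mean = 0.5,
                       n_negative_controls = 4,
                       mock_taxa = c("Allocotocera pulchella",
                                     "Coenosia mollicula",
                                     "Grypotes puncticollis",
                                     "Phygadeuon sp.",
                                     "Crambus heringiellus",
                                     "Apamea remissa"),
                       mock_orders = c("Diptera", "Diptera", "Hemiptera",
                                       "Hymenoptera", "Lepidoptera",
                                       "Lepidoptera"),
                       replicate_dropout = 0.1,
                       detection_prob = 0.9,
                       predator_read_mean = 0.5,
                       n_contaminant_taxa = 8,
                       contaminant_read_mean = 25,
                       n_spurious_asvs = 6,
                       spurious_read_mean = 3,
                       prob_species_resolution = 0.7,
                       max_asvs_per_taxon = 3,
                       primer_sets = c("Leray", "ANML"),
                       seed = 1) {
  if (is.null(sex_effect_taxa)) {
    sex_effect_taxa <- list(Taxon001 = c(female = 0.30, male = 0.10),
                            Taxon002 = c(female = 0.10, male = 0.30),
                            Taxon003 = c(female = 0.25, male = 0.08),
                            Taxon004 = c(female = 0.08, male = 0.25))
  }
  cfg <- list(n_female = as.integer(n_female), n_male = as.integer(n_male),
              n_taxa = as.integer(n_taxa),
              prevalence_shape = prevalence_shape,
              sex_effect_taxa = sex_effect_taxa,
              reads_per_sample = reads_per_sample,
              overdispersion = overdispersion,
              tag_jump_rate = tag_jump_rate,
              negative_contamination_mean = negative_contamination_mean,
              n_negative_controls = as.integer(n_negative_controls),
              mock_taxa = mock_taxa, mock_orders = mock_orders,
              replicate_dropout = replicate_dropout,
              detection_prob = detection_prob,
              predator_read_mean = predator_read_mean,
              n_contaminant_taxa = as.integer(n_contaminant_taxa),
              contaminant_read_mean = contaminant_read_mean,
              n_spurious_asvs = as.integer(n_spurious_asvs),
              spurious_read_mean = spurious_read_mean,
              prob_species_resolution = prob_species_resolution,
              max_asvs_per_taxon = as.integer(max_asvs_per_taxon),
              primer_sets = primer_sets, seed = as.integer(seed))
  probs <- c(tag_jump_rate, replicate_dropout, detection_prob,
             prob_species_resolution)
  if (any(probs < 0 | probs > 1))
    pd_config_error("probabilities must lie in [0, 1]")
  if (tag_jump_rate > 0.05)
    pd_config_error("tag_jump_rate above 0.05 is outside the supported range")
  if (reads_per_sample <= 0) pd_config_error("reads_per_sample must be > 0")
  if (cfg$n_taxa < length(sex_effect_taxa))
    pd_config_error("n_taxa is smaller than the number of sex_effect_taxa")
  if (length(mock_taxa) != length(mock_orders))
    pd_config_error("mock_taxa and mock_orders must have equal length")
  class(cfg) <- "prey_sim_config"
  cfg
}

# Uniform per-read misassignment within one dataset: each read moves to a
# uniformly chosen *other* column with probability `rate`.  Row (ASV) totals
# and the grand total are conserved.  Returns the jumped matrix plus the
# number of reads moved.
tag_jump_apply <- function(mat, rate) {
  n <- ncol(mat)
  if (rate <= 0 || n < 2) return(list(mat = mat, moved = 0L))
  moved_total <- 0L
  for (i in which(rowSums(mat) > 0)) {
    row <- mat[i, ]
    moved <- stats::rbinom(n, row, rate)
    if (!any(moved > 0)) next
    row <- row - moved
    for (j in which(moved > 0)) {
      dest <- sample((1:n)[-j], moved[j], replace = TRUE)
      row <- row + tabulate(dest, n)
    }
    mat[i, ] <- row
    moved_total <- moved_total + sum(moved)
  }
  list(mat = mat, moved = moved_total)
}

# Monotone confidence chain order >= family >= genus >= species (and
# kingdom >= phylum >= order), optionally degraded so the ASV resolves at a
# coarser rank.
draw_confidences <- function(n, p_species) {
  ord <- stats::runif(n, 0.85, 1)
  fam <- ord * stats::runif(n, 0.85, 1)
  gen <- fam * stats::runif(n, 0.85, 1)
  spe <- gen * stats::runif(n, 0.85, 1)
  degrade <- stats::runif(n) > p_species
  spe[degrade] <- pmin(spe[degrade], stats::runif(sum(degrade), 0.02, 0.40))
  deeper <- degrade & stats::runif(n) < 0.3
  gen[deeper] <- pmin(gen[deeper], stats::runif(sum(deeper), 0.02, 0.35))
  spe <- pmin(spe, gen)
  data.frame(order_conf = ord, family_conf = fam, genus_conf = gen,
             species_conf = spe, phylum_conf = sqrt(ord),
             kingdom_conf = sqrt(sqrt(ord)))
}

#' Simulate a complete synthetic metabarcoding experiment
#'
#' Generation order per dataset (primer set x replicate) is fixed: (1) draw
#' each specimen's true diet by per-taxon, per-sex Bernoulli; (2) draw clean
#' read counts for present, channel-detected, non-dropout taxa from a
#' negative-binomial law scaled to depth and split them over the taxon's
#' ASVs; (3) add near-zero predator reads plus reagent contaminant and
#' spurious-ASV reads to specimen columns; (4) move each read to a uniformly
#' random other sample with probability `tag_jump_rate`; (5) populate
#' negative controls with low-rate contamination; (6) populate the mock
#' sample from the mock taxa (its non-mock content is exactly the strays
#' that jumped in at step 4); (7) replicate dropout is applied independently
#' per replicate at step 2; (8) emit taxonomy with confidences from the
#' resolution law. The same seed yields bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `datasets` (named `"<primer>_<rep>"` list of
#'   [read_matrix()]), `taxonomy`, `meta`, `truth` (true presence, per-sex
#'   prevalence vectors, realized tag-jump fraction per primer set, taxon
#'   pool), and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 8)
  n_spec <- cfg$n_female + cfg$n_male
  spec_ids <- c(sprintf("F%03d", seq_len(cfg$n_female)),
                sprintf("M%03d", seq_len(cfg$n_male)))
  sex <- rep(c("female", "male"), c(cfg$n_female, cfg$n_male))
  neg_ids <- sprintf("NEG%d", seq_len(cfg$n_negative_controls))
  mock_id <- "MOCK"
  all_ids <- c(spec_ids, neg_ids, mock_id)

  ## -- taxon pool, prevalences, ASV map, taxonomy structure ---------------
  pool <- with_seed(seeds[1], {
    orders <- c("Diptera", "Araneae", "Hemiptera", "Coleoptera",
                "Lepidoptera", "Hymenoptera", "Trichoptera", "Psocodea",
                "Thysanoptera", "Orthoptera")
    ord <- sample(orders, cfg$n_taxa, replace = TRUE,
                  prob = c(30, 15, 15, 10, 8, 7, 5, 4, 3, 3))
    prev <- sort(stats::rbeta(cfg$n_taxa, cfg$prevalence_shape[1],
                              cfg$prevalence_shape[2]), decreasing = TRUE)
    taxa <- data.frame(
      taxon = sprintf("Taxon%03d", seq_len(cfg$n_taxa)),
      genus = sprintf("Genus%03d", seq_len(cfg$n_taxa)),
      family = paste0(ord, "_family_", 1 + (seq_len(cfg$n_taxa) %% 5)),
      order = ord, prevalence = prev, stringsAsFactors = FALSE)
    p_f <- p_m <- prev
    names(p_f) <- names(p_m) <- taxa$taxon
    for (nm in names(cfg$sex_effect_taxa)) {
      if (!nm %in% taxa$taxon)
        pd_config_error(sprintf("sex_effect_taxa names unknown taxon %s",
                                sQuote(nm)))
      p_f[nm] <- cfg$sex_effect_taxa[[nm]][1]
      p_m[nm] <- cfg$sex_effect_taxa[[nm]][2]
    }
    n_asv <- sample(seq_len(cfg$max_asvs_per_taxon), cfg$n_taxa,
                    replace = TRUE,
                    prob = c(0.6, 0.3, 0.1)[seq_len(cfg$max_asvs_per_taxon)])
    list(taxa = taxa, p_f = p_f, p_m = p_m, n_asv = n_asv)
  })
  taxa <- pool$taxa

  ## -- true diets ---------------------------------------------------------
  truth_presence <- with_seed(seeds[2], {
    p <- ifelse(matrix(sex == "female", cfg$n_taxa, n_spec, byrow = TRUE),
                pool$p_f, pool$p_m)
    m <- matrix(as.integer(stats::runif(length(p)) < p), cfg$n_taxa, n_spec,
                dimnames = list(taxa$taxon, spec_ids))
    m
  })

  ## -- ASV universe -------------------------------------------------------
  asv <- with_seed(seeds[3], {
    taxon_of <- rep(seq_len(cfg$n_taxa), pool$n_asv)
    ids <- sprintf("ASV%04d", seq_along(taxon_of))
    w <- stats::rgamma(length(taxon_of), shape = 2)
    w <- unlist(lapply(split(w, taxon_of), function(x) x / sum(x)),
                use.names = FALSE)
    list(ids = ids, taxon_of = taxon_of, weight = w)
  })
  mock_asvs <- sprintf("ASV_MOCK%d", seq_along(cfg$mock_taxa))
  contam_asvs <- if (cfg$n_contaminant_taxa)
    sprintf("ASV_CONT%02d", seq_len(cfg$n_contaminant_taxa)) else character()
  spur_asvs <- if (cfg$n_spurious_asvs)
    sprintf("ASV_SPUR%02d", seq_len(cfg$n_spurious_asvs)) else character()
  pred_asv <- "ASV_PRED"
  all_asvs <- c(asv$ids, mock_asvs, contam_asvs, spur_asvs, pred_asv)

  ## -- taxonomy table -----------------------------------------------------
  taxonomy <- with_seed(seeds[4], {
    conf_prey <- draw_confidences(length(asv$ids), cfg$prob_species_resolution)
    t_of <- asv$taxon_of
    prey <- data.frame(asv_id = asv$ids, species = taxa$taxon[t_of],
                       genus = taxa$genus[t_of], family = taxa$family[t_of],
                       order = taxa$order[t_of], phylum = "Arthropoda",
                       kingdom = "Animalia", conf_prey, is_mock = FALSE,
                       stringsAsFactors = FALSE)
    conf_hi <- draw_confidences(length(mock_asvs) + 1, 1)
    mock <- data.frame(asv_id = mock_asvs, species = cfg$mock_taxa,
                       genus = sub(" .*", "", cfg$mock_taxa),
                       family = paste0(cfg$mock_orders, "_family_0"),
                       order = cfg$mock_orders, phylum = "Arthropoda",
                       kingdom = "Animalia",
                       conf_hi[seq_along(mock_asvs), ], is_mock = TRUE,
                       stringsAsFactors = FALSE)
    pred <- data.frame(asv_id = pred_asv, species = "Leucorrhinia intacta",
                       genus = "Leucorrhinia", family = "Libellulidae",
                       order = "Odonata", phylum = "Arthropoda",
                       kingdom = "Animalia",
                       conf_hi[nrow(conf_hi), , drop = FALSE],
                       is_mock = FALSE, stringsAsFactors = FALSE)
    parts <- list(prey, mock, pred)
    if (length(contam_asvs)) {
      conf_c <- draw_confidences(length(contam_asvs), 1)
      parts <- c(parts, list(data.frame(
        asv_id = contam_asvs,
        species = sprintf("Contaminant%02d", seq_along(contam_asvs)),
        genus = sprintf("Contagenus%02d", seq_along(contam_asvs)),
        family = "Hypocreaceae", order = "Hypocreales",
        phylum = "Ascomycota", kingdom = "Fungi", conf_c,
        is_mock = FALSE, stringsAsFactors = FALSE)))
    }
    if (length(spur_asvs)) {
      ordc <- stats::runif(length(spur_asvs), 0.01, 0.15)
      conf_s <- data.frame(order_conf = ordc, family_conf = ordc * 0.9,
                           genus_conf = ordc * 0.8, species_conf = ordc * 0.7,
                           phylum_conf = sqrt(ordc),
                           kingdom_conf = sqrt(sqrt(ordc)))
      parts <- c(parts, list(data.frame(
        asv_id = spur_asvs, species = "", genus = "", family = "",
        order = "", phylum = "", kingdom = "", conf_s,
        is_mock = FALSE, stringsAsFactors = FALSE)))
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    names(out) <- sub("^conf_", "", names(out))
    taxonomy_table(out)
  })

  ## -- detection channels (shared between replicates of a primer set) -----
  detect <- with_seed(seeds[5], {
    out <- lapply(cfg$primer_sets, function(p)
      matrix(stats::runif(cfg$n_taxa * n_spec) < cfg$detection_prob,
             cfg$n_taxa, n_spec))
    names(out) <- cfg$primer_sets
    out
  })

  ## -- read matrices ------------------------------------------------------
  n_all <- length(all_ids)
  dataset_names <- as.vector(outer(cfg$primer_sets, 1:2, paste, sep = "_"))
  ds_seeds <- derive_seeds(seeds[6], length(dataset_names))
  datasets <- list()
  moved <- total_prejump <- stats::setNames(numeric(length(cfg$primer_sets)),
                                            cfg$primer_sets)
  k <- 0
  for (primer in cfg$primer_sets) for (rep_i in 1:2) {
    k <- k + 1
    datasets[[dataset_names[k]]] <- with_seed(ds_seeds[k], {
      mat <- matrix(0L, length(all_asvs), n_all,
                    dimnames = list(all_asvs, all_ids))
      # (2) clean prey reads with channel detection and replicate dropout
      active <- truth_presence == 1L & detect[[primer]] &
        matrix(stats::runif(cfg$n_taxa * n_spec) >= cfg$replicate_dropout,
               cfg$n_taxa, n_spec)
      for (s in seq_len(n_spec)) {
        tx <- which(active[, s])
        if (!length(tx)) next
        w <- stats::rgamma(length(tx), shape = 1)
        mu <- cfg$reads_per_sample * w / sum(w)
        reads <- stats::rnbinom(length(tx), mu = mu,
                                size = cfg$overdispersion)
        for (i in seq_along(tx)) {
          if (reads[i] == 0) next
          rows <- which(asv$taxon_of == tx[i])
          if (length(rows) == 1) {
            mat[rows, s] <- mat[rows, s] + reads[i]
          } else {
            split_r <- stats::rmultinom(1, reads[i], asv$weight[rows])[, 1]
            mat[rows, s] <- mat[rows, s] + split_r
          }
        }
      }
      # (3) predator, reagent-contaminant and spurious reads in specimens
      mat[pred_asv, seq_len(n_spec)] <-
        stats::rpois(n_spec, cfg$predator_read_mean)
      if (length(contam_asvs))
        mat[contam_asvs, seq_len(n_spec)] <-
          mat[contam_asvs, seq_len(n_spec)] +
          stats::rpois(length(contam_asvs) * n_spec,
                       cfg$contaminant_read_mean)
      if (length(spur_asvs))
        mat[spur_asvs, seq_len(n_spec)] <-
          mat[spur_asvs, seq_len(n_spec)] +
          stats::rpois(length(spur_asvs) * n_spec, cfg$spurious_read_mean)
      # (4) tag-jumping across all columns of this dataset
      pre <- sum(mat)
      tj <- tag_jump_apply(mat, cfg$tag_jump_rate)
      mat <- tj$mat
      # the braces evaluate in this function's frame, so plain assignment
      # updates the per-primer accumulators
      moved[primer] <- moved[primer] + tj$moved
      total_prejump[primer] <- total_prejump[primer] + pre
      # (5) negative-control contamination
      if (length(neg_ids)) {
        mat[asv$ids, neg_ids] <- mat[asv$ids, neg_ids] +
          stats::rpois(length(asv$ids) * length(neg_ids),
                       cfg$negative_contamination_mean)
        if (length(contam_asvs))
          mat[contam_asvs, neg_ids] <- mat[contam_asvs, neg_ids] +
            stats::rpois(length(contam_asvs) * length(neg_ids),
                         cfg$contaminant_read_mean)
      }
      # (6) mock community
      mock_w <- stats::rgamma(length(mock_asvs), shape = 5)
      mat[mock_asvs, mock_id] <- mat[mock_asvs, mock_id] +
        stats::rmultinom(1, cfg$reads_per_sample, mock_w)[, 1]
      read_matrix(mat, primer_set = primer, replicate = rep_i)
    })
  }

  ## -- metadata -----------------------------------------------------------
  meta1 <- data.frame(sample_id = all_ids,
                      role = rep(c("specimen", "negative_control", "mock"),
                                 c(n_spec, length(neg_ids), 1)),
                      sex = c(sex, rep(NA_character_, length(neg_ids) + 1)),
                      stringsAsFactors = FALSE)
  meta <- do.call(rbind, lapply(cfg$primer_sets, function(p)
    do.call(rbind, lapply(1:2, function(r)
      cbind(meta1, primer_set = p, replicate = r)))))
  meta <- sample_metadata(meta)

  truth <- list(
    presence = truth_presence,
    prevalence_female = pool$p_f, prevalence_male = pool$p_m,
    empirical_prevalence_female =
      rowMeans(truth_presence[, sex == "female", drop = FALSE]),
    empirical_prevalence_male =
      rowMeans(truth_presence[, sex == "male", drop = FALSE]),
    tag_jump_realized = ifelse(total_prejump > 0, moved / total_prejump, 0),
    taxa = taxa)
  list(datasets = datasets, taxonomy = taxonomy, meta = meta,
       truth = truth, config = cfg)
}

#' Simulate a null experiment (no sex effect)
#'
#' Identical to [simulate_experiment()] but with an empty sex-effect map, so
#' both sexes share one prevalence vector. Used for type-I-error studies of
#' the downstream tests.
#'
#' @param config A [sim_config()]; its `sex_effect_taxa` is ignored.
#' @return As [simulate_experiment()].
#' @export
null_experiment <- function(config = sim_config()) {
  config$sex_effect_taxa <- list()
  simulate_experiment(config)
}

#' Write a simulated experiment to a directory
#'
#' Emits the canonical file set: `counts.<primer>.<rep>.tsv` per dataset,
#' `taxonomy.tsv`, `metadata.tsv` and `ground_truth.tsv` (true presence).
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$datasets)) {
    m <- sim$datasets[[nm]]
    write_count_table(m, file.path(dir, sprintf(
      "counts.%s.%d.tsv", attr(m, "primer_set"), attr(m, "replicate"))))
  }
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  gt <- data.frame(taxon = rownames(sim$truth$presence),
                   sim$truth$presence, check.names = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
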