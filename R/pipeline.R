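# Orchestration: config-driven end-to-end runs and the command-line entry
# point (subcommands: simulate, clean, prevalence, community, all).

#' Run configuration with the canonical statistical settings
#'
#' Defaults equal the analysis settings of the emulated study: alpha 0.05,
#' 10,000 PERMANOVA permutations, 200 assemblage-test iterations, 1,000
#' accumulation randomizations.
#'
#' @param alpha Significance level.
#' @param permutations PERMANOVA permutations.
#' @param ecotest_iterations Assemblage-test reshufflings.
#' @param randomizations Accumulation-curve orderings.
#' @param bootstrap_B BCa bootstrap resamples.
#' @param seed Master seed.
#' @param filter A [filter_config()].
#' @param sim A [sim_config()] or `NULL`.
#' @return A `"prey_run_config"` list.
#' @export
run_config <- function(alpha = 0.05, permutations = 10000,
                       ecotest_iterations = 200, randomizations = 1000,
                       bootstrap_B = 2000, seed = 1,
                       filter = filter_config(), sim = NULL) {
  structure(list(alpha = alpha, permutations = as.integer(permutations),
                 ecotest_iterations = as.integer(ecotest_iterations),
                 randomizations = as.integer(randomizations),
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), filter = filter, sim = sim),
            class = "prey_run_config")
}

#' Read a YAML (or JSON) run configuration
#'
#' Recognized top-level keys: `alpha`, `permutations`, `ecotest_iterations`,
#' `randomizations`, `bootstrap_B`, `seed`, `filter` (fields of
#' [filter_config()]), `sim` (fields of [sim_config()]).
#'
#' @param path File path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) pd_parse_error(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  fc <- if (!is.null(raw$filter)) {
    f <- raw$filter
    if (!is.null(f$rank_thresholds)) f$rank_thresholds <- unlist(f$rank_thresholds)
    do.call(filter_config, f)
  } else filter_config()
  sc <- if (!is.null(raw$sim)) {
    s <- raw$sim
    if (!is.null(s$sex_effect_taxa))
      s$sex_effect_taxa <- lapply(s$sex_effect_taxa, unlist)
    do.call(sim_config, s)
  } else NULL
  args <- raw[intersect(names(raw), c("alpha", "permutations",
                                      "ecotest_iterations", "randomizations",
                                      "bootstrap_B", "seed"))]
  do.call(run_config, c(args, list(filter = fc, sim = sc)))
}

read_input_dir <- function(dir) {
  for (f in c("taxonomy.tsv", "metadata.tsv"))
    if (!file.exists(file.path(dir, f)))
      pd_validation_error(sprintf("missing input file: %s",
                                  file.path(dir, f)))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  files <- list.files(dir, pattern = "^counts\\..+\\.[12]\\.tsv$")
  if (!length(files))
    pd_validation_error(sprintf("no counts.<primer>.<rep>.tsv files in %s",
                                dir))
  datasets <- list()
  for (f in files) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    primer <- paste(parts[2:(length(parts) - 2)], collapse = ".")
    rep_i <- as.integer(parts[length(parts) - 1])
    datasets[[sprintf("%s_%d", primer, rep_i)]] <-
      read_count_table(file.path(dir, f), primer, rep_i, meta = meta)
  }
  list(datasets = datasets, tax = tax, meta = meta)
}

#' Run the full pipeline into a directory
#'
#' Simulates (when `config$sim` is set) or reads the input file set, runs
#' the decontamination cascade, the prevalence table and the community
#' statistics, and writes: the cleaned presence matrix, the cascade report
#' (JSON), a prevalence TSV, a community-results JSON, accumulation curves
#' (long-format TSV) and a run manifest. Reruns with the same config and
#' seed are bit-identical.
#'
#' @param config A [run_config()].
#' @param input_dir Directory with the canonical input file set (ignored
#'   when simulating).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config, input_dir = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- seeds[1]
    sim <- sim_config_reseed(sim)
    experiment <- simulate_experiment(sim)
    write_experiment(experiment, file.path(out_dir, "input"))
    datasets <- experiment$datasets
    tax <- experiment$taxonomy
    meta <- experiment$meta
  } else {
    if (is.null(input_dir))
      pd_validation_error("input_dir is required when not simulating")
    inp <- read_input_dir(input_dir)
    datasets <- inp$datasets; tax <- inp$tax; meta <- inp$meta
  }
  cascade <- run_cascade(datasets, tax, meta, config$filter)
  pm <- cascade$presence
  write_presence(pm, file.path(out_dir, "presence.tsv"))
  report <- cascade$report
  jsonlite::write_json(
    list(stages = report$stages,
         tag_jump_rate = as.list(report$tag_jump_rate),
         removed_nontarget = report$removed_nontarget,
         dropped_specimens = report$dropped_specimens,
         n_taxa = report$n_taxa, n_specimens = report$n_specimens),
    file.path(out_dir, "cascade_report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  prev <- prevalence_table(pm, alpha = config$alpha)
  utils::write.table(prev, file.path(out_dir, "prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sex <- attr(pm, "sex")
  d <- pairwise_distances(pm)
  perm <- permanova(d, n_perm = config$permutations, seed = seeds[2])
  disp <- dispersion_homogeneity(d, n_perm = min(config$permutations, 999),
                                 seed = seeds[3])
  eco <- assemblage_ecotest(pm, iterations = config$ecotest_iterations,
                            seed = seeds[4])
  md <- mean_dissimilarity(d, B = config$bootstrap_B,
                           alpha = config$alpha, seed = seeds[5])
  rich <- richness_per_sample(pm)
  mw <- mann_whitney(rich[sex == "female"], rich[sex == "male"])
  rb_seeds <- derive_seeds(seeds[6], 3)
  rich_ci <- list(
    female = bca_bootstrap_ci(rich[sex == "female"], B = config$bootstrap_B,
                              alpha = config$alpha, seed = rb_seeds[1]),
    male = bca_bootstrap_ci(rich[sex == "male"], B = config$bootstrap_B,
                            alpha = config$alpha, seed = rb_seeds[2]))
  acc <- lapply(split(colnames(pm), sex), function(ids)
    accumulation_ensemble(pm[, ids], R = config$randomizations,
                          seed = rb_seeds[3]))
  acc_long <- do.call(rbind, lapply(names(acc), function(g) {
    cv <- acc[[g]]$curves
    data.frame(group = g,
               randomization = rep(seq_len(nrow(cv)), ncol(cv)),
               m = rep(seq_len(ncol(cv)), each = nrow(cv)),
               richness = as.vector(cv))
  }))
  utils::write.table(acc_long, file.path(out_dir, "accumulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  community <- list(
    mean_dissimilarity = md$mean,
    mean_dissimilarity_ci = as.list(md$ci),
    permanova = list(F = perm$statistic, R2 = perm$R2, df = perm$df,
                     p = perm$p, n_permutations = perm$n_permutations),
    dispersion = list(F = disp$statistic, df = disp$df, p = disp$p,
                      p_f = disp$p_f),
    ecotest = list(statistic = eco$statistic, p = eco$p,
                   iterations = eco$n_permutations),
    richness = list(mean_female = mean(rich[sex == "female"]),
                    mean_male = mean(rich[sex == "male"]),
                    ci_female = as.list(rich_ci$female),
                    ci_male = as.list(rich_ci$male),
                    mann_whitney = mw))
  jsonlite::write_json(community, file.path(out_dir, "community.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("preydna")),
    seed = config$seed,
    settings = config[c("alpha", "permutations", "ecotest_iterations",
                        "randomizations", "bootstrap_B")],
    filter = unclass(config$filter),
    simulated = !is.null(config$sim),
    config_hash = content_hash(jsonlite::toJSON(
      unclass_recursive(config), auto_unbox = TRUE, digits = NA)),
    n_taxa = nrow(pm), n_specimens = ncol(pm))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(presence = pm, report = report, prevalence = prev,
                 community = community, manifest = manifest))
}

# re-validate a sim config after field surgery
sim_config_reseed <- function(cfg) {
  do.call(sim_config, unclass(cfg))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `clean`, `prevalence`, `community`, `all`.
#' Shared options: `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--in <dir>` (inputs), plus `--simulate` for `all`.
#' Exit codes: 0 ok, 2 validation/config error, 3 runtime error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
preydna_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: preydna <simulate|clean|prevalence|community|all>",
    "[--config FILE] [--in DIR] [--out DIR] [--seed N] [--simulate]")
  code <- tryCatch({
    if (!length(args)) { message(usage); return(invisible(2L)) }
    cmd <- args[1]
    opt <- parse_cli_opts(args[-1])
    config <- if (!is.null(opt$config)) read_run_config(opt$config)
    else run_config()
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    switch(cmd,
      simulate = {
        sim <- config$sim %||% sim_config()
        sim$seed <- config$seed
        write_experiment(simulate_experiment(sim_config_reseed(sim)),
                         opt$out %||% ".")
      },
      clean = {
        inp <- read_input_dir(opt$`in` %||% ".")
        out_dir <- opt$out %||% "."
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        res <- run_cascade(inp$datasets, inp$tax, inp$meta, config$filter)
        write_presence(res$presence, file.path(out_dir, "presence.tsv"))
        jsonlite::write_json(
          list(stages = res$report$stages,
               tag_jump_rate = as.list(res$report$tag_jump_rate)),
          file.path(out_dir, "cascade_report.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      prevalence = {
        meta <- read_metadata(opt$meta %||% file.path(opt$`in` %||% ".",
                                                      "metadata.tsv"))
        pm <- read_presence(opt$presence %||% file.path(opt$`in` %||% ".",
                                                        "presence.tsv"), meta)
        tbl <- prevalence_table(pm, top = as_int_or_null(opt$top),
                                alpha = config$alpha)
        utils::write.table(tbl, opt$out %||% stdout(), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      community = {
        config$sim <- NULL
        meta <- read_metadata(opt$meta %||% file.path(opt$`in` %||% ".",
                                                      "metadata.tsv"))
        pm <- read_presence(opt$presence %||% file.path(opt$`in` %||% ".",
                                                        "presence.tsv"), meta)
        seeds <- derive_seeds(config$seed, 3)
        d <- pairwise_distances(pm)
        out <- list(
          permanova = unclass(permanova(d, n_perm = config$permutations,
                                        seed = seeds[1]))[
            c("statistic", "R2", "df", "p")],
          dispersion = unclass(dispersion_homogeneity(
            d, n_perm = min(config$permutations, 999),
            seed = seeds[2]))[c("statistic", "df", "p", "p_f")],
          ecotest = unclass(assemblage_ecotest(
            pm, iterations = config$ecotest_iterations,
            seed = seeds[3]))[c("statistic", "p")])
        jsonlite::write_json(out, opt$out %||% "community.json",
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      all = {
        if (is.null(config$sim) && isTRUE(opt$simulate))
          config$sim <- sim_config()
        run_all(config, input_dir = opt$`in`, out_dir = opt$out %||% "run")
      },
      { message(usage); return(invisible(2L)) })
    0L
  },
  preydna_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  invisible(code)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--simulate") { opt$simulate <- TRUE; i <- i + 1; next }
    if (!startsWith(a, "--"))
      pd_validation_error(sprintf("unexpected argument %s", sQuote(a)))
    if (i == length(args))
      pd_validation_error(sprintf("option %s needs a value", sQuote(a)))
    opt[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opt
}

as_int_or_null <- function(x) if (is.null(x)) NULL else as.integer(x)
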