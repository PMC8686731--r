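# The decontamination cascade: raw ASV x sample read matrices -> merged,
# cleaned taxon x specimen table -> prey presence/absence.
#
# Canonical stage order (enforced by run_cascade): negative-control filter
# per dataset -> taxonomy resolution -> ASV collapse -> replicate
# consistency filter per primer set -> non-target removal -> tag-jump
# estimation and filter per primer set -> primer-set merge -> removal of
# mock and excluded taxa -> presence/absence.  Every filter is a pointwise
# non-increasing map on counts; the stages do not commute.

#' Remove reads explainable by negative-control contamination
#'
#' For every ASV the removal threshold is the maximum read count observed
#' for that ASV across all negative controls of the dataset; every specimen
#' cell at or below the threshold is zeroed. Reads at the threshold are
#' indistinguishable from contamination, so ties are removed.
#' Negative-control and mock columns are retained unchanged (mocks feed the
#' tag-jump estimator, which must see the stray reads).
#'
#' @param m A [read_matrix()].
#' @param meta [sample_metadata()] identifying the negative controls.
#' @return The filtered [read_matrix()].
#' @export
negative_control_filter <- function(m, meta) {
  roles <- sample_roles(m, meta)
  neg <- colnames(m)[roles == "negative_control"]
  if (!length(neg)) {
    warning("no negative controls in dataset; negative filter is a no-op",
            call. = FALSE)
    return(m)
  }
  thr <- apply(unwrap(m)[, neg, drop = FALSE], 1, max)
  spec_cols <- colnames(m)[roles == "specimen"]
  out <- unwrap(m)
  sub <- out[, spec_cols, drop = FALSE]
  sub[sub <= thr] <- 0L  # thr recycles down columns: per-ASV threshold
  out[, spec_cols] <- sub
  read_matrix(out, attr(m, "primer_set"), attr(m, "replicate"))
}

sample_roles <- function(m, meta) {
  mm <- meta[meta$primer_set == attr(m, "primer_set") &
               meta$replicate == attr(m, "replicate"), ]
  lut <- stats::setNames(mm$role, mm$sample_id)
  miss <- setdiff(colnames(m), names(lut))
  if (length(miss))
    pd_validation_error(sprintf("sample(s) missing from metadata: %s",
                                paste(sQuote(miss), collapse = ", ")))
  lut[colnames(m)]
}

#' Resolve each ASV to its deepest trustworthy rank
#'
#' Acceptance ladder: assign at species if the species confidence reaches
#' its threshold, else demote to genus, family, then order; an ASV whose
#' order confidence is below the order threshold is discarded. A missing
#' label at an otherwise acceptable rank demotes further.
#'
#' @param tax A [taxonomy_table()].
#' @param cfg A [filter_config()] supplying `rank_thresholds`.
#' @return Data.frame with one row per ASV: `asv_id`, `rank`, `label`
#'   (rank `"DISCARD"` and empty label for discarded ASVs).
#' @export
resolve_taxonomy <- function(tax, cfg = filter_config()) {
  th <- cfg$rank_thresholds
  n <- nrow(tax)
  rank <- rep("DISCARD", n)
  label <- rep("", n)
  for (r in c("species", "genus", "family", "order")) {
    open <- rank == "DISCARD"
    ok <- open & tax[[paste0(r, "_conf")]] >= th[[r]] & nzchar(tax[[r]])
    rank[ok] <- r
    label[ok] <- tax[[r]][ok]
  }
  data.frame(asv_id = tax$asv_id, rank = rank, label = label,
             stringsAsFactors = FALSE)
}

#' Collapse ASV counts into resolved-taxon counts
#'
#' Reads of all ASVs resolved to the same (rank, label) are summed within
#' each sample; discarded ASVs are dropped. Only specimen columns are
#' retained in the resulting [taxon_table()].
#'
#' @param m A [read_matrix()] (typically negative-filtered).
#' @param resolution Output of [resolve_taxonomy()] covering all ASVs of `m`.
#' @param meta [sample_metadata()] used to keep specimen columns only.
#' @return A [taxon_table()].
#' @export
collapse_to_taxa <- function(m, resolution, meta) {
  res <- resolution[match(rownames(m), resolution$asv_id), ]
  if (anyNA(res$asv_id))
    pd_validation_error("resolution does not cover all ASVs in the matrix")
  keep <- res$rank != "DISCARD"
  roles <- sample_roles(m, meta)
  spec_cols <- colnames(m)[roles == "specimen"]
  sub <- unwrap(m)[keep, spec_cols, drop = FALSE]
  key <- taxon_key(res$rank[keep], res$label[keep])
  agg <- rowsum(sub, key)
  first <- !duplicated(key)
  taxa <- data.frame(rank = res$rank[keep][first],
                     label = res$label[keep][first])
  taxa <- taxa[match(rownames(agg), taxon_key(taxa$rank, taxa$label)), ]
  taxon_table(agg, taxa, provenance = attr(m, "primer_set"))
}

# Outer-align two taxon tables on the union of taxa and samples (absent = 0).
align_tables <- function(a, b) {
  taxa_a <- attr(a, "taxa"); taxa_b <- attr(b, "taxa")
  keys <- union(rownames(a), rownames(b))
  samples <- union(colnames(a), colnames(b))
  expand <- function(x) {
    out <- matrix(0L, length(keys), length(samples),
                  dimnames = list(keys, samples))
    out[rownames(x), colnames(x)] <- unwrap(x)
    out
  }
  taxa <- rbind(taxa_a, taxa_b)
  taxa <- taxa[!duplicated(taxon_key(taxa$rank, taxa$label)), ]
  taxa <- taxa[match(keys, taxon_key(taxa$rank, taxa$label)), ]
  list(a = expand(a), b = expand(b), taxa = taxa, samples = samples)
}

#' Keep only detections confirmed in both technical replicates
#'
#' A (taxon, sample) cell is retained only if both replicates produced at
#' least one read; retained cells carry the summed reads of the two
#' replicates.
#'
#' @param rep1,rep2 [taxon_table()]s from replicates 1 and 2 of the same
#'   primer set.
#' @return A [taxon_table()].
#' @export
replicate_consistency_filter <- function(rep1, rep2) {
  al <- align_tables(rep1, rep2)
  out <- al$a + al$b
  out[al$a == 0L | al$b == 0L] <- 0L
  taxon_table(out, al$taxa,
              provenance = unique(c(attr(rep1, "provenance"),
                                    attr(rep2, "provenance"))))
}

#' Remove taxa outside the target phylum
#'
#' Keeps taxa whose phylum (looked up from the taxonomy of their member
#' ASVs) equals `cfg$target_phylum`; typically removes fungi, bacteria and
#' other non-arthropod amplification by-products.
#'
#' @param t A [taxon_table()].
#' @param tax A [taxonomy_table()] supplying phylum labels.
#' @param cfg A [filter_config()].
#' @return The filtered [taxon_table()]; the removed read fraction is
#'   available as attribute `removed_fraction`.
#' @export
remove_nontarget <- function(t, tax, cfg = filter_config()) {
  phyla <- taxon_phylum(t, tax)
  keep <- !is.na(phyla) & phyla == cfg$target_phylum
  total <- sum(t)
  out <- taxon_table(unwrap(t)[keep, , drop = FALSE],
                     attr(t, "taxa")[keep, , drop = FALSE],
                     provenance = attr(t, "provenance"))
  attr(out, "removed_fraction") <-
    if (total > 0) 1 - sum(out) / total else 0
  attr(out, "removed_taxa") <- attr(t, "taxa")$label[!keep]
  out
}

# Phylum of each resolved taxon, by majority over the ASVs carrying the
# taxon's (rank, label) in the taxonomy.
taxon_phylum <- function(t, tax) {
  taxa <- attr(t, "taxa")
  vapply(seq_len(nrow(taxa)), function(i) {
    r <- taxa$rank[i]
    hit <- tax$phylum[tax[[r]] == taxa$label[i]]
    if (!length(hit)) NA_character_ else names(sort(table(hit),
                                                    decreasing = TRUE))[1]
  }, character(1))
}

#' Estimate the tag-jump (index cross-talk) rate from mock samples
#'
#' The mock community has known composition, so any read in a mock sample
#' assigned to a non-mock ASV must have been misassigned across samples.
#' The rate is the proportion of non-mock reads out of all reads in the
#' dataset's mock samples; with multiple matrices (e.g. both replicates of
#' a primer set), reads are pooled before dividing.
#'
#' @param mats A [read_matrix()] or list of them (same primer set).
#' @param meta [sample_metadata()] identifying mock samples.
#' @param tax A [taxonomy_table()]; ASVs with `is_mock = TRUE` count as mock.
#' @return The rate in \[0, 1\], with attributes `non_mock_reads` and
#'   `total_mock_reads`.
#' @export
estimate_tag_jump_rate <- function(mats, meta, tax) {
  if (inherits(mats, "prey_read_matrix")) mats <- list(mats)
  non_mock <- total <- 0
  for (m in mats) {
    roles <- sample_roles(m, meta)
    mock_cols <- colnames(m)[roles == "mock"]
    if (!length(mock_cols)) next
    is_mock_asv <- rownames(m) %in% tax$asv_id[tax$is_mock]
    sub <- unwrap(m)[, mock_cols, drop = FALSE]
    total <- total + sum(sub)
    non_mock <- non_mock + sum(sub[!is_mock_asv, ])
  }
  if (total == 0)
    pd_validation_error("no reads in mock samples; cannot estimate tag-jump rate")
  structure(non_mock / total, non_mock_reads = non_mock,
            total_mock_reads = total)
}

#' Zero out cells below the tag-jump proportion of their sample total
#'
#' Within each sample column, any cell whose count is strictly less than
#' `rate` times the column's current total is set to 0. Thresholds are
#' computed once per column from the totals entering this stage.
#'
#' @param t A [taxon_table()] (or any count matrix).
#' @param rate Estimated tag-jump rate in \[0, 1\].
#' @return Same type as `t`.
#' @export
tag_jump_filter <- function(t, rate) {
  if (rate < 0 || rate > 1) pd_validation_error("rate must lie in [0, 1]")
  mat <- unwrap(t)
  thr <- rate * colSums(mat)
  mat[sweep(mat, 2, thr, "<")] <- 0L
  if (inherits(t, "prey_taxon_table"))
    taxon_table(mat, attr(t, "taxa"), provenance = attr(t, "provenance"))
  else mat
}

#' Merge the taxon tables of two primer sets
#'
#' Union of taxa over the shared specimen universe; per-cell counts are
#' summed (downstream analyses use presence only, so any support-preserving
#' merge is equivalent — summing keeps the report interpretable).
#'
#' @param a,b [taxon_table()]s from different primer sets.
#' @return A merged [taxon_table()] with combined provenance.
#' @export
merge_primer_sets <- function(a, b) {
  al <- align_tables(a, b)
  taxon_table(al$a + al$b, al$taxa,
              provenance = unique(c(attr(a, "provenance"),
                                    attr(b, "provenance"))))
}

#' Drop mock-community and explicitly excluded taxa
#'
#' @param t A [taxon_table()].
#' @param cfg A [filter_config()]; its `exclusion_taxa` labels are removed.
#' @param tax Optional [taxonomy_table()]; any taxon whose label matches a
#'   mock ASV's labels is removed as well.
#' @return The filtered [taxon_table()].
#' @export
remove_excluded_taxa <- function(t, cfg = filter_config(), tax = NULL) {
  labels <- attr(t, "taxa")$label
  drop <- labels %in% cfg$exclusion_taxa
  if (!is.null(tax)) {
    mock_rows <- tax[tax$is_mock, , drop = FALSE]
    mock_labels <- unique(unlist(mock_rows[RANKS[1:4]]))
    mock_labels <- mock_labels[nzchar(mock_labels)]
    drop <- drop | labels %in% mock_labels
  }
  out <- taxon_table(unwrap(t)[!drop, , drop = FALSE],
                     attr(t, "taxa")[!drop, , drop = FALSE],
                     provenance = attr(t, "provenance"))
  if (nrow(out) == 0)
    warning("all taxa removed by exclusion filter", call. = FALSE)
  attr(out, "excluded") <- labels[drop]
  out
}

#' Convert a taxon count table to prey presence/absence
#'
#' @param t A [taxon_table()].
#' @param sex Named per-specimen sex vector (see [specimen_sex()]).
#' @return A [presence_matrix()]; specimens left with no detected taxon are
#'   dropped and recorded in the `dropped_samples` attribute.
#' @export
to_presence <- function(t, sex) {
  presence_matrix((unwrap(t) > 0) * 1L, sex)
}

#' Run the full decontamination cascade
#'
#' Applies, in the canonical order, every cleaning stage from raw per-primer
#' per-replicate read matrices to the final prey presence/absence matrix,
#' tracking read totals throughout.
#'
#' @param datasets Named list of [read_matrix()] objects (both replicates of
#'   each primer set).
#' @param tax A [taxonomy_table()].
#' @param meta [sample_metadata()].
#' @param cfg A [filter_config()].
#' @return List with elements `presence` ([presence_matrix()]), `table` (the
#'   merged, cleaned [taxon_table()]) and `report` (a `"prey_cascade_report"`:
#'   per-stage read totals and taxon counts, estimated tag-jump rate per
#'   primer set, removed taxa, dropped specimens).
#' @export
run_cascade <- function(datasets, tax, meta, cfg = filter_config()) {
  primers <- unique(vapply(datasets, attr, "", "primer_set"))
  resolution <- resolve_taxonomy(tax, cfg)
  stages <- list()
  note <- function(primer, stage, reads, taxa) {
    stages[[length(stages) + 1]] <<- data.frame(
      primer_set = primer, stage = stage, reads = reads, taxa = taxa,
      stringsAsFactors = FALSE)
  }
  per_primer <- list()
  rates <- stats::setNames(numeric(length(primers)), primers)
  removed_nontarget <- character()
  for (p in primers) {
    reps <- datasets[vapply(datasets, attr, "", "primer_set") == p]
    rep_no <- vapply(reps, attr, 1L, "replicate")
    if (!setequal(rep_no, c(1L, 2L)))
      pd_validation_error(sprintf(
        "primer set %s needs replicates 1 and 2 (found: %s)", sQuote(p),
        paste(rep_no, collapse = ", ")))
    reps <- reps[order(rep_no)]
    spec_reads <- function(m) {
      roles <- sample_roles(m, meta)
      sum(unwrap(m)[, roles == "specimen", drop = FALSE])
    }
    note(p, "input", sum(vapply(reps, spec_reads, 0)), nrow(reps[[1]]))
    filtered <- lapply(reps, negative_control_filter, meta = meta)
    note(p, "negative_control_filter",
         sum(vapply(filtered, spec_reads, 0)), nrow(filtered[[1]]))
    rates[p] <- estimate_tag_jump_rate(filtered, meta, tax)
    collapsed <- lapply(filtered, collapse_to_taxa,
                        resolution = resolution, meta = meta)
    note(p, "collapse_to_taxa", sum(vapply(collapsed, sum, 0)),
         nrow(collapsed[[1]]))
    tbl <- replicate_consistency_filter(collapsed[[1]], collapsed[[2]])
    note(p, "replicate_consistency_filter", sum(tbl), nrow(tbl))
    tbl <- remove_nontarget(tbl, tax, cfg)
    removed_nontarget <- union(removed_nontarget, attr(tbl, "removed_taxa"))
    note(p, "remove_nontarget", sum(tbl), nrow(tbl))
    tbl <- tag_jump_filter(tbl, rates[p])
    note(p, "tag_jump_filter", sum(tbl), nrow(tbl))
    per_primer[[p]] <- tbl
  }
  merged <- Reduce(merge_primer_sets, per_primer)
  note("combined", "merge_primer_sets", sum(merged), nrow(merged))
  merged <- remove_excluded_taxa(merged, cfg, tax)
  note("combined", "remove_excluded_taxa", sum(merged), nrow(merged))
  # keep only taxa with at least one surviving read
  nonzero <- rowSums(merged) > 0
  merged <- taxon_table(unwrap(merged)[nonzero, , drop = FALSE],
                        attr(merged, "taxa")[nonzero, , drop = FALSE],
                        provenance = attr(merged, "provenance"))
  pm <- to_presence(merged, specimen_sex(meta))
  report <- structure(list(stages = do.call(rbind, stages),
                           tag_jump_rate = rates,
                           removed_nontarget = removed_nontarget,
                           dropped_specimens = attr(pm, "dropped_samples"),
                           n_taxa = nrow(pm), n_specimens = ncol(pm),
                           config = cfg),
                      class = "prey_cascade_report")
  list(presence = pm, table = merged, report = report)
}

#' @export
print.prey_cascade_report <- function(x, ...) {
  cat("<prey_cascade_report>\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("tag-jump rate: %s\n",
              paste(sprintf("%s=%.4f%%", names(x$tag_jump_rate),
                            100 * x$tag_jump_rate), collapse = ", ")))
  cat(sprintf("final: %d taxa x %d specimens; %d specimen(s) dropped\n",
              x$n_taxa, x$n_specimens, length(x$dropped_specimens)))
  invisible(x)
}
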