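# Domain containers shared by every pipeline stage.
#
# All containers are light S3 wrappers around base matrices/data.frames so
# they stay printable, subsettable and diffable; validation happens at
# construction and after file I/O, never silently.

RANKS <- c("species", "genus", "family", "order", "phylum", "kingdom")
ROLES <- c("specimen", "negative_control", "mock")
SEXES <- c("female", "male")

#' Sample metadata table
#'
#' One row per (sample, primer set, technical replicate). Specimens carry a
#' sex; negative controls (extraction blanks, PCR negatives) and the mock
#' community sample do not.
#'
#' @param df A data.frame with columns `sample_id`, `role`
#'   (`"specimen"`, `"negative_control"`, `"mock"`), `sex` (`"female"`,
#'   `"male"`, or `NA` for non-specimens), `primer_set`, `replicate` (1 or 2).
#' @return The validated data.frame with class `"prey_sample_meta"`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "role", "sex", "primer_set", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pd_validation_error(paste0("metadata is missing column(s): ",
                               paste(miss, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$role <- as.character(df$role)
  df$sex <- as.character(df$sex)
  df$sex[df$sex %in% c("NA", "")] <- NA_character_
  df$primer_set <- as.character(df$primer_set)
  df$replicate <- as.integer(df$replicate)
  bad_role <- setdiff(unique(df$role), ROLES)
  if (length(bad_role))
    pd_validation_error(sprintf(
      "unknown role(s) %s; allowed roles are: %s",
      paste(sQuote(bad_role), collapse = ", "),
      paste(ROLES, collapse = ", ")))
  bad_sex <- setdiff(unique(df$sex[!is.na(df$sex)]), SEXES)
  if (length(bad_sex))
    pd_validation_error(sprintf("unknown sex value(s): %s",
                                paste(sQuote(bad_sex), collapse = ", ")))
  spec <- df$role == "specimen"
  if (any(spec & is.na(df$sex)))
    pd_validation_error("specimen samples must have sex 'female' or 'male'")
  if (any(!spec & !is.na(df$sex)))
    pd_validation_error(sprintf(
      "sex must be NA for non-specimen samples (offending: %s)",
      paste(sQuote(unique(df$sample_id[!spec & !is.na(df$sex)])),
            collapse = ", ")))
  if (!all(df$replicate %in% c(1L, 2L)))
    pd_validation_error("replicate must be 1 or 2")
  key <- paste(df$sample_id, df$primer_set, df$replicate)
  if (anyDuplicated(key))
    pd_validation_error(sprintf(
      "duplicated (sample_id, primer_set, replicate): %s",
      paste(sQuote(unique(key[duplicated(key)])), collapse = ", ")))
  class(df) <- c("prey_sample_meta", "data.frame")
  df
}

#' ASV-by-sample read-count matrix
#'
#' @param counts Integer matrix, ASVs in rows (rownames = ASV ids), samples
#'   in columns (colnames = sample ids). All cells must be non-negative
#'   integers.
#' @param primer_set Primer-set label (e.g. `"Leray"`, `"ANML"`).
#' @param replicate Technical replicate, 1 or 2.
#' @param meta Optional [sample_metadata()]; if given, every column of
#'   `counts` must have a metadata record for this primer set and replicate.
#' @return A `"prey_read_matrix"` object.
#' @export
read_matrix <- function(counts, primer_set, replicate, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    pd_validation_error("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    pd_validation_error(sprintf(
      "duplicate ASV id(s): %s",
      paste(sQuote(unique(rownames(counts)[duplicated(rownames(counts))])),
            collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    pd_validation_error("duplicate sample ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    pd_parse_error(sprintf(
      "count cell must be a non-negative integer (ASV %s, sample %s: %s)",
      sQuote(rownames(counts)[bad[1]]), sQuote(colnames(counts)[bad[2]]),
      format(counts[bad[1], bad[2]])))
  }
  storage.mode(counts) <- "integer"
  replicate <- as.integer(replicate)
  if (!replicate %in% c(1L, 2L))
    pd_validation_error("replicate must be 1 or 2")
  if (!is.null(meta)) {
    m <- meta[meta$primer_set == primer_set & meta$replicate == replicate, ]
    unknown <- setdiff(colnames(counts), m$sample_id)
    if (length(unknown))
      pd_validation_error(sprintf(
        "sample id(s) without metadata for %s replicate %d: %s",
        primer_set, replicate, paste(sQuote(unknown), collapse = ", ")))
  }
  structure(counts, class = c("prey_read_matrix", class(counts)),
            primer_set = as.character(primer_set), replicate = replicate)
}

#' Per-ASV taxonomy with per-rank classifier confidences
#'
#' Holds the label and confidence (in \[0, 1\]) assigned at each rank from
#' kingdom down to species, plus a flag marking ASVs of mock-community taxa.
#' Confidences from a naive Bayes-style classifier are expected to be
#' non-increasing from coarse to fine ranks; real data violating this is
#' accepted with a warning.
#'
#' @param df Data.frame with columns `asv_id`, `<rank>` label and
#'   `<rank>_conf` for each rank in species/genus/family/order/phylum/kingdom,
#'   and logical `is_mock`.
#' @return A `"prey_taxonomy"` data.frame.
#' @export
taxonomy_table <- function(df) {
  need <- c("asv_id", RANKS, paste0(RANKS, "_conf"), "is_mock")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pd_validation_error(paste0("taxonomy is missing column(s): ",
                               paste(miss, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$asv_id <- as.character(df$asv_id)
  if (anyDuplicated(df$asv_id))
    pd_validation_error("duplicate asv_id in taxonomy")
  for (r in RANKS) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]])] <- ""
    cc <- paste0(r, "_conf")
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])) || any(df[[cc]] < 0 | df[[cc]] > 1))
      pd_validation_error(sprintf("%s must lie in [0, 1]", cc))
  }
  df$is_mock <- as.logical(df$is_mock)
  if (anyNA(df$is_mock))
    pd_validation_error("is_mock must be TRUE/FALSE")
  non_mono <- df$order_conf < df$family_conf - 1e-12 |
    df$family_conf < df$genus_conf - 1e-12 |
    df$genus_conf < df$species_conf - 1e-12
  if (any(non_mono))
    warning(sprintf(
      "%d ASV(s) have confidences increasing from coarse to fine rank",
      sum(non_mono)), call. = FALSE)
  class(df) <- c("prey_taxonomy", "data.frame")
  df
}

#' Decontamination-cascade configuration
#'
#' @param rank_thresholds Named numeric vector of minimum classifier
#'   confidences per rank; an ASV is assigned at the deepest rank whose
#'   confidence reaches its threshold.
#' @param target_phylum Taxa outside this phylum are removed.
#' @param exclusion_taxa Taxon labels excluded from all diet
#'   characterizations (default: the parasitic water mite
#'   *Arrenurus reflexus*, whose reads likely reflect parasite contamination
#'   rather than predation).
#' @param negative_rule Rule turning negative-control counts into a per-ASV
#'   removal threshold; only `"max_across_negatives"` is implemented.
#' @param alpha Significance level carried into downstream reports.
#' @return A `"prey_filter_config"` list.
#' @export
filter_config <- function(rank_thresholds = c(species = 0.45, genus = 0.40,
                                              family = 0.30, order = 0.20),
                          target_phylum = "Arthropoda",
                          exclusion_taxa = "Arrenurus reflexus",
                          negative_rule = "max_across_negatives",
                          alpha = 0.05) {
  need <- c("species", "genus", "family", "order")
  if (!all(need %in% names(rank_thresholds)))
    pd_config_error("rank_thresholds must name species, genus, family, order")
  th <- rank_thresholds[need]
  if (any(th <= 0 | th >= 1))
    pd_config_error("rank thresholds must lie in (0, 1)")
  if (is.unsorted(rev(th)))
    pd_config_error(
      "rank thresholds must satisfy species >= genus >= family >= order")
  negative_rule <- match.arg(negative_rule, "max_across_negatives")
  structure(list(rank_thresholds = th, target_phylum = target_phylum,
                 exclusion_taxa = as.character(exclusion_taxa),
                 negative_rule = negative_rule, alpha = alpha),
            class = "prey_filter_config")
}

#' Resolved-taxon by specimen count table
#'
#' Counts after ASV-to-taxon collapse. Rows are resolved taxa identified by
#' `(rank, label)`; columns are specimen samples only (negative controls and
#' mock samples are excluded by construction).
#'
#' @param counts Non-negative integer matrix, taxa x specimens; rownames are
#'   taxon keys as produced by [taxon_key()].
#' @param taxa Data.frame with columns `rank` and `label`, one row per row of
#'   `counts`.
#' @param provenance Character vector of primer-set labels that contributed.
#' @return A `"prey_taxon_table"` object.
#' @export
taxon_table <- function(counts, taxa, provenance = character()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(taxa))
    pd_validation_error("taxa must have one row per taxon row of counts")
  if (any(counts < 0) || any(counts != round(counts)))
    pd_validation_error("taxon counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  taxa <- data.frame(rank = as.character(taxa$rank),
                     label = as.character(taxa$label),
                     stringsAsFactors = FALSE)
  rownames(counts) <- taxon_key(taxa$rank, taxa$label)
  structure(counts, class = c("prey_taxon_table", class(counts)),
            taxa = taxa, provenance = as.character(provenance))
}

#' Canonical key for a resolved taxon
#'
#' @param rank,label Character vectors.
#' @return `"<rank>|<label>"` keys.
#' @export
taxon_key <- function(rank, label) paste(rank, label, sep = "|")

#' Binary prey presence/absence matrix
#'
#' The object every diet statistic consumes: taxa in rows, specimens in
#' columns, entries 0/1, with per-specimen sex labels. Specimens with no
#' detected taxon are dropped at construction and recorded.
#'
#' @param mat Matrix coercible to 0/1; rownames = taxon keys or labels,
#'   colnames = specimen ids.
#' @param sex Named character vector (`"female"`/`"male"`) covering every
#'   column of `mat`.
#' @return A `"prey_presence"` object with attributes `sex` (aligned to the
#'   retained columns) and `dropped_samples`.
#' @export
presence_matrix <- function(mat, sex) {
  mat <- as.matrix(mat)
  if (any(!mat %in% c(0, 1)))
    pd_validation_error("presence entries must be 0 or 1")
  storage.mode(mat) <- "integer"
  miss <- setdiff(colnames(mat), names(sex))
  if (length(miss))
    pd_validation_error(sprintf("no sex label for specimen(s): %s",
                                paste(sQuote(miss), collapse = ", ")))
  sex <- as.character(sex[colnames(mat)])
  names(sex) <- colnames(mat)
  if (any(!sex %in% SEXES))
    pd_validation_error("sex labels must be 'female' or 'male'")
  empty <- colSums(mat) == 0
  dropped <- colnames(mat)[empty]
  if (length(dropped)) {
    message(sprintf("dropping %d specimen(s) with no detected taxon: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    mat <- mat[, !empty, drop = FALSE]
    sex <- sex[!empty]
  }
  structure(mat, class = c("prey_presence", class(mat)),
            sex = sex, dropped_samples = dropped)
}

#' @export
print.prey_read_matrix <- function(x, ...) {
  cat(sprintf("<prey_read_matrix> %d ASVs x %d samples (%s, replicate %d), %s reads\n",
              nrow(x), ncol(x), attr(x, "primer_set"), attr(x, "replicate"),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.prey_taxon_table <- function(x, ...) {
  cat(sprintf("<prey_taxon_table> %d taxa x %d specimens [%s], %s reads\n",
              nrow(x), ncol(x),
              paste(attr(x, "provenance"), collapse = "+"),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.prey_presence <- function(x, ...) {
  sex <- attr(x, "sex")
  cat(sprintf("<prey_presence> %d taxa x %d specimens (%d female, %d male)\n",
              nrow(x), ncol(x), sum(sex == "female"), sum(sex == "male")))
  invisible(x)
}

# Subsetting keeps class and attributes coherent for the two matrix wrappers.
#' @export
`[.prey_presence` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  sex <- attr(x, "sex")
  structure(out, class = class(x), sex = sex[colnames(out)],
            dropped_samples = attr(x, "dropped_samples"))
}

# Plain matrix view: drops the wrapper class and every attribute other
# than dim/dimnames.
unwrap <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}
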