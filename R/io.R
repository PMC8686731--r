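# Tab-separated readers/writers for the canonical interchange files.
#
# All files are UTF-8 TSV with '.' decimal separator.  Matrices carry ASV or
# taxon ids in the first column and sample ids in the header; write/read
# round-trips are bit-exact for canonical files.

#' Read an ASV-by-sample count table
#'
#' @param path TSV file: first column ASV ids, remaining columns one per
#'   sample, integer cells.
#' @param primer_set,replicate Dataset labels attached to the matrix.
#' @param meta Optional [sample_metadata()] used to validate sample ids.
#' @return A [read_matrix()].
#' @export
read_count_table <- function(path, primer_set, replicate, meta = NULL) {
  if (!file.exists(path)) pd_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) pd_parse_error(sprintf("%s has no sample columns", path))
  ids <- df[[1]]
  mat <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    pd_parse_error(sprintf(
      "malformed count in %s at ASV %s, sample %s: %s",
      path, sQuote(ids[b[1]]), sQuote(colnames(mat)[b[2]]),
      sQuote(mat[b[1], b[2]])))
  }
  rownames(num) <- ids
  read_matrix(num, primer_set = primer_set, replicate = replicate, meta = meta)
}

#' @rdname read_count_table
#' @param m A [read_matrix()] (or any labelled integer matrix) to write.
#' @export
write_count_table <- function(m, path) {
  df <- data.frame(asv_id = rownames(m), unwrap(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the sample metadata table
#'
#' @param path TSV with columns sample_id, role, sex, primer_set, replicate.
#' @return [sample_metadata()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) pd_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param meta A [sample_metadata()] table.
#' @export
write_metadata <- function(meta, path) {
  df <- as.data.frame(meta)
  df$sex[is.na(df$sex)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the per-ASV taxonomy table
#'
#' @param path TSV with columns asv_id, one label and one `_conf` column per
#'   rank (kingdom..species), and is_mock.
#' @return [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) pd_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  for (cc in paste0(RANKS, "_conf"))
    if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]])
  if ("is_mock" %in% names(df)) df$is_mock <- df$is_mock %in% c("TRUE", "1")
  taxonomy_table(df)
}

#' @rdname read_taxonomy
#' @param tax A [taxonomy_table()].
#' @export
write_taxonomy <- function(tax, path) {
  df <- as.data.frame(tax)
  for (cc in paste0(RANKS, "_conf"))
    df[[cc]] <- format(df[[cc]], trim = TRUE, digits = 15)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a presence/absence matrix
#'
#' The file stores taxa in rows and specimens in columns, with a `taxon`
#' first column; specimen sexes are read from a metadata table.
#' @param path TSV path.
#' @param meta [sample_metadata()] supplying specimen sexes.
#' @return [presence_matrix()].
#' @export
read_presence <- function(path, meta) {
  if (!file.exists(path)) pd_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- df[[1]]
  sex <- specimen_sex(meta)
  presence_matrix(mat, sex)
}

#' @rdname read_presence
#' @param pm A [presence_matrix()].
#' @export
write_presence <- function(pm, path) {
  df <- data.frame(taxon = rownames(pm), unwrap(pm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-specimen sex lookup from metadata
#'
#' @param meta [sample_metadata()].
#' @return Named character vector, one entry per distinct specimen id.
#' @export
specimen_sex <- function(meta) {
  m <- meta[meta$role == "specimen", ]
  m <- m[!duplicated(m$sample_id), ]
  stats::setNames(m$sex, m$sample_id)
}
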