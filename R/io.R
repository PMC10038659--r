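# Readers and writers for the package's canonical plain-text formats:
# FASTA protein databases (via Biostrings), tab-separated PSM / PRM tables
# (UTF-8, '.' decimal separator, '#' comment headers).

#' Read a protein database from FASTA
#'
#' The FASTA header is split at the first space into accession and
#' description.
#'
#' @param path FASTA file.
#' @return `data.frame`: `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(accession = acc, description = desc,
             sequence = as.character(aa), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a protein database to FASTA
#'
#' @param db `data.frame` with `accession`, `description`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- ifelse(nzchar(db$description),
                      paste(db$accession, db$description), db$accession)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Provenance header written at the top of every output table.
.tsv_header <- function(parameters = NULL, seed = NULL) {
  # no timestamp: output files must be bit-identical across fixed-seed reruns
  lines <- sprintf("# eccquant %s",
                   as.character(utils::packageVersion("eccquant")))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (length(parameters))
    lines <- c(lines, sprintf("# %s: %s", names(parameters),
                              vapply(parameters, function(x)
                                paste(format(x), collapse = ","),
                                character(1))))
  lines
}

#' Write a table as TSV with a provenance comment header
#'
#' Tab-separated, UTF-8, `'.'` decimal separator; `#`-prefixed header lines
#' record the package version, parameters and seed.
#'
#' @param x `data.frame`.
#' @param path Output file.
#' @param parameters Optional named list recorded in the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, parameters = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.tsv_header(parameters, seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# Shared TSV reader: skips '#' comments, checks required/numeric columns,
# reports offending rows by line.
.read_tsv_checked <- function(path, required, numeric_cols) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d of %s: '%s'",
                   col, bad[1L], path, df[[col]][bad[1L]]))
    df[[col]] <- v
  }
  df
}

#' Read a PSM table from TSV
#'
#' Reporter columns are returned in the declared channel order regardless of
#' their position in the file; non-numeric intensities are reported with row
#' and column.
#'
#' @param path TSV file with `accession`, `peptide` and one intensity column
#'   per channel.
#' @param channels Reporter channel column names (default TMT 10-plex).
#' @return PSM `data.frame` with `attr(,"channels")` set.
#' @export
read_psm_tsv <- function(path, channels = tmt10_channels()) {
  df <- .read_tsv_checked(path, c("accession", "peptide", channels), channels)
  extra <- setdiff(names(df), channels)
  if ("is_calibration" %in% names(df))
    df$is_calibration <- as.logical(df$is_calibration)
  df <- df[, c(setdiff(extra, channels), channels)]
  attr(df, "channels") <- channels
  df
}

#' Read a PRM table from TSV
#'
#' @param path TSV file with `sample_id`, `accession`, `peptide`,
#'   `light_area`, `heavy_area`, `sample_tic` (and optionally `condition`).
#' @return PRM `data.frame`.
#' @export
read_prm_tsv <- function(path) {
  .read_tsv_checked(
    path,
    c("sample_id", "accession", "peptide", "light_area", "heavy_area",
      "sample_tic"),
    c("light_area", "heavy_area", "sample_tic")
  )
}
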