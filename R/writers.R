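# Alignment and partition writers/readers.

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path File path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a relaxed PHYLIP alignment
#' @param seqs Named character vector (equal lengths).
#' @param path Output path.
#' @export
write_phylip <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(seqs), nchar(seqs[1])), con)
  writeLines(sprintf("%s  %s", names(seqs), unname(seqs)), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#' @param path File path.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  setNames(vapply(parts, `[`, character(1), 2),
           vapply(parts, `[`, character(1), 1))
}

#' Write a NEXUS alignment with charset blocks
#' @param m A `Supermatrix`.
#' @param path Output path.
#' @param scheme Partition scheme for the charsets (see
#'   [partition_scheme()]).
#' @export
write_nexus <- function(m, path, scheme = "gene") {
  seqs <- m$seqs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
                     nchar(seqs[1])), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  writeLines(sprintf("    %s  %s", names(seqs), unname(seqs)), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  p <- partition_scheme(m, scheme)
  writeLines("BEGIN SETS;", con)
  writeLines(sprintf("  CHARSET %s = %d-%d%s;", p$name, p$start, p$end,
                     ifelse(p$step == 3L, "\\3", "")), con)
  writeLines("END;", con)
  invisible(path)
}

#' Write a plain-text partition file
#'
#' One `DNA, name = start-end` (or `start-end\\3` for codon-position
#' partitions) line per partition, consumable by common
#' model-selection/inference tools.
#'
#' @param m A `Supermatrix`.
#' @param path Output path.
#' @param scheme `"gene"` or `"gene_codon"`.
#' @export
write_partitions <- function(m, path, scheme = "gene") {
  p <- partition_scheme(m, scheme)
  writeLines(sprintf("DNA, %s = %d-%d%s", p$name, p$start, p$end,
                     ifelse(p$step == 3L, "\\3", "")), path)
  invisible(path)
}
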