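# Reference fixtures: the two published Pylorgus feature ledgers,
# transcribed from the deposited annotations (accessions OP793792 and
# OQ064783). Sizes and intergenic values are carried for comparison
# only; all package statistics recompute them from coordinates.

FIXTURE_GENOME_LENGTHS <- c(porrectus = 15174L, sordidus = 15399L)

#' Path to a bundled reference feature table
#' @param which `"porrectus"` or `"sordidus"`.
#' @return File path inside the installed package.
#' @export
fixture_table_path <- function(which = c("porrectus", "sordidus")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_features.tsv"),
              package = "mitocomp", mustWork = TRUE)
}

#' Load a bundled reference feature table
#'
#' @param which `"porrectus"` or `"sordidus"`.
#' @return List: `features` (parsed via [read_feature_table()]),
#'   `printed` (the raw transcription incl. printed size/intergenic
#'   columns), `genome_length`.
#' @export
fixture_features <- function(which = c("porrectus", "sordidus")) {
  which <- match.arg(which)
  path <- fixture_table_path(which)
  list(features = read_feature_table(path,
                                     FIXTURE_GENOME_LENGTHS[[which]]),
       printed = read.delim(path, stringsAsFactors = FALSE),
       genome_length = FIXTURE_GENOME_LENGTHS[[which]])
}

#' Write the bundled reference feature tables to a directory
#'
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of the two written paths.
#' @export
write_fixture_tables <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vapply(c("porrectus", "sordidus"), function(w) {
    dst <- file.path(dir, paste0(w, "_features.tsv"))
    file.copy(fixture_table_path(w), dst, overwrite = TRUE)
    dst
  }, character(1))
  invisible(out)
}
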