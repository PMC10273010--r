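# Minimal GenBank flat-file I/O for annotated mitogenomes.
#
# Covers the subset of the format these analyses need: LOCUS line,
# FEATURES table with CDS / tRNA / rRNA / D-loop / misc_feature entries
# (locations `a..b`, `complement(a..b)`, and origin-wrapping
# `join(a..L,1..b)`), and the ORIGIN sequence block. `gene` features are
# skipped as duplicates of their CDS/tRNA/rRNA counterparts.

.GB_TYPE_MAP <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  `D-loop` = "control", misc_feature = "control")

#' Read a GenBank flat file into a MitoGenome
#'
#' Gene names are canonicalized via [canonical_gene_name()]; features
#' whose names are not in the 37-gene vocabulary are kept but flagged
#' with a warning and excluded from vocabulary-dependent statistics.
#'
#' @param path Path to a GenBank flat file.
#' @param genetic_code_id Translation table (default 5).
#' @return A `MitoGenome`.
#' @export
read_genbank <- function(path, genetic_code_id = 5L) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: ", path)
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  accession <- if (length(locus) >= 2) locus[2] else "unknown"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN block: ", path)
  seq_lines <- lines[(ori[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("empty sequence in GenBank file: ", path)

  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("GenBank file has no FEATURES table: ", path)
  flines <- lines[(fstart[1] + 1):(ori[1] - 1)]

  # Feature entries start with a key at column 6; continuation/qualifier
  # lines are indented to column 22.
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  feats <- list()
  unknown <- character()
  for (k in seq_along(idx)) {
    block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1
                            else length(flines))]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    if (!key %in% names(.GB_TYPE_MAP)) next
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    parsed <- .parse_gb_location(loc)
    quals <- block[grepl("^\\s+/", block)]
    name <- .gb_qualifier(quals, "gene") %||%
      .gb_qualifier(quals, "product") %||%
      .gb_qualifier(quals, "note") %||%
      paste0(key, "_", k)
    cname <- canonical_gene_name(name)
    if (!attr(cname, "known")) unknown <- c(unknown, name)
    gtype <- if (attr(cname, "known")) gene_type_of(cname)
             else .GB_TYPE_MAP[[key]]
    feats[[length(feats) + 1L]] <- gene_feature(
      cname, parsed$start, parsed$end,
      direction = if (parsed$complement) "reverse" else "forward",
      strand_label = if (parsed$complement) "J" else "N",
      gene_type = gtype, wraps_origin = parsed$wraps)
  }
  if (!length(feats)) stop("no usable features in GenBank file: ", path)
  if (length(unknown))
    warning("unknown gene names preserved: ",
            paste(unique(unknown), collapse = ", "))
  features <- do.call(rbind, feats)
  features <- features[order(features$start), , drop = FALSE]
  mito_genome(sequence, features, accession = accession,
              genetic_code_id = genetic_code_id)
}

.parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
  wraps <- grepl("^join\\(", inner)
  if (wraps) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", inner), ",")[[1]]
    a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
    list(start = a[1], end = b[2], complement = complement, wraps = TRUE)
  } else {
    ab <- as.integer(strsplit(inner, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (anyNA(ab)) stop("unparseable GenBank location: ", loc)
    list(start = ab[1], end = ab[2], complement = complement, wraps = FALSE)
  }
}

.gb_qualifier <- function(quals, key) {
  pat <- paste0("^\\s+/", key, "=\"?([^\"]*)\"?$")
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(pat, "\\1", hit[1])
}

#' Write a MitoGenome as a GenBank-style flat file
#'
#' Emits the subset of the format that [read_genbank()] parses; a
#' written-then-reread genome has identical sequence, coordinates, and
#' directions.
#'
#' @param g A `MitoGenome`.
#' @param path Output path.
#' @export
write_genbank <- function(g, path) {
  glen <- nchar(g$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     circular INV",
                     g$accession, glen), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     g$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control = "D-loop")
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    key <- key_of[[if (is.na(f$gene_type)) "control" else f$gene_type]]
    span <- if (f$wraps_origin)
      sprintf("join(%d..%d,1..%d)", f$start, glen, f$end)
    else sprintf("%d..%d", f$start, f$end)
    loc <- if (f$direction == "reverse")
      sprintf("complement(%s)", span) else span
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  seq <- tolower(g$sequence)
  for (off in seq(1L, glen, by = 60L)) {
    chunk <- substr(seq, off, min(off + 59L, glen))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
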