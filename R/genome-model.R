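# Genome model: coordinate conventions live here.
#
# Coordinates are 1-based, fully inclusive (a feature 1-64 has length 64).
# Internal truth for strandedness is `direction`; the N/J strand labels
# are presentation only and must map one-to-one onto directions within a
# genome.

#' Construct a gene feature
#'
#' @param name Gene name (canonicalized via [canonical_gene_name()]).
#' @param start,end 1-based inclusive coordinates (bp).
#' @param direction `"forward"` or `"reverse"` reading direction.
#' @param strand_label Presentation label, `"N"` or `"J"`.
#' @param gene_type Optional; inferred from the vocabulary when `NULL`.
#' @param wraps_origin Does the feature span the circular origin?
#' @return A one-row data.frame (a feature table row).
#' @export
gene_feature <- function(name, start, end, direction,
                         strand_label = NA_character_,
                         gene_type = NULL, wraps_origin = FALSE) {
  cname <- canonical_gene_name(name)
  known <- attr(cname, "known")
  if (is.null(gene_type))
    gene_type <- ifelse(known, gene_type_of(cname), NA_character_)
  stopifnot(start >= 1, wraps_origin || end >= start)
  if (!direction %in% c("forward", "reverse"))
    stop("direction must be 'forward' or 'reverse'")
  data.frame(name = as.character(cname), gene_type = gene_type,
             start = as.integer(start), end = as.integer(end),
             strand_label = strand_label, direction = direction,
             wraps_origin = wraps_origin, stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' @param sequence Nucleotide string (circular, plus strand).
#' @param features Feature table (rows as from [gene_feature()]).
#' @param accession Identifier text.
#' @param genetic_code_id Translation-table id (default 5, invertebrate
#'   mitochondrial).
#' @return An object of class `MitoGenome`.
#' @export
mito_genome <- function(sequence, features, accession = "unknown",
                        genetic_code_id = 5L) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("sequence must be non-empty")
  if (nrow(features) > 0) {
    glen <- nchar(sequence)
    if (any(features$end > glen) || any(features$start > glen))
      stop("feature coordinates exceed sequence length (", glen, ")")
    dup <- features$name[duplicated(features$name)]
    if (length(dup))
      stop("duplicate feature names: ", paste(unique(dup), collapse = ", "))
    .check_strand_pairing(features)
  }
  structure(list(accession = accession, sequence = sequence,
                 features = features,
                 genetic_code_id = as.integer(genetic_code_id)),
            class = "MitoGenome")
}

.check_strand_pairing <- function(features) {
  lab <- features$strand_label
  ok <- !is.na(lab)
  if (!any(ok)) return(invisible(TRUE))
  tab <- unique(data.frame(lab = lab[ok], dir = features$direction[ok]))
  if (anyDuplicated(tab$lab))
    stop("inconsistent strand_label/direction pairing")
  invisible(TRUE)
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat("MitoGenome", x$accession, "-", nchar(x$sequence), "bp,",
      nrow(x$features), "features, genetic code", x$genetic_code_id, "\n")
  tab <- table(factor(x$features$gene_type,
                      levels = c("PCG", "tRNA", "rRNA", "control")))
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  invisible(x)
}

#' Wrap-aware feature length
#'
#' @param f A feature row (or several).
#' @param genome_length Genome length in bp (needed for wrapping
#'   features).
#' @return Integer length(s) in bp, inclusive of both endpoints.
#' @export
feature_length <- function(f, genome_length = NA_integer_) {
  ifelse(f$wraps_origin,
         as.integer(genome_length) - f$start + 1L + f$end,
         f$end - f$start + 1L)
}

#' Reverse complement of a nucleotide string
#' @param seq Character scalar over the IUPAC alphabet.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a feature's sequence in reading direction
#'
#' Wrap-aware: a feature with `wraps_origin = TRUE` is read across the
#' circular origin. Reverse-direction features are reverse-complemented.
#'
#' @param g A `MitoGenome`.
#' @param f A single feature row.
#' @return Character scalar of length [feature_length()].
#' @export
extract_sequence <- function(g, f) {
  glen <- nchar(g$sequence)
  if (f$start > glen || f$end > glen || f$start < 1L)
    stop("feature out of bounds")
  s <- if (f$wraps_origin) {
    paste0(substr(g$sequence, f$start, glen), substr(g$sequence, 1L, f$end))
  } else {
    substr(g$sequence, f$start, f$end)
  }
  if (f$direction == "reverse") revcomp(s) else s
}

#' Read a tab-separated feature table
#'
#' Expected columns: `gene`, `start`, `end`, `strand`, `direction`
#' (header row required). Features are returned sorted by start; sizes
#' are always recomputed from coordinates, never read from the file.
#'
#' @param path File path.
#' @param genome_length Optional genome length for bounds checking.
#' @return Feature data.frame sorted by `start`.
#' @export
read_feature_table <- function(path, genome_length = NA_integer_) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (nrow(tab) == 0L) {
    warning("empty feature table: ", path)
    return(.empty_features())
  }
  need <- c("gene", "start", "end", "strand", "direction")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  st <- suppressWarnings(as.integer(tab$start))
  en <- suppressWarnings(as.integer(tab$end))
  if (anyNA(st) || anyNA(en))
    stop("non-numeric coordinates in feature table")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene names in feature table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  feats <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    gene_feature(tab$gene[i], st[i], en[i],
                 direction = tolower(tab$direction[i]),
                 strand_label = tab$strand[i],
                 wraps_origin = !is.na(genome_length) && en[i] < st[i])
  }))
  if (!is.na(genome_length) && any(feats$end > genome_length))
    stop("feature coordinates exceed genome length")
  feats[order(feats$start), , drop = FALSE]
}

.empty_features <- function() {
  data.frame(name = character(), gene_type = character(),
             start = integer(), end = integer(),
             strand_label = character(), direction = character(),
             wraps_origin = logical(), stringsAsFactors = FALSE)
}

#' Write a feature table
#'
#' Round-trip partner of [read_feature_table()]: coordinates, strand
#' labels, and directions are written verbatim.
#'
#' @param features Feature data.frame.
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  out <- data.frame(gene = features$name, start = features$start,
                    end = features$end, strand = features$strand_label,
                    direction = features$direction)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a mitogenome annotation
#'
#' Report-only check against the 37-gene vocabulary: missing and extra
#' genes, duplicates, bound violations, and counts by gene type.
#'
#' @param g A `MitoGenome`.
#' @return A list with `counts` (named integer vector by gene type),
#'   `missing`, `extra`, `findings` (character vector of messages), and
#'   `n_findings`.
#' @export
validate_annotation <- function(g) {
  voc <- gene_vocabulary()
  expected <- voc$name[voc$gene_type != "control"]
  f <- g$features
  annotated <- f$name[!is.na(f$gene_type) & f$gene_type != "control"]
  missing <- setdiff(expected, annotated)
  extra <- setdiff(f$name, voc$name)
  dup <- unique(f$name[duplicated(f$name)])
  glen <- nchar(g$sequence)
  oob <- f$name[!f$wraps_origin & (f$end > glen | f$start < 1L)]
  counts <- table(factor(f$gene_type, levels = c("PCG", "tRNA", "rRNA",
                                                 "control")))
  findings <- c(
    if (length(missing)) paste("missing gene:", missing),
    if (length(extra)) paste("unknown gene:", extra),
    if (length(dup)) paste("duplicate:", dup),
    if (length(oob)) paste("out of bounds:", oob)
  )
  list(counts = setNames(as.integer(counts), names(counts)),
       missing = missing, extra = extra,
       findings = findings %||% character(),
       n_findings = length(findings))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
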