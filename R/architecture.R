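# Gene architecture: adjacency ledger (overlaps / intergenic spacers),
# strand distribution, and circular gene-order comparison.

#' Intergenic adjacency ledger
#'
#' For start-sorted annotated features, each consecutive pair
#' contributes `gap = next.start - prev.end - 1`: negative gaps are
#' overlaps, positive gaps spacers. The control region is excluded (it
#' is the unannotated remainder, not a gene), and the wrap pair (last
#' annotated gene back to the first through the control region) is
#' reported separately in `wrap_pair`, outside the summary counts.
#'
#' @param features Feature data.frame (any row order; sorting is
#'   internal).
#' @param genome_length Optional genome length; enables the wrap-pair
#'   record.
#' @return A list of class `AdjacencyLedger`: `pairs` (data.frame
#'   prev, next, gap), `n_overlaps`, `max_overlap`, `overlap_pair`,
#'   `n_spacers`, `max_spacer`, `spacer_pair`, `wrap_pair`.
#' @export
intergenic_ledger <- function(features, genome_length = NA_integer_) {
  f <- features[is.na(features$gene_type) |
                  features$gene_type != "control", , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  if (nrow(f) >= 2L && any(diff(f$start) < 0L))
    stop("features not sortable by start")
  if (nrow(f) < 2L) {
    pairs <- data.frame(prev = character(), nxt = character(),
                        gap = integer(), stringsAsFactors = FALSE)
  } else {
    i <- seq_len(nrow(f) - 1L)
    pairs <- data.frame(prev = f$name[i], nxt = f$name[i + 1L],
                        gap = f$start[i + 1L] - f$end[i] - 1L,
                        stringsAsFactors = FALSE)
  }
  ov <- pairs$gap < 0L
  sp <- pairs$gap > 0L
  pick <- function(mask, extreme) {
    if (!any(mask)) return(list(len = 0L, pair = NA_character_))
    g <- abs(pairs$gap)
    g[!mask] <- -1L
    j <- which.max(g)
    list(len = abs(pairs$gap[j]),
         pair = paste(pairs$prev[j], pairs$nxt[j], sep = "/"))
  }
  ovx <- pick(ov)
  spx <- pick(sp)
  wrap <- NULL
  if (!is.na(genome_length) && nrow(f) >= 2L) {
    wrap <- data.frame(prev = f$name[nrow(f)], nxt = f$name[1L],
                       gap = genome_length - f$end[nrow(f)] - 1L +
                         f$start[1L],
                       stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs,
                 n_overlaps = sum(ov), max_overlap = ovx$len,
                 overlap_pair = ovx$pair,
                 n_spacers = sum(sp), max_spacer = spx$len,
                 spacer_pair = spx$pair,
                 wrap_pair = wrap),
            class = "AdjacencyLedger")
}

#' @export
print.AdjacencyLedger <- function(x, ...) {
  cat(sprintf("AdjacencyLedger: %d pairs, %d overlaps (max %d bp at %s), %d spacers (max %d bp at %s)\n",
              nrow(x$pairs), x$n_overlaps, x$max_overlap, x$overlap_pair,
              x$n_spacers, x$max_spacer, x$spacer_pair))
  invisible(x)
}

#' Overlap summary
#' @param l An `AdjacencyLedger`.
#' @return List with `count`, `max_bp`, `pair`.
#' @export
overlap_summary <- function(l) {
  list(count = l$n_overlaps, max_bp = l$max_overlap, pair = l$overlap_pair)
}

#' Intergenic spacer summary
#' @param l An `AdjacencyLedger`.
#' @return List with `count`, `max_bp`, `pair`.
#' @export
spacer_summary <- function(l) {
  list(count = l$n_spacers, max_bp = l$max_spacer, pair = l$spacer_pair)
}

#' Strand distribution of genes
#'
#' Cross-tabulates gene counts by gene type and reading direction.
#'
#' @param features Feature data.frame.
#' @return A list with `table` (gene_type x direction matrix) and
#'   `totals` (named counts by direction).
#' @export
strand_distribution <- function(features) {
  f <- features[is.na(features$gene_type) |
                  features$gene_type != "control", , drop = FALSE]
  tab <- table(factor(f$gene_type, levels = c("PCG", "tRNA", "rRNA")),
               factor(f$direction, levels = c("forward", "reverse")))
  list(table = unclass(tab),
       totals = c(forward = sum(tab[, "forward"]),
                  reverse = sum(tab[, "reverse"])))
}

#' Extract the circular gene order of a genome
#'
#' @param features Feature data.frame (control region excluded).
#' @param origin Optional gene name to linearize the circle at (that
#'   gene becomes position 1).
#' @return A data.frame of class `GeneOrder` with columns `name`,
#'   `direction`, in circular (start-sorted) order.
#' @export
gene_order <- function(features, origin = NULL) {
  f <- features[is.na(features$gene_type) |
                  features$gene_type != "control", , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  out <- data.frame(name = f$name, direction = f$direction,
                    stringsAsFactors = FALSE)
  if (!is.null(origin)) {
    i <- match(origin, out$name)
    if (is.na(i)) stop("origin gene not in this genome: ", origin)
    if (i > 1L) out <- rbind(out[i:nrow(out), ], out[1:(i - 1L), ])
    rownames(out) <- NULL
  }
  class(out) <- c("GeneOrder", "data.frame")
  out
}

#' Compare two circular gene orders
#'
#' Equality is tested under circular rotation, direction-sensitively;
#' reflection (reading the circle the other way) is not considered
#' equivalent, because strandedness is biologically meaningful.
#'
#' @param a,b `GeneOrder` objects (or data.frames with `name`,
#'   `direction`).
#' @return List with `identical` (logical) and `first_difference`
#'   (1-based position in `a` of the first mismatch under the best
#'   rotation, or `NA`).
#' @export
compare_gene_order <- function(a, b) {
  ka <- paste(a$name, a$direction)
  kb <- paste(b$name, b$direction)
  n <- length(ka)
  if (n != length(kb))
    return(list(identical = FALSE, first_difference = 1L))
  for (r in seq_len(n) - 1L) {
    rot <- c(kb[(r + 1):n], if (r > 0) kb[1:r])
    if (identical(ka, rot))
      return(list(identical = TRUE, first_difference = NA_integer_))
  }
  # report the mismatch position as linearized (identity rotation)
  diff_at <- which(ka != kb)[1]
  list(identical = FALSE,
       first_difference = if (is.na(diff_at)) 1L else diff_at)
}

#' Feature ledger report (tab-separated)
#'
#' Mirrors the printed per-gene table: gene, position, size, strand,
#' direction, intergenic nucleotides, start/stop codons (PCGs only).
#'
#' @param g A `MitoGenome`.
#' @param path Output path; when `NULL` the data.frame is returned.
#' @return The report data.frame.
#' @export
ledger_report <- function(g, path = NULL) {
  f <- g$features[order(g$features$start), , drop = FALSE]
  led <- intergenic_ledger(f, genome_length = nchar(g$sequence))
  ig <- c(0L, led$pairs$gap)
  codons <- tryCatch(start_stop_codons(g), error = function(e) NULL)
  cod_col <- rep("", nrow(f))
  if (!is.null(codons)) {
    m <- match(f$name, codons$gene)
    hit <- !is.na(m)
    cod_col[hit] <- paste0(codons$start_codon[m[hit]], "/",
                           codons$stop_codon[m[hit]])
  }
  keep <- is.na(f$gene_type) | f$gene_type != "control"
  fk <- f[keep, , drop = FALSE]
  out <- data.frame(
    Gene = fk$name,
    Position = paste0(fk$start, "-", fk$end),
    Size = feature_length(fk, nchar(g$sequence)),
    Strand = fk$strand_label,
    Direction = fk$direction,
    Intergenic = ig[seq_len(nrow(fk))],
    Codons = cod_col[keep],
    stringsAsFactors = FALSE)
  names(out) <- c("Gene", "Position (bp)", "Size (bp)", "Strand",
                  "Direction", "Intergenic nucleotides",
                  "Start/stop codons")
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
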