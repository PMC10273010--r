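# Codon counting and relative synonymous codon usage (RSCU).

ALL_CODONS <- {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character())
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count codons over a set of in-frame coding sequences
#'
#' Each CDS is read in frame from position 1. A trailing incomplete
#' codon is dropped; codons containing ambiguity are dropped and tallied
#' in `n_excluded_codons`. Stop codons are counted but flagged so RSCU
#' can exclude them.
#'
#' @param cds_set Character vector (or list) of oriented CDS strings.
#' @param code Genetic-code id (default 5, invertebrate mitochondrial).
#' @return A list of class `CodonUsageTable`: `counts` (named over the
#'   64 codons), `genetic_code_id`, `n_excluded_codons`, `rscu` (`NULL`
#'   until [rscu()] is applied).
#' @export
codon_counts <- function(cds_set, code = 5L) {
  counts <- setNames(integer(64), ALL_CODONS)
  excluded <- 0L
  for (cds in cds_set) {
    cds <- toupper(as.character(cds))
    if (nchar(cds) < 3L) {
      warning("CDS shorter than one codon skipped")
      next
    }
    cod <- .split_codons(cds)
    ok <- grepl("^[ACGT]{3}$", cod)
    excluded <- excluded + sum(!ok)
    tab <- table(factor(cod[ok], levels = ALL_CODONS))
    counts <- counts + as.integer(tab)
  }
  structure(list(counts = counts, genetic_code_id = as.integer(code),
                 n_excluded_codons = excluded, rscu = NULL),
            class = "CodonUsageTable")
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * family_size / sum(counts over the synonymous
#' family)`. Families with zero total usage are reported as `NA`
#' (undefined), not 0. Stop codons are excluded from families unless
#' `include_stops = TRUE`.
#'
#' @param tab A `CodonUsageTable` from [codon_counts()].
#' @param include_stops Treat stop codons as one synonymous family?
#' @return The table with `rscu` (named numeric over included codons),
#'   `aa` (amino-acid label per codon under the active code), and
#'   `family_size` filled in.
#' @export
rscu <- function(tab, include_stops = FALSE) {
  gc <- genetic_code(tab$genetic_code_id)
  aa <- gc[ALL_CODONS]
  keep <- if (include_stops) rep(TRUE, 64) else aa != "*"
  codons <- ALL_CODONS[keep]
  aak <- aa[keep]
  fam_size <- table(aak)[aak]
  fam_tot <- tapply(tab$counts[codons], aak, sum)[aak]
  vals <- ifelse(fam_tot > 0,
                 tab$counts[codons] * as.numeric(fam_size) / fam_tot,
                 NA_real_)
  tab$rscu <- setNames(as.numeric(vals), codons)
  tab$aa <- setNames(unname(aak), codons)
  tab$family_size <- setNames(as.integer(fam_size), codons)
  tab
}

#' Top codons by RSCU
#'
#' @param tab A `CodonUsageTable` with RSCU filled.
#' @param k Number of codons to return.
#' @return A data.frame ranked by decreasing RSCU, ties broken
#'   alphabetically by codon; columns codon, aa, count, rscu.
#' @export
top_codons <- function(tab, k = 5L) {
  if (is.null(tab$rscu)) stop("call rscu() first")
  ord <- order(-tab$rscu, names(tab$rscu), na.last = TRUE)
  top <- head(ord, k)
  data.frame(codon = names(tab$rscu)[top], aa = unname(tab$aa[top]),
             count = unname(tab$counts[names(tab$rscu)[top]]),
             rscu = unname(tab$rscu[top]), stringsAsFactors = FALSE)
}

#' Codon usage of a genome's concatenated PCGs
#'
#' Convenience wrapper: extracts the 13 protein-coding genes in
#' canonical order, concatenates them, and returns counts + RSCU (the
#' per-species presentation used in mitogenome reports).
#'
#' @param g A `MitoGenome`.
#' @param code Genetic-code id; defaults to the genome's.
#' @param include_stops Passed to [rscu()].
#' @return A `CodonUsageTable` with RSCU filled.
#' @export
genome_rscu <- function(g, code = g$genetic_code_id,
                        include_stops = FALSE) {
  pcg <- g$features[!is.na(g$features$gene_type) &
                      g$features$gene_type == "PCG", , drop = FALSE]
  pcg <- pcg[order(match(pcg$name, PCG_CONCAT_ORDER)), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(pcg)),
                 function(i) extract_sequence(g, pcg[i, ]), character(1))
  rscu(codon_counts(seqs, code = code), include_stops = include_stops)
}

#' Write a tab-separated RSCU report
#'
#' Columns: codon, amino acid, count, RSCU, family size.
#'
#' @param tab A `CodonUsageTable` with RSCU filled.
#' @param path Output path.
#' @export
rscu_report <- function(tab, path) {
  if (is.null(tab$rscu)) stop("call rscu() first")
  out <- data.frame(codon = names(tab$rscu), aa = unname(tab$aa),
                    count = unname(tab$counts[names(tab$rscu)]),
                    rscu = round_half_away(unname(tab$rscu), 2),
                    family_size = unname(tab$family_size))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
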