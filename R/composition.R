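# Base composition, AT/GC skew, and start/stop codon typing.

#' Round half away from zero
#'
#' Reporting convention for all printed statistics (base R's `round()`
#' rounds half to even, which would turn -0.205 into -0.20 instead of
#' -0.21).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Base composition of a nucleotide sequence
#'
#' Percentages are computed over unambiguous A/C/G/T only; other IUPAC
#' letters are tallied as `n_ambiguous` and excluded from percentages
#' and skew denominators.
#'
#' @param seq Nucleotide string.
#' @return A list of class `CompositionProfile` with `counts` (named
#'   A/T/G/C), `pct` (percentages), `at_content` (A+T %), `at_skew`,
#'   `gc_skew`, `n_ambiguous`, and `length`.
#' @export
base_composition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("empty sequence")
  cnt <- table(factor(strsplit(seq, "")[[1]],
                      levels = c("A", "T", "G", "C")))
  counts <- setNames(as.integer(cnt), names(cnt))
  n_unamb <- sum(counts)
  if (n_unamb == 0L) stop("sequence has no unambiguous bases")
  pct <- 100 * counts / n_unamb
  structure(list(
    counts = counts,
    pct = pct,
    at_content = unname(pct["A"] + pct["T"]),
    at_skew = unname((counts["A"] - counts["T"]) /
                       (counts["A"] + counts["T"])),
    gc_skew = unname((counts["G"] - counts["C"]) /
                       (counts["G"] + counts["C"])),
    n_ambiguous = nchar(seq) - n_unamb,
    length = nchar(seq)
  ), class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("A=%.1f T=%.1f G=%.1f C=%.1f  A+T=%.1f  AT-skew=%.2f  GC-skew=%.2f\n",
              x$pct["A"], x$pct["T"], x$pct["G"], x$pct["C"],
              round_half_away(x$at_content, 1),
              round_half_away(x$at_skew, 2),
              round_half_away(x$gc_skew, 2)))
  invisible(x)
}

#' AT skew from A and T percentages
#'
#' `(A - T) / (A + T)`. This percentage-argument form serves table-only
#' workflows; when a sequence is available, [base_composition()]
#' computes the skew from raw counts instead.
#'
#' @param a_pct,t_pct Percentages (or counts; only the ratio matters).
#' @return Dimensionless skew in `[-1, 1]`; `NA` with a warning when
#'   `A + T == 0`.
#' @export
at_skew <- function(a_pct, t_pct) {
  if (a_pct + t_pct == 0) {
    warning("A + T is zero; skew undefined")
    return(NA_real_)
  }
  (a_pct - t_pct) / (a_pct + t_pct)
}

#' GC skew from G and C percentages
#'
#' `(G - C) / (G + C)`; same contract as [at_skew()].
#'
#' @param g_pct,c_pct Percentages (or counts).
#' @return Dimensionless skew; `NA` with a warning when `G + C == 0`.
#' @export
gc_skew <- function(g_pct, c_pct) {
  if (g_pct + c_pct == 0) {
    warning("G + C is zero; skew undefined")
    return(NA_real_)
  }
  (g_pct - c_pct) / (g_pct + c_pct)
}

#' Per-gene composition profiles
#'
#' One [base_composition()] profile per feature, computed on the
#' oriented (reading-direction) gene sequence.
#'
#' @param g A `MitoGenome`.
#' @return A data.frame with one row per feature: gene, length, A/T/G/C
#'   percentages, at_content, at_skew, gc_skew.
#' @export
per_gene_composition <- function(g) {
  rows <- lapply(seq_len(nrow(g$features)), function(i) {
    f <- g$features[i, ]
    p <- base_composition(extract_sequence(g, f))
    data.frame(gene = f$name, length = p$length,
               A = unname(p$pct["A"]), T = unname(p$pct["T"]),
               G = unname(p$pct["G"]), C = unname(p$pct["C"]),
               at_content = p$at_content, at_skew = p$at_skew,
               gc_skew = p$gc_skew, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Start/stop codon annotation of protein-coding genes
#'
#' The start codon is the first 3 nt in reading direction. A gene whose
#' length is divisible by 3 has a complete 3-nt stop; otherwise the stop
#' is incomplete and typed from the remainder: `"T-"` (remainder 1,
#' terminal T) or `"TA-"` (remainder 2, terminal TA), completed to TAA
#' by transcript polyadenylation. Starts other than ATN/TTG/GTG are
#' flagged non-canonical.
#'
#' @param g A `MitoGenome`.
#' @return A data.frame: gene, start_codon, stop_codon, complete,
#'   canonical_start.
#' @export
start_stop_codons <- function(g) {
  pcg <- g$features[!is.na(g$features$gene_type) &
                      g$features$gene_type == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    f <- pcg[i, ]
    s <- extract_sequence(g, f)
    n <- nchar(s)
    if (n < 6L) stop("PCG ", f$name, " shorter than 6 nt")
    start <- substr(s, 1L, 3L)
    rem <- n %% 3L
    if (rem == 0L) {
      stop_c <- substr(s, n - 2L, n)
      complete <- TRUE
    } else {
      tail_nt <- substr(s, n - rem + 1L, n)
      stop_c <- paste0(tail_nt, "-")
      complete <- FALSE
    }
    data.frame(gene = f$name, start_codon = start, stop_codon = stop_c,
               complete = complete,
               canonical_start = grepl("^AT[ACGT]$|^TTG$|^GTG$", start),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Whole-genome composition report (tab-separated)
#'
#' Mirrors the printed base-content table column set (size, A, T, G, C,
#' A+T%, AT-skew, GC-skew), one row per genome plus optional gene-level
#' rows.
#'
#' @param genomes List of `MitoGenome` objects.
#' @param path Output path; when `NULL` the data.frame is returned only.
#' @param per_gene Also emit per-gene rows?
#' @return The report data.frame, invisibly when written.
#' @export
composition_report <- function(genomes, path = NULL, per_gene = FALSE) {
  rows <- lapply(genomes, function(g) {
    p <- base_composition(g$sequence)
    whole <- data.frame(
      Gene = g$accession, Size = p$length,
      A = round_half_away(unname(p$pct["A"]), 1),
      T = round_half_away(unname(p$pct["T"]), 1),
      G = round_half_away(unname(p$pct["G"]), 1),
      C = round_half_away(unname(p$pct["C"]), 1),
      `A.T.` = round_half_away(p$at_content, 1),
      AT.skew = round_half_away(p$at_skew, 2),
      GC.skew = round_half_away(p$gc_skew, 2),
      check.names = FALSE, stringsAsFactors = FALSE)
    if (!per_gene) return(whole)
    pg <- per_gene_composition(g)
    gene_rows <- data.frame(
      Gene = paste0(g$accession, ":", pg$gene), Size = pg$length,
      A = round_half_away(pg$A, 1), T = round_half_away(pg$T, 1),
      G = round_half_away(pg$G, 1), C = round_half_away(pg$C, 1),
      `A.T.` = round_half_away(pg$at_content, 1),
      AT.skew = round_half_away(pg$at_skew, 2),
      GC.skew = round_half_away(pg$gc_skew, 2),
      check.names = FALSE, stringsAsFactors = FALSE)
    rbind(whole, gene_rows)
  })
  rep <- do.call(rbind, rows)
  names(rep) <- c("Gene", "Size (bp)", "A", "T", "G", "C", "A+T%",
                  "AT-skew", "GC-skew")
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
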