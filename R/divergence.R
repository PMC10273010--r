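# Pairwise molecular evolution: nucleotide diversity (p-distance Pi)
# and Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.

BASES <- c("A", "C", "G", "T")

.ng86_env <- new.env(parent = emptyenv())

.codon_translate <- function(codon, gc) unname(gc[codon])

#' NG86 synonymous/nonsynonymous site counts for one codon
#'
#' Per codon position, the synonymous-site fraction is the proportion of
#' the single-base changes at that position that are synonymous, among
#' changes that do not create a stop codon (stop-creating mutations are
#' excluded from the denominator). Each position contributes one site,
#' so syn + nonsyn sites always total 3 per codon.
#'
#' @param codon 3-letter codon over A/C/G/T.
#' @param code Genetic-code id.
#' @return Named numeric `c(syn =, nonsyn =)`; `NA`s for stop or
#'   ambiguous codons (excluded marker).
#' @export
ng86_site_counts <- function(codon, code = 5L) {
  codon <- toupper(codon)
  key <- paste0("S", code)
  if (is.null(.ng86_env[[key]])) {
    gc <- genetic_code(code)
    tab <- t(vapply(ALL_CODONS, function(cd) {
      if (gc[cd] == "*") return(c(NA_real_, NA_real_))
      syn <- 0
      for (pos in 1:3) {
        ref <- substr(cd, pos, pos)
        nsyn <- 0L; nvalid <- 0L
        for (b in setdiff(BASES, ref)) {
          mut <- cd
          substr(mut, pos, pos) <- b
          if (gc[mut] == "*") next
          nvalid <- nvalid + 1L
          if (gc[mut] == gc[cd]) nsyn <- nsyn + 1L
        }
        if (nvalid > 0L) syn <- syn + nsyn / nvalid
      }
      c(syn, 3 - syn)
    }, numeric(2)))
    colnames(tab) <- c("syn", "nonsyn")
    .ng86_env[[key]] <- tab
  }
  if (!grepl("^[ACGT]{3}$", codon)) return(c(syn = NA_real_, nonsyn = NA_real_))
  out <- .ng86_env[[key]][codon, ]
  c(syn = unname(out["syn"]), nonsyn = unname(out["nonsyn"]))
}

#' NG86 pathway-averaged substitution counts between two codons
#'
#' For k mismatched positions the k! orderings of the single-base steps
#' are enumerated; orderings passing through a stop codon are discarded
#' and the synonymous/nonsynonymous step counts are averaged over the
#' remaining pathways. If every pathway hits a stop, the average falls
#' back to all orderings with a warning.
#'
#' @param a,b Unambiguous codons.
#' @param code Genetic-code id.
#' @return Named numeric `c(syn =, nonsyn =)`.
#' @export
ng86_path_differences <- function(a, b, code = 5L) {
  a <- toupper(a); b <- toupper(b)
  if (a == b) return(c(syn = 0, nonsyn = 0))
  key <- paste0("P", code)
  if (is.null(.ng86_env[[key]]))
    .ng86_env[[key]] <- new.env(parent = emptyenv())
  cache <- .ng86_env[[key]]
  ck <- paste0(a, b)
  hit <- cache[[ck]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code(code)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  perms <- .permutations(pos)
  paths <- lapply(perms, function(ord) {
    cur <- a
    syn <- 0L; nonsyn <- 0L; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[nxt] == "*" && nxt != b) blocked <- TRUE
      if (gc[nxt] == gc[cur]) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, blocked = blocked)
  })
  open <- !vapply(paths, `[[`, logical(1), "blocked")
  use <- if (any(open)) paths[open] else {
    warning("all pathways between ", a, " and ", b,
            " pass through stops; averaging over all orderings")
    paths
  }
  res <- c(syn = mean(vapply(use, `[[`, integer(1), "syn")),
           nonsyn = mean(vapply(use, `[[`, integer(1), "nonsyn")))
  cache[[ck]] <- res
  res
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' Pairwise nucleotide diversity (p-distance)
#'
#' Proportion of differing sites over the positions where both aligned
#' sequences carry unambiguous, ungapped bases. For more than two
#' sequences, [mean_pi()] averages this over all pairs.
#'
#' @param a,b Equal-length aligned nucleotide strings.
#' @return Differences per site in `[0, 1]`; `NA` with a warning when
#'   no site is comparable.
#' @export
pairwise_pi <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% BASES & b %in% BASES
  if (!any(ok)) {
    warning("no comparable sites")
    return(NA_real_)
  }
  mean(a[ok] != b[ok])
}

#' Mean pairwise nucleotide diversity over n sequences
#' @param seqs Character vector of equal-length aligned sequences.
#' @return Mean of [pairwise_pi()] over all pairs.
#' @export
mean_pi <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(ij) pairwise_pi(seqs[ij[1]], seqs[ij[2]])))
}

#' NG86 Ka/Ks between two aligned coding sequences
#'
#' Sequences are read in frame from position 1; a trailing incomplete
#' codon is dropped and terminal stop codons are trimmed. Codon pairs
#' with gaps or ambiguity in either sequence are excluded pairwise;
#' internal stops raise a warning and are excluded. Site counts are
#' averaged over the two sequences; the Jukes-Cantor correction
#' `d = -3/4 * log(1 - 4p/3)` is applied to both classes, with `p >=
#' 3/4` flagged as saturated (corrected value undefined).
#'
#' @param a,b Equal-length aligned in-frame CDS strings.
#' @param code Genetic-code id.
#' @param gene Optional gene name carried into the result.
#' @return A list of class `DivergenceResult`: `gene`, `pi`, `ka`, `ks`,
#'   `ratio`, `n_sites_compared`, `n_syn_sites`, `n_nonsyn_sites`,
#'   `saturated`.
#' @export
ka_ks <- function(a, b, code = 5L, gene = NA_character_) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("CDSs must be aligned (equal length)")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  gc <- genetic_code(code)
  n <- length(ca)
  # trim terminal stop codons
  while (n > 0L && ((grepl("^[ACGT]{3}$", ca[n]) && gc[ca[n]] == "*") ||
                    (grepl("^[ACGT]{3}$", cb[n]) && gc[cb[n]] == "*"))) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  unamb <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  stops <- unamb & (gc[ca] == "*" | gc[cb] == "*")
  stops[is.na(stops)] <- FALSE
  if (any(stops))
    warning(sum(stops), " internal stop codon pair(s) excluded")
  use <- which(unamb & !stops)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in use) {
    sa <- ng86_site_counts(ca[i], code)
    sb <- ng86_site_counts(cb[i], code)
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    d <- ng86_path_differences(ca[i], cb[i], code)
    Sd <- Sd + d["syn"]
    Nd <- Nd + d["nonsyn"]
  }
  jc <- function(p) {
    if (is.na(p)) return(list(d = NA_real_, sat = FALSE))
    if (p >= 0.75) return(list(d = NA_real_, sat = TRUE))
    list(d = -0.75 * log(1 - 4 * p / 3), sat = FALSE)
  }
  pS <- if (S > 0) unname(Sd / S) else NA_real_
  pN <- if (N > 0) unname(Nd / N) else NA_real_
  ks <- jc(pS); ka <- jc(pN)
  ratio <- if (is.na(ka$d) || is.na(ks$d) || ks$d == 0) NA_real_
           else ka$d / ks$d
  pi <- pairwise_pi(paste(ca[use], collapse = ""),
                    paste(cb[use], collapse = ""))
  structure(list(gene = gene, pi = pi, ka = ka$d, ks = ks$d,
                 ratio = ratio, n_sites_compared = 3L * length(use),
                 n_syn_sites = unname(S), n_nonsyn_sites = unname(N),
                 saturated = ka$sat || ks$sat),
            class = "DivergenceResult")
}

#' @export
print.DivergenceResult <- function(x, ...) {
  cat(sprintf("%s: Pi=%.4f Ka=%.4f Ks=%.4f Ka/Ks=%s (%d sites)\n",
              ifelse(is.na(x$gene), "pair", x$gene), x$pi,
              ifelse(is.na(x$ka), NaN, x$ka),
              ifelse(is.na(x$ks), NaN, x$ks),
              ifelse(is.na(x$ratio), "undef", sprintf("%.4f", x$ratio)),
              x$n_sites_compared))
  invisible(x)
}

#' Per-gene divergence between two annotated genomes
#'
#' For every shared protein-coding gene, extracts the oriented CDSs,
#' aligns them (positional identity when equal length, otherwise the
#' codon-aware aligner), and computes Pi and NG86 Ka/Ks.
#'
#' @param ga,gb `MitoGenome` objects.
#' @param code Genetic-code id; defaults to `ga`'s.
#' @return A data.frame: gene, pi, ka, ks, ratio, n_sites, n_syn_sites,
#'   n_nonsyn_sites.
#' @export
divergence_table <- function(ga, gb, code = ga$genetic_code_id) {
  shared <- intersect(ga$features$name[ga$features$gene_type %in% "PCG"],
                      gb$features$name[gb$features$gene_type %in% "PCG"])
  shared <- shared[order(match(shared, PCG_CONCAT_ORDER))]
  if (!length(shared)) stop("genomes share no protein-coding genes")
  rows <- lapply(shared, function(gene) {
    fa <- ga$features[ga$features$name == gene, ]
    fb <- gb$features[gb$features$name == gene, ]
    sa <- extract_sequence(ga, fa)
    sb <- extract_sequence(gb, fb)
    if (nchar(sa) != nchar(sb)) {
      aln <- align_gene(setNames(c(sa, sb), c("a", "b")), code = code)
      sa <- aln[["a"]]; sb <- aln[["b"]]
    }
    r <- ka_ks(sa, sb, code = code, gene = gene)
    data.frame(gene = gene, pi = r$pi, ka = r$ka, ks = r$ks,
               ratio = r$ratio, n_sites = r$n_sites_compared,
               n_syn_sites = r$n_syn_sites,
               n_nonsyn_sites = r$n_nonsyn_sites,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
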