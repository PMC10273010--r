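# Codon-aware alignment, strict trimming, concatenation into a
# partitioned supermatrix, distances, and format writers.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z",
                  "X", "*", "-")

.aa_score_matrix <- function() {
  if (is.null(.ng86_env$aa_score)) {
    blo <- .load_blosum62()
    n <- length(.AA_ALPHABET)
    S <- matrix(-4, n, n, dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
    common <- intersect(rownames(blo), .AA_ALPHABET)
    S[common, common] <- blo[common, common]
    S["-", ] <- -4
    S[, "-"] <- -4
    S["-", "-"] <- 0
    .ng86_env$aa_score <- S
  }
  .ng86_env$aa_score
}

.load_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Complete an incomplete terminal stop codon
#'
#' Pads a CDS whose length is not a multiple of 3 with `A` characters,
#' mirroring the post-transcriptional polyadenylation that completes a
#' terminal `T`/`TA` to `TAA`. Complete CDSs are returned unchanged.
#'
#' @param cds CDS string.
#' @return CDS string with length a multiple of 3.
#' @export
complete_stop <- function(cds) {
  rem <- nchar(cds) %% 3L
  if (rem == 0L) return(cds)
  paste0(cds, strrep("A", 3L - rem))
}

.trim_terminal_stop <- function(cds, gc) {
  n <- nchar(cds)
  last <- substr(cds, n - 2L, n)
  if (grepl("^[ACGT]{3}$", last) && gc[last] == "*")
    substr(cds, 1L, n - 3L)
  else cds
}

#' Codon-based multiple alignment of orthologous CDSs
#'
#' Each CDS is completed ([complete_stop()]), its terminal stop codon
#' trimmed, and translated; the proteins are aligned progressively
#' (pairwise-to-profile, global affine-gap alignment on BLOSUM62 scores,
#' guide order = input order, deterministic tie-breaks) and the codons
#' threaded back, so gaps occur only in multiples of 3. Removing the
#' gaps from any output row reproduces that row's preprocessed CDS
#' exactly.
#'
#' @param orthologs Named character vector of CDSs (names = taxa).
#' @param code Genetic-code id.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @return Named character vector: aligned CDSs, equal length, length a
#'   multiple of 3. Taxa whose CDS has an internal stop after trimming
#'   are excluded with a warning.
#' @export
align_gene <- function(orthologs, code = 5L, gap_open = -10,
                       gap_extend = -1) {
  if (length(orthologs) < 2L) stop("need at least two taxa")
  if (is.null(names(orthologs)) || anyDuplicated(names(orthologs)))
    stop("orthologs must carry unique taxon names")
  gc <- genetic_code(code)
  prep <- lapply(orthologs, function(s)
    .trim_terminal_stop(complete_stop(toupper(s)), gc))
  prots <- lapply(prep, function(s) {
    cods <- .split_codons(s)
    aa <- ifelse(grepl("^[ACGT]{3}$", cods), gc[cods], "X")
    aa[is.na(aa)] <- "X"
    aa
  })
  bad <- vapply(prots, function(p) any(p == "*"), logical(1))
  if (any(bad)) {
    warning("excluded taxa with internal stops: ",
            paste(names(prots)[bad], collapse = ", "))
    prep <- prep[!bad]
    prots <- prots[!bad]
    if (length(prots) < 2L) stop("fewer than two translatable taxa")
  }
  S <- .aa_score_matrix()
  enc <- function(x) match(x, .AA_ALPHABET)

  # progressive: grow a profile matrix (rows = taxa, cols = positions)
  prof <- matrix(prots[[1]], nrow = 1)
  for (k in seq_along(prots)[-1]) {
    newrow <- matrix(prots[[k]], nrow = 1)
    A <- matrix(enc(prof), nrow = nrow(prof))
    B <- matrix(enc(newrow), nrow = 1)
    moves <- .profile_align_cpp(A, B, S, gap_open, gap_extend)
    La <- length(moves)
    out <- matrix("-", nrow = nrow(prof) + 1L, ncol = La)
    ai <- 0L; bi <- 0L
    for (m in seq_len(La)) {
      if (moves[m] != 3L) ai <- ai + 1L
      if (moves[m] != 2L) bi <- bi + 1L
      if (moves[m] != 3L) out[seq_len(nrow(prof)), m] <- prof[, ai]
      if (moves[m] != 2L) out[nrow(prof) + 1L, m] <- newrow[1, bi]
    }
    prof <- out
  }

  # thread codons back through the protein alignment
  aligned <- vapply(seq_len(nrow(prof)), function(r) {
    cods <- .split_codons(prep[[r]])
    res <- character(ncol(prof))
    ci <- 0L
    for (m in seq_len(ncol(prof))) {
      if (prof[r, m] == "-") res[m] <- "---"
      else { ci <- ci + 1L; res[m] <- cods[ci] }
    }
    paste(res, collapse = "")
  }, character(1))
  setNames(aligned, names(prep))
}

#' Strict codon-column trimming
#'
#' A deterministic stand-in for ambiguity filters: drops every codon
#' column that contains a gap or ambiguity character in any taxon.
#'
#' @param aln Named character vector codon alignment (lengths equal,
#'   multiple of 3).
#' @return List: `alignment` (trimmed), `retained_fraction` (of codon
#'   columns), `removed_columns` (1-based codon-column indices).
#' @export
trim_alignment <- function(aln) {
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("rows differ in length")
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3")
  ncod <- L %/% 3L
  mat <- do.call(rbind, lapply(aln, function(s)
    matrix(strsplit(s, "")[[1]], nrow = 1)))
  keep <- vapply(seq_len(ncod), function(k) {
    block <- mat[, (3L * k - 2L):(3L * k), drop = FALSE]
    all(block %in% c("A", "C", "G", "T"))
  }, logical(1))
  if (!any(keep)) stop("all codon columns removed by trimming")
  cols <- as.vector(vapply(which(keep), function(k)
    (3L * k - 2L):(3L * k), integer(3)))
  trimmed <- vapply(seq_along(aln), function(i)
    paste(mat[i, cols], collapse = ""), character(1))
  list(alignment = setNames(trimmed, names(aln)),
       retained_fraction = mean(keep),
       removed_columns = which(!keep))
}

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are joined in the canonical mitochondrial order (nad2, cox1,
#' cox2, atp8, atp6, cox3, nad3, nad5, nad4, nad4l, nad6, cob, nad1);
#' genes not in that list follow alphabetically. Taxa missing from a
#' gene are filled with gap rows and flagged.
#'
#' @param gene_alignments Named list (gene -> named character vector of
#'   aligned CDSs).
#' @return An object of class `Supermatrix`: `taxa`, `seqs` (named
#'   aligned strings), `partitions` (data.frame gene, start, end),
#'   `filled` (data.frame gene, taxon for gap-filled rows).
#' @export
concatenate <- function(gene_alignments) {
  if (is.null(names(gene_alignments)))
    stop("gene_alignments must be named by gene")
  ord <- order(match(names(gene_alignments), PCG_CONCAT_ORDER),
               names(gene_alignments))
  gene_alignments <- gene_alignments[ord]
  taxa <- unique(unlist(lapply(gene_alignments, names)))
  if (anyDuplicated(taxa)) stop("duplicated taxon names")
  seqs <- setNames(rep("", length(taxa)), taxa)
  parts <- list()
  filled <- list()
  pos <- 0L
  for (gene in names(gene_alignments)) {
    aln <- gene_alignments[[gene]]
    if (anyDuplicated(names(aln)))
      stop("duplicated taxon in gene ", gene)
    L <- unique(nchar(aln))
    if (length(L) != 1L) stop("unequal row lengths in gene ", gene)
    miss <- setdiff(taxa, names(aln))
    if (length(miss)) {
      filled[[gene]] <- data.frame(gene = gene, taxon = miss,
                                   stringsAsFactors = FALSE)
      aln[miss] <- strrep("-", L)
    }
    seqs <- paste0(seqs, aln[taxa])
    parts[[gene]] <- data.frame(gene = gene, start = pos + 1L,
                                end = pos + L, stringsAsFactors = FALSE)
    pos <- pos + L
  }
  structure(list(taxa = taxa, seqs = setNames(seqs, taxa),
                 partitions = do.call(rbind, c(parts,
                                               make.row.names = FALSE)),
                 filled = if (length(filled))
                   do.call(rbind, c(filled, make.row.names = FALSE))
                 else NULL),
            class = "Supermatrix")
}

#' @export
print.Supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x",
      nchar(x$seqs[1]), "columns,", nrow(x$partitions), "gene partitions\n")
  invisible(x)
}

#' Partition scheme of a supermatrix
#'
#' @param m A `Supermatrix`.
#' @param scheme `"gene"` (one partition per gene) or `"gene_codon"`
#'   (three codon-position partitions per gene).
#' @return A data.frame: name, start, end, step (3 for codon-position
#'   partitions, 1 otherwise).
#' @export
partition_scheme <- function(m, scheme = c("gene", "gene_codon")) {
  scheme <- match.arg(scheme)
  p <- m$partitions
  if (scheme == "gene")
    return(data.frame(name = p$gene, start = p$start, end = p$end,
                      step = 1L, stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    data.frame(name = paste0(p$gene[i], "_pos", 1:3),
               start = p$start[i] + 0:2, end = p$end[i] - 2:0 + 2L - 2L,
               step = 3L, stringsAsFactors = FALSE)
  }))
}

#' Pairwise distance matrix from a supermatrix
#'
#' @param m A `Supermatrix` (or named character vector of aligned
#'   sequences).
#' @param model `"p"` (p-distance) or `"K2P"` (Kimura two-parameter,
#'   `d = -1/2 log((1-2P-Q) sqrt(1-2Q))`).
#' @return A symmetric numeric matrix with zero diagonal; entries are
#'   `NA` when a pair shares no comparable site or the K2P log argument
#'   is non-positive.
#' @export
distance_matrix <- function(m, model = c("p", "K2P")) {
  model <- match.arg(model)
  seqs <- if (inherits(m, "Supermatrix")) m$seqs else m
  n <- length(seqs)
  if (n < 2L) stop("need at least two taxa")
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  is_ts <- function(x, y) (x %in% c("A", "G") & y %in% c("A", "G")) |
    (x %in% c("C", "T") & y %in% c("C", "T"))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a %in% BASES & b %in% BASES
    if (!any(ok)) { D[i, j] <- D[j, i] <- NA_real_; next }
    a <- a[ok]; b <- b[ok]
    if (model == "p") {
      d <- mean(a != b)
    } else {
      diffs <- a != b
      P <- mean(diffs & is_ts(a, b))
      Q <- mean(diffs & !is_ts(a, b))
      arg1 <- 1 - 2 * P - Q
      arg2 <- 1 - 2 * Q
      d <- if (arg1 <= 0 || arg2 <= 0) NA_real_
           else -0.5 * log(arg1 * sqrt(arg2))
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "model") <- model
  D
}
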