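# Independent brute-force oracles, kept free of the package's own
# counting code paths.

# Table 2-style composition used across tests (plus-strand proportions).
TEST_COMP <- c(A = 0.427, T = 0.318, G = 0.096, C = 0.158) / 0.999

oracle_genetic_code <- function(code = 5L)
  Biostrings::getGeneticCode(as.character(code))

# All single-base mutants of a codon at one position.
oracle_mutants <- function(codon, pos) {
  out <- character(0)
  for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    m <- codon
    substr(m, pos, pos) <- b
    out <- c(out, m)
  }
  out
}

# Fractional synonymous sites by direct enumeration of the 9 mutants.
oracle_site_counts <- function(codon, code = 5L) {
  gc <- oracle_genetic_code(code)
  aa <- gc[[codon]]
  syn <- 0
  for (pos in 1:3) {
    muts <- oracle_mutants(codon, pos)
    keep <- vapply(muts, function(m) gc[[m]] != "*", logical(1))
    if (!any(keep)) next
    syn <- syn + sum(gc[muts[keep]] == aa) / sum(keep)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# All orderings of a set of positions, generated non-recursively.
oracle_orderings <- function(pos) {
  k <- length(pos)
  if (k == 1) return(list(pos))
  grid <- expand.grid(rep(list(pos), k), stringsAsFactors = FALSE)
  keep <- apply(grid, 1, function(r) length(unique(r)) == k)
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

# Pathway-averaged syn/nonsyn differences by exhaustive enumeration.
oracle_path_diffs <- function(a, b, code = 5L) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  gc <- oracle_genetic_code(code)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  res <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- a
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[[nxt]] == "*" && nxt != b) blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(syn, nonsyn, blocked)
  }
  m <- do.call(rbind, res)
  use <- m[m[, 3] == 0, , drop = FALSE]
  if (nrow(use) == 0) use <- m
  c(syn = mean(use[, 1]), nonsyn = mean(use[, 2]))
}

# Toy genome builder for coordinate/extraction tests.
toy_genome <- function(sequence, feats) {
  mito_genome(sequence, do.call(rbind, feats), accession = "toy")
}
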