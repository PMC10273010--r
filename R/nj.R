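# Canonical neighbor-joining with deterministic tie-breaks.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei's agglomerative algorithm. At each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined; ties are
#' broken by the (sorted) names of the candidate nodes so the output is
#' deterministic. Negative branch lengths are clamped to 0 with the
#' deficit moved to the sibling branch (preserving the path length
#' through the new node). The result is an unrooted tree written with a
#' trifurcating root, compatible with standard Newick readers.
#'
#' @param d Symmetric distance matrix with taxon dimnames, >= 3 taxa,
#'   all entries defined.
#' @return Newick string (terminated by `;`).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d))) stop("need a named matrix")
  if (anyNA(d)) stop("undefined distance entries")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  nwk <- labels          # newick fragment per active node
  key <- labels          # tie-break key per active node
  D <- d

  while (n > 3L) {
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - r[i] - r[j]
      cand_key <- paste(sort(c(key[i], key[j])), collapse = "|")
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 && cand_key < best$key))
        best <- list(i = i, j = j, q = q, key = cand_key)
    }
    i <- best$i; j <- best$j
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], bi, nwk[j], bj)
    new_key <- min(key[i], key[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    D <- D2
    n <- n - 1L
  }

  # final trifurcation: three nodes joined at one internal vertex
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("b1", "b2", "b3"))
    assign(v, max(0, get(v)))
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          nwk[1], b1, nwk[2], b2, nwk[3], b3)
}
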