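test_that("complete_stop pads incomplete terminal stops", {
  expect_equal(complete_stop("ATGAAAT"), "ATGAAATAA")
  expect_equal(complete_stop("ATGAAATA"), "ATGAAATAA")
  expect_equal(complete_stop("ATGAAATAA"), "ATGAAATAA")
})

test_that("align_gene: identity, clean indels, and protein-guided gaps", {
  a <- "ATGAAAGTTCCA"
  ident <- align_gene(c(x = a, y = a))
  expect_equal(unname(ident), c(a, a))

  # clean 3-bp deletion restored as one codon gap
  b <- "ATGGTTCCA"  # AAA codon deleted
  aln <- align_gene(c(x = a, y = b))
  expect_equal(nchar(aln[["x"]]), nchar(aln[["y"]]))
  expect_equal(gsub("-", "", aln[["y"]]), b)
  expect_equal(aln[["x"]], a)
  expect_equal(unname(aln[["y"]]), "ATG---GTTCCA")

  # MKV vs MV: single residue gap at position 2
  mkv <- align_gene(c(x = "ATGAAAGTA", y = "ATGGTA"))
  expect_equal(unname(mkv[["y"]]), "ATG---GTA")

  # taxa with internal stops are excluded with a warning
  expect_warning(
    tri <- align_gene(c(x = a, y = a, z = "ATGTAAGTTCCA")),
    "internal stops")
  expect_equal(names(tri), c("x", "y"))
  expect_error(align_gene(c(x = a)), "at least two")
})

test_that("back-threading reproduces inputs after degapping", {
  set.seed(12)
  for (i in 1:10) {
    anc <- random_cds(60 * 3, TEST_COMP)
    anc <- substr(anc, 1, nchar(anc) - 3)  # drop stop: stays untouched
    seqs <- c(a = anc,
              b = mitocomp:::.delete_codons(anc, 0.1),
              c = mitocomp:::.delete_codons(anc, 0.1))
    aln <- align_gene(seqs)
    expect_equal(gsub("-", "", aln), seqs)
    expect_equal(unique(nchar(aln) %% 3), 0L)
  }
})

test_that("trim_alignment drops exactly the gap/ambiguity codon columns", {
  aln <- c(a = "ATGAAAGTT", b = "ATG---GTT")
  tr <- trim_alignment(aln)
  expect_equal(unname(tr$alignment), c("ATGGTT", "ATGGTT"))
  expect_equal(tr$retained_fraction, 2 / 3)
  expect_equal(tr$removed_columns, 2L)

  clean <- c(a = "ATGAAA", b = "ATGAAA")
  expect_equal(trim_alignment(clean)$alignment, clean)
  expect_error(trim_alignment(c(a = "---", b = "AAA")), "all codon")

  # recount oracle on a simulated alignment with ~10% codon deletions
  set.seed(13)
  anc <- random_cds(300, TEST_COMP)
  seqs <- c(a = anc, b = mitocomp:::.delete_codons(anc, 0.1),
            c = mitocomp:::.delete_codons(anc, 0.1))
  aln2 <- align_gene(seqs)
  tr2 <- trim_alignment(aln2)
  ncod <- nchar(aln2[[1]]) / 3
  gapfree <- sum(vapply(seq_len(ncod), function(k) {
    blocks <- substring(aln2, 3 * k - 2, 3 * k)
    all(!grepl("[^ACGT]", blocks))
  }, logical(1)))
  expect_equal(tr2$retained_fraction, gapfree / ncod)
})

test_that("concatenate builds a tiling partition map", {
  g1 <- c(t1 = strrep("A", 300), t2 = strrep("C", 300))
  g2 <- c(t1 = strrep("G", 600), t2 = strrep("T", 600))
  m <- concatenate(list(cox1 = g1, cox2 = g2))
  expect_equal(nchar(m$seqs[["t1"]]), 900)
  expect_equal(m$partitions$start, c(1L, 301L))
  expect_equal(m$partitions$end, c(300L, 900L))

  # single gene: supermatrix equals the alignment
  ms <- concatenate(list(cox1 = g1))
  expect_equal(ms$seqs, g1)

  # missing taxon filled with gaps and flagged
  g3 <- c(t1 = strrep("A", 30))
  mf <- concatenate(list(cox1 = g3, cox2 = c(t1 = strrep("G", 9),
                                             t2 = strrep("T", 9))))
  expect_equal(substr(mf$seqs[["t2"]], 1, 30), strrep("-", 30))
  expect_equal(mf$filled$taxon, "t2")

  expect_error(concatenate(list(cox1 = c(a = "AAA", a = "CCC"))),
               "duplicated taxon")
})

test_that("partition schemes tile the supermatrix", {
  set.seed(14)
  alns <- lapply(setNames(nm = c("nad2", "cox1", "cox2")), function(g)
    c(a = random_cds(30, TEST_COMP), b = random_cds(30, TEST_COMP)))
  m <- concatenate(alns)
  pg <- partition_scheme(m, "gene")
  expect_equal(nrow(pg), 3L)
  expect_equal(pg$start[1], 1L)
  expect_equal(pg$end[nrow(pg)], nchar(m$seqs[[1]]))
  # gene intervals tile without overlap
  expect_equal(pg$start[-1], pg$end[-nrow(pg)] + 1L)

  pc <- partition_scheme(m, "gene_codon")
  expect_equal(nrow(pc), 9L)
  covered <- sort(unlist(lapply(seq_len(nrow(pc)), function(i)
    seq(pc$start[i], pc$end[i], by = pc$step[i]))))
  expect_equal(covered, seq_len(nchar(m$seqs[[1]])))
})

test_that("distance_matrix: p-distance and K2P closed form", {
  m <- c(a = "AAAA", b = "AATT")
  D <- distance_matrix(m, "p")
  expect_equal(D["a", "b"], 0.5)
  expect_equal(diag(D), c(a = 0, b = 0))

  ident <- distance_matrix(c(a = "ACGT", b = "ACGT"), "K2P")
  expect_equal(ident["a", "b"], 0)

  # constructed P/Q case: 2 transitions + 1 transversion over 10 sites
  x <- c(a = "AAAACCCCGT", b = "GAAATCCCGA")
  P <- 0.2; Q <- 0.1
  Dk <- distance_matrix(x, "K2P")
  expect_equal(Dk["a", "b"], -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
})

test_that("K2P agrees with an independent implementation", {
  set.seed(15)
  seqs <- c(a = random_cds(300, TEST_COMP), b = random_cds(300, TEST_COMP),
            c = random_cds(300, TEST_COMP))
  D <- distance_matrix(seqs, "K2P")
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  Dape <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80"))
  expect_equal(unclass(D)[names(seqs), names(seqs)],
               Dape[names(seqs), names(seqs)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("alignment writers round-trip sequence content", {
  set.seed(16)
  aln <- align_gene(c(tax1 = random_cds(60, TEST_COMP),
                      tax2 = random_cds(60, TEST_COMP)))
  m <- concatenate(list(cox1 = aln))

  fa <- tempfile(fileext = ".fasta")
  write_fasta(m$seqs, fa)
  expect_equal(read_fasta(fa), m$seqs)

  phy <- tempfile(fileext = ".phy")
  write_phylip(m$seqs, phy)
  expect_equal(read_phylip(phy), m$seqs)

  nex <- tempfile(fileext = ".nex")
  write_nexus(m, nex)
  nx <- ape::read.nexus.data(nex)
  got <- vapply(nx, function(ch) toupper(paste(ch, collapse = "")),
                character(1))
  expect_equal(got[names(m$seqs)], m$seqs)

  pt <- tempfile(fileext = ".txt")
  write_partitions(m, pt, scheme = "gene_codon")
  lines <- readLines(pt)
  expect_length(lines, 3L)
  expect_match(lines[1], "^DNA, cox1_pos1 = 1-\\d+\\\\3$")
})
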