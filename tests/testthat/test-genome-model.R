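test_that("feature lengths reproduce every printed size in both fixtures", {
  for (w in c("porrectus", "sordidus")) {
    fx <- fixture_features(w)
    lens <- feature_length(fx$features, fx$genome_length)
    printed <- fx$printed$size[match(fx$features$name, fx$printed$gene)]
    expect_equal(lens, printed, info = w)
    expect_equal(nrow(fx$features), 37L)
  }
})

test_that("feature_length is wrap-aware", {
  f <- gene_feature("trnI", 15170, 10, "forward", wraps_origin = TRUE)
  expect_equal(feature_length(f, 15174L), 15L)
  expect_equal(feature_length(gene_feature("trnR", 5861, 5920, "forward")),
               60L)
})

test_that("extract_sequence honors direction and circularity", {
  g <- toy_genome("ATGCC", list(
    gene_feature("trnI", 1, 4, "forward"),
    gene_feature("trnQ", 1, 4, "reverse", gene_type = "tRNA")))
  expect_error(mito_genome("ATGCC", rbind(
    gene_feature("trnI", 1, 4, "forward", strand_label = "N"),
    gene_feature("trnQ", 1, 4, "reverse", strand_label = "N"))),
    "pairing")
  expect_equal(extract_sequence(g, g$features[1, ]), "ATGC")
  expect_equal(extract_sequence(g, g$features[2, ]), "GCAT")
  # wrap-around forward feature crosses the origin
  gw <- toy_genome("ATGCC", list(
    gene_feature("trnI", 4, 2, "forward", wraps_origin = TRUE)))
  expect_equal(extract_sequence(gw, gw$features[1, ]), "CCAT")
  expect_error(extract_sequence(g, gene_feature("cox1", 2, 9, "forward")),
               "bounds")
})

test_that("extract_sequence length equals feature_length on random circular genomes", {
  set.seed(42)
  for (i in 1:1000) {
    glen <- sample(50:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), glen, TRUE), collapse = "")
    start <- sample(glen, 1)
    span <- sample(glen - 1, 1)
    end0 <- start + span - 1L
    wraps <- end0 > glen
    f <- gene_feature("cox1", start, if (wraps) end0 - glen else end0,
                      sample(c("forward", "reverse"), 1),
                      wraps_origin = wraps)
    g <- mito_genome(seq, f)
    expect_equal(nchar(extract_sequence(g, f)), feature_length(f, glen))
  }
})

test_that("feature tables round-trip bit-for-bit and reject bad input", {
  fx <- fixture_features("porrectus")
  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(fx$features, tmp)
  back <- read_feature_table(tmp, fx$genome_length)
  expect_equal(back$start, fx$features$start)
  expect_equal(back$end, fx$features$end)
  expect_equal(back$strand_label, fx$features$strand_label)
  expect_equal(back$direction, fx$features$direction)
  expect_equal(back$name, fx$features$name)

  bad <- tempfile()
  writeLines(c("gene\tstart\tend\tstrand\tdirection",
               "trnI\t1\t64\tN\tforward",
               "trnI\t70\t130\tN\tforward"), bad)
  expect_error(read_feature_table(bad), "duplicate")
  writeLines(c("gene\tstart\tend\tstrand\tdirection",
               "trnI\tone\t64\tN\tforward"), bad)
  expect_error(read_feature_table(bad), "coordinates")
  writeLines("gene\tstart\tend\tstrand\tdirection", bad)
  expect_warning(empty <- read_feature_table(bad), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("gene names canonicalize through the synonym map", {
  out <- canonical_gene_name(c("COI", "ND4L", "CYTB", "tRNA-Met",
                               "16S rRNA", "mystery"))
  expect_equal(unname(out[1:5]), c("cox1", "nad4l", "cob", "trnM", "rrnL"))
  expect_false(attr(out, "known")[6])
  expect_equal(gene_type_of(c("cox1", "trnM", "rrnL", "dloop")),
               c("PCG", "tRNA", "rRNA", "control"))
})

test_that("validate_annotation reports the 37-gene census and findings", {
  fx <- fixture_features("porrectus")
  g <- mito_genome(strrep("A", fx$genome_length), fx$features)
  v <- validate_annotation(g)
  expect_equal(unname(v$counts[c("PCG", "tRNA", "rRNA")]), c(13L, 22L, 2L))
  expect_length(v$missing, 0)
  expect_equal(v$n_findings, 0L)

  drop <- fx$features[fx$features$name != "trnV", ]
  v2 <- validate_annotation(mito_genome(strrep("A", fx$genome_length), drop))
  expect_equal(v2$missing, "trnV")
  expect_match(v2$findings, "missing gene: trnV", all = FALSE)
})

test_that("GenBank files round-trip through write_genbank/read_genbank", {
  cfg <- sim_config(seed = 11)
  anc <- simulate_ancestor(cfg)$genome
  tmp <- tempfile(fileext = ".gb")
  write_genbank(anc, tmp)
  back <- read_genbank(tmp)
  expect_equal(back$sequence, anc$sequence)
  expect_equal(back$features$name, anc$features$name)
  expect_equal(back$features$start, anc$features$start)
  expect_equal(back$features$end, anc$features$end)
  expect_equal(back$features$direction, anc$features$direction)
  expect_error(read_genbank(fixture_table_path("porrectus")),
               "not a GenBank")
})
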