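test_that("cmd_profile writes composition, ledger, RSCU, and strand reports", {
  cfg <- sim_config(seed = 41)
  anc <- simulate_ancestor(cfg)$genome
  dir <- tempfile()
  suppressMessages(cmd_profile(list(anc), out_dir = dir))
  expect_true(file.exists(file.path(dir, "composition.tsv")))
  led <- read.delim(file.path(dir, paste0("ledger_", anc$accession, ".tsv")),
                    check.names = FALSE, comment.char = "#")
  expect_equal(nrow(led), 37L)
  expect_true(file.exists(file.path(dir, paste0("rscu_", anc$accession,
                                                ".tsv"))))
  strand <- read.delim(file.path(dir, paste0("strand_", anc$accession,
                                             ".tsv")), comment.char = "#")
  expect_equal(sum(strand$forward), 23L)
  # reports carry a tool/config header
  expect_match(readLines(file.path(dir, "composition.tsv"), n = 1),
               "^# mitocomp .* genetic code 5")
})

test_that("cmd_profile on the published ledger reproduces the 11 overlaps", {
  fx <- fixture_features("porrectus")
  set.seed(42)
  g <- mito_genome(paste(sample(c("A", "C", "G", "T"), fx$genome_length,
                                TRUE, prob = TEST_COMP), collapse = ""),
                   fx$features, accession = "porrectus_fixture")
  dir <- tempfile()
  suppressMessages(cmd_profile(list(g), out_dir = dir))
  led <- read.delim(file.path(dir, "ledger_porrectus_fixture.tsv"),
                    check.names = FALSE, comment.char = "#")
  expect_equal(sum(led$`Intergenic nucleotides` < 0), 11L)
})

test_that("cmd_profile degrades gracefully on FASTA-only input and bad paths", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(plain = strrep("ACGT", 100)), fa)
  dir <- tempfile()
  expect_message(cmd_profile(fa, out_dir = dir), "skipped")
  expect_true(file.exists(file.path(dir, "composition.tsv")))
  expect_length(list.files(dir), 1L)
  expect_error(cmd_profile("no/such/file.gb", out_dir = tempfile()),
               "not found")
})

test_that("cmd_compare reports per-gene divergence and self-comparison zeros", {
  cfg <- sim_config(seed = 43)
  pair <- evolve_pair(simulate_ancestor(cfg), cfg)
  out <- tempfile(fileext = ".tsv")
  div <- suppressMessages(cmd_compare(pair$a, pair$b, out = out))
  expect_equal(nrow(div), 13L)
  expect_true(all(div$ratio < 1, na.rm = TRUE))
  expect_true(file.exists(out))

  self <- suppressMessages(cmd_compare(pair$a, pair$a,
                                       out = tempfile(fileext = ".tsv")))
  expect_true(all(self$pi == 0))

  fa_only <- mito_genome("ACGTACGT", mitocomp:::.empty_features())
  expect_error(suppressMessages(cmd_compare(pair$a, fa_only)), "annotated")
})

test_that("cmd_supermatrix recovers the generating quartet", {
  cfg_root <- sim_config(seed = 44, syn_branch_length = 0.25)
  root <- simulate_ancestor(cfg_root)
  inner <- evolve_pair(root, cfg_root)
  cfg_tip <- sim_config(seed = 45, syn_branch_length = 0.08)
  ab <- evolve_pair(inner$a, cfg_tip)
  cfg_tip2 <- sim_config(seed = 46, syn_branch_length = 0.08)
  cd <- evolve_pair(inner$b, cfg_tip2)
  taxa <- list(ab$a, ab$b, cd$a, cd$b)
  dir <- tempfile()
  m <- suppressMessages(cmd_supermatrix(taxa, out_dir = dir))
  expect_equal(nrow(m$partitions), 13L)
  for (f in c("supermatrix.fasta", "supermatrix.phy", "supermatrix.nex",
              "partitions.txt", "nj.nwk"))
    expect_true(file.exists(file.path(dir, f)), info = f)
  tr <- ape::read.tree(file.path(dir, "nj.nwk"))
  labs <- c(ab$a$accession, ab$b$accession, cd$a$accession, cd$b$accession)
  ref <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));", labs[1],
                                       labs[2], labs[3], labs[4]))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  expect_error(suppressMessages(cmd_supermatrix(taxa[1:2])), "at least 3")
  expect_error(suppressMessages(cmd_supermatrix(list(ab$a, ab$a, cd$a))),
               "duplicate")
})

test_that("mito_cli dispatches, honors config files, and reports failures", {
  dir <- tempfile()
  expect_equal(suppressMessages(
    mito_cli(c("simulate", "--seed", "7", "--out", dir))), 0L)
  gb <- file.path(dir, "SIM000007.gb")
  expect_true(file.exists(gb))
  expect_true(file.exists(file.path(dir, "truth.tsv")))

  out2 <- tempfile()
  expect_equal(suppressMessages(
    mito_cli(c("profile", gb, "--out", out2))), 0L)
  expect_true(file.exists(file.path(out2, "composition.tsv")))

  expect_output(expect_equal(suppressMessages(mito_cli(c("validate", gb))),
                             0L), "13 PCG, 22 tRNA, 2 rRNA, 0 findings")

  # config file supplies --out; command line is absent
  cfgf <- tempfile()
  out3 <- tempfile()
  writeLines(paste0("out: ", out3), cfgf)
  expect_equal(suppressMessages(
    mito_cli(c("profile", gb, "--config", cfgf))), 0L)
  expect_true(file.exists(file.path(out3, "composition.tsv")))

  # failures exit nonzero, never throw
  expect_message(expect_equal(mito_cli(c("profile", "missing.gb")), 1L),
                 "error")
  expect_message(expect_equal(mito_cli(character()), 1L), "usage")
  expect_message(expect_equal(mito_cli(c("frobnicate")), 1L), "unknown")
})

test_that("cli runs are re-runnable byte-for-byte", {
  d1 <- tempfile(); d2 <- tempfile()
  suppressMessages(mito_cli(c("simulate", "--seed", "9", "--out", d1)))
  suppressMessages(mito_cli(c("simulate", "--seed", "9", "--out", d2)))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})
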