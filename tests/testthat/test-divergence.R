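test_that("pairwise_pi is the p-distance over comparable sites", {
  expect_equal(pairwise_pi("AAAA", "AAAT"), 0.25)
  expect_equal(pairwise_pi("ACGT", "ACGT"), 0)
  # gaps/ambiguity excluded pairwise
  expect_equal(pairwise_pi("AA-N", "ATTT"), 0.5)
  expect_error(pairwise_pi("AAA", "AAAA"), "aligned")
  expect_warning(expect_true(is.na(pairwise_pi("NN", "AA"))), "comparable")
  expect_equal(mean_pi(c("AAAA", "AAAT", "AATT")),
               mean(c(0.25, 0.5, 0.25)))
})

test_that("NG86 site counts: spot checks against direct enumeration", {
  # fourfold third position: Gly GGA
  sc <- ng86_site_counts("GGA")
  expect_equal(unname(sc["syn"]), oracle_site_counts("GGA")[["syn"]])
  expect_gte(sc[["syn"]], 1)  # third position fully synonymous
  # Met ATG in code 5: no synonymous one-step change at positions 1-2
  expect_equal(ng86_site_counts("ATG")[["syn"]],
               oracle_site_counts("ATG")[["syn"]])
  # stop and ambiguous codons are excluded markers
  expect_true(all(is.na(ng86_site_counts("TAA"))))
  expect_true(all(is.na(ng86_site_counts("ANA"))))
})

test_that("NG86 path differences match hand enumeration for small cases", {
  expect_equal(ng86_path_differences("AAA", "AAA"), c(syn = 0, nonsyn = 0))
  # one synonymous step: Lys AAA -> AAG (code 5)
  expect_equal(ng86_path_differences("AAA", "AAG"), c(syn = 1, nonsyn = 0))
  # two-position pair, both orderings enumerated by hand:
  # TTA(L) -> TCT(S): via TCA(S) = 1 nonsyn + 1 syn; via TTT(F) = 2 nonsyn
  expect_equal(ng86_path_differences("TTA", "TCT"),
               c(syn = 0.5, nonsyn = 1.5))
})

test_that("NG86 operators are symmetric", {
  set.seed(10)
  gc <- oracle_genetic_code()
  nonstop <- names(gc)[gc != "*"]
  for (i in 1:100) {
    ab <- sample(nonstop, 2)
    expect_equal(ng86_path_differences(ab[1], ab[2]),
                 ng86_path_differences(ab[2], ab[1]))
  }
})

test_that("ka_ks handles identity, hand-computed toys, and saturation", {
  r0 <- ka_ks("ATGAAA", "ATGAAA")
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(is.na(r0$ratio))
  expect_equal(r0$n_syn_sites + r0$n_nonsyn_sites, 6)

  # one synonymous difference over three codons (two fourfold Gly sites
  # keep pS below saturation); expectations built from the brute-force
  # oracle, then Jukes-Cantor corrected in closed form
  a <- "ATGGGAGGA"; b <- "ATGGGAGGG"
  S <- sum(vapply(c("ATG", "GGA", "GGA"), function(cd)
    oracle_site_counts(cd)[["syn"]], numeric(1))) / 2 +
    sum(vapply(c("ATG", "GGA", "GGG"), function(cd)
      oracle_site_counts(cd)[["syn"]], numeric(1))) / 2
  r <- ka_ks(a, b)
  expect_equal(r$n_syn_sites, S)
  expect_equal(r$ks, -0.75 * log(1 - 4 * (1 / S) / 3))
  expect_equal(r$ka, 0)
  expect_equal(r$ratio, 0)

  # all-synonymous saturation: repeated Leu TTA vs CTG gives pS = 3
  sat <- ka_ks(strrep("TTA", 30), strrep("CTG", 30))
  expect_true(sat$saturated)
  expect_true(is.na(sat$ks))

  # internal stop pairs excluded with a warning
  expect_warning(ka_ks("ATGTAAAAA", "ATGTAAAAA"), "internal stop")
  # terminal stops trimmed silently
  rt <- ka_ks("ATGAAATAA", "ATGAAATAG")
  expect_equal(rt$n_sites_compared, 6L)
})

test_that("site + path counters agree with brute force for every codon pair", {
  gc <- oracle_genetic_code(5L)
  nonstop <- names(gc)[gc != "*"]
  for (cd in nonstop) {
    expect_equal(ng86_site_counts(cd), oracle_site_counts(cd),
                 tolerance = 1e-12, info = cd)
  }
  suppressWarnings(
    for (a in nonstop) for (b in nonstop) {
      expect_equal(ng86_path_differences(a, b),
                   suppressWarnings(oracle_path_diffs(a, b)),
                   tolerance = 1e-12, info = paste(a, b))
    }
  )
})

test_that("divergence_table reports per-gene statistics for shared PCGs", {
  cfg <- sim_config(seed = 21, syn_branch_length = 0.1)
  anc <- simulate_ancestor(cfg)
  pair <- evolve_pair(anc, cfg)
  div <- divergence_table(pair$a, pair$b)
  expect_equal(div$gene, c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
                           "nad3", "nad5", "nad4", "nad4l", "nad6", "cob",
                           "nad1"))
  expect_true(all(div$pi >= 0 & div$pi <= 1))
  expect_true(all(div$ks > 0))
  expect_equal(div$n_syn_sites + div$n_nonsyn_sites, div$n_sites,
               tolerance = 1e-6)
  # genome vs itself: all Pi zero
  self <- divergence_table(pair$a, pair$a)
  expect_true(all(self$pi == 0))
})
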