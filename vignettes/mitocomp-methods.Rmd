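---
title: "mitocomp: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocomp: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette is the package's own account of its science: the models
it implements, the conventions and defaults it commits to, what its
synthetic data does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The genome model and its conventions

A `MitoGenome` is a circular plus-strand nucleotide sequence with an
ordered table of `GeneFeature`s. Three conventions are fixed package
wide and everything else is derived from them:

* **Coordinates are 1-based and fully inclusive** — a feature spanning
  positions 1–64 has length 64. This matches how mitogenome papers
  print their gene tables, so transcribed ledgers can be compared
  cell-for-cell without off-by-one adjustments. Features may wrap the
  circular origin (`wraps_origin`), in which case the length is
  `L − start + 1 + end` for genome length `L`.
* **Direction is the internal truth; strand labels are presentation.**
  Published tables label strands N/J, but usage is inconsistent across
  the heteropteran literature (some papers call the gene-rich strand N,
  others J). The package therefore computes everything from
  `direction` (forward/reverse reading on the plus strand) and only
  checks that each label maps to exactly one direction within a
  genome. The bundled reference ledgers follow their source: N carries
  the 23 majority-strand genes.
* **Unknown gene names are preserved, not rejected.** They are flagged
  by `validate_annotation()` and excluded from vocabulary-dependent
  statistics; real annotations are messy and a hard failure would make
  the tool unusable on slightly nonstandard GenBank records. The two
  leucine and serine tRNAs are disambiguated as `trnL1`/`trnL2`,
  `trnS1`/`trnS2`.

The control region is treated as the unannotated remainder of the
circle (for the reference ledgers, everything after `rrnS`), because
published gene tables typically give no explicit D-loop coordinates.
The linearization origin is configurable (`gene_order(origin = ...)`).

## Composition and skews

Strand asymmetry is summarized by

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C}.$$

When the sequence is available, skews are computed from raw base
counts; the percentage-argument forms `at_skew(a, t)` / `gc_skew(g, c)`
exist for table-only workflows where only printed percentages survive.
Both routes agree at the 2-decimal reporting precision on the bundled
data. Reporting rounds **half away from zero** (1 dp for percentages,
2 dp for skews) because that is how the source tables are rounded;
base R's banker's rounding would disagree on exact halves. IUPAC
ambiguity codes are excluded from all four base counts and from skew
denominators, and reported as `n_ambiguous`.

Stop codons of PCGs are typed purely from `length mod 3` and the
terminal residue(s): remainder 1 ending in T is `T-`, remainder 2
ending in TA is `TA-`, both completed to TAA by post-transcriptional
polyadenylation. No transcript-level verification is attempted.

## Codon usage

RSCU for codon $c$ in a synonymous family of size $k$ is
$\mathrm{RSCU}(c) = n_c \, k / \sum_{c' \in \mathrm{fam}} n_{c'}$, so
the mean within every used family is exactly 1 and an unused family is
*undefined* (`NA`), not zero. RSCU is computed on the concatenation of
the 13 PCGs per genome, with stop codons excluded from families by
default (`include_stops` reverses this).

The default genetic code is the invertebrate mitochondrial code
(translation table 5), which is correct for hemipteran mitogenomes.
Note a labeling pitfall this choice exposes: AGA is serine under
table 5 but arginine under the standard code, and some published RSCU
figures carry the standard-code label. Amino-acid labels here always
follow the user-selected code; the discrepancy is documented rather
than silently resolved.

## Architecture ledgers

For start-sorted features, each consecutive pair contributes
`gap = next.start − prev.end − 1`; negative gaps are overlaps,
positive gaps spacers. The control region is excluded from adjacency
(it is unannotated remainder), and the wrap pair from the last
annotated gene back to the first is reported separately so it never
inflates the summary counts — this matches how overlap counts are
reported in the literature this package mirrors. Overlap/spacer counts
are reported **per genome**. On non-wrapping annotations the identity
`Σ lengths − Σ overlaps + Σ spacers + control-region length = genome
length` holds exactly and is tested.

Gene-order comparison is equality under circular rotation, direction
sensitive, and deliberately ignores reflection: reading the circle
from the other strand is a biologically different arrangement. The
built-in `ancestral_insect_order()` is the 37-gene arrangement of the
putative insect ancestor, which the bundled ledgers match.

## Divergence: Pi and NG86 Ka/Ks

Pi between two aligned sequences is the p-distance over sites where
both carry unambiguous, ungapped bases (`mean_pi()` averages over
pairs for n > 2). This is the n = 2 special case of standard
nucleotide diversity.

Ka/Ks uses Nei–Gojobori (1986) counting:

* **Sites.** Each codon position contributes one site, split into a
  synonymous fraction equal to the proportion of its single-base
  changes that are synonymous *among changes not creating a stop
  codon*. Stop-creating mutations are excluded from the denominator
  rather than counted as nonsynonymous, so syn + nonsyn sites always
  total 3 per codon. Site counts are averaged over the two sequences.
* **Differences.** For a codon pair differing at k positions, the k!
  orderings of single-base steps are enumerated; orderings passing
  through a stop codon are discarded, and synonymous/nonsynonymous
  step counts are averaged over the rest (with a fall-back to all
  orderings, flagged by a warning, in the degenerate case where every
  pathway is blocked).
* **Correction.** Both proportions get the Jukes–Cantor correction
  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; $p \ge 3/4$ is flagged as
  saturated and the corrected value is undefined, as is the ratio when
  Ks = 0.

Codon pairs with gaps or ambiguity in either sequence are excluded
pairwise; internal stops warn and are excluded; terminal stops are
trimmed. The counters are verified against brute-force enumeration
over every unambiguous codon pair of the active code.

The source analyses for this package's statistics were run in DnaSP,
whose classical Ka/Ks is NG86-with-JC; exact numerical agreement with
any particular DnaSP configuration is not guaranteed (its gap and
correction settings are rarely printed), and the claims this package
treats as hard — all mitochondrial PCG ratios well below 1 — are
robust to such method deltas.

## Supermatrix construction

`align_gene()` completes incomplete stops, trims terminal stop codons,
translates, aligns the proteins progressively (pairwise-to-profile),
and threads codons back so gaps occur only in multiples of 3. The
alignment DP (in C++) is global with affine gap penalties (open −10,
extend −1) on BLOSUM62 scores, mean sum-of-pairs over profile columns,
and fully deterministic tie-breaks (diagonal, then up, then left;
guide order = input order). A guide tree would add nothing at the
≤25-taxon scale this targets, and fixed input order keeps outputs
byte-for-byte reproducible. Degapping any output row reproduces that
row's (preprocessed) input exactly — a tested invariant.

`trim_alignment()` is an explicit, deterministic stand-in for
block-filtering tools (whose parameters the source workflows rarely
record): it drops every codon column containing any gap or ambiguity
in any taxon and logs the retained fraction. This is stricter than
Gblocks defaults; it trades a few retained columns for exact
testability.

`concatenate()` joins genes in the canonical order (nad2, cox1, cox2,
atp8, atp6, cox3, nad3, nad5, nad4, nad4l, nad6, cob, nad1), fills
missing taxa with flagged gap rows, and records a partition map
exported in the common "gene and codon" naming (`DNA, nad2_pos1 =
1-987\3`) so external model-selection and inference tools can consume
it. Tree inference itself is out of scope; `nj_tree()` provides a
deterministic neighbor-joining tree (ties broken by node name,
negative branches clamped to 0 with the deficit moved to the sibling)
adequate for sanity checks, and is verified to reproduce 100 random
additive matrices exactly.

## The simulator: a stated world

`sim_config()` commits to one set of defaults, chosen once from the
published genomes the package mirrors, and the test suite treats them
as the world under study:

| parameter | default | why |
|---|---|---|
| genome length | 15,174 bp | published reference genome |
| gene sizes / arrangement | the published 37-gene ledger | same |
| composition (plus strand) | A .427, T .318, G .096, C .158 | published base content |
| syn branch length | 0.15 /site /lineage | gives pairwise per-gene Pi ≈ 0.05–0.12, the observed range |
| omega | 0.1 (per gene, scalar recycled) | middle of the observed 0.01–0.13 Ka/Ks range |
| ts/tv proposal ratio | 1 | see below |
| indel rate | 0 (deletions only when enabled) | real congeneric mito CDSs are nearly indel-free |

Reverse-strand genes are generated from the complemented composition
so the plus strand shows the target skews everywhere; PCGs get valid
frames (ATN starts, TTG for *cox1*/*nad4l*, complete TAA or
incomplete T/TA stops matched to the published lengths).

Evolution runs at codon resolution inside PCGs: Poisson(t) proposal
events per nucleotide position, applied sequentially (multiple hits
happen), each proposal drawn from the alternatives that do not create
a stop codon, accepted with probability 1 if synonymous and omega if
nonsynonymous. Everything outside PCGs (and the held-fixed terminal
stop/tail) evolves neutrally at rate t. Two design points deserve
justification:

* **Proposals are restricted to the non-stop neighborhood** rather
  than proposed freely and rejected. Both satisfy "stops are always
  rejected", but only the restricted kernel makes the realized rates
  exactly t per synonymous site and omega·t per nonsynonymous site
  *under the same site normalization the NG86 counter uses* (which
  also excludes stop mutations from its denominators). With a
  free-proposal kernel the generator's own ground truth drifts from
  its nominal omega, which would make estimator calibration tests
  meaningless.
* **The default ts/tv proposal ratio is 1.** NG86 counting assumes
  equal exchange rates; simulating with a transition bias while
  estimating with an equal-rate counter would conflate generator
  realism with estimator bias. The default keeps ground truth directly
  interpretable; `tstv` is configurable when that bias is itself the
  object of study.

What the simulator does **not** emulate: tRNA/rRNA secondary
structure, gene overlaps (simulated genes are laid back-to-back; the
overlap machinery is exercised by the transcribed real ledgers
instead), origin-wrapping features (supported by the model, not
emitted by default), insertions (only deletions), and among-site rate
variation. A green recovery test therefore establishes that the
estimators are calibrated under a clean codon model — not that they
are robust to every real-data pathology.

All randomness flows from the mandatory seed (`evolve_pair` reseeds at
`seed + 1` so ancestor and descendants are independently
reproducible); identical seed and config give byte-identical outputs,
which is tested.

## Numerical and degenerate-input choices

* Rounding: half away from zero everywhere a printed table is
  mirrored.
* 0/0 statistics (skew of an AT-free sequence, RSCU of an unused
  family, Ka/Ks with Ks = 0, saturated JC input) are `NA` with a flag
  or warning — never silently 0.
* NG86 recovery is tested at omega ∈ {0.05, 0.2, 0.5} with 50
  replicate genes of 300 codons each (the gene count follows the
  stated protocol; the gene length is set by the test-time budget) and
  requires the median estimate within ±30% of truth.
* The NJ tie-break (sorted node-name key) and the alignment tie-break
  (diagonal preference) make every output deterministic; both are
  regression-tested by re-running on identical inputs.

## Known limitations

* GenBank parsing covers the flat-file subset mitogenome records use
  (CDS/tRNA/rRNA/D-loop features, `complement()` and origin-spanning
  `join()` locations); it is not a general GenBank parser.
* The one-decimal printed base percentages reproduce printed skews at
  2 dp, but recomputing composition from raw sequence requires the
  actual sequence; the package ships ledgers, not full published
  sequences, so sequence-level checks run on simulated genomes.
* Ka/Ks is counting-based (NG86); no maximum-likelihood codon models,
  no confidence intervals, no sliding windows.
* Neighbor joining is a desk-scale sanity tool, not a substitute for
  Bayesian/ML inference; bootstrap support is out of scope.
* One printed intergenic value in the bundled second ledger is
  internally inconsistent with its own printed coordinates (gap 7 vs
  printed 10 at trnY); the package reproduces coordinates, so that
  single cell is not matched. The discrepancy is asserted, not hidden,
  in the acceptance suite.
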