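# Seeded synthetic mitogenome simulator.
#
# The generator emulates the stated world of the two Pylorgus-type
# genomes: a circular ~15.2 kb molecule carrying the 37 genes of the
# ancestral insect arrangement at the published gene sizes, strong A/T
# bias with positive AT-skew and negative GC-skew on the plus strand,
# valid PCG reading frames (ATN/TTG starts, complete or incomplete
# stops), and two descendant lineages diverged under per-gene omega in
# (0, 1]. PCGs evolve at codon resolution by acceptance-rejection
# (synonymous proposals always accepted, nonsynonymous with probability
# omega, stops always rejected); everything else evolves neutrally at
# the synonymous rate.

#' Simulator configuration
#'
#' @param seed Integer seed (mandatory; there is no implicit
#'   randomness).
#' @param genome_length Target genome length in bp.
#' @param composition Named proportions (A, T, G, C) of the plus
#'   strand; defaults to the published whole-genome base content
#'   (A 42.7, T 31.8, G 9.6, C 15.8 %).
#' @param omega Per-gene dN/dS in (0, 1]; a scalar is recycled over the
#'   13 PCGs.
#' @param syn_branch_length Expected synonymous substitutions per
#'   synonymous site on each descendant lineage.
#' @param tstv Transition/transversion proposal ratio (1 = no bias; the
#'   default keeps the acceptance-rejection ground truth directly
#'   comparable to equal-rate counting estimators).
#' @param indel_rate Per-codon deletion probability per lineage within
#'   PCGs (for alignment/trimming tests).
#' @param gene_sizes Named integer vector of gene sizes; defaults to
#'   the published porrectus ledger sizes.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       genome_length = 15174L,
                       composition = c(A = 0.427, T = 0.318,
                                       G = 0.096, C = 0.158),
                       omega = 0.1,
                       syn_branch_length = 0.15,
                       tstv = 1,
                       indel_rate = 0,
                       gene_sizes = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  composition <- composition[c("A", "T", "G", "C")]
  # printed percentages carry rounding; renormalize within 1%
  stopifnot(abs(sum(composition) - 1) < 0.01)
  composition <- composition / sum(composition)
  stopifnot(all(omega > 0),
            all(omega <= 1), syn_branch_length >= 0, tstv > 0,
            indel_rate >= 0, indel_rate < 1)
  if (is.null(gene_sizes)) {
    printed <- fixture_features("porrectus")
    gene_sizes <- setNames(feature_length(printed$features),
                           printed$features$name)
    # sizes in arrangement (circular) order, not start order
    ord <- ancestral_insect_order()
    gene_sizes <- gene_sizes[ord$name]
  }
  om <- if (length(omega) == 1L)
    setNames(rep(omega, length(PCG_NAMES)), PCG_NAMES)
  else omega
  if (!all(PCG_NAMES %in% names(om)))
    stop("omega must cover all 13 PCGs")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 composition = composition, omega = om,
                 syn_branch_length = syn_branch_length, tstv = tstv,
                 indel_rate = indel_rate, gene_sizes = gene_sizes),
            class = "SimConfig")
}

.flip_comp <- function(comp) {
  c(A = unname(comp["T"]), T = unname(comp["A"]),
    G = unname(comp["C"]), C = unname(comp["G"]))
}

.sample_bases <- function(n, comp) {
  if (n == 0L) return("")
  paste(sample(names(comp), n, replace = TRUE, prob = comp),
        collapse = "")
}

#' Random in-frame CDS
#'
#' Start codon, internal non-stop codons drawn from a base composition,
#' and a complete (`TAA`) or incomplete (`T`/`TA`) terminal stop chosen
#' to hit the requested length exactly.
#'
#' @param size Total CDS length in bp (>= 9).
#' @param comp Named base proportions.
#' @param code Genetic-code id.
#' @param start_codon Start codon (e.g. `"ATT"`, `"TTG"`).
#' @return CDS string of length `size`.
#' @export
random_cds <- function(size, comp, code = 5L, start_codon = "ATT") {
  stopifnot(size >= 9L)
  gc <- genetic_code(code)
  rem <- size %% 3L
  tail_nt <- switch(as.character(rem), "0" = "TAA", "1" = "T", "2" = "TA")
  n_internal <- (size - 3L - nchar(tail_nt)) %/% 3L
  internal <- character(n_internal)
  i <- 1L
  while (i <= n_internal) {
    cod <- .sample_bases(3L, comp)
    if (gc[cod] != "*") { internal[i] <- cod; i <- i + 1L }
  }
  paste0(start_codon, paste(internal, collapse = ""), tail_nt)
}

#' Simulate an ancestral annotated mitogenome
#'
#' @param cfg A `SimConfig`.
#' @return List: `genome` (a `MitoGenome`), `truth` (target
#'   composition, arrangement, per-gene omega).
#' @export
simulate_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  arr <- ancestral_insect_order()
  sizes <- cfg$gene_sizes[arr$name]
  if (anyNA(sizes)) stop("gene_sizes must cover the full arrangement")
  if (sum(sizes) >= cfg$genome_length)
    stop("gene sizes exceed genome length")
  gc <- genetic_code(5L)
  plus <- character(nrow(arr))
  feats <- vector("list", nrow(arr))
  pos <- 0L
  for (i in seq_len(nrow(arr))) {
    gene <- arr$name[i]
    dirn <- arr$direction[i]
    size <- sizes[[gene]]
    comp <- if (dirn == "forward") cfg$composition
            else .flip_comp(cfg$composition)
    sense <- if (gene %in% PCG_NAMES) {
      start <- if (gene %in% c("cox1", "nad4l")) "TTG"
               else sample(c("ATT", "ATA", "ATG", "ATC"), 1)
      random_cds(size, comp, start_codon = start)
    } else {
      .sample_bases(size, comp)
    }
    plus[i] <- if (dirn == "reverse") revcomp(sense) else sense
    feats[[i]] <- gene_feature(gene, pos + 1L, pos + size,
                               direction = dirn,
                               strand_label = if (dirn == "forward") "N"
                                              else "J")
    pos <- pos + size
  }
  cr_len <- cfg$genome_length - pos
  cr <- .sample_bases(cr_len, cfg$composition)
  feats[[length(feats) + 1L]] <- gene_feature(
    "dloop", pos + 1L, cfg$genome_length, direction = "forward",
    strand_label = "N", gene_type = "control")
  genome <- mito_genome(paste0(paste(plus, collapse = ""), cr),
                        do.call(rbind, feats),
                        accession = sprintf("SIM%06d", cfg$seed))
  list(genome = genome,
       truth = list(composition = cfg$composition,
                    arrangement = arr, omega = cfg$omega,
                    gene_sizes = sizes))
}

#' Evolve one coding sequence under acceptance-rejection selection
#'
#' Proposals arrive per nucleotide position as Poisson(`t`) events and
#' are applied sequentially (multiple hits allowed). A proposal
#' replaces the current base by one of the alternatives that do not
#' create a stop codon (stops are thus always rejected), transitions
#' weighted `tstv`. Synonymous changes are always accepted;
#' nonsynonymous changes are accepted with probability `omega`.
#' Proposing only within the non-stop neighborhood makes the realized
#' rates exactly `t` per synonymous site and `omega * t` per
#' nonsynonymous site under the same site normalization the
#' Nei-Gojobori counter uses. An incomplete terminal stop tail is left
#' untouched.
#'
#' @param cds In-frame CDS string.
#' @param t Expected proposals per site (the synonymous branch length).
#' @param omega Acceptance probability for nonsynonymous changes.
#' @param tstv Transition/transversion proposal ratio.
#' @param code Genetic-code id.
#' @return List: `seq`, `n_syn`, `n_nonsyn` (realized accepted counts).
#' @export
evolve_cds <- function(cds, t, omega, tstv = 1, code = 5L) {
  gc <- genetic_code(code)
  n_cod <- nchar(cds) %/% 3L
  tail_nt <- substr(cds, 3L * n_cod + 1L, nchar(cds))
  cods <- .split_codons(cds)
  n_syn <- 0L; n_nonsyn <- 0L
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  # a complete terminal stop is constrained; hold it fixed like the tail
  n_evolve <- if (n_cod > 0L && gc[cods[n_cod]] %in% "*") n_cod - 1L
              else n_cod
  for (k in seq_len(n_evolve)) {
    cod <- cods[k]
    n_events <- rpois(3L, t)
    if (sum(n_events) == 0L) next
    order_pos <- rep.int(1:3, n_events)
    if (length(order_pos) > 1L)
      order_pos <- sample(order_pos)
    for (p in order_pos) {
      ref <- substr(cod, p, p)
      others <- setdiff(c("A", "C", "G", "T"), ref)
      cands <- vapply(others, function(b) {
        prop <- cod
        substr(prop, p, p) <- b
        prop
      }, character(1))
      valid <- gc[cands] != "*"
      if (!any(valid)) next
      others <- others[valid]
      w <- ifelse(others == ts_partner[[ref]], tstv, 1)
      b <- others[sample.int(length(others), 1L, prob = w)]
      prop <- cod
      substr(prop, p, p) <- b
      if (gc[prop] == gc[cod]) {
        cod <- prop; n_syn <- n_syn + 1L
      } else if (runif(1) < omega) {
        cod <- prop; n_nonsyn <- n_nonsyn + 1L
      }
    }
    cods[k] <- cod
  }
  list(seq = paste0(paste(cods, collapse = ""), tail_nt),
       n_syn = n_syn, n_nonsyn = n_nonsyn)
}

.evolve_neutral <- function(seq, t, tstv = 1) {
  ch <- strsplit(seq, "")[[1]]
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  n_events <- rpois(length(ch), t)
  for (i in which(n_events > 0L)) {
    for (e in seq_len(n_events[i])) {
      ref <- ch[i]
      if (!ref %in% names(ts_partner)) next
      others <- setdiff(c("A", "C", "G", "T"), ref)
      w <- ifelse(others == ts_partner[[ref]], tstv, 1)
      ch[i] <- sample(others, 1L, prob = w)
    }
  }
  paste(ch, collapse = "")
}

.delete_codons <- function(cds, rate) {
  if (rate <= 0) return(cds)
  n_cod <- nchar(cds) %/% 3L
  tail_nt <- substr(cds, 3L * n_cod + 1L, nchar(cds))
  cods <- .split_codons(cds)
  # never delete the start codon
  drop <- c(FALSE, runif(n_cod - 1L) < rate)
  paste0(paste(cods[!drop], collapse = ""), tail_nt)
}

#' Evolve two descendant genomes from a simulated ancestor
#'
#' Each lineage evolves independently: PCGs under the
#' acceptance-rejection codon model of [evolve_cds()], all other
#' regions neutrally at the synonymous rate. With `indel_rate > 0`,
#' codons are deleted within PCGs and all downstream coordinates are
#' rebuilt.
#'
#' @param ancestor Output of [simulate_ancestor()] (or a `MitoGenome`).
#' @param cfg The `SimConfig` (its `seed + 1` seeds this step).
#' @return List: `a`, `b` (MitoGenomes), `truth` (per gene and lineage:
#'   realized synonymous/nonsynonymous substitution counts, true
#'   omega).
#' @export
evolve_pair <- function(ancestor, cfg) {
  g <- if (inherits(ancestor, "MitoGenome")) ancestor
       else ancestor$genome
  set.seed(cfg$seed + 1L)
  evolve_one <- function(tag) {
    plus <- character(0)
    feats <- list()
    rec <- list()
    pos <- 0L
    for (i in seq_len(nrow(g$features))) {
      f <- g$features[i, ]
      sense <- extract_sequence(g, f)
      if (!is.na(f$gene_type) && f$gene_type == "PCG") {
        om <- cfg$omega[[f$name]]
        ev <- evolve_cds(sense, cfg$syn_branch_length, om, cfg$tstv)
        out <- .delete_codons(ev$seq, cfg$indel_rate)
        rec[[f$name]] <- data.frame(gene = f$name, lineage = tag,
                                    n_syn = ev$n_syn,
                                    n_nonsyn = ev$n_nonsyn,
                                    omega = om,
                                    stringsAsFactors = FALSE)
      } else {
        out <- .evolve_neutral(sense, cfg$syn_branch_length, cfg$tstv)
      }
      size <- nchar(out)
      plus <- c(plus, if (f$direction == "reverse") revcomp(out) else out)
      feats[[i]] <- gene_feature(f$name, pos + 1L, pos + size,
                                 direction = f$direction,
                                 strand_label = f$strand_label,
                                 gene_type = f$gene_type)
      pos <- pos + size
    }
    list(genome = mito_genome(paste(plus, collapse = ""),
                              do.call(rbind, feats),
                              accession = paste0(g$accession, "_", tag)),
         rec = do.call(rbind, c(rec, make.row.names = FALSE)))
  }
  la <- evolve_one("A")
  lb <- evolve_one("B")
  list(a = la$genome, b = lb$genome,
       truth = list(events = rbind(la$rec, lb$rec),
                    omega = cfg$omega))
}
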