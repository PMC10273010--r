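# Command surface: profile / compare / supermatrix, with re-runnable
# tab-separated reports. Logging goes to standard error, data to files.

.report_header <- function(code) {
  ver <- as.character(utils::packageVersion("mitocomp"))
  sprintf("# mitocomp %s | genetic code %d", ver, code)
}

.write_report <- function(df, path, code) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.report_header(code), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

.load_genome_input <- function(x, code = 5L) {
  if (inherits(x, "MitoGenome")) return(x)
  if (!file.exists(x)) stop("input not found: ", x)
  first <- readLines(x, n = 1, warn = FALSE)
  if (grepl("^LOCUS", first)) return(read_genbank(x, code))
  if (grepl("^>", first)) {
    seqs <- read_fasta(x)
    return(mito_genome(seqs[[1]], .empty_features(),
                       accession = names(seqs)[1] %||% basename(x),
                       genetic_code_id = code))
  }
  stop("unrecognized input format: ", x)
}

#' Profile one or more genomes
#'
#' Writes the composition report (whole-genome base content and skews),
#' and for annotated inputs also the per-gene feature ledger, RSCU
#' table, and strand distribution. FASTA-only inputs get the
#' composition report with a notice that annotation-dependent reports
#' were skipped.
#'
#' @param inputs Character vector of GenBank/FASTA paths, or a list of
#'   `MitoGenome` objects.
#' @param out_dir Output directory.
#' @param code Genetic-code id.
#' @return Invisible list of written paths.
#' @export
cmd_profile <- function(inputs, out_dir = ".", code = 5L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  genomes <- lapply(inputs, .load_genome_input, code = code)
  written <- character()
  comp_path <- file.path(out_dir, "composition.tsv")
  .write_report(composition_report(genomes), comp_path, code)
  written <- c(written, comp_path)
  for (g in genomes) {
    if (nrow(g$features) == 0L) {
      message("note: ", g$accession,
              " has no annotation; ledger/RSCU/strand reports skipped")
      next
    }
    led <- file.path(out_dir, paste0("ledger_", g$accession, ".tsv"))
    .write_report(ledger_report(g), led, code)
    ru <- file.path(out_dir, paste0("rscu_", g$accession, ".tsv"))
    tab <- genome_rscu(g, code = code)
    con <- file(ru, "w")
    writeLines(.report_header(code), con)
    close(con)
    rdf <- data.frame(codon = names(tab$rscu), aa = unname(tab$aa),
                      count = unname(tab$counts[names(tab$rscu)]),
                      rscu = round_half_away(unname(tab$rscu), 2),
                      family_size = unname(tab$family_size))
    suppressWarnings(write.table(rdf, ru, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    sd <- strand_distribution(g$features)
    sdf <- as.data.frame.matrix(sd$table)
    sdf <- cbind(gene_type = rownames(sdf), sdf)
    sp <- file.path(out_dir, paste0("strand_", g$accession, ".tsv"))
    .write_report(sdf, sp, code)
    written <- c(written, led, ru, sp)
  }
  invisible(written)
}

#' Compare two annotated genomes gene by gene
#'
#' Writes the per-gene divergence report (Pi, Ka, Ks, Ka/Ks, site
#' counts) over the shared protein-coding genes, plus a summary line on
#' standard error.
#'
#' @param a,b GenBank paths or `MitoGenome` objects.
#' @param out Output path for the report.
#' @param code Genetic-code id.
#' @return The divergence data.frame, invisibly.
#' @export
cmd_compare <- function(a, b, out = "divergence.tsv", code = 5L) {
  ga <- .load_genome_input(a, code)
  gb <- .load_genome_input(b, code)
  if (nrow(ga$features) == 0L || nrow(gb$features) == 0L)
    stop("both genomes must be annotated")
  div <- divergence_table(ga, gb, code = code)
  .write_report(transform(div,
                          pi = round_half_away(pi, 4),
                          ka = round_half_away(ka, 4),
                          ks = round_half_away(ks, 4),
                          ratio = round_half_away(ratio, 4)),
                out, code)
  defined <- div[!is.na(div$ratio), ]
  message(sprintf(
    "Pi range %.3f (%s) - %.3f (%s); max Ka/Ks %.3f (%s)",
    min(div$pi), div$gene[which.min(div$pi)],
    max(div$pi), div$gene[which.max(div$pi)],
    if (nrow(defined)) max(defined$ratio) else NA,
    if (nrow(defined)) defined$gene[which.max(defined$ratio)] else "-"))
  invisible(div)
}

#' Build the 13-PCG supermatrix for a taxon set
#'
#' Aligns every shared protein-coding gene codon-wise, trims gap/
#' ambiguity codon columns, concatenates in canonical order, and writes
#' FASTA, relaxed PHYLIP, NEXUS (with charsets), a partition file, and
#' a neighbor-joining Newick tree.
#'
#' @param inputs >= 3 GenBank paths or `MitoGenome` objects.
#' @param out_dir Output directory.
#' @param code Genetic-code id.
#' @param scheme Partition scheme (`"gene"` or `"gene_codon"`).
#' @param dist_model `"p"` or `"K2P"` for the NJ distances.
#' @return The `Supermatrix`, invisibly.
#' @export
cmd_supermatrix <- function(inputs, out_dir = ".", code = 5L,
                            scheme = "gene", dist_model = "K2P") {
  if (length(inputs) < 3L) stop("need at least 3 taxa")
  genomes <- lapply(inputs, .load_genome_input, code = code)
  taxa <- vapply(genomes, `[[`, character(1), "accession")
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  shared <- Reduce(intersect, lapply(genomes, function(g)
    g$features$name[g$features$gene_type %in% "PCG"]))
  if (!length(shared)) stop("no shared protein-coding genes")
  shared <- shared[order(match(shared, PCG_CONCAT_ORDER))]
  alns <- list()
  for (gene in shared) {
    cds <- setNames(vapply(genomes, function(g) {
      f <- g$features[g$features$name == gene, ]
      extract_sequence(g, f)
    }, character(1)), taxa)
    aln <- align_gene(cds, code = code)
    tr <- trim_alignment(aln)
    message(sprintf("%s: retained %.1f%% of codon columns", gene,
                    100 * tr$retained_fraction))
    alns[[gene]] <- tr$alignment
  }
  m <- concatenate(alns)
  write_fasta(m$seqs, file.path(out_dir, "supermatrix.fasta"))
  write_phylip(m$seqs, file.path(out_dir, "supermatrix.phy"))
  write_nexus(m, file.path(out_dir, "supermatrix.nex"), scheme = scheme)
  write_partitions(m, file.path(out_dir, "partitions.txt"),
                   scheme = scheme)
  D <- distance_matrix(m, model = dist_model)
  writeLines(nj_tree(D), file.path(out_dir, "nj.nwk"))
  invisible(m)
}
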