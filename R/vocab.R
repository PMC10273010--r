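#' @useDynLib mitocomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

# The 37 canonical mitochondrial genes of insects, plus the control region.
PCG_NAMES <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
               "nad5", "nad4", "nad4l", "nad6", "cob", "nad1")

TRNA_NAMES <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                "trnV")

RRNA_NAMES <- c("rrnL", "rrnS")

CONTROL_NAME <- "dloop"

#' Canonical gene vocabulary
#'
#' The 37 mitochondrial genes of the typical insect mitogenome (13
#' protein-coding genes, 22 tRNAs, 2 rRNAs) plus the control region,
#' with their expected gene type.
#'
#' @return A data.frame with columns `name` and `gene_type`
#'   (one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`).
#' @export
gene_vocabulary <- function() {
  data.frame(
    name = c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES, CONTROL_NAME),
    gene_type = c(rep("PCG", length(PCG_NAMES)),
                  rep("tRNA", length(TRNA_NAMES)),
                  rep("rRNA", length(RRNA_NAMES)),
                  "control"),
    stringsAsFactors = FALSE
  )
}

# Synonym map: common annotation spellings -> canonical names. Keys are
# matched case-insensitively after stripping spaces/hyphens/underscores.
.SYNONYMS <- c(
  coi = "cox1", co1 = "cox1", cox1 = "cox1", coxi = "cox1",
  coii = "cox2", co2 = "cox2", cox2 = "cox2", coxii = "cox2",
  coiii = "cox3", co3 = "cox3", cox3 = "cox3", coxiii = "cox3",
  cytb = "cob", cob = "cob", cytochromeb = "cob",
  nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
  nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
  nd4l = "nad4l", nad4l = "nad4l", nd5 = "nad5", nad5 = "nad5",
  nd6 = "nad6", nad6 = "nad6",
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
  rrnl = "rrnL", "16s" = "rrnL", "16srrna" = "rrnL", lrrna = "rrnL",
  rrn16 = "rrnL",
  rrns = "rrnS", "12s" = "rrnS", "12srrna" = "rrnS", srrna = "rrnS",
  rrn12 = "rrnS",
  dloop = "dloop", controlregion = "dloop", crregion = "dloop",
  trni = "trnI", trnq = "trnQ", trnm = "trnM", trnw = "trnW",
  trnc = "trnC", trny = "trnY", trnk = "trnK", trnd = "trnD",
  trng = "trnG", trna = "trnA", trnr = "trnR", trnn = "trnN",
  trne = "trnE", trnf = "trnF", trnh = "trnH", trnt = "trnT",
  trnp = "trnP", trnv = "trnV",
  trnl1 = "trnL1", trnl2 = "trnL2", trns1 = "trnS1", trns2 = "trnS2",
  trnaile = "trnI", trnagln = "trnQ", trnamet = "trnM", trnatrp = "trnW",
  trnacys = "trnC", trnatyr = "trnY", trnalys = "trnK", trnaasp = "trnD",
  trnagly = "trnG", trnaala = "trnA", trnaarg = "trnR", trnaasn = "trnN",
  trnaglu = "trnE", trnaphe = "trnF", trnahis = "trnH", trnathr = "trnT",
  trnapro = "trnP", trnaval = "trnV"
)

#' Canonicalize a gene name
#'
#' Maps common annotation spellings (e.g. `COI`, `ND4L`, `CYTB`,
#' `tRNA-Met`, `16S rRNA`) to the canonical vocabulary used throughout
#' the package. Unknown names are returned unchanged with
#' `attr(, "known") = FALSE`.
#'
#' @param name Character vector of gene names as annotated.
#' @return Character vector of canonical names; attribute `known` is a
#'   logical vector flagging names that resolved to the vocabulary.
#' @export
canonical_gene_name <- function(name) {
  key <- tolower(gsub("[ _()-]", "", name))
  hit <- .SYNONYMS[key]
  known <- !is.na(hit)
  out <- ifelse(known, hit, name)
  # Already-canonical names pass through as known
  voc <- gene_vocabulary()$name
  direct <- out %in% voc
  attr(out, "known") <- known | direct
  names(out) <- NULL
  out
}

#' Expected gene type for a canonical name
#' @param name Canonical gene name(s).
#' @return Character vector: `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`,
#'   or `NA` for names outside the vocabulary.
#' @export
gene_type_of <- function(name) {
  voc <- gene_vocabulary()
  voc$gene_type[match(name, voc$name)]
}

#' Putative ancestral insect gene arrangement
#'
#' The circular order and reading direction of the 37 genes in the
#' putative ancestral arrangement of insects, linearized at `trnI`.
#'
#' @return A data.frame with columns `name` and `direction`
#'   (`"forward"`/`"reverse"`).
#' @export
ancestral_insect_order <- function() {
  ord <- c(
    trnI = "forward", trnQ = "reverse", trnM = "forward",
    nad2 = "forward", trnW = "forward", trnC = "reverse",
    trnY = "reverse", cox1 = "forward", trnL2 = "forward",
    cox2 = "forward", trnK = "forward", trnD = "forward",
    atp8 = "forward", atp6 = "forward", cox3 = "forward",
    trnG = "forward", nad3 = "forward", trnA = "forward",
    trnR = "forward", trnN = "forward", trnS1 = "forward",
    trnE = "forward", trnF = "reverse", nad5 = "reverse",
    trnH = "reverse", nad4 = "reverse", nad4l = "reverse",
    trnT = "forward", trnP = "reverse", nad6 = "forward",
    cob = "forward", trnS2 = "forward", nad1 = "reverse",
    trnL1 = "reverse", rrnL = "reverse", trnV = "reverse",
    rrnS = "reverse"
  )
  data.frame(name = names(ord), direction = unname(ord),
             stringsAsFactors = FALSE)
}

# Canonical PCG concatenation order used for supermatrices.
PCG_CONCAT_ORDER <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
                      "nad3", "nad5", "nad4", "nad4l", "nad6", "cob",
                      "nad1")

#' Fetch a genetic code table
#'
#' @param code Integer translation-table identifier (1 = standard,
#'   5 = invertebrate mitochondrial, the package default).
#' @return Named character vector mapping the 64 codons to one-letter
#'   amino acids (`*` = stop), as returned by
#'   [Biostrings::getGeneticCode()].
#' @export
genetic_code <- function(code = 5L) {
  Biostrings::getGeneticCode(as.character(code))
}
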