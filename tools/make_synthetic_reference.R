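# Builds inst/extdata/rcrs_gene_map.tsv and inst/extdata/rcrs_synthetic.fasta.
#
# The gene map carries the canonical rCRS (NC_012920 coordinate frame) feature
# boundaries. The FASTA is a SYNTHETIC 16,569-bp sequence: randomly generated,
# then pinned so that (a) every documented variant site carries its published
# reference allele and codon context (amino-acid changes reproduce), (b) every
# protein gene is a valid ORF under the vertebrate mitochondrial code on its
# strand, including the ATP8/ATP6, ND4L/ND4 and ATP6/CO3 overlap frames, and
# (c) genes with polyadenylation-completed stops end in T/TA.
# It is NOT the rCRS sequence and is labelled synthetic in the FASTA header.

set.seed(12920)

GENOME_LEN <- 16569L

features <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name    start   end     strand  category        complex incomplete_stop
DLOOP   16024   576     H       dloop   .       0
TRNF    577     647     H       tRNA    .       0
RNR1    648     1601    H       rRNA    .       0
TRNV    1602    1670    H       tRNA    .       0
RNR2    1671    3229    H       rRNA    .       0
TRNL1   3230    3304    H       tRNA    .       0
NC1     3305    3306    H       intergenic      .       0
ND1     3307    4262    H       protein I       2
TRNI    4263    4331    H       tRNA    .       0
TRNQ    4329    4400    L       tRNA    .       0
NC2     4401    4401    H       intergenic      .       0
TRNM    4402    4469    H       tRNA    .       0
ND2     4470    5511    H       protein I       1
TRNW    5512    5579    H       tRNA    .       0
NC3     5580    5586    H       intergenic      .       0
TRNA    5587    5655    L       tRNA    .       0
NC4     5656    5656    H       intergenic      .       0
TRNN    5657    5729    L       tRNA    .       0
OLR1    5721    5798    L       regulatory      .       0
TRNC    5761    5826    L       tRNA    .       0
TRNY    5826    5891    L       tRNA    .       0
NC5     5892    5903    H       intergenic      .       0
CO1     5904    7445    H       protein IV      0
TRNS1   7446    7514    L       tRNA    .       0
NC6     7515    7517    H       intergenic      .       0
TRND    7518    7585    H       tRNA    .       0
CO2     7586    8269    H       protein IV      1
NC7     8270    8294    H       intergenic      .       0
TRNK    8295    8364    H       tRNA    .       0
NC8     8365    8365    H       intergenic      .       0
ATP8    8366    8572    H       protein V       0
ATP6    8527    9207    H       protein V       0
CO3     9207    9990    H       protein IV      1
TRNG    9991    10058   H       tRNA    .       0
ND3     10059   10404   H       protein I       1
TRNR    10405   10469   H       tRNA    .       0
ND4L    10470   10766   H       protein I       0
ND4     10760   12137   H       protein I       1
TRNH    12138   12206   H       tRNA    .       0
TRNS2   12207   12265   H       tRNA    .       0
TRNL2   12266   12336   H       tRNA    .       0
ND5     12337   14148   H       protein I       0
ND6     14149   14673   L       protein I       0
TRNE    14674   14742   L       tRNA    .       0
NC9     14743   14746   H       intergenic      .       0
CYB     14747   15887   H       protein III     1
TRNT    15888   15953   H       tRNA    .       0
NC10    15954   15955   H       intergenic      .       0
TRNP    15956   16023   L       tRNA    .       0
LPS     192     445     L       regulatory      .       0
TAS     16157   16172   H       regulatory      .       0
")

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(features, "inst/extdata/rcrs_gene_map.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- sequence -------------------------------------------------------------

BASES <- c("A", "C", "G", "T")
comp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

seqv <- sample(BASES, GENOME_LEN, replace = TRUE,
               prob = c(0.309, 0.313, 0.131, 0.247))
locked <- rep(FALSE, GENOME_LEN)

lock1 <- function(pos, base) {
  stopifnot(!locked[pos] | seqv[pos] == base)
  seqv[pos] <<- base
  locked[pos] <<- TRUE
}
lock3 <- function(pos, codon) {
  b <- strsplit(codon, "")[[1]]
  for (i in 0:2) lock1(pos + i, b[i + 1])
}

## Reference alleles at every site the source tables and text document,
## plus the bundled haplogroup panel markers.
singles <- c(
  `207` = "G", `5567` = "T", `5581` = "A", `10463` = "T", `15928` = "G",
  `15995` = "G", `16134` = "C", `16162` = "A", `16163` = "A", `16248` = "C",
  `16261` = "C", `16294` = "C", `16296` = "C", `16527` = "C",
  `3219` = "G", `3631` = "T", `7124` = "A", `2641` = "A", `3535` = "T",
  `5726` = "T", `5777` = "G", `8292` = "A", `11221` = "A", `16150` = "C",
  `644` = "A", `15496` = "A", `15115` = "T", `16270` = "C",
  `146` = "T", `153` = "A", `235` = "A", `663` = "A", `1736` = "A",
  `4248` = "T", `4824` = "A", `8027` = "G", `8794` = "C", `16111` = "C",
  `16290` = "C", `16319` = "G", `16362` = "T", `16519` = "T",
  `16189` = "T", `10398` = "A", `10400` = "C", `12705` = "T",
  # haplogroup panel markers
  `827` = "A", `16217` = "T", `4977` = "T", `6473` = "C", `9950` = "T",
  `3552` = "T", `9545` = "A", `13263` = "A", `14318` = "T", `16327` = "C",
  `4883` = "C", `5178` = "C", `8414` = "C", `14668` = "C",
  `2706` = "A", `7028` = "C", `6776` = "T", `3992` = "C", `456` = "C",
  `295` = "C", `489` = "T", `12612` = "A", `13708` = "G", `13650` = "C",
  `16069` = "C", `2758` = "G", `3594` = "C", `7256` = "C", `16187` = "C"
)
for (p in names(singles)) lock1(as.integer(p), singles[[p]])

## Codon contexts reproducing the documented amino-acid changes.
lock3(3394,  "TAC")  # ND1  T3394C  Y -> H
lock3(4821,  "GTT")  # ND2  T4823C  V synonymous
lock3(6369,  "TCC")  # CO1  C6371T  S synonymous
lock3(7389,  "TAC")  # CO1  T7389C  Y -> H
lock3(8429,  "CTC")  # ATP8 T8430A  L22H
lock3(8438,  "CAA")  # ATP8 A8439C  Q25P
lock3(10290, "GCC")  # ND3  G10290A A -> T
lock3(12628, "TGG")  # ND5  G12630A W synonymous
lock3(13333, "GCC")  # ND5  G13333A A -> T
lock3(13966, "ACC")  # ND5  A13966G T -> A
lock3(15830, "ATC")  # CYB  T15831C I -> T
lock3(15836, "ATC")  # CYB  A15836C I -> L
# ND6 (L strand) T14470C, G synonymous: coding codon GGA at genome 14472..14470
lock1(14470, "T"); lock1(14471, "C"); lock1(14472, "C")

## ---- ORF construction -----------------------------------------------------

prot <- features[features$category == "protein", ]
STOPS <- c("TAA", "TAG", "AGA", "AGG")

# coding-frame codon at index ci (0-based) for a gene row g
codon_pos <- function(g, ci) {
  if (g$strand == "H") g$start + 3 * ci + 0:2 else g$end - 3 * ci - 0:2
}
codon_at <- function(g, ci) {
  pos <- codon_pos(g, ci)
  b <- seqv[pos]
  if (g$strand == "L") b <- comp(b)
  paste(b, collapse = "")
}
set_codon <- function(g, ci, codon) {
  pos <- codon_pos(g, ci)
  b <- strsplit(codon, "")[[1]]
  if (g$strand == "L") b <- comp(b)
  for (i in 1:3) lock1(pos[i], b[i])
}

n_codons <- function(g) (g$end - g$start + 1 - g$incomplete_stop) %/% 3

# Start and stop codons. Order matters at shared bases: ATP6 stop (9205..9207)
# supplies the A that begins CO3's ATG; ND4's ATG sits inside ND4L.
for (nm in c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "ND4L", "ND4",
             "CO3", "ND3", "ND5", "ND6", "CYB")) {
  g <- prot[prot$name == nm, ]
  set_codon(g, 0, "ATG")
  nc <- n_codons(g)
  if (g$incomplete_stop == 0) {
    set_codon(g, nc - 1, if (nm == "CO1") "AGA" else "TAA")
  } else {
    tail_pos <- (g$end - g$incomplete_stop + 1):g$end
    tb <- if (g$incomplete_stop == 1) "T" else c("T", "A")
    for (i in seq_along(tail_pos)) lock1(tail_pos[i], tb[i])
  }
}

# Sweep: remove in-frame stops from every internal codon using free bases.
internal_stops <- function() {
  out <- list()
  for (k in seq_len(nrow(prot))) {
    g <- prot[k, ]
    nc <- n_codons(g)
    last_internal <- if (g$incomplete_stop == 0) nc - 2 else nc - 1
    for (ci in 1:last_internal) {
      if (codon_at(g, ci) %in% STOPS) out[[length(out) + 1]] <- list(g = g, ci = ci)
    }
  }
  out
}

for (iter in 1:200) {
  bad <- internal_stops()
  if (length(bad) == 0) break
  for (s in bad) {
    pos <- codon_pos(s$g, s$ci)
    free <- pos[!locked[pos]]
    stopifnot(length(free) > 0)
    fixed <- FALSE
    for (p in sample(free)) {
      old <- seqv[p]
      for (b in sample(setdiff(BASES, old))) {
        seqv[p] <- b
        if (!(codon_at(s$g, s$ci) %in% STOPS)) { fixed <- TRUE; break }
      }
      if (fixed) break else seqv[p] <- old
    }
    stopifnot(fixed)
  }
}
stopifnot(length(internal_stops()) == 0)

## ---- verification ---------------------------------------------------------

suppressPackageStartupMessages(library(Biostrings))
code2 <- getGeneticCode("2")
tr1 <- function(codon) unname(code2[codon])

gene_of <- function(nm) prot[prot$name == nm, ]
aa_at <- function(nm, genome_pos, alt = NULL) {
  g <- gene_of(nm)
  off <- if (g$strand == "H") genome_pos - g$start else g$end - genome_pos
  ci <- off %/% 3
  pos <- codon_pos(g, ci)
  b <- seqv[pos]
  if (!is.null(alt)) b[pos == genome_pos] <- alt
  if (g$strand == "L") b <- comp(b)
  tr1(paste(b, collapse = ""))
}
check <- function(nm, pos, ref, alt, aa_ref, aa_alt) {
  stopifnot(seqv[pos] == ref,
            aa_at(nm, pos) == aa_ref,
            aa_at(nm, pos, alt) == aa_alt)
}
check("ND1", 3394, "T", "C", "Y", "H")
check("ND2", 4823, "T", "C", "V", "V")
check("CO1", 6371, "C", "T", "S", "S")
check("CO1", 7389, "T", "C", "Y", "H")
check("ATP8", 8430, "T", "A", "L", "H")
check("ATP8", 8439, "A", "C", "Q", "P")
check("ND3", 10290, "G", "A", "A", "T")
check("ND5", 12630, "G", "A", "W", "W")
check("ND5", 13333, "G", "A", "A", "T")
check("ND5", 13966, "A", "G", "T", "A")
check("ND6", 14470, "T", "C", "G", "G")
check("CYB", 15831, "T", "C", "I", "T")
check("CYB", 15836, "A", "C", "I", "L")

# full-ORF check per gene via Biostrings translation
for (k in seq_len(nrow(prot))) {
  g <- prot[k, ]
  nc <- n_codons(g)
  cds <- paste(vapply(0:(nc - 1), function(ci) codon_at(g, ci), ""), collapse = "")
  aa <- as.character(translate(DNAString(cds), genetic.code = code2))
  stopifnot(substr(aa, 1, 1) == "M")
  body <- substr(aa, 2, nc - ifelse(g$incomplete_stop == 0, 1, 0))
  stopifnot(!grepl("\\*", body))
  if (g$incomplete_stop == 0) stopifnot(substr(aa, nc, nc) == "*")
}

## ---- write ----------------------------------------------------------------

fa <- file("inst/extdata/rcrs_synthetic.fasta", "w")
writeLines(paste0(">rCRS_synthetic 16569 bp | SYNTHETIC sequence on the rCRS ",
                  "coordinate frame (not NC_012920); documented variant sites ",
                  "and codon contexts are pinned, remainder simulated"), fa)
s <- paste(seqv, collapse = "")
writeLines(substring(s, seq(1, GENOME_LEN, 70), pmin(seq(1, GENOME_LEN, 70) + 69, GENOME_LEN)), fa)
close(fa)

cat("wrote gene map (", nrow(features), "features ) and synthetic FASTA\n")
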