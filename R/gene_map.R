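#' The mitochondrial gene map and reference utilities
#'
#' Functions serving the 16,569-bp rCRS coordinate frame: the feature
#' annotation (13 protein genes, 22 tRNAs, 2 rRNAs, the circular D-Loop,
#' regulatory elements and intergenic gaps), the bundled reference sequence,
#' and the vertebrate mitochondrial genetic code.
#'
#' @name mito_reference
NULL

MT_GENOME_LENGTH <- 16569L

#' Load the bundled mitochondrial gene map
#'
#' Reads the tab-delimited feature annotation (1-based inclusive rCRS
#' coordinates) and, optionally, a single-record 16,569-bp reference FASTA.
#' The bundled FASTA is a synthetic sequence on the rCRS coordinate frame:
#' documented variant sites and their codon contexts match the published
#' alleles, the remainder is simulated (see the package vignette).
#'
#' Features whose span crosses the origin (the D-Loop, 16024..576) are stored
#' with `start > end` and handled circularly. Protein genes whose stop codon
#' is completed by polyadenylation carry `incomplete_stop` of 1 or 2
#' (trailing bases not part of a full codon).
#'
#' @param path path to the feature table; defaults to the bundled map.
#' @param fasta path to the reference FASTA, `NA` to skip loading a sequence;
#'   defaults to the bundled synthetic reference.
#' @return an object of class `MitoGeneMap`: a list with `genome_length`,
#'   `features` (data.frame: name, start, end, strand, category, complex,
#'   incomplete_stop), and `sequence` (character vector of 16,569 bases, or
#'   `NULL`).
#' @examples
#' map <- load_gene_map()
#' subset(map$features, name == "ND1")
#' @export
load_gene_map <- function(path = system.file("extdata", "rcrs_gene_map.tsv",
                                             package = "mitopair"),
                          fasta = system.file("extdata", "rcrs_synthetic.fasta",
                                              package = "mitopair")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("gene map file not found: ", path, call. = FALSE)
  }
  feats <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "start", "end", "strand", "category", "complex")
  if (!all(needed %in% names(feats))) {
    stop("malformed gene map: expected columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (is.null(feats$incomplete_stop)) feats$incomplete_stop <- 0L
  if (any(feats$start < 1 | feats$start > MT_GENOME_LENGTH |
          feats$end < 1 | feats$end > MT_GENOME_LENGTH)) {
    stop("malformed gene map: coordinates outside 1..16569", call. = FALSE)
  }
  if (!all(feats$strand %in% c("H", "L"))) {
    stop("malformed gene map: strand must be H or L", call. = FALSE)
  }

  sequence <- NULL
  if (!is.na(fasta) && nzchar(fasta)) {
    if (!file.exists(fasta)) {
      stop("reference FASTA not found: ", fasta, call. = FALSE)
    }
    dna <- Biostrings::readDNAStringSet(fasta)
    if (length(dna) != 1L || Biostrings::width(dna)[1] != MT_GENOME_LENGTH) {
      stop("reference FASTA must hold one record of ", MT_GENOME_LENGTH,
           " bp", call. = FALSE)
    }
    sequence <- strsplit(toupper(as.character(dna[[1]])), "")[[1]]
  }

  # position -> feature indices, computed once (circular spans wrap)
  cover <- vector("list", MT_GENOME_LENGTH)
  for (i in seq_len(nrow(feats))) {
    pos <- feature_positions(feats$start[i], feats$end[i])
    for (p in pos) cover[[p]] <- c(cover[[p]], i)
  }
  if (any(lengths(cover) == 0)) {
    stop("malformed gene map: positions not covered by any feature: ",
         paste(utils::head(which(lengths(cover) == 0)), collapse = ", "),
         call. = FALSE)
  }

  structure(list(genome_length = MT_GENOME_LENGTH, features = feats,
                 sequence = sequence, .cover = cover),
            class = "MitoGeneMap")
}

# positions spanned by a feature, wrapping across the origin when start > end
feature_positions <- function(start, end) {
  if (start <= end) start:end else c(start:MT_GENOME_LENGTH, 1:end)
}

#' Length of a feature in bp, circular wrap-aware
#'
#' @param map a `MitoGeneMap`
#' @param name feature name(s)
#' @return integer vector of lengths
#' @export
feature_length <- function(map, name) {
  i <- match(name, map$features$name)
  if (anyNA(i)) stop("unknown feature: ", paste(name[is.na(i)], collapse = ", "),
                     call. = FALSE)
  s <- map$features$start[i]; e <- map$features$end[i]
  ifelse(s <= e, e - s + 1L, map$genome_length - s + 1L + e)
}

#' Locate the features covering a genomic position
#'
#' Every position 1..16569 maps to at least one feature (intergenic gaps are
#' features). Positions inside the D-Loop on either side of the origin
#' resolve to the D-Loop feature; overlap regions (e.g. ATP8/ATP6,
#' 8527..8572) return every overlapping feature.
#'
#' @param position a single 1-based rCRS coordinate
#' @param map a `MitoGeneMap`
#' @return data.frame of covering features (subset of `map$features`)
#' @examples
#' map <- load_gene_map()
#' locate(8550, map)$name   # ATP8 and ATP6
#' @export
locate <- function(position, map) {
  stopifnot(inherits(map, "MitoGeneMap"))
  if (length(position) != 1L || is.na(position) ||
      position < 1 || position > map$genome_length || position != round(position)) {
    stop("position must be a single integer in 1..", map$genome_length,
         call. = FALSE)
  }
  map$features[map$.cover[[as.integer(position)]], , drop = FALSE]
}

#' @export
print.MitoGeneMap <- function(x, ...) {
  cat("MitoGeneMap:", x$genome_length, "bp,", nrow(x$features), "features",
      if (is.null(x$sequence)) "(no reference sequence)" else
        "(reference sequence loaded)", "\n")
  tab <- table(x$features$category)
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Reference base(s) at rCRS position(s)
#'
#' @param map a `MitoGeneMap` with a loaded sequence
#' @param position integer vector of 1-based positions
#' @return character vector of bases
#' @export
ref_base <- function(map, position) {
  stopifnot(inherits(map, "MitoGeneMap"))
  if (is.null(map$sequence)) {
    stop("no reference sequence loaded; pass a FASTA to load_gene_map()",
         call. = FALSE)
  }
  if (any(position < 1 | position > map$genome_length)) {
    stop("position out of range 1..", map$genome_length, call. = FALSE)
  }
  map$sequence[position]
}

#' The vertebrate mitochondrial genetic code
#'
#' Translation table 2: compared with the standard nuclear code, ATA encodes
#' Met, TGA encodes Trp, and AGA/AGG are stop codons. Stops are written `*`.
#'
#' @return named character vector of 64 one-letter amino acids, names are
#'   codons; attributes `start_codons` and `stop_codons`.
#' @examples
#' code <- mito_genetic_code()
#' code[["TGA"]]  # "W"
#' @export
mito_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(b, each = 4, times = 4),
                   rep(b, times = 16))
  # standard code in TCAG order, then the four mitochondrial differences
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  code <- stats::setNames(aa, codons)
  code[["ATA"]] <- "M"
  code[["TGA"]] <- "W"
  code[["AGA"]] <- "*"
  code[["AGG"]] <- "*"
  attr(code, "start_codons") <- c("ATG", "ATA", "ATT")
  attr(code, "stop_codons") <- names(code)[code == "*"]
  code
}

#' Translate one codon under a genetic code
#'
#' @param codon 3-character string over A/C/G/T (case-insensitive)
#' @param code a code table from [mito_genetic_code()]
#' @return one-letter amino acid, `"*"` for stop, or `NA` for an ambiguous
#'   or invalid codon (annotation then falls back to an unknown effect)
#' @export
translate_codon <- function(codon, code = mito_genetic_code()) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) return(NA_character_)
  unname(code[[codon]])
}

# complement of a base vector (A/C/G/T only)
complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}
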