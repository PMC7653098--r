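# shared fixtures and independent oracles used across test files

the_map <- load_gene_map()
the_panel <- load_haplogroup_panel()

# a small hand-built paired table: one patient pair of each origin class
tiny_paired <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    position   = c(663L, 13333L, 8430L, 663L, 4823L),
    ref        = c("A", "G", "T", "A", "T"),
    alt        = c("G", "A", "A", "G", "C"),
    blood_alt  = c(980L, 0L, 3L, 150L, 0L),
    blood_depth = c(1000L, 1000L, 1000L, 1000L, 2000L),
    tumor_alt  = c(990L, 300L, 950L, 900L, 0L),
    tumor_depth = c(1000L, 1000L, 1000L, 1000L, 2000L),
    stringsAsFactors = FALSE)
}

tiny_classified <- function() {
  df <- tiny_paired()
  df$blood_maf <- df$blood_alt / df$blood_depth
  df$tumor_maf <- df$tumor_alt / df$tumor_depth
  classify_origin(df)
}

# Mann-Whitney U by brute-force enumeration over all (x, y) pairs
brute_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# whole-gene retranslation oracle: every SNV at every full-codon position of
# a protein gene, effect derived by rebuilding and translating the complete
# CDS with the Biostrings vertebrate-mitochondrial code (independent of the
# package's codon-offset fast path)
oracle_gene_snvs <- function(gene_name, map) {
  g <- map$features[map$features$name == gene_name, ]
  len <- g$end - g$start + 1L
  nc <- (len - g$incomplete_stop) %/% 3L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds_pos <- if (g$strand == "H") g$start + 0:(3L * nc - 1L) else
    g$end - (0:(3L * nc - 1L))
  ref_g <- map$sequence[cds_pos]
  ref_cds <- if (g$strand == "H") ref_g else unname(comp[ref_g])
  code2 <- Biostrings::getGeneticCode("2")
  ref_prot <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(paste(ref_cds, collapse = "")),
    genetic.code = code2, no.init.codon = TRUE)), "")[[1]]

  rows <- list()
  mut_cds <- character(0)
  for (k in seq_along(cds_pos)) {
    for (b in setdiff(c("A", "C", "G", "T"), ref_g[k])) {
      cds <- ref_cds
      cds[k] <- if (g$strand == "H") b else unname(comp[b])
      mut_cds <- c(mut_cds, paste(cds, collapse = ""))
      rows[[length(rows) + 1L]] <- data.frame(
        position = cds_pos[k], ref = ref_g[k], alt = b,
        codon_index = (k - 1L) %/% 3L + 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(mut_cds), genetic.code = code2,
    no.init.codon = TRUE))
  aa_alt <- substr(prot, out$codon_index, out$codon_index)
  aa_ref <- ref_prot[out$codon_index]
  out$effect <- ifelse(aa_alt == aa_ref, "synonymous",
                       ifelse(aa_alt == "*", "nonsense", "missense"))
  out$aa_change <- paste0(aa_ref, "/", aa_alt)
  out
}
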