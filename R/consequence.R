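#' Variant consequence annotation on the mitochondrial genome
#'
#' Strand-aware annotation under the vertebrate mitochondrial genetic code.
#' Light-strand genes (ND6 and eight tRNAs) are read on the complement;
#' positions covered by several features (the ATP8/ATP6 overlap, tRNAs inside
#' the L-strand replication origin) yield one consequence per feature.
#'
#' @name consequence_annotation
NULL

#' Variant type from normalized alleles
#'
#' @param ref,alt character vectors of normalized alleles
#' @return character vector: "SNV", "insertion" or "deletion"
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
}

#' Transition/transversion class of a substitution
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) changes are
#' transitions; all others transversions. Non-SNVs are `not_applicable`.
#'
#' @param ref,alt character vectors of alleles
#' @return character vector: "transition", "transversion", "not_applicable"
#' @export
substitution_class <- function(ref, alt) {
  purine <- function(b) b %in% c("A", "G")
  ifelse(variant_type(ref, alt) != "SNV", "not_applicable",
         ifelse(purine(ref) == purine(alt), "transition", "transversion"))
}

EFFECT_LEVELS <- c("synonymous", "missense", "nonsense", "frameshift",
                   "inframe_indel", "stop_region", "tRNA", "rRNA",
                   "regulatory", "dloop_noncoding", "intergenic", "unknown")

# effect ranking used to pick the primary consequence for a multi-feature
# position (protein consequences outrank RNA, regulatory, then non-coding)
EFFECT_PRIORITY <- c(frameshift = 1, nonsense = 2, missense = 3,
                     stop_region = 4, inframe_indel = 5, synonymous = 6,
                     tRNA = 7, rRNA = 8, regulatory = 9,
                     dloop_noncoding = 10, intergenic = 11, unknown = 12)

# codon-aware annotation of one variant against one protein feature
protein_consequence <- function(position, ref, alt, g, map, code) {
  vt <- variant_type(ref, alt)
  if (vt != "SNV") {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L
    return(list(effect = if (shift != 0L) "frameshift" else "inframe_indel",
                aa_change = NA_character_, aa_pos = NA_integer_))
  }
  len <- g$end - g$start + 1L
  off <- if (g$strand == "H") position - g$start else g$end - position
  ci <- off %/% 3L
  n_codons <- (len - g$incomplete_stop) %/% 3L
  if (ci >= n_codons) {
    # trailing base(s) of a polyadenylation-completed stop codon
    return(list(effect = "stop_region", aa_change = NA_character_,
                aa_pos = NA_integer_))
  }
  cpos <- if (g$strand == "H") g$start + 3L * ci + 0:2 else g$end - 3L * ci - 0:2
  b <- ref_base(map, cpos)
  if (b[cpos == position] != ref) {
    stop("reference base mismatch at position ", position, ": expected ",
         b[cpos == position], ", got ", ref, call. = FALSE)
  }
  b_alt <- b
  b_alt[cpos == position] <- alt
  if (g$strand == "L") { b <- complement_base(b); b_alt <- complement_base(b_alt) }
  aa_ref <- translate_codon(paste(b, collapse = ""), code)
  aa_alt <- translate_codon(paste(b_alt, collapse = ""), code)
  if (is.na(aa_ref) || is.na(aa_alt)) {
    return(list(effect = "unknown", aa_change = NA_character_,
                aa_pos = NA_integer_))
  }
  effect <- if (aa_alt == aa_ref) "synonymous"
            else if (aa_alt == "*") "nonsense" else "missense"
  list(effect = effect, aa_change = paste0(aa_ref, "/", aa_alt),
       aa_pos = ci + 1L)
}

#' Annotate a variant with every overlapping feature's consequence
#'
#' Protein features get codon-level effects (synonymous / missense /
#' nonsense; indels become frameshift or in-frame changes by length mod 3;
#' variants in a polyadenylation-completed stop are `stop_region`).
#' Non-protein features get their category-level effect (tRNA, rRNA,
#' regulatory, dloop_noncoding, intergenic). Requires the reference sequence
#' for protein SNVs; a reference mismatch raises an error naming the
#' position.
#'
#' @param position 1-based rCRS coordinate
#' @param ref,alt normalized alleles
#' @param map a `MitoGeneMap` with sequence loaded
#' @param code genetic code table (default [mito_genetic_code()])
#' @return data.frame with one row per covering feature: region, category,
#'   strand, variant_type, substitution_class, effect, aa_change, aa_pos
#' @examples
#' map <- load_gene_map()
#' annotate_variant(13333, "G", "A", map)  # ND5 missense A/T
#' @export
annotate_variant <- function(position, ref, alt, map,
                             code = mito_genetic_code()) {
  feats <- locate(position, map)
  vt <- variant_type(ref, alt)
  sc <- substitution_class(ref, alt)
  if (vt == "SNV" && !is.null(map$sequence)) {
    have <- ref_base(map, position)
    if (have != ref) {
      stop("reference base mismatch at position ", position, ": expected ",
           have, ", got ", ref, call. = FALSE)
    }
  }
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    g <- feats[i, ]
    if (g$category == "protein") {
      if (is.null(map$sequence)) {
        stop("protein annotation at position ", position,
             " requires a reference sequence", call. = FALSE)
      }
      pc <- protein_consequence(position, ref, alt, g, map, code)
    } else {
      eff <- switch(g$category, tRNA = "tRNA", rRNA = "rRNA",
                    regulatory = "regulatory", dloop = "dloop_noncoding",
                    intergenic = "intergenic", "unknown")
      pc <- list(effect = eff, aa_change = NA_character_, aa_pos = NA_integer_)
    }
    data.frame(region = g$name, category = g$category, strand = g$strand,
               variant_type = vt, substitution_class = sc,
               effect = pc$effect, aa_change = pc$aa_change, aa_pos = pc$aa_pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate every variant of a classified table
#'
#' Adds annotation columns to a (classified) paired variant table. For
#' positions covered by several features, the row keeps the highest-priority
#' consequence (protein effects first) and `region` joins all covering
#' feature names with `,` so overlap double-counting stays visible; the full
#' per-feature set is available via [annotate_variant()].
#'
#' @param records paired/classified variant data.frame
#' @param map a `MitoGeneMap` with sequence loaded
#' @param code genetic code table
#' @return `records` plus region, variant_type, substitution_class, effect,
#'   aa_change columns
#' @export
annotate_cohort <- function(records, map, code = mito_genetic_code()) {
  keys <- unique(records[, c("position", "ref", "alt")])
  ann <- lapply(seq_len(nrow(keys)), function(i) {
    a <- annotate_variant(keys$position[i], keys$ref[i], keys$alt[i], map, code)
    best <- a[order(EFFECT_PRIORITY[a$effect])[1], ]
    data.frame(position = keys$position[i], ref = keys$ref[i],
               alt = keys$alt[i],
               region = paste(a$region, collapse = ","),
               variant_type = best$variant_type,
               substitution_class = best$substitution_class,
               effect = best$effect, aa_change = best$aa_change,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  merge(records, ann, by = c("position", "ref", "alt"), sort = FALSE)
}
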