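#' Paired blood-tumor variant input/output
#'
#' Readers for the flat TSV dialect and for two-sample VCF 4.2 with per-allele
#' read depths, plus the writer/reader pair for classified variant tables.
#' A paired-variant table has one row per (patient, position, ref, alt) with
#' allele counts and mutant allele fractions (MAF = alt reads / depth) in both
#' tissues. A variant absent from one tissue is represented with 0 alt reads
#' at that tissue's observed depth, never as a missing record.
#'
#' @name variant_io
NULL

PAIRED_COLS <- c("patient_id", "position", "ref", "alt",
                 "blood_alt", "blood_depth", "tumor_alt", "tumor_depth")

# normalize one allele pair: strip shared suffix, then shared prefix
# (keeping >= 1 base and the VCF anchor convention), left-adjusting position
normalize_allele_pair <- function(position, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(position = position, ref = ref, alt = alt)
}

finalize_paired <- function(df, min_depth) {
  df$position <- as.integer(df$position)
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)

  bad_allele <- df$ref == df$alt | grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)
  if (any(bad_allele)) {
    stop("invalid alleles at row(s) ", paste(utils::head(which(bad_allele)),
                                             collapse = ", "), call. = FALSE)
  }
  over <- df$blood_alt > df$blood_depth | df$tumor_alt > df$tumor_depth
  if (any(over)) {
    stop("alt reads exceed depth at row(s) ",
         paste(utils::head(which(over)), collapse = ", "), call. = FALSE)
  }

  norm <- Map(normalize_allele_pair, df$position, df$ref, df$alt)
  df$position <- vapply(norm, `[[`, integer(1), "position")
  df$ref <- vapply(norm, `[[`, character(1), "ref")
  df$alt <- vapply(norm, `[[`, character(1), "alt")

  zero <- df$blood_depth == 0L | df$tumor_depth == 0L
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero depth excluded", call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  shallow <- df$blood_depth < min_depth | df$tumor_depth < min_depth
  if (any(shallow)) {
    warning(sum(shallow), " record(s) below ", min_depth,
            "x depth excluded", call. = FALSE)
    df <- df[!shallow, , drop = FALSE]
  }
  df$blood_maf <- ifelse(df$blood_depth > 0, df$blood_alt / df$blood_depth, 0)
  df$tumor_maf <- ifelse(df$tumor_depth > 0, df$tumor_alt / df$tumor_depth, 0)
  rownames(df) <- NULL
  df[, c(PAIRED_COLS, "blood_maf", "tumor_maf")]
}

#' Read paired variant observations from a TSV
#'
#' Expected columns: `patient_id, position, ref, alt, blood_alt, blood_depth,
#' tumor_alt, tumor_depth`. MAFs are computed as alt reads over depth. Rows
#' with zero depth in either tissue are excluded with a warning; rows below
#' `min_depth` in either tissue are excluded with a warning (the study design
#' requires at least 300x per base). Indel alleles are normalized to the
#' left-aligned, parsimonious VCF convention with an anchor base.
#'
#' @param path TSV path
#' @param min_depth minimum per-tissue depth for inclusion (default 300)
#' @return data.frame with one row per (patient, variant) and columns
#'   `patient_id, position, ref, alt, blood_alt, blood_depth, tumor_alt,
#'   tumor_depth, blood_maf, tumor_maf`
#' @export
read_paired_tsv <- function(path, min_depth = 300L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  if (nrow(df) == 0L) {
    out <- data.frame(patient_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      blood_alt = integer(), blood_depth = integer(),
                      tumor_alt = integer(), tumor_depth = integer(),
                      blood_maf = numeric(), tumor_maf = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  missing <- setdiff(PAIRED_COLS, names(df))
  if (length(missing)) {
    stop("paired TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  finalize_paired(df[, PAIRED_COLS], min_depth)
}

#' Read paired variant observations from a two-sample VCF
#'
#' Expects VCF 4.2 with per-sample allelic depths (`AD` FORMAT field).
#' Multiallelic sites are decomposed into one record per ALT allele; the
#' per-allele depth comes from `AD`, the site depth is the sum of all `AD`
#' entries for the sample. Patient id defaults to the tumor sample name.
#'
#' @param path VCF path (plain or bgzipped)
#' @param blood_sample_name,tumor_sample_name sample column names
#' @param patient_id id recorded for all records (default: tumor sample name)
#' @param min_depth minimum per-tissue depth for inclusion (default 300)
#' @return as [read_paired_tsv()]
#' @export
read_paired_vcf <- function(path, blood_sample_name, tumor_sample_name,
                            patient_id = tumor_sample_name, min_depth = 300L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(read_paired_tsv(textConnection(
    paste(PAIRED_COLS, collapse = "\t"))))
  samples <- colnames(v@gt)[-1]
  for (s in c(blood_sample_name, tumor_sample_name)) {
    if (!s %in% samples) stop("sample not in VCF: ", s, call. = FALSE)
  }
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF lacks the AD (allelic depth) FORMAT field", call. = FALSE)
  }

  rows <- list()
  pos <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt_field <- v@fix[, "ALT"]
  for (i in seq_len(nrow(v@fix))) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    ad_b <- suppressWarnings(as.integer(strsplit(ad[i, blood_sample_name], ",")[[1]]))
    ad_t <- suppressWarnings(as.integer(strsplit(ad[i, tumor_sample_name], ",")[[1]]))
    if (anyNA(ad_b) || anyNA(ad_t) ||
        length(ad_b) != length(alts) + 1L || length(ad_t) != length(alts) + 1L) {
      stop("missing or malformed AD for sample at ", ref[i], pos[i],
           " (site ", pos[i], ")", call. = FALSE)
    }
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, position = pos[i], ref = ref[i],
        alt = alts[k],
        blood_alt = ad_b[k + 1L], blood_depth = sum(ad_b),
        tumor_alt = ad_t[k + 1L], tumor_depth = sum(ad_t),
        stringsAsFactors = FALSE)
    }
  }
  finalize_paired(do.call(rbind, rows), min_depth)
}

CLASSIFIED_COLS <- c("patient_id", "position", "ref", "alt",
                     "blood_alt", "blood_depth", "tumor_alt", "tumor_depth",
                     "blood_maf", "tumor_maf",
                     "origin", "blood_ploidy", "tumor_ploidy",
                     "region", "variant_type", "substitution_class",
                     "effect", "aa_change")

#' Write a classified variant table to TSV
#'
#' One row per (patient, variant) with a fixed, bit-stable column order;
#' missing annotation fields are written as `.`. Read back with
#' [read_classified()]; the round trip is the identity on content.
#'
#' @param path output path
#' @param records classified (and optionally annotated) variant data.frame
#' @export
write_classified <- function(path, records) {
  out <- records
  for (col in CLASSIFIED_COLS) if (is.null(out[[col]])) out[[col]] <- NA
  out <- out[, CLASSIFIED_COLS]
  for (col in names(out)) {
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write: ", path, call. = FALSE))
  on.exit(close(con))
  for (col in c("blood_maf", "tumor_maf")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
}

#' Read back a classified variant table written by [write_classified()]
#'
#' @param path TSV path
#' @return data.frame in the classified column layout
#' @export
read_classified <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  int_cols <- c("position", "blood_alt", "blood_depth", "tumor_alt", "tumor_depth")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  df
}
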