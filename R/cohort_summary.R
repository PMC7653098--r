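#' Cohort-level summaries
#'
#' Per-gene variant counts and per-kilobase rates, origin/effect/type
#' breakdowns with explicit denominators, subtype stratification and sharing,
#' association tests, and unsupervised clustering of mutation profiles.
#'
#' @name cohort_summary
NULL

#' Bundle classified variants with patient metadata
#'
#' @param variants classified (annotated) variant data.frame
#' @param patients metadata data.frame with at least `patient_id`; typically
#'   also `subtype` (LA, LB, H2, TN or NA), `age`, `follow_up_months`,
#'   `vital_status` (1 = death, 0 = censored) and covariates
#' @return list of class `mito_cohort`
#' @export
mito_cohort <- function(variants, patients) {
  stopifnot(is.data.frame(variants), is.data.frame(patients),
            !is.null(patients$patient_id))
  orphan <- setdiff(unique(variants$patient_id), patients$patient_id)
  if (length(orphan)) {
    stop("variant records for unknown patient(s): ",
         paste(utils::head(orphan), collapse = ", "), call. = FALSE)
  }
  structure(list(variants = variants, patients = patients),
            class = "mito_cohort")
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat("mito_cohort:", nrow(x$patients), "patients,",
      nrow(x$variants), "variant records\n")
  if (!is.null(x$variants$origin)) {
    print(table(origin = x$variants$origin))
  }
  invisible(x)
}

#' Variants per kilobase
#'
#' `count * 1000 / length_bp`. Full precision is returned; display rounding
#' is left to the caller (the conventional display is 1 decimal).
#'
#' @param count number of variants
#' @param length_bp feature length in bases (> 0)
#' @return numeric rate
#' @examples
#' rate_per_kb(709, 16569)  # 42.79...
#' @export
rate_per_kb <- function(count, length_bp) {
  if (any(length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  count * 1000 / length_bp
}

#' Percentage with half-up rounding to one decimal
#'
#' @param numerator,denominator counts
#' @param digits decimals (default 1)
#' @return numeric percentage rounded half-up
#' @examples
#' pct(68, 92)   # 73.9
#' @export
pct <- function(numerator, denominator, digits = 1) {
  x <- 100 * numerator / denominator
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-feature variant counts and rates
#'
#' Counts cohort variants per gene-map feature. Because a variant's identity
#' is ambiguous between "distinct positions" and "distinct (position, allele)
#' pairs", both tallies are reported (`n_positions`, `n_alleles`), along with
#' rates per kb computed from `n_positions`. Positions in overlap regions
#' count for every covering feature.
#'
#' @param cohort a `mito_cohort` (or classified variant data.frame)
#' @param map a `MitoGeneMap`
#' @param classes origin classes to include (default: all detected)
#' @return data.frame: name, category, length_bp, n_positions, n_alleles,
#'   rate_per_kb
#' @export
gene_rates <- function(cohort, map,
                       classes = c("germline", "somatic", "probable_mutation")) {
  v <- if (inherits(cohort, "mito_cohort")) cohort$variants else cohort
  if (!is.null(v$origin)) v <- v[v$origin %in% classes, , drop = FALSE]
  keys <- unique(v[, c("position", "ref", "alt")])

  feats <- map$features
  n_pos <- integer(nrow(feats)); n_all <- integer(nrow(feats))
  if (nrow(keys) > 0) {
    hits <- lapply(keys$position, function(p) map$.cover[[p]])
    for (i in seq_len(nrow(feats))) {
      in_feat <- vapply(hits, function(h) i %in% h, logical(1))
      n_pos[i] <- length(unique(keys$position[in_feat]))
      n_all[i] <- sum(in_feat)
    }
  }
  len <- feature_length(map, feats$name)
  data.frame(name = feats$name, category = feats$category,
             length_bp = len, n_positions = n_pos, n_alleles = n_all,
             rate_per_kb = rate_per_kb(n_pos, len),
             stringsAsFactors = FALSE)
}

#' Cohort breakdown with explicit denominators
#'
#' Counts and percentages per origin class; per variant type, substitution
#' class, tumor ploidy and effect among the selected origin class (default
#' somatic, distinct variants); coding vs non-coding split; and the fraction
#' of patients carrying at least one somatic mutation.
#'
#' @param cohort a `mito_cohort`
#' @param origin_class class summarized in the type/effect tables
#' @return list of data.frames, each carrying its numerator and denominator
#' @export
class_breakdown <- function(cohort, origin_class = "somatic") {
  v <- cohort$variants
  n_patients <- nrow(cohort$patients)
  if (is.null(v$origin) || nrow(v) == 0L) {
    return(list(origin = data.frame(), positive_tumors = data.frame(
      n_positive = 0L, n_patients = n_patients, percent = 0)))
  }
  det <- v[v$origin != "absent", , drop = FALSE]

  # distinct variants per origin class
  ok <- !duplicated(cbind(variant_id(det), as.character(det$origin)))
  uvar <- det[ok, , drop = FALSE]
  origin_tab <- as.data.frame(table(origin = uvar$origin))
  names(origin_tab)[2] <- "n"
  origin_tab$denominator <- nrow(uvar)
  origin_tab$percent <- pct(origin_tab$n, nrow(uvar))

  sel <- uvar[uvar$origin == origin_class, , drop = FALSE]
  count_tab <- function(x, denom = length(x)) {
    t <- as.data.frame(table(x), stringsAsFactors = FALSE)
    names(t) <- c("level", "n")
    t$denominator <- denom
    t$percent <- pct(t$n, denom)
    t
  }
  res <- list(origin = origin_tab)
  if (!is.null(sel$variant_type)) {
    res$variant_type <- count_tab(sel$variant_type)
    snv <- sel[sel$variant_type == "SNV", , drop = FALSE]
    res$substitution_class <- count_tab(snv$substitution_class, nrow(snv))
  }
  if (!is.null(sel$effect)) {
    coding_eff <- c("synonymous", "missense", "nonsense", "frameshift",
                    "inframe_indel", "stop_region")
    sel$coding <- ifelse(sel$effect %in% coding_eff, "coding", "non_coding")
    res$coding <- count_tab(sel$coding)
    res$effect <- count_tab(sel$effect)
    nonsyn <- sel$effect %in% setdiff(coding_eff, "synonymous")
    res$non_synonymous <- data.frame(
      n = sum(nonsyn), denominator = sum(sel$coding == "coding"),
      percent = pct(sum(nonsyn), max(1L, sum(sel$coding == "coding"))))
  }
  if (!is.null(sel$tumor_ploidy)) {
    res$tumor_ploidy <- count_tab(as.character(sel$tumor_ploidy))
  }

  pos_patients <- unique(v$patient_id[v$origin == "somatic"])
  res$positive_tumors <- data.frame(
    n_positive = length(pos_patients), n_patients = n_patients,
    percent = pct(length(pos_patients), n_patients))
  res
}

#' Somatic mutation sharing across tumor subtypes
#'
#' A mutation is a distinct (position, ref, alt) key. Patients without a
#' subtype label are excluded (their count is reported). Returns per-subtype
#' totals, exclusive counts, per-subtype mutation rate over the whole genome
#' (length 16,569 bp), and the Venn partition over subtype combinations.
#'
#' @param cohort a `mito_cohort` with a `subtype` metadata column
#' @return list: `per_subtype` (subtype, n_mutations, n_exclusive,
#'   rate_per_kb), `venn` (combination, n), `n_unassigned_patients`
#' @export
subtype_sharing <- function(cohort) {
  v <- cohort$variants
  som <- v[v$origin == "somatic", , drop = FALSE]
  meta <- cohort$patients
  som$subtype <- meta$subtype[match(som$patient_id, meta$patient_id)]
  unassigned <- sum(is.na(som$subtype))
  som <- som[!is.na(som$subtype), , drop = FALSE]

  key <- variant_id(som)
  sets <- split(som$subtype, key)
  combos <- vapply(sets, function(s) paste(sort(unique(s)), collapse = "+"), "")
  venn <- as.data.frame(table(combination = combos), stringsAsFactors = FALSE)
  names(venn)[2] <- "n"

  subtypes <- sort(unique(som$subtype))
  per <- do.call(rbind, lapply(subtypes, function(st) {
    in_st <- vapply(sets, function(s) st %in% s, logical(1))
    excl <- vapply(sets, function(s) all(s == st), logical(1))
    data.frame(subtype = st, n_mutations = sum(in_st),
               n_exclusive = sum(excl),
               rate_per_kb = rate_per_kb(sum(in_st), MT_GENOME_LENGTH),
               stringsAsFactors = FALSE)
  }))
  list(per_subtype = per, venn = venn,
       n_unassigned_patients = unassigned)
}

#' Association test for a contingency table
#'
#' Fisher's exact test when any expected cell count is below 5 in a 2x2
#' table; larger sparse tables fall back to chi-square with a warning;
#' otherwise Pearson chi-square without continuity correction. Two-sided.
#'
#' @param tab matrix (or table) of non-negative integer counts
#' @return list: statistic (NA for Fisher), p_value, test_used
#' @examples
#' association_test(matrix(c(5, 0, 0, 5), 2))  # Fisher, p ~ 0.0079
#' @export
association_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sparse <- any(expected < 5)
  if (sparse && all(dim(tab) == 2L)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                test_used = "fisher"))
  }
  if (sparse) {
    warning("expected counts < 5 in a table larger than 2x2; ",
            "using chi-square", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       test_used = "chi_square")
}

#' Unsupervised clustering of patient mutation profiles
#'
#' Builds the binary patient x somatic-mutation presence matrix (patients
#' sorted by id for a deterministic tie-break), computes Jaccard distances
#' and average-linkage hierarchical clustering.
#'
#' @param cohort a `mito_cohort`
#' @return list: `hclust` (an [stats::hclust] object), `leaf_order`
#'   (patient ids in dendrogram order), `matrix` (the presence matrix)
#' @export
cluster_profiles <- function(cohort) {
  v <- cohort$variants
  som <- v[v$origin == "somatic", , drop = FALSE]
  ids <- sort(unique(som$patient_id))
  if (length(ids) < 2L) {
    stop("clustering needs >= 2 patients with >= 1 somatic mutation",
         call. = FALSE)
  }
  keys <- sort(unique(variant_id(som)))
  m <- matrix(0L, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  m[cbind(som$patient_id, variant_id(som))] <- 1L
  d <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, leaf_order = ids[hc$order], matrix = m)
}
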