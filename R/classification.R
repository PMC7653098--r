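#' MAF-threshold variant classification
#'
#' Implements the matched-pair classification rules: a somatic mutation has
#' MAF < 0.001 in blood and > 0.01 in tumor; a germline variant has blood
#' MAF > 0.01 in at least one patient (and is then germline for every
#' carrier, regardless of its tumor MAF); records with blood MAF between
#' 0.001 and 0.01 and tumor MAF > 0.01 are probable mutations. Heteroplasmy
#' is a MAF in \[0.01, 0.95); homoplasmy is a MAF >= 0.95.
#'
#' @name variant_classification
NULL

#' Classification thresholds
#'
#' @param somatic_normal_max blood MAF strictly below this is compatible with
#'   somatic origin (default 0.001)
#' @param somatic_tumor_min tumor MAF strictly above this is required for a
#'   somatic or probable-mutation call (default 0.01)
#' @param germline_blood_min blood MAF strictly above this defines germline
#'   evidence (default 0.01)
#' @param het_low detection threshold; MAF at or above it is heteroplasmic
#'   (default 0.01)
#' @param hom_min MAF at or above it is homoplasmic (default 0.95; exactly
#'   0.95 is classified homoplasmic)
#' @return a validated list of class `classification_config`
#' @export
classification_config <- function(somatic_normal_max = 0.001,
                                  somatic_tumor_min = 0.01,
                                  germline_blood_min = 0.01,
                                  het_low = 0.01,
                                  hom_min = 0.95) {
  cfg <- list(somatic_normal_max = somatic_normal_max,
              somatic_tumor_min = somatic_tumor_min,
              germline_blood_min = germline_blood_min,
              het_low = het_low, hom_min = hom_min)
  if (!(somatic_normal_max > 0 && somatic_normal_max < somatic_tumor_min)) {
    stop("require 0 < somatic_normal_max < somatic_tumor_min", call. = FALSE)
  }
  if (!(het_low < hom_min)) stop("require het_low < hom_min", call. = FALSE)
  structure(cfg, class = "classification_config")
}

ORIGIN_LEVELS <- c("germline", "somatic", "probable_mutation", "absent")
PLOIDY_LEVELS <- c("undetected", "heteroplasmic", "homoplasmic")

check_maf <- function(maf, what = "MAF") {
  if (any(is.na(maf)) || any(maf < 0 | maf > 1)) {
    stop(what, " outside [0, 1]", call. = FALSE)
  }
  maf
}

#' Classify ploidy status from one tissue's MAF
#'
#' Step function: MAF >= `hom_min` is homoplasmic, MAF in
#' \[`het_low`, `hom_min`) heteroplasmic, below `het_low` undetected.
#'
#' @param maf numeric vector of MAFs in \[0, 1\]
#' @param cfg a [classification_config()]
#' @return factor with levels undetected, heteroplasmic, homoplasmic
#' @export
classify_ploidy <- function(maf, cfg = classification_config()) {
  check_maf(maf)
  out <- ifelse(maf >= cfg$hom_min, "homoplasmic",
                ifelse(maf >= cfg$het_low, "heteroplasmic", "undetected"))
  factor(out, levels = PLOIDY_LEVELS)
}

#' Classify variant origin across a cohort
#'
#' Adds `origin`, `blood_ploidy` and `tumor_ploidy` columns to a paired
#' variant table. Germline evidence (blood MAF > `germline_blood_min` in any
#' patient) propagates across the cohort: a germline-evidenced variant is
#' classed germline for every carrier and is ineligible to be called somatic
#' in other patients. Otherwise, with tumor MAF > `somatic_tumor_min`, blood
#' MAF < `somatic_normal_max` gives somatic and blood MAF in
#' \[`somatic_normal_max`, `germline_blood_min`\] gives probable_mutation
#' (blood MAF of exactly `somatic_normal_max` is probable, the somatic rule
#' being strict). Records detected in neither tissue are absent.
#'
#' @param records paired variant data.frame (see [read_paired_tsv()])
#' @param cfg a [classification_config()]
#' @return `records` with `origin` (factor: germline, somatic,
#'   probable_mutation, absent), `blood_ploidy`, `tumor_ploidy` columns
#' @export
classify_origin <- function(records, cfg = classification_config()) {
  check_maf(records$blood_maf, "blood MAF")
  check_maf(records$tumor_maf, "tumor MAF")

  key <- variant_id(records)
  germ_evidence <- unique(key[records$blood_maf > cfg$germline_blood_min])

  origin <- rep("absent", nrow(records))
  is_germ <- key %in% germ_evidence
  tumor_pos <- records$tumor_maf > cfg$somatic_tumor_min
  origin[is_germ] <- "germline"
  origin[!is_germ & tumor_pos &
           records$blood_maf < cfg$somatic_normal_max] <- "somatic"
  origin[!is_germ & tumor_pos &
           records$blood_maf >= cfg$somatic_normal_max &
           records$blood_maf <= cfg$germline_blood_min] <- "probable_mutation"

  records$origin <- factor(origin, levels = ORIGIN_LEVELS)
  records$blood_ploidy <- classify_ploidy(records$blood_maf, cfg)
  records$tumor_ploidy <- classify_ploidy(records$tumor_maf, cfg)
  records
}

# canonical "position:ref>alt" variant identity string
variant_id <- function(records) {
  paste0(records$position, ":", records$ref, ">", records$alt)
}

#' Blood-to-tumor heteroplasmy shift analysis
#'
#' For each germline variant, computes the per-carrier MAF delta
#' (tumor - blood), a two-sided Mann-Whitney U test comparing the blood and
#' tumor MAF distributions across carriers, and the number of carriers whose
#' tumor MAF reaches homoplasmy while the blood MAF is heteroplasmic. The U
#' statistic is the number of (tumor, blood) pairs in which the tumor value
#' ranks higher (ties counted 1/2). Exact enumeration is used for n <= 8
#' without ties; otherwise the normal approximation with tie correction.
#'
#' @param records classified variant data.frame (from [classify_origin()])
#' @param variant optional "position:ref>alt" string (or a one-row data.frame
#'   with position/ref/alt) restricting the analysis to one variant
#' @param cfg a [classification_config()]
#' @return data.frame with one row per variant: position, ref, alt, n_pairs,
#'   mean_delta, statistic (U), p_value, n_shift_to_homoplasmy, and a `delta`
#'   list column of per-carrier deltas. Zero-carrier requests return a
#'   zero-row data.frame.
#' @export
shift_analysis <- function(records, variant = NULL,
                           cfg = classification_config()) {
  stopifnot(!is.null(records$origin))
  germ <- records[records$origin == "germline", , drop = FALSE]
  if (!is.null(variant)) {
    if (is.data.frame(variant)) variant <- variant_id(variant)
    germ <- germ[variant_id(germ) %in% variant, , drop = FALSE]
  }
  if (nrow(germ) == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), n_pairs = integer(),
                      mean_delta = numeric(), statistic = numeric(),
                      p_value = numeric(), n_shift_to_homoplasmy = integer()))
  }
  out <- lapply(split(germ, variant_id(germ)), function(g) {
    delta <- g$tumor_maf - g$blood_maf
    n <- nrow(g)
    exact <- n <= 8 && !anyDuplicated(c(g$tumor_maf, g$blood_maf))
    wt <- suppressWarnings(
      stats::wilcox.test(g$tumor_maf, g$blood_maf, exact = exact,
                         correct = !exact))
    # fully tied samples have zero rank variance; the null is then untestable
    # and the two distributions are identical, so report p = 1
    if (is.nan(wt$p.value)) wt$p.value <- 1
    shift <- sum(g$tumor_maf >= cfg$hom_min & g$blood_maf < cfg$hom_min &
                   g$blood_maf >= cfg$het_low)
    d <- data.frame(position = g$position[1], ref = g$ref[1], alt = g$alt[1],
                    n_pairs = n, mean_delta = mean(delta),
                    statistic = unname(wt$statistic), p_value = wt$p.value,
                    n_shift_to_homoplasmy = shift, stringsAsFactors = FALSE)
    d$delta <- list(delta)
    d
  })
  out <- do.call(rbind, out)
  out <- out[order(out$position, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Per-variant carrier counts and singleton flags
#'
#' Counts the patients carrying each (variant, origin class) combination
#' among detected records (origin not absent). A singleton is carried by
#' exactly one patient; cohort frequency is carriers / `n_patients`.
#'
#' @param records classified variant data.frame
#' @param n_patients cohort size used as the frequency denominator (default:
#'   number of distinct patient ids in `records`)
#' @return data.frame: position, ref, alt, origin, carriers, singleton,
#'   frequency
#' @export
recurrence <- function(records,
                       n_patients = length(unique(records$patient_id))) {
  stopifnot(!is.null(records$origin))
  det <- records[records$origin != "absent", , drop = FALSE]
  if (nrow(det) == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), origin = character(),
                      carriers = integer(), singleton = logical(),
                      frequency = numeric()))
  }
  agg <- stats::aggregate(
    list(carriers = det$patient_id),
    by = list(position = det$position, ref = det$ref, alt = det$alt,
              origin = as.character(det$origin)),
    FUN = function(x) length(unique(x)))
  agg$singleton <- agg$carriers == 1L
  agg$frequency <- agg$carriers / n_patients
  agg <- agg[order(agg$position, agg$ref, agg$alt, agg$origin), ]
  rownames(agg) <- NULL
  agg
}
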