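#' Synthetic matched blood-tumor cohort generator
#'
#' Generates matched-pair variant observations with recorded ground truth so
#' the whole pipeline is testable without external data. Per patient: a
#' haplogroup backbone of panel markers plus random germline variants with a
#' homoplasmic / low-heteroplasmy blood MAF mixture, a tumor shift model
#' under which a fraction of heteroplasmic germline variants drifts toward
#' homoplasmy in the tumor, and somatic mutations absent from blood with
#' tumor MAFs spanning 1-100%. Observed read counts are beta-binomial draws
#' at per-site depths of 300-6000x.
#'
#' @name synthetic_cohort
NULL

#' Default simulation parameters
#'
#' Defaults emulate the study conditions: 92 patients; blood variant counts
#' ~ Normal(37, 9) truncated to 16..75 (tumor totals then emerge as germline
#' + somatic, ~ 42 on average); 26.1% of tumors somatic-negative, positives
#' carrying a truncated-geometric 1..17 mutations (cohort mean ~2); 21.4% of
#' somatic tumor MAFs homoplasmic; somatic transition fraction 0.84; subtype
#' frequencies LA .633 / LB .244 / TN .067 / H2 .056; seven-haplogroup
#' backbone frequencies as observed in the study population. Free modeling
#' choices (Beta shapes, dropout, overdispersion rho = 0.002) are documented
#' in the package vignette.
#'
#' @param ... overrides of the defaults listed above
#' @return a validated list of class `simulation_params`
#' @export
simulation_params <- function(...) {
  p <- list(
    n_patients = 92L,
    depth_min = 300L, depth_max = 6000L,
    germline_mean = 37, germline_sd = 9, germline_min = 16L, germline_max = 75L,
    somatic_zero_prob = 0.261,
    somatic_mean_positive = 2.7, somatic_max = 17L,
    germline_hom_prob = 0.55,
    blood_het_shape = c(0.8, 25), blood_het_range = c(0.01, 0.199),
    shift_prob = 0.405, shift_shape = c(8, 2),
    hom_shape = c(60, 1),
    somatic_hom_prob = 0.214,
    somatic_het_shape = c(1.3, 3.5), somatic_het_range = c(0.011, 0.949),
    somatic_ti_prob = 0.84, germline_ti_prob = 0.65,
    somatic_indel_prob = 0.02, germline_indel_prob = 0.03,
    marker_dropout = 0.05,
    subtype_probs = c(LA = 0.633, LB = 0.244, TN = 0.067, H2 = 0.056),
    unassigned_prob = 0.022,
    haplogroup_freqs = c(A = 0.446, B = 0.228, C = 0.119, D = 0.120,
                         L = 0.054, H = 0.022, J = 0.011),
    rho = 0.002,
    log_hr = 0, baseline_rate = log(2) / 150, censor_range = c(30, 124),
    age_mean = 53.8, age_sd = 11.5, age_range = c(33, 92))
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  probs <- c(p$somatic_zero_prob, p$germline_hom_prob, p$shift_prob,
             p$somatic_hom_prob, p$somatic_ti_prob, p$germline_ti_prob,
             p$somatic_indel_prob, p$germline_indel_prob, p$marker_dropout,
             p$unassigned_prob, p$subtype_probs, p$haplogroup_freqs)
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameter outside [0, 1]", call. = FALSE)
  }
  if (p$rho < 0) stop("rho must be >= 0", call. = FALSE)
  structure(p, class = "simulation_params")
}

#' Beta-binomial read-count draw
#'
#' Draws alt-supporting read counts at the given depth around a true MAF
#' with overdispersion `rho` (the intraclass correlation of the underlying
#' beta); `rho = 0` degenerates to a binomial draw. True MAFs of exactly 0
#' or 1 are returned noise-free.
#'
#' @param true_maf numeric vector in \[0, 1\]
#' @param depth integer vector of read depths (>= 1)
#' @param rho overdispersion in \[0, 1)
#' @return integer vector of alt read counts
#' @export
generate_read_counts <- function(true_maf, depth, rho = 0.002) {
  if (rho < 0) stop("rho must be >= 0", call. = FALSE)
  if (any(true_maf < 0 | true_maf > 1)) stop("true_maf outside [0, 1]",
                                             call. = FALSE)
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  n <- max(length(true_maf), length(depth))
  true_maf <- rep_len(true_maf, n); depth <- rep_len(depth, n)
  p <- true_maf
  mid <- true_maf > 0 & true_maf < 1
  if (rho > 0 && any(mid)) {
    a <- true_maf[mid] * (1 - rho) / rho
    b <- (1 - true_maf[mid]) * (1 - rho) / rho
    p[mid] <- stats::rbeta(sum(mid), a, b)
  }
  out <- integer(n)
  out[mid] <- stats::rbinom(sum(mid), depth[mid], p[mid])
  out[true_maf == 1] <- depth[true_maf == 1]
  out
}

# truncated helpers (quantile-based, deterministic under the RNG stream)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}
rtrunc_beta <- function(n, shape, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape[1], shape[2]),
                    stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# draw alt alleles (and possibly turn SNVs into 1-bp indels) for positions
draw_alleles <- function(pos, map, ti_prob, indel_prob) {
  ref <- ref_base(map, pos)
  alt <- character(length(pos))
  is_ti <- stats::runif(length(pos)) < ti_prob
  alt[is_ti] <- TRANSITION[ref[is_ti]]
  for (i in which(!is_ti)) {
    tv <- setdiff(c("A", "C", "G", "T"), c(ref[i], TRANSITION[[ref[i]]]))
    alt[i] <- sample(tv, 1L)
  }
  out <- data.frame(position = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  indel <- stats::runif(length(pos)) < indel_prob & pos < map$genome_length
  for (i in which(indel)) {
    if (stats::runif(1) < 0.5) {
      out$alt[i] <- paste0(out$ref[i], sample(c("A", "C", "G", "T"), 1L))
    } else {
      out$ref[i] <- paste0(out$ref[i], ref_base(map, pos[i] + 1L))
      out$alt[i] <- substr(out$ref[i], 1L, 1L)
    }
  }
  out
}

#' Generate a synthetic matched-pair cohort with ground truth
#'
#' @param params a [simulation_params()] object
#' @param seed integer seed; the full output is reproducible from it
#' @param map a `MitoGeneMap` with sequence (default: bundled)
#' @param panel haplogroup marker panel (default: bundled)
#' @param annotate_truth add the planted `effect` column to the truth table
#'   (consumes no randomness; skip for speed when effects are not needed)
#' @return list of class `mito_sim`: `records` (paired variant observations,
#'   as [read_paired_tsv()] returns), `patients` (metadata: subtype, age,
#'   stage covariates, follow-up and vital status), `truth` (per-record true
#'   origin class, true MAFs, planted effect label, backbone haplogroup,
#'   plus per-patient true burden)
#' @examples
#' sim <- generate_cohort(simulation_params(n_patients = 4), seed = 1)
#' head(sim$truth)
#' @export
generate_cohort <- function(params = simulation_params(), seed,
                            map = load_gene_map(),
                            panel = load_haplogroup_panel(),
                            annotate_truth = TRUE) {
  stopifnot(inherits(params, "simulation_params"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(seed)
  p <- params
  n <- p$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  hg_freq <- p$haplogroup_freqs / sum(p$haplogroup_freqs)
  hgs <- sample(names(hg_freq), n, replace = TRUE, prob = hg_freq)

  ## phase 1 -- germline per patient: haplogroup backbone markers (with
  ## dropout) + positions drawn uniformly over the genome
  germ_list <- vector("list", n)
  for (i in seq_len(n)) {
    mk <- panel[panel$haplogroup == hgs[i], , drop = FALSE]
    keep <- stats::runif(nrow(mk)) >= p$marker_dropout
    mk <- mk[keep, c("position", "ref", "alt")]
    n_germ <- round(rtrunc_norm(1, p$germline_mean, p$germline_sd,
                                p$germline_min, p$germline_max))
    n_extra <- max(0L, n_germ - nrow(mk))
    pos_pool <- setdiff(seq_len(map$genome_length), mk$position)
    extra_pos <- sort(sample(pos_pool, n_extra))
    extra <- draw_alleles(extra_pos, map, p$germline_ti_prob,
                          p$germline_indel_prob)
    germ <- rbind(mk, extra)

    n_g <- nrow(germ)
    is_marker <- c(rep(TRUE, nrow(mk)), rep(FALSE, nrow(extra)))
    hom <- is_marker | stats::runif(n_g) < p$germline_hom_prob
    blood_maf <- numeric(n_g)
    blood_maf[hom] <- rtrunc_beta(sum(hom), p$hom_shape, 0.95, 1)
    blood_maf[!hom] <- rtrunc_beta(sum(!hom), p$blood_het_shape,
                                   p$blood_het_range[1], p$blood_het_range[2])
    tumor_maf <- blood_maf
    tumor_maf[hom] <- rtrunc_beta(sum(hom), p$hom_shape, 0.95, 1)
    shifted <- !hom & stats::runif(n_g) < p$shift_prob
    tumor_maf[shifted] <- stats::rbeta(sum(shifted), p$shift_shape[1],
                                       p$shift_shape[2])
    germ$true_blood_maf <- blood_maf
    germ$true_tumor_maf <- tumor_maf
    germ_list[[i]] <- germ
  }
  # any key carried as germline by >= 1 patient would be classed germline
  # cohort-wide, so planted somatic truth must avoid these keys
  germ_keys <- unique(unlist(lapply(
    germ_list, function(g) paste0(g$position, ":", g$ref, ">", g$alt))))

  ## phase 2 -- somatic per patient: absent from blood, tumor MAF mixture
  rec_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    germ <- germ_list[[i]]
    n_g <- nrow(germ)
    n_som <- if (stats::runif(1) < p$somatic_zero_prob) 0L else
      min(p$somatic_max, stats::rgeom(1, 1 / p$somatic_mean_positive) + 1L)
    som <- NULL
    if (n_som > 0L) {
      pool <- setdiff(seq_len(map$genome_length), germ$position)
      som <- draw_alleles(sort(sample(pool, n_som)), map,
                          p$somatic_ti_prob, p$somatic_indel_prob)
      clash <- paste0(som$position, ":", som$ref, ">", som$alt) %in% germ_keys
      for (tries in 1:20) {
        if (!any(clash)) break
        pool2 <- setdiff(pool, som$position)
        redraw <- draw_alleles(sample(pool2, sum(clash)), map,
                               p$somatic_ti_prob, p$somatic_indel_prob)
        som[clash, ] <- redraw
        clash <- paste0(som$position, ":", som$ref, ">", som$alt) %in% germ_keys
      }
      som <- som[!clash, , drop = FALSE]
      n_som <- nrow(som)
      s_hom <- stats::runif(n_som) < p$somatic_hom_prob
      s_maf <- numeric(n_som)
      s_maf[s_hom] <- rtrunc_beta(sum(s_hom), p$hom_shape, 0.95, 1)
      s_maf[!s_hom] <- rtrunc_beta(sum(!s_hom), p$somatic_het_shape,
                                   p$somatic_het_range[1],
                                   p$somatic_het_range[2])
    }

    gcols <- c("position", "ref", "alt")
    all_var <- rbind(germ[, gcols], if (!is.null(som)) som[, gcols])
    true_class <- c(rep("germline", n_g), rep("somatic", n_som))
    true_blood <- c(germ$true_blood_maf, rep(0, n_som))
    true_tumor <- c(germ$true_tumor_maf, if (n_som > 0) s_maf)

    m <- nrow(all_var)
    bd <- sample(p$depth_min:p$depth_max, m, replace = TRUE)
    td <- sample(p$depth_min:p$depth_max, m, replace = TRUE)
    rec_list[[i]] <- data.frame(
      patient_id = ids[i], position = all_var$position, ref = all_var$ref,
      alt = all_var$alt,
      blood_alt = generate_read_counts(true_blood, bd, p$rho),
      blood_depth = bd,
      tumor_alt = generate_read_counts(true_tumor, td, p$rho),
      tumor_depth = td, stringsAsFactors = FALSE)
    truth_list[[i]] <- data.frame(
      patient_id = ids[i], position = all_var$position, ref = all_var$ref,
      alt = all_var$alt, true_class = true_class,
      true_blood_maf = true_blood, true_tumor_maf = true_tumor,
      haplogroup = hgs[i], stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec_list)
  truth <- do.call(rbind, truth_list)
  records$blood_maf <- records$blood_alt / records$blood_depth
  records$tumor_maf <- records$tumor_alt / records$tumor_depth

  ## planted consequence labels, derived once from the gene map
  if (annotate_truth) {
    keys <- unique(truth[, c("position", "ref", "alt")])
    ann <- annotate_cohort(keys, map)
    truth <- merge(truth, ann[, c("position", "ref", "alt", "effect")],
                   by = c("position", "ref", "alt"), sort = FALSE)
  } else {
    truth$effect <- NA_character_
  }
  truth <- truth[order(truth$patient_id, truth$position, truth$ref,
                       truth$alt), ]
  ord <- c("patient_id", "position", "ref", "alt", "true_class",
           "true_blood_maf", "true_tumor_maf", "effect", "haplogroup")
  truth <- truth[, ord]
  rownames(truth) <- NULL

  ## patient metadata
  subtype <- sample(names(p$subtype_probs), n, replace = TRUE,
                    prob = p$subtype_probs)
  subtype[stats::runif(n) < p$unassigned_prob] <- NA
  hr_status <- ifelse(is.na(subtype), sample(c("positive", "negative"), n,
                                             replace = TRUE),
                      ifelse(subtype %in% c("LA", "LB"), "positive",
                             "negative"))
  burden <- as.integer(table(factor(truth$patient_id[truth$true_class ==
                                                       "somatic"],
                                    levels = ids)))
  surv <- generate_survival(burden > 2, p$log_hr,
                            baseline_rate = p$baseline_rate,
                            censor_range = p$censor_range)
  patients <- data.frame(
    patient_id = ids,
    age = round(rtrunc_norm(n, p$age_mean, p$age_sd,
                            p$age_range[1], p$age_range[2])),
    subtype = subtype,
    hr_status = hr_status,
    tumor_stage = sample(c("T1", "T2", "T3"), n, replace = TRUE,
                         prob = c(0.3, 0.5, 0.2)),
    clinical_stage = sample(c("I", "II", "III"), n, replace = TRUE,
                            prob = c(0.25, 0.5, 0.25)),
    true_burden = burden,
    follow_up_months = surv$time,
    vital_status = surv$event,
    haplogroup = hgs,
    stringsAsFactors = FALSE)

  structure(list(records = records, patients = patients, truth = truth,
                 params = p, seed = seed), class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("mito_sim:", nrow(x$patients), "patients,", nrow(x$records),
      "paired variant records (seed", x$seed, ")\n")
  print(table(true_class = x$truth$true_class))
  invisible(x)
}

#' Generate survival outcomes for burden groups
#'
#' Exponential event times with the high-burden hazard scaled by
#' `exp(log_hr)`; administrative censoring uniform over `censor_range`
#' months.
#'
#' @param high_burden logical vector (TRUE = high-burden group)
#' @param log_hr log hazard ratio of the high-burden group
#' @param baseline_rate exponential baseline hazard (events per month)
#' @param censor_range censoring window in months, default c(30, 124)
#' @return data.frame: time (months), event (1 = death, 0 = censored),
#'   group
#' @export
generate_survival <- function(high_burden, log_hr = 0,
                              baseline_rate = log(2) / 150,
                              censor_range = c(30, 124)) {
  n <- length(high_burden)
  rate <- baseline_rate * exp(log_hr * as.numeric(high_burden))
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, censor_range[1], censor_range[2])
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = factor(ifelse(high_burden, "high", "low"),
                            levels = c("low", "high")))
}

#' Run classification on a simulation and compare with truth
#'
#' Convenience wrapper: classifies the simulated records and joins the truth
#' labels. Records whose true MAFs lie at least `margin` times away from
#' every classification threshold (on both sides) are flagged `clear`; the
#' origin-class recovery rate among clear records is the headline metric.
#'
#' @param sim a `mito_sim`
#' @param cfg a [classification_config()]
#' @param margin multiplicative distance from thresholds defining a clear
#'   record (default 2)
#' @return list: `merged` (records + truth + clear flag), `recovery_clear`
#'   (fraction of clear records recovering their true class), `recovery_all`
#' @export
classification_recovery <- function(sim, cfg = classification_config(),
                                    margin = 2) {
  cls <- classify_origin(sim$records, cfg)
  m <- merge(cls, sim$truth,
             by = c("patient_id", "position", "ref", "alt"), sort = FALSE)
  away <- function(maf, thr) maf <= thr / margin | maf >= thr * margin
  thrs <- c(cfg$somatic_normal_max, cfg$somatic_tumor_min,
            cfg$germline_blood_min)
  clear_one <- function(maf) Reduce(`&`, lapply(thrs, function(t) away(maf, t)))
  m$clear <- clear_one(m$true_blood_maf) & clear_one(m$true_tumor_maf)
  m$recovered <- as.character(m$origin) == m$true_class
  list(merged = m,
       recovery_clear = mean(m$recovered[m$clear]),
       recovery_all = mean(m$recovered))
}
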