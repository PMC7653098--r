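#' Survival by mitochondrial mutational burden
#'
#' Stratifies patients by somatic mtDNA mutation count and estimates overall
#' survival differences: Kaplan-Meier product-limit curves, log-rank test,
#' and a Cox proportional-hazards hazard ratio adjusted for covariates.
#' Model fitting is delegated to the survival package (Efron tie handling).
#'
#' @name survival_analysis
NULL

#' Stratify patients by somatic mutational burden
#'
#' Under `rule = "any"` patients split into negative (0 somatic mutations)
#' vs positive. Under `rule = "mean"` the threshold is the cohort mean
#' burden rounded to the nearest integer; burden at or below it is `low`,
#' above it `high`. Patients with missing survival fields are excluded with
#' a message.
#'
#' @param cohort a `mito_cohort`; metadata needs `follow_up_months` and
#'   `vital_status` (1 = death, 0 = censored)
#' @param rule "any" or "mean"
#' @return data.frame: patient_id, time, event, burden, group, plus any
#'   metadata covariate columns; the mean-split threshold is attached as
#'   attribute `threshold`
#' @export
stratify_burden <- function(cohort, rule = c("any", "mean")) {
  rule <- match.arg(rule)
  v <- cohort$variants
  meta <- cohort$patients
  som <- v[v$origin == "somatic", , drop = FALSE]
  burden <- table(factor(som$patient_id, levels = meta$patient_id))
  out <- meta
  out$burden <- as.integer(burden[meta$patient_id])
  out$time <- meta$follow_up_months
  out$event <- meta$vital_status

  drop <- is.na(out$time) | is.na(out$event) | out$time <= 0
  if (any(drop)) {
    message(sum(drop), " patient(s) without usable survival data excluded")
    out <- out[!drop, , drop = FALSE]
  }
  if (rule == "any") {
    threshold <- 0L
    out$group <- factor(ifelse(out$burden > 0, "positive", "negative"),
                        levels = c("negative", "positive"))
  } else {
    threshold <- as.integer(floor(mean(out$burden) + 0.5))
    out$group <- factor(ifelse(out$burden > threshold, "high", "low"),
                        levels = c("low", "high"))
  }
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator; censored subjects leave the risk set without an
#' event step. An all-censored group yields a flat curve at 1.
#'
#' @param records data.frame with `time`, `event` (1 = death, 0 = censored)
#'   and optionally `group`
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv
#' @export
km_curve <- function(records) {
  if (is.null(records$group)) records$group <- factor("all")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test between burden groups
#'
#' @param records data.frame with time, event, group
#' @return list: chisq, df, p_value
#' @export
logrank_test <- function(records) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratio for the burden group
#'
#' Partial-likelihood fit with Efron tie handling, adjusted for the given
#' covariates; reports the hazard ratio of the second group level with a
#' Wald 95% confidence interval. Non-estimable settings (a single group, no
#' events) return `NA` estimates with a reason.
#'
#' @param records data.frame from [stratify_burden()]
#' @param covariates character vector of adjustment columns present in
#'   `records` (e.g. age, tumor_stage, clinical_stage, hr_status)
#' @return list: hr, ci_lower, ci_upper, p_value, n, n_events, reason
#' @export
hazard_ratio <- function(records, covariates = character()) {
  na_out <- function(reason) list(hr = NA_real_, ci_lower = NA_real_,
                                  ci_upper = NA_real_, p_value = NA_real_,
                                  n = nrow(records),
                                  n_events = sum(records$event),
                                  reason = reason)
  if (length(unique(records$group[!is.na(records$group)])) < 2L) {
    return(na_out("single group"))
  }
  if (sum(records$event) < 1L) return(na_out("no events"))
  fml <- stats::reformulate(c("group", covariates),
                            response = "survival::Surv(time, event)")
  fit <- tryCatch(
    survival::coxph(fml, data = records, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = records, ties = "efron"))
    })
  if (is.null(fit)) return(na_out("fit failed"))
  i <- grep("^group", names(stats::coef(fit)))[1]
  beta <- stats::coef(fit)[i]
  se <- sqrt(diag(stats::vcov(fit)))[i]
  if (!is.finite(beta) || !is.finite(se)) return(na_out("non-finite estimate"))
  z <- stats::qnorm(0.975)
  list(hr = unname(exp(beta)),
       ci_lower = unname(exp(beta - z * se)),
       ci_upper = unname(exp(beta + z * se)),
       p_value = unname(2 * stats::pnorm(-abs(beta / se))),
       n = nrow(records), n_events = sum(records$event), reason = "ok")
}
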