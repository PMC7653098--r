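#' Haplogroup assignment by marker-panel scoring
#'
#' A simplified lineage caller: each candidate haplogroup is scored against
#' the blood variant profile restricted to the panel's marker universe using
#' the Kulczynski measure, `score = (n_found / n_expected +
#' n_found / (n_found + n_extra)) / 2`, where `n_extra` counts observed
#' panel markers belonging to other haplogroups. The bundled panel covers the
#' seven top-level haplogroups A, B, C, D, H, J and L with canonical
#' diagnostic markers; a fuller panel in the same TSV format
#' (haplogroup, position, ref, alt) can be supplied.
#'
#' @name haplogroup_typing
NULL

#' Load a haplogroup marker panel
#'
#' @param path panel TSV (columns haplogroup, position, ref, alt); defaults
#'   to the bundled seven-haplogroup panel
#' @return data.frame of markers
#' @export
load_haplogroup_panel <- function(path = system.file(
    "extdata", "haplogroup_panel.tsv", package = "mitopair")) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("haplogroup", "position", "ref", "alt")
  if (!all(needed %in% names(panel)) || nrow(panel) == 0L) {
    stop("malformed or empty haplogroup panel", call. = FALSE)
  }
  panel
}

#' Score one blood variant profile against a haplogroup panel
#'
#' Observed variants are restricted to the panel's marker universe before
#' scoring; lineage-defining markers are expected (near-)homoplasmic, so
#' callers should pass only high-MAF blood variants (see
#' [assign_haplogroups()]). Ties are broken lexicographically and flagged.
#'
#' @param blood_variants data.frame with position, ref, alt columns (the
#'   patient's blood variants)
#' @param panel marker panel from [load_haplogroup_panel()]
#' @return one-row data.frame: haplogroup, score, n_expected, n_found,
#'   n_extra, tie, no_call (TRUE when no panel marker is observed)
#' @export
assign_haplogroup <- function(blood_variants, panel = load_haplogroup_panel()) {
  if (nrow(panel) == 0L) stop("empty haplogroup panel", call. = FALSE)
  marker_id <- paste0(panel$position, ":", panel$ref, ">", panel$alt)
  obs <- unique(paste0(blood_variants$position, ":", blood_variants$ref,
                       ">", blood_variants$alt))
  obs <- intersect(obs, marker_id)

  groups <- sort(unique(panel$haplogroup))
  scores <- vapply(groups, function(hg) {
    expected <- marker_id[panel$haplogroup == hg]
    n_found <- length(intersect(obs, expected))
    n_extra <- length(setdiff(obs, expected))
    if (n_found + n_extra == 0L) return(c(0, length(expected), 0, 0))
    s <- 0.5 * (n_found / length(expected) + n_found / (n_found + n_extra))
    c(s, length(expected), n_found, n_extra)
  }, numeric(4))

  best <- which(scores[1, ] == max(scores[1, ]))
  data.frame(haplogroup = groups[best[1]], score = scores[1, best[1]],
             n_expected = as.integer(scores[2, best[1]]),
             n_found = as.integer(scores[3, best[1]]),
             n_extra = as.integer(scores[4, best[1]]),
             tie = length(best) > 1L,
             no_call = length(obs) == 0L,
             stringsAsFactors = FALSE)
}

#' Assign haplogroups to every patient of a cohort
#'
#' Only homoplasmic-or-high-MAF blood variants (blood MAF > `min_maf`)
#' enter scoring, since panel markers are lineage-defining.
#'
#' @param records paired (or classified) variant data.frame
#' @param panel marker panel
#' @param min_maf minimum blood MAF for a variant to be used (default 0.5)
#' @return data.frame with one row per patient: patient_id plus the
#'   [assign_haplogroup()] columns
#' @export
assign_haplogroups <- function(records, panel = load_haplogroup_panel(),
                               min_maf = 0.5) {
  use <- records[records$blood_maf > min_maf, , drop = FALSE]
  ids <- sort(unique(records$patient_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    call <- assign_haplogroup(use[use$patient_id == id, , drop = FALSE], panel)
    cbind(data.frame(patient_id = id, stringsAsFactors = FALSE), call)
  }))
  rownames(out) <- NULL
  out
}
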