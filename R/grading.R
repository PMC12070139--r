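#' @keywords internal
ATYPIA_FEATURES <- c("hypercellularity", "sheet_like_growth",
                     "prominent_nucleoli", "spotty_necrosis",
                     "small_cell_change")

#' @keywords internal
GRADE2_SUBTYPES <- c("chordoid", "clear_cell")

#' @keywords internal
GRADE2_FLOOR_SUBTYPES <- c("rhabdoid", "papillary")

#' Effective mitotic count
#'
#' Mitotic counts may be reported twice for referred cases (by the referring
#' pathologist and on local review); when they disagree the higher value is
#' used for grading.
#'
#' @param local,referred mitoses per 10 HPF (non-negative integers); either
#'   may be NA.
#' @return the maximum of the available counts, or NA if both are absent
#'   (undefined-count status).
#' @export
effective_mitotic_count <- function(local, referred = NA) {
  v <- c(local, referred)
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  if (any(v < 0)) stop("mitotic counts must be non-negative")
  max(v)
}

#' Convert a per-10-HPF mitotic count to mitoses per mm^2
#'
#' With the standard high-power field of 0.16 mm^2, the Grade 2 threshold of
#' 4 mitoses / 10 HPF equals 2.5 mitoses/mm^2 and the Grade 3 threshold of
#' 20 / 10 HPF equals 12.5 mitoses/mm^2.
#'
#' @param count_per_10hpf mitoses per 10 high-power fields.
#' @param hpf_area_mm2 area of one HPF in mm^2 (default 0.16).
#' @return mitoses per mm^2.
#' @export
mitoses_per_mm2 <- function(count_per_10hpf, hpf_area_mm2 = 0.16) {
  if (any(!is.finite(hpf_area_mm2)) || any(hpf_area_mm2 <= 0))
    stop("hpf_area_mm2 must be positive")
  count_per_10hpf / (10 * hpf_area_mm2)
}

#' Assign the CNS WHO grade of a meningioma
#'
#' Applies the 2021 CNS WHO criteria. Grade 3 if the effective mitotic count
#' is 20 or more per 10 HPF, or CDKN2A/B is homozygously deleted, or a TERT
#' promoter mutation is present. Otherwise Grade 2 if any of: mitotic count
#' 4--19, brain invasion, chordoid or clear cell subtype, or at least 3 of
#' the 5 features of cytoarchitectural atypia (hypercellularity, sheet-like
#' growth, prominent nucleoli, spotty necrosis, small cell change).
#' Rhabdoid and papillary subtypes are graded by the same criteria but floor
#' at Grade 2 (Grade 1 is not an option). Otherwise Grade 1. Samples that
#' cannot be assessed (crush/cautery artefact, small sample) are "ungraded".
#'
#' Tri-state molecular flags and unassessable brain invasion are treated as
#' absent evidence: an "unknown" never upgrades the grade, and unknown
#' molecular flags are recorded in \code{caveats}.
#'
#' For Grade 2 tumours \code{criterion_category} mirrors the four mutually
#' exclusive reporting strata: \code{brain_invasion_plus_mitoses} when both
#' fired, else \code{brain_invasion}, else \code{mitotic_count}, else
#' \code{histology_type} (subtype or atypia).
#'
#' @param features list/row with fields \code{mitoses_local},
#'   \code{mitoses_referred}, \code{brain_invasion} (yes/no/unassessable),
#'   \code{subtype}, \code{atypia_features} (character vector) and
#'   \code{gradeable} (logical).
#' @param flags list with \code{cdkn2ab_deleted} and
#'   \code{tert_promoter_mutant}, each yes/no/unknown (logical NA accepted).
#' @return list of class \code{mnr_grade}: \code{grade} ("1", "2", "3" or
#'   "ungraded"), \code{criteria_fired}, \code{criterion_category},
#'   \code{mitoses} (effective count), \code{caveats}.
#' @export
assign_grade <- function(features, flags = list(cdkn2ab_deleted = "unknown",
                                                tert_promoter_mutant = "unknown")) {
  tri <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x)) return("unknown")
    if (is.logical(x)) return(if (x) "yes" else "no")
    x <- as.character(x)
    if (!x %in% c("yes", "no", "unknown", "unassessable"))
      stop("tri-state value must be yes/no/unknown, got '", x, "'")
    x
  }
  gradeable <- !isFALSE(features$gradeable)
  m <- effective_mitotic_count(
    features$mitoses_local %||% NA,
    features$mitoses_referred %||% NA)
  if (!gradeable) {
    return(structure(list(grade = "ungraded", criteria_fired = character(0),
                          criterion_category = "none", mitoses = m,
                          caveats = character(0)), class = "mnr_grade"))
  }
  cdkn <- tri(flags$cdkn2ab_deleted)
  tert <- tri(flags$tert_promoter_mutant)
  caveats <- character(0)
  if (cdkn == "unknown") caveats <- c(caveats, "CDKN2A/B status unknown")
  if (tert == "unknown") caveats <- c(caveats, "TERT promoter status unknown")

  atyp <- features$atypia_features %||% character(0)
  bad <- setdiff(atyp, ATYPIA_FEATURES)
  if (length(bad) > 0)
    stop("unknown atypia feature(s): ", paste(bad, collapse = ", "))
  subtype <- as.character(features$subtype %||% "unspecified")
  invasion <- tri(features$brain_invasion) == "yes"

  fired <- character(0)
  # Grade 3 routes
  if (isTRUE(m >= 20)) fired <- c(fired, "mitotic_count")
  if (cdkn == "yes" || tert == "yes") fired <- c(fired, "molecular_grade3")
  if (length(fired) > 0) {
    return(structure(list(grade = "3", criteria_fired = fired,
                          criterion_category = "none", mitoses = m,
                          caveats = caveats), class = "mnr_grade"))
  }
  # Grade 2 routes
  mit2 <- isTRUE(m >= 4) && isTRUE(m <= 19)
  if (mit2) fired <- c(fired, "mitotic_count")
  if (invasion) fired <- c(fired, "brain_invasion")
  if (subtype %in% GRADE2_SUBTYPES) fired <- c(fired, "histology_subtype")
  if (length(atyp) >= 3) fired <- c(fired, "atypia_features")
  floored <- subtype %in% GRADE2_FLOOR_SUBTYPES
  if (length(fired) > 0 || floored) {
    if (length(fired) == 0) fired <- "histology_subtype"  # rhabdoid/papillary floor
    category <- if (invasion && mit2) "brain_invasion_plus_mitoses"
      else if (invasion) "brain_invasion"
      else if (mit2) "mitotic_count"
      else "histology_type"
    return(structure(list(grade = "2", criteria_fired = fired,
                          criterion_category = category, mitoses = m,
                          caveats = caveats), class = "mnr_grade"))
  }
  structure(list(grade = "1", criteria_fired = character(0),
                 criterion_category = "none", mitoses = m,
                 caveats = caveats), class = "mnr_grade")
}

#' @export
print.mnr_grade <- function(x, ...) {
  cat("CNS WHO grade:", x$grade, "\n")
  if (length(x$criteria_fired) > 0)
    cat("  criteria:", paste(x$criteria_fired, collapse = ", "), "\n")
  if (x$criterion_category != "none")
    cat("  category:", x$criterion_category, "\n")
  if (length(x$caveats) > 0)
    cat("  caveats:", paste(x$caveats, collapse = "; "), "\n")
  invisible(x)
}

#' Grade every sample of a cohort sheet
#'
#' Vectorised driver around \code{\link{assign_grade}}. The cohort sheet
#' uses the documented dialect: columns \code{sample_id},
#' \code{mitoses_local}, \code{mitoses_referred}, \code{brain_invasion},
#' \code{subtype}, five \code{atypia_*} logical columns, \code{gradeable},
#' and optionally \code{tert_promoter}. CDKN2A/B status is taken from the
#' CNV profile table when supplied, so that a molecular Grade 3 call can be
#' made from the copy-number data.
#'
#' @param sheet cohort sheet data.frame.
#' @param cnv optional CNV profile table from
#'   \code{\link{call_cnv_profiles}}, matched on \code{sample_id}.
#' @return the sheet with added columns \code{mitoses_effective},
#'   \code{grade} and \code{criterion_category}.
#' @export
assign_grades <- function(sheet, cnv = NULL) {
  cd_map <- NULL
  if (!is.null(cnv))
    cd_map <- setNames(cnv$cdkn2ab_call, cnv$sample_id)
  n <- nrow(sheet)
  grade <- character(n); category <- character(n); meff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    feats <- list(
      mitoses_local = sheet$mitoses_local[i],
      mitoses_referred = if ("mitoses_referred" %in% names(sheet))
        sheet$mitoses_referred[i] else NA,
      brain_invasion = sheet$brain_invasion[i],
      subtype = sheet$subtype[i],
      atypia_features = ATYPIA_FEATURES[unlist(
        sheet[i, paste0("atypia_", ATYPIA_FEATURES)], use.names = FALSE) %in%
          c(TRUE, "yes", 1)],
      gradeable = sheet$gradeable[i]
    )
    cd <- if (!is.null(cd_map) && sheet$sample_id[i] %in% names(cd_map)) {
      switch(cd_map[[sheet$sample_id[i]]],
             deleted = "yes", not_deleted = "no", "unknown")
    } else "unknown"
    tert <- if ("tert_promoter" %in% names(sheet))
      sheet$tert_promoter[i] else "unknown"
    g <- assign_grade(feats, list(cdkn2ab_deleted = cd,
                                  tert_promoter_mutant = tert))
    grade[i] <- g$grade
    category[i] <- g$criterion_category
    meff[i] <- g$mitoses
  }
  sheet$mitoses_effective <- meff
  sheet$grade <- grade
  sheet$criterion_category <- category
  sheet
}

`%||%` <- function(a, b) if (is.null(a)) b else a
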