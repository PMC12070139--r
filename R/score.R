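#' Score component contributed by the CNS WHO grade
#'
#' Grade 1 contributes 0 points, Grade 2 contributes 1, Grade 3 contributes
#' 2. Ungraded tumours have no model score (they are reported with CNV and
#' methylation results only).
#'
#' @param grade "1", "2", "3" (numeric accepted) or "ungraded".
#' @return integer 0/1/2, or NA for ungraded (no-score status).
#' @export
grade_component <- function(grade) {
  g <- as.character(grade)
  out <- rep(NA_integer_, length(g))
  out[g == "1"] <- 0L
  out[g == "2"] <- 1L
  out[g == "3"] <- 2L
  bad <- !(g %in% c("1", "2", "3", "ungraded")) & !is.na(g)
  if (any(bad)) stop("invalid grade: ", paste(unique(g[bad]), collapse = ", "))
  out
}

#' Score component contributed by the methylation family
#'
#' Methylation family benign contributes 0 points, intermediate 2,
#' malignant 4. The SMARCE1-altered class has no published point value; by
#' default it is scored with the benign family (configurable via
#' \code{smarce1_points}). Class "other" yields no score.
#'
#' @param mc_class one of benign / intermediate / malignant /
#'   SMARCE1_altered / other.
#' @param smarce1_points points assigned to the SMARCE1-altered class
#'   (default 0).
#' @return integer component, or NA (no-score status) for class "other".
#' @export
mf_component <- function(mc_class, smarce1_points = 0L) {
  stopifnot(smarce1_points %in% c(0L, 2L, 4L))
  m <- as.character(mc_class)
  bad <- !m %in% c("benign", "intermediate", "malignant", "SMARCE1_altered",
                   "other") & !is.na(m)
  if (any(bad))
    stop("invalid methylation class: ", paste(unique(m[bad]), collapse = ", "))
  out <- rep(NA_integer_, length(m))
  out[m == "benign"] <- 0L
  out[m == "intermediate"] <- 2L
  out[m == "malignant"] <- 4L
  out[m == "SMARCE1_altered"] <- as.integer(smarce1_points)
  out
}

#' Score component contributed by chromosome-arm losses
#'
#' Counts losses among 1p, 6q and 14q: no loss contributes 0 points, one or
#' two losses contribute 2, loss of all three arms contributes 3.
#'
#' @param lost_1p,lost_6q,lost_14q logical vectors.
#' @return integer 0/2/3 (NA where any input is NA).
#' @export
chrom_component <- function(lost_1p, lost_6q, lost_14q) {
  n <- as.integer(lost_1p) + as.integer(lost_6q) + as.integer(lost_14q)
  ifelse(is.na(n), NA_integer_, c(0L, 2L, 2L, 3L)[n + 1L])
}

#' Bin an integrated model score into a risk group
#'
#' Scores 0--2 are low risk, 3--5 intermediate risk, 6--9 high risk (of
#' early recurrence).
#'
#' @param total integer score(s) in 0..9.
#' @return factor with levels low/intermediate/high (NA preserved).
#' @export
risk_group <- function(total) {
  ok <- is.na(total) | (total >= 0 & total <= 9 & total == round(total))
  if (!all(ok)) stop("model score must be an integer in 0..9")
  cut(total, breaks = c(-0.5, 2.5, 5.5, 9.5),
      labels = c("low", "intermediate", "high"))
}

#' Attainable model scores for a grade
#'
#' Exhaustively enumerates the component grid: grade points plus the
#' methylation-family points \{0, 2, 4\} plus the chromosome points
#' \{0, 2, 3\}. For Grade 2 this reproduces the published facts that the
#' minimum score is 1 and that totals 2 and 9 are unattainable.
#'
#' @param grade "1", "2" or "3".
#' @return sorted integer vector of attainable totals.
#' @export
reachable_scores <- function(grade) {
  gc <- grade_component(grade)
  if (is.na(gc)) stop("reachable_scores requires a graded tumour")
  grid <- expand.grid(mf = c(0L, 2L, 4L), chrom = c(0L, 2L, 3L))
  sort(unique(gc + grid$mf + grid$chrom))
}

#' Compute the integrated model score
#'
#' Adds the grade, methylation-family and chromosome components and bins the
#' total into a risk group. Any undefined component (ungraded tumour,
#' unresolvable methylation class, missing CNV) propagates to an undefined
#' score.
#'
#' @inheritParams grade_component
#' @inheritParams mf_component
#' @inheritParams chrom_component
#' @return data.frame with columns \code{grade_component},
#'   \code{mf_component}, \code{chrom_component}, \code{n_arms_lost},
#'   \code{total} and \code{risk_group}.
#' @export
model_score <- function(grade, mc_class, lost_1p, lost_6q, lost_14q,
                        smarce1_points = 0L) {
  gc <- grade_component(grade)
  mf <- mf_component(mc_class, smarce1_points = smarce1_points)
  cc <- chrom_component(lost_1p, lost_6q, lost_14q)
  n_lost <- as.integer(lost_1p) + as.integer(lost_6q) + as.integer(lost_14q)
  total <- gc + mf + cc
  data.frame(grade_component = gc, mf_component = mf, chrom_component = cc,
             n_arms_lost = n_lost, total = total, risk_group = risk_group(total))
}

#' Score every sample of a graded cohort
#'
#' Joins the graded cohort sheet with the CNV profile table and computes the
#' model score for samples that are gradeable and pass the calibrated-score
#' gate. Samples failing the gate or lacking a grade keep NA scores.
#'
#' @param sheet graded cohort sheet (see \code{\link{assign_grades}}).
#' @param cnv CNV profile table (\code{\link{call_cnv_profiles}}).
#' @param cs_gate calibrated-score inclusion threshold (default 0.9,
#'   closed lower bound).
#' @param smarce1_points see \code{\link{mf_component}}.
#' @return the sheet with the CNV loss columns and score columns appended.
#' @export
score_cohort <- function(sheet, cnv, cs_gate = 0.9, smarce1_points = 0L) {
  if (any(sheet$calibrated_score < 0 | sheet$calibrated_score > 1, na.rm = TRUE))
    stop("calibrated_score outside [0, 1]")
  idx <- match(sheet$sample_id, cnv$sample_id)
  for (col in c("lost_1p", "lost_6q", "lost_14q", "lost_22q",
                "frac_1p", "frac_6q", "frac_14q", "frac_22q",
                "cdkn2ab_log2", "cdkn2ab_call"))
    sheet[[col]] <- cnv[[col]][idx]
  sc <- model_score(sheet$grade, sheet$mc_class,
                    sheet$lost_1p, sheet$lost_6q, sheet$lost_14q,
                    smarce1_points = smarce1_points)
  gated_out <- is.na(sheet$calibrated_score) | sheet$calibrated_score < cs_gate
  sc[gated_out, ] <- NA
  cbind(sheet, sc)
}
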