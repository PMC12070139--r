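#' Fraction of a chromosome arm covered by lost segments
#'
#' A segment counts as "lost" when its log2 copy-number ratio is at or below
#' \code{loss_log2} (the default -0.1 corresponds to the loss of one copy in
#' the methylation-array CNV export). The fraction is the length of the
#' union of all lost-segment overlaps with the arm, divided by the arm
#' length; overlapping segments are therefore not double counted, and a
#' segment spanning the arm boundary contributes only its overlap.
#'
#' @param segments data.frame of segments (0-based half-open; see
#'   \code{\link{read_seg}}). Segments on other chromosomes are ignored.
#' @param arm one row of an arm-definition table
#'   (\code{\link{load_arm_definitions}}).
#' @param loss_log2 calling threshold: a segment is lost iff
#'   \code{log2_ratio <= loss_log2}.
#' @return fraction in \[0, 1\].
#' @export
arm_loss_fraction <- function(segments, arm, loss_log2 = -0.1) {
  stopifnot(nrow(arm) == 1)
  arm_len <- arm$end - arm$start
  if (!is.finite(arm_len) || arm_len <= 0) stop("zero-length arm: ", arm$arm_key)
  keep <- segments$chrom == arm$chrom & segments$log2_ratio <= loss_log2
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg) == 0) return(0)
  # clip to arm, then take the union (IRanges are 1-based closed)
  s <- pmax(seg$start, arm$start)
  e <- pmin(seg$end, arm$end)
  ok <- e > s
  if (!any(ok)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[ok] + 1, end = e[ok]))
  sum(IRanges::width(ir)) / arm_len
}

#' Call arm-loss status from a loss fraction
#'
#' An arm qualifies as lost when strictly more than \code{min_fraction}
#' (default 5\%) of its length is covered by lost segments.
#'
#' @param fraction_lost fraction in \[0, 1\].
#' @param min_fraction calling cutoff (strict inequality).
#' @return logical.
#' @export
call_arm_status <- function(fraction_lost, min_fraction = 0.05) {
  if (any(!is.finite(fraction_lost)) ||
      any(fraction_lost < 0) || any(fraction_lost > 1))
    stop("fraction_lost must lie in [0, 1]")
  fraction_lost > min_fraction
}

#' Call CDKN2A/B homozygous deletion status
#'
#' The locus-level log2 value is the minimum segment log2 ratio among
#' segments overlapping the locus; a homozygous deletion is called when that
#' minimum falls below \code{deletion_log2}. When no segment overlaps the
#' locus the result is an explicit no-call (\code{NA} log2,
#' \code{call = "no-call"}), never silently "not deleted".
#'
#' @param segments data.frame of segments (0-based half-open).
#' @param locus one row of a locus-definition table
#'   (\code{\link{load_locus_definitions}}).
#' @param deletion_log2 calling threshold (strict \code{<}).
#' @return list with \code{log2} (numeric or NA), \code{deleted} (logical or
#'   NA) and \code{call} (\code{"deleted"}, \code{"not_deleted"} or
#'   \code{"no-call"}).
#' @export
call_cdkn2ab <- function(segments, locus, deletion_log2 = -0.4) {
  stopifnot(nrow(locus) == 1)
  ov <- segments$chrom == locus$chrom &
    segments$start < locus$end & segments$end > locus$start
  if (!any(ov))
    return(list(log2 = NA_real_, deleted = NA, call = "no-call"))
  m <- min(segments$log2_ratio[ov])
  deleted <- m < deletion_log2
  list(log2 = m, deleted = deleted,
       call = if (deleted) "deleted" else "not_deleted")
}

#' Build a per-sample CNV profile
#'
#' Composes \code{\link{arm_loss_fraction}}, \code{\link{call_arm_status}}
#' and \code{\link{call_cdkn2ab}} over the arms used for risk scoring
#' (1p, 6q, 14q) plus 22q, and the CDKN2A/B locus.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame of this sample's segments (0-based half-open).
#' @param arms arm-definition table containing at least 1p, 6q, 14q and 22q.
#' @param loci locus-definition table containing CDKN2A/B.
#' @param loss_log2,min_fraction,deletion_log2 calling thresholds; see the
#'   component functions.
#' @param arm_keys arms to call (default the four used in the analysis).
#' @return one-row data.frame: \code{sample_id}, per-arm \code{frac_<arm>}
#'   and \code{lost_<arm>} columns, \code{cdkn2ab_log2},
#'   \code{cdkn2ab_deleted}, \code{cdkn2ab_call}.
#' @export
build_cnv_profile <- function(sample_id, segments, arms, loci,
                              loss_log2 = -0.1, min_fraction = 0.05,
                              deletion_log2 = -0.4,
                              arm_keys = c("1p", "6q", "14q", "22q")) {
  miss <- setdiff(arm_keys, arms$arm_key)
  if (length(miss) > 0)
    stop("arm definitions missing required arm(s): ", paste(miss, collapse = ", "))
  locus <- loci[loci$name == "CDKN2A/B", , drop = FALSE]
  if (nrow(locus) != 1)
    stop("locus definitions must contain exactly one CDKN2A/B entry")
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  for (k in arm_keys) {
    arm <- arms[arms$arm_key == k, , drop = FALSE]
    fr <- arm_loss_fraction(segments, arm, loss_log2 = loss_log2)
    out[[paste0("frac_", k)]] <- fr
    out[[paste0("lost_", k)]] <- call_arm_status(fr, min_fraction = min_fraction)
  }
  cd <- call_cdkn2ab(segments, locus, deletion_log2 = deletion_log2)
  out$cdkn2ab_log2 <- cd$log2
  out$cdkn2ab_deleted <- cd$deleted
  out$cdkn2ab_call <- cd$call
  out
}

#' Call CNV profiles for a whole cohort
#'
#' @param segments data.frame of segments for many samples (must carry
#'   \code{sample_id}).
#' @param sample_ids samples to profile; defaults to those present in
#'   \code{segments}.
#' @inheritParams build_cnv_profile
#' @return data.frame with one row per sample (see
#'   \code{\link{build_cnv_profile}}).
#' @export
call_cnv_profiles <- function(segments, arms, loci, sample_ids = NULL,
                              loss_log2 = -0.1, min_fraction = 0.05,
                              deletion_log2 = -0.4) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  by_sample <- split(seq_len(nrow(segments)), segments$sample_id)
  rows <- lapply(sample_ids, function(sid) {
    idx <- by_sample[[sid]]
    seg <- if (is.null(idx)) segments[0, , drop = FALSE]
           else segments[idx, , drop = FALSE]
    build_cnv_profile(sid, seg, arms, loci, loss_log2 = loss_log2,
                      min_fraction = min_fraction,
                      deletion_log2 = deletion_log2)
  })
  do.call(rbind, rows)
}
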