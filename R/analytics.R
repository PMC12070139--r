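#' Partition a cohort by classifier calibrated score
#'
#' Methylation-classifier results are only considered robust at a calibrated
#' score of at least \code{lo} (default 0.9, closed bound); results between
#' \code{unclassified} and \code{lo} form a low-confidence band, and below
#' \code{unclassified} (default 0.3) the sample counts as unclassified. The
#' three bands are disjoint and exhaustive.
#'
#' @param records data.frame with a \code{calibrated_score} column in \[0,1\].
#' @param lo inclusion threshold (\code{cs >= lo} is included).
#' @param unclassified lower band edge (\code{cs < unclassified} is
#'   unclassified).
#' @return the input with an added factor column \code{cs_band} with levels
#'   \code{included}, \code{low_band}, \code{unclassified}.
#' @export
gate_by_calibrated_score <- function(records, lo = 0.9, unclassified = 0.3) {
  cs <- records$calibrated_score
  if (any(is.na(cs)) || any(cs < 0 | cs > 1))
    stop("calibrated scores must lie in [0, 1]")
  band <- ifelse(cs >= lo, "included",
                 ifelse(cs >= unclassified, "low_band", "unclassified"))
  records$cs_band <- factor(band, levels = c("included", "low_band",
                                             "unclassified"))
  records
}

#' Cross-tabulate a cohort
#'
#' Builds a labelled contingency table of counts with row proportions
#' rounded to 2 decimals, the shape used in the published allocation tables
#' (grading criteria by methylation class, criteria by risk group, ...).
#'
#' @param records data.frame.
#' @param row_key,col_key names of columns to tabulate.
#' @param row_levels,col_levels optional explicit level orders.
#' @return object of class \code{mnr_xtab}: list with \code{counts} (integer
#'   matrix), \code{row_props} (rounded), \code{row_totals},
#'   \code{col_totals}, \code{n}.
#' @export
crosstab <- function(records, row_key, col_key,
                     row_levels = NULL, col_levels = NULL) {
  r <- records[[row_key]]
  c_ <- records[[col_key]]
  keep <- !is.na(r) & !is.na(c_)
  r <- factor(r[keep], levels = row_levels %||% sort(unique(as.character(r[keep]))))
  c_ <- factor(c_[keep], levels = col_levels %||% sort(unique(as.character(c_[keep]))))
  counts <- unclass(table(r, c_))
  crosstab_from_counts(counts, row_key = row_key, col_key = col_key)
}

#' @rdname crosstab
#' @param counts an integer matrix of counts (with dimnames), e.g. a printed
#'   table to be re-expressed as row proportions.
#' @export
crosstab_from_counts <- function(counts, row_key = "row", col_key = "col") {
  counts <- as.matrix(counts)
  names(dimnames(counts)) <- NULL
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  row_totals <- rowSums(counts)
  props <- counts / ifelse(row_totals == 0, 1, row_totals)
  structure(list(counts = counts,
                 row_props = round(props, 2),
                 row_totals = row_totals,
                 col_totals = colSums(counts),
                 n = sum(counts),
                 row_key = row_key, col_key = col_key),
            class = "mnr_xtab")
}

#' @export
print.mnr_xtab <- function(x, ...) {
  cat("Cross-tabulation:", x$row_key, "x", x$col_key,
      " (n =", x$n, ")\n\ncounts:\n")
  print(cbind(x$counts, total = x$row_totals))
  cat("\nrow proportions:\n")
  print(x$row_props)
  invisible(x)
}

#' Expand a cross-tab back into unit records
#'
#' Inverse of \code{\link{crosstab}} up to row order: one record per counted
#' unit, used for re-aggregation checks.
#'
#' @param x an \code{mnr_xtab}.
#' @return data.frame with the two key columns.
#' @export
xtab_expand <- function(x) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  rows <- rep(rownames(x$counts)[idx[, 1]], x$counts[idx])
  cols <- rep(colnames(x$counts)[idx[, 2]], x$counts[idx])
  out <- data.frame(rows, cols, stringsAsFactors = FALSE)
  names(out) <- c(x$row_key, x$col_key)
  out
}

#' Mitotic-count stratum
#'
#' Bins a per-10-HPF mitotic count into the reporting strata 0--3, 4--7,
#' 8--11, 12--15, 16--19 and 20--30 (closed integer bins). Counts above 30
#' are assigned to the top stratum with a warning.
#'
#' @param count_per_10hpf non-negative count(s).
#' @return factor over the six strata (NA preserved).
#' @export
mitotic_stratum <- function(count_per_10hpf) {
  if (any(count_per_10hpf < 0, na.rm = TRUE))
    stop("mitotic count must be non-negative")
  if (any(count_per_10hpf > 30, na.rm = TRUE))
    warning("mitotic count above 30 assigned to the 20-30 stratum")
  labs <- c("0-3", "4-7", "8-11", "12-15", "16-19", "20-30")
  cut(pmin(count_per_10hpf, 30), breaks = c(-0.5, 3.5, 7.5, 11.5, 15.5, 19.5, 30.5),
      labels = labs)
}

#' Female-to-male ratio by a stratifying key
#'
#' Reports, per level of \code{key}, the female and male counts and the F:M
#' ratio in the "x:1" convention (female count divided by male count). A
#' stratum without males has an undefined ratio (NA, flagged).
#'
#' @param records data.frame with a \code{sex} column coded F/M.
#' @param key column name to stratify by.
#' @return data.frame with columns \code{level}, \code{n_f}, \code{n_m},
#'   \code{ratio} (NA when either count is zero: the ratio is reported as
#'   counts only), \code{label}.
#' @export
sex_ratio_by <- function(records, key) {
  k <- records[[key]]
  keep <- !is.na(k) & !is.na(records$sex)
  records <- records[keep, , drop = FALSE]
  if (!all(records$sex %in% c("F", "M")))
    stop("sex must be coded F/M")
  k <- factor(records[[key]])
  n_f <- tapply(records$sex == "F", k, sum)
  n_m <- tapply(records$sex == "M", k, sum)
  ratio <- ifelse(n_m == 0 | n_f == 0, NA_real_, n_f / n_m)
  data.frame(level = levels(k),
             n_f = as.integer(n_f), n_m = as.integer(n_m),
             ratio = as.numeric(ratio),
             label = ifelse(is.na(ratio), "undefined",
                            paste0(round(ratio, 1), ":1")),
             stringsAsFactors = FALSE)
}

#' Partition a cohort by joint 1p / 22q status
#'
#' Segregates samples into the four groups (1) 1p intact & 22q intact,
#' (2) 1p intact & 22q deleted, (3) 1p deleted & 22q intact,
#' (4) 1p deleted & 22q deleted. Samples without CNV calls are excluded and
#' counted in a remainder bucket.
#'
#' @param records data.frame with logical \code{lost_1p} and \code{lost_22q}
#'   columns.
#' @return list with \code{records} (input rows with a \code{cochrom_group}
#'   factor), \code{n_no_cnv}, and \code{by_grade} (counts per grade if a
#'   \code{grade} column is present, else NULL).
#' @export
cochromosome_groups <- function(records) {
  has_cnv <- !is.na(records$lost_1p) & !is.na(records$lost_22q)
  grp <- rep(NA_character_, nrow(records))
  grp[has_cnv] <- ifelse(records$lost_1p[has_cnv],
                         ifelse(records$lost_22q[has_cnv],
                                "1p_del_22q_del", "1p_del_22q_intact"),
                         ifelse(records$lost_22q[has_cnv],
                                "1p_intact_22q_del", "1p_intact_22q_intact"))
  lv <- c("1p_intact_22q_intact", "1p_intact_22q_del",
          "1p_del_22q_intact", "1p_del_22q_del")
  records$cochrom_group <- factor(grp, levels = lv)
  by_grade <- NULL
  if ("grade" %in% names(records))
    by_grade <- crosstab(records[has_cnv, , drop = FALSE],
                         "grade", "cochrom_group", col_levels = lv)
  list(records = records, n_no_cnv = sum(!has_cnv), by_grade = by_grade)
}

#' Correlation of mitotic count with the CDKN2A/B copy-number value
#'
#' Pearson correlation between the effective mitotic count and the
#' quantitative CDKN2A/B log2 value (the locus minimum from the CNV
#' profile). Requires at least 3 complete pairs and nonzero variance on
#' both sides; otherwise a no-result status is returned.
#'
#' @param records data.frame with \code{mitoses_effective} and
#'   \code{cdkn2ab_log2} columns.
#' @return list with \code{r} (Pearson coefficient or NA), \code{n_pairs},
#'   \code{status} ("ok", "insufficient_pairs" or "zero_variance") and
#'   \code{pairs} (the data used).
#' @export
correlate_mitoses_cdkn2ab <- function(records) {
  pairs <- data.frame(mitoses = records$mitoses_effective,
                      cdkn2ab_log2 = records$cdkn2ab_log2)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3)
    return(list(r = NA_real_, n_pairs = nrow(pairs),
                status = "insufficient_pairs", pairs = pairs))
  if (stats::sd(pairs$mitoses) == 0 || stats::sd(pairs$cdkn2ab_log2) == 0)
    return(list(r = NA_real_, n_pairs = nrow(pairs),
                status = "zero_variance", pairs = pairs))
  list(r = stats::cor(pairs$mitoses, pairs$cdkn2ab_log2),
       n_pairs = nrow(pairs), status = "ok", pairs = pairs)
}

#' Percentage with nearest-integer rounding
#'
#' Formats a count over a denominator in the reporting convention used for
#' in-text percentages (nearest integer, or one decimal with
#' \code{digits = 1}).
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals to keep (default 0).
#' @return numeric percentage on the 0--100 scale.
#' @export
pct <- function(num, den, digits = 0) {
  round(100 * num / den, digits)
}
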