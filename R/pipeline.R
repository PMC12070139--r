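MC_LEVELS <- c("benign", "intermediate", "SMARCE1_altered", "malignant")
GRADE_LEVELS <- c("1", "2", "3", "ungraded")
CATEGORY_LEVELS <- c("brain_invasion", "mitotic_count", "histology_type",
                     "brain_invasion_plus_mitoses")
RISK_LEVELS <- c("low", "intermediate", "high")

#' Default run configuration
#'
#' All analysis thresholds surfaced in one place; the published values are
#' defaults, not constants.
#'
#' @param loss_log2 segment-loss calling threshold (log2 <= loss_log2).
#' @param min_arm_fraction arm-loss cutoff (fraction > min_arm_fraction).
#' @param cdkn2ab_log2 CDKN2A/B homozygous-deletion threshold (log2 <).
#' @param cs_gate calibrated-score inclusion gate (cs >= gate).
#' @param cs_unclassified lower calibrated-score band edge.
#' @param smarce1_points model-score points for the SMARCE1-altered class.
#' @param seed RNG seed recorded in the manifest.
#' @return list of class \code{mnr_config}.
#' @export
run_config <- function(loss_log2 = -0.1, min_arm_fraction = 0.05,
                       cdkn2ab_log2 = -0.4, cs_gate = 0.9,
                       cs_unclassified = 0.3, smarce1_points = 0L,
                       seed = NULL) {
  stopifnot(loss_log2 < 0, min_arm_fraction > 0, min_arm_fraction < 1,
            cdkn2ab_log2 < 0, cs_gate > 0, cs_gate <= 1,
            cs_unclassified >= 0, cs_unclassified < cs_gate)
  structure(list(loss_log2 = loss_log2, min_arm_fraction = min_arm_fraction,
                 cdkn2ab_log2 = cdkn2ab_log2, cs_gate = cs_gate,
                 cs_unclassified = cs_unclassified,
                 smarce1_points = as.integer(smarce1_points), seed = seed),
            class = c("mnr_config", "list"))
}

#' Run the integrated risk-stratification pipeline
#'
#' Chains the analysis end to end: per-sample arm-loss and CDKN2A/B calling
#' from the segments, calibrated-score gating, CNS WHO grading, integrated
#' model scores, and the cohort-level report tables (grade and Grade 2
#' criteria by methylation class, criteria by risk group and by individual
#' score, mitotic strata by risk group, sex ratio by score, joint 1p/22q
#' groups, and the mitoses--CDKN2A/B correlation).
#'
#' @param sheet cohort sheet data.frame, or path to a CSV/TSV file.
#' @param segments segment data.frame (0-based half-open) or path to a SEG
#'   file.
#' @param arms,loci annotation tables or paths (defaults: bundled hg19-style
#'   tables).
#' @param config a \code{\link{run_config}} list.
#' @return object of class \code{mnr_run}: list with \code{samples} (the
#'   per-sample audit table: one row per sample with band, grade, criterion,
#'   CNV calls, score components, total and risk group), \code{cnv},
#'   \code{tables} (named list of \code{mnr_xtab}/data.frame reports),
#'   \code{correlation}, \code{manifest}.
#' @export
run_pipeline <- function(sheet, segments,
                         arms = load_arm_definitions(default_arm_table()),
                         loci = load_locus_definitions(default_locus_table()),
                         config = run_config()) {
  if (is.character(sheet)) sheet <- read_cohort_sheet(sheet)
  if (is.character(segments)) segments <- read_seg(segments)
  if (is.character(arms)) arms <- load_arm_definitions(arms)
  if (is.character(loci)) loci <- load_locus_definitions(loci)
  validate_cohort_sheet(sheet)

  cnv <- call_cnv_profiles(segments, arms, loci,
                           sample_ids = sheet$sample_id,
                           loss_log2 = config$loss_log2,
                           min_fraction = config$min_arm_fraction,
                           deletion_log2 = config$cdkn2ab_log2)
  sheet <- gate_by_calibrated_score(sheet, lo = config$cs_gate,
                                    unclassified = config$cs_unclassified)
  sheet <- assign_grades(sheet, cnv)
  scored <- score_cohort(sheet, cnv, cs_gate = config$cs_gate,
                         smarce1_points = config$smarce1_points)
  scored$mitotic_stratum <- mitotic_stratum(scored$mitoses_effective)

  inc <- scored[scored$cs_band == "included", , drop = FALSE]
  g2 <- inc[inc$grade == "2", , drop = FALSE]
  g2$criterion_category <- factor(g2$criterion_category,
                                  levels = CATEGORY_LEVELS)
  tables <- list(
    grade_by_mc = crosstab(inc, "grade", "mc_class",
                           row_levels = GRADE_LEVELS, col_levels = MC_LEVELS),
    criteria_by_mc = crosstab(g2, "criterion_category", "mc_class",
                              row_levels = CATEGORY_LEVELS,
                              col_levels = MC_LEVELS),
    criteria_by_risk = crosstab(g2, "criterion_category", "risk_group",
                                row_levels = CATEGORY_LEVELS,
                                col_levels = RISK_LEVELS),
    scores_by_criteria = crosstab(g2, "criterion_category", "total",
                                  row_levels = CATEGORY_LEVELS),
    strata_by_risk = crosstab(inc, "mitotic_stratum", "risk_group",
                              col_levels = RISK_LEVELS),
    sex_by_score = sex_ratio_by(inc[!is.na(inc$total), , drop = FALSE],
                                "total"),
    sex_by_grade = sex_ratio_by(inc, "grade")
  )
  cochrom <- cochromosome_groups(inc)
  tables$cochrom_by_grade <- cochrom$by_grade
  correlation <- correlate_mitoses_cdkn2ab(inc)

  manifest <- list(
    package = "meningrisk",
    version = as.character(packageVersion("meningrisk")),
    config = unclass(config),
    n_samples = nrow(scored),
    n_included = nrow(inc),
    n_low_band = sum(scored$cs_band == "low_band"),
    n_unclassified = sum(scored$cs_band == "unclassified"))

  structure(list(samples = scored, cnv = cnv, tables = tables,
                 correlation = correlation, manifest = manifest),
            class = "mnr_run")
}

#' @export
print.mnr_run <- function(x, ...) {
  cat("meningrisk pipeline run:", x$manifest$n_samples, "samples;",
      x$manifest$n_included, "included at calibrated score >=",
      x$manifest$config$cs_gate, "\n")
  cat("risk groups (included, graded):\n")
  print(table(x$samples$risk_group[x$samples$cs_band == "included"]))
  invisible(x)
}

#' Read/validate a cohort sheet
#'
#' Delimited text (comma or tab, auto-detected from the header line) with
#' the documented dialect: \code{sample_id, sex, age, mitoses_local,
#' mitoses_referred, brain_invasion, subtype, atypia_* (5 logical columns),
#' gradeable, mc_class, calibrated_score} (plus optional \code{pathway},
#' \code{tert_promoter}).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_sheet <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  sheet <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_cohort_sheet(sheet)
  sheet
}

validate_cohort_sheet <- function(sheet) {
  req <- c("sample_id", "sex", "mitoses_local", "brain_invasion", "subtype",
           paste0("atypia_", ATYPIA_FEATURES), "gradeable", "mc_class",
           "calibrated_score")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0)
    stop("cohort sheet is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(duplicated(sheet$sample_id)))
    stop("cohort sheet: duplicated sample_id")
  cs <- sheet$calibrated_score
  if (any(is.na(cs)) || any(cs < 0 | cs > 1))
    stop("cohort sheet: calibrated_score outside [0, 1]")
  invisible(sheet)
}

#' Write the report tables of a pipeline run
#'
#' One CSV per report table (counts and row proportions side by side), the
#' per-sample audit table, the CNV profile table, and a JSON run manifest
#' recording config, seed and software version. Output is deterministic for
#' identical inputs and config.
#'
#' @param run an \code{mnr_run} object.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(run$samples, "samples")
  wr(run$cnv, "cnv_profiles")
  for (nm in names(run$tables)) {
    t <- run$tables[[nm]]
    if (inherits(t, "mnr_xtab")) {
      df <- data.frame(t$counts, check.names = FALSE)
      df <- cbind(data.frame(row = rownames(t$counts)), df,
                  total = t$row_totals,
                  setNames(data.frame(t$row_props, check.names = FALSE),
                           paste0("prop_", colnames(t$row_props))))
      wr(df, nm)
    } else {
      wr(t, nm)
    }
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(c(run$manifest,
                         list(correlation_mitoses_cdkn2ab = run$correlation$r,
                              correlation_n_pairs = run$correlation$n_pairs)),
                       mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(paths, mpath))
}
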