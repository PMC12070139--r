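#' Parameters of the synthetic meningioma cohort
#'
#' Builds (and validates) the parameter list for
#' \code{\link{generate_cohort}}. Defaults encode the cohort structure the
#' analysis assumes: grade prevalences of 80.1\% Grade 1, 18.3\% Grade 2 and
#' 1.5\% Grade 3 in routine diagnostic practice, with about 3.9\% of samples
#' ungradeable; the published allocation of the four Grade 2 criteria and
#' the conditional methylation-class proportions per grade stratum;
#' published 1p and 22q loss rates per grade (with the per-methylation-class
#' conditionals chosen to reproduce those marginals); and a segment-level
#' noise model that keeps neutral and lost segments clearly on either side
#' of the -0.1 calling threshold, so that arm calls are recoverable exactly.
#'
#' @param n_samples cohort size.
#' @param p_grade probabilities of planted grades 1/2/3 (normalised).
#' @param p_ungraded probability that a sample's histology is masked
#'   (ungradeable: crush/cautery artefact or small sample); masking leaves
#'   the molecular channels intact.
#' @param p_criterion probabilities of the four Grade 2 criterion strata.
#' @param mc_probs matrix of conditional methylation-class probabilities,
#'   one row per stratum (g1, the four g2 criteria, g3), columns benign /
#'   intermediate / SMARCE1_altered / malignant; rows sum to 1.
#' @param arm_probs list of per-grade matrices (rows: methylation class;
#'   columns: arms 1p, 6q, 14q, 22q) of loss probabilities.
#' @param p_g3_molecular probability that a Grade 3 tumour is graded via
#'   CDKN2A/B homozygous deletion (mitoses 6--19) rather than mitotic count
#'   >= 20.
#' @param p_g3_histo_cdkn2ab probability of CDKN2A/B co-deletion in a
#'   mitotically defined Grade 3 tumour.
#' @param cs_mix probabilities of the three calibrated-score bands
#'   (>= 0.9, 0.3--0.9, < 0.3).
#' @param p_female probability of female sex per grade 1/2/3.
#' @param age_mean,age_sd age model per grade (years, truncated to 16--91).
#' @param noise segment-level noise model; see Details in the package
#'   vignette. \code{cdkn2ab_cor} is the target Pearson correlation between
#'   mitotic count and the CDKN2A/B locus log2 value.
#' @return validated list of class \code{mnr_params}.
#' @export
cohort_params <- function(
    n_samples = 1000,
    p_grade = c(`1` = 0.801, `2` = 0.183, `3` = 0.015),
    p_ungraded = 0.039,
    p_criterion = c(brain_invasion = 95, mitotic_count = 247,
                    histology_type = 70, brain_invasion_plus_mitoses = 28) / 441,
    mc_probs = default_mc_probs(),
    arm_probs = default_arm_probs(),
    p_g3_molecular = 0.15,
    p_g3_histo_cdkn2ab = 0.3,
    cs_mix = c(included = 0.81, low_band = 0.16, unclassified = 0.03),
    p_female = c(`1` = 0.706, `2` = 0.615, `3` = 0.412),
    age_mean = c(`1` = 58, `2` = 60, `3` = 62),
    age_sd = 14,
    noise = list(neutral_mean = 0, neutral_sd = 0.05, neutral_floor = -0.08,
                 lost_mean = -0.35, lost_sd = 0.05, lost_ceiling = -0.15,
                 del_mean = -1.2, del_sd = 0.1, del_ceiling = -0.5,
                 locus_mu = -0.05, locus_sigma = 0.08,
                 locus_clamp = c(-0.35, 0.3),
                 cdkn2ab_cor = -0.38,
                 lost_frac_range = c(0.30, 0.98))) {
  stopifnot(n_samples > 0)
  p_grade <- p_grade / sum(p_grade)
  p_criterion <- p_criterion / sum(p_criterion)
  cs_mix <- cs_mix / sum(cs_mix)
  if (abs(sum(p_grade) - 1) > 1e-9) stop("p_grade must sum to 1")
  if (p_ungraded < 0 || p_ungraded >= 1) stop("p_ungraded must be in [0, 1)")
  if (!all(abs(rowSums(mc_probs) - 1) < 1e-9))
    stop("each row of mc_probs must sum to 1")
  stopifnot(all(unlist(arm_probs) >= 0), all(unlist(arm_probs) <= 1),
            noise$neutral_sd >= 0, noise$lost_sd >= 0,
            noise$lost_ceiling <= -0.1, noise$neutral_floor > -0.1)
  p <- list(n_samples = as.integer(n_samples), p_grade = p_grade,
            p_ungraded = p_ungraded, p_criterion = p_criterion,
            mc_probs = mc_probs, arm_probs = arm_probs,
            p_g3_molecular = p_g3_molecular,
            p_g3_histo_cdkn2ab = p_g3_histo_cdkn2ab,
            cs_mix = cs_mix, p_female = p_female,
            age_mean = age_mean, age_sd = age_sd, noise = noise)
  class(p) <- c("mnr_params", "list")
  p
}

#' @rdname cohort_params
#' @export
default_mc_probs <- function() {
  classes <- c("benign", "intermediate", "SMARCE1_altered", "malignant")
  m <- rbind(
    g1 = c(408, 46, 1, 0),
    g2_brain_invasion = c(69, 24, 0, 2),
    g2_mitotic_count = c(154, 80, 1, 12),
    g2_histology_type = c(55, 9, 6, 0),
    g2_brain_invasion_plus_mitoses = c(7, 20, 0, 2),
    g3 = c(7, 10, 0, 10))
  colnames(m) <- classes
  m / rowSums(m)
}

#' @rdname cohort_params
#' @export
default_arm_probs <- function() {
  arms <- c("1p", "6q", "14q", "22q")
  classes <- c("benign", "intermediate", "SMARCE1_altered", "malignant")
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(classes, arms)
    m
  }
  list(
    # chosen so the marginal loss rates match the published per-grade rates
    # (1p: 31% / 56% / 100%; 22q: 52% / 69% / 100%)
    `1` = mk(c(0.27, 0.06, 0.08, 0.49),
             c(0.65, 0.25, 0.35, 0.78),
             c(0.30, 0.10, 0.20, 0.50),
             c(0.90, 0.60, 0.80, 1.00)),
    `2` = mk(c(0.46, 0.10, 0.15, 0.62),
             c(0.72, 0.35, 0.50, 0.82),
             c(0.50, 0.10, 0.20, 0.60),
             c(0.95, 0.60, 0.80, 1.00)),
    `3` = mk(c(1.00, 0.40, 0.50, 1.00),
             c(1.00, 0.60, 0.80, 1.00),
             c(1.00, 0.50, 0.50, 1.00),
             c(1.00, 0.80, 0.90, 1.00)))
}

g1_mitoses <- function(n) sample(0:3, n, replace = TRUE,
                                 prob = c(0.45, 0.30, 0.15, 0.10))

g2_mitoses <- function(n) {
  # per-count weights follow the published strata frequencies among
  # mitotically defined tumours (4-7: 234, 8-11: 38, 12-15: 14, 16-19: 13)
  w <- c(rep(234 / 4, 4), rep(38 / 4, 4), rep(14 / 4, 4), rep(13 / 4, 4))
  sample(4:19, n, replace = TRUE, prob = w)
}

g3_mitoses <- function(n) sample(20:30, n, replace = TRUE,
                                 prob = rev(seq(2, 12, length.out = 11)))

COMMON_SUBTYPES <- c("meningothelial", "transitional", "fibrous",
                     "psammomatous")

#' Generate a seeded synthetic meningioma cohort
#'
#' Draws a cohort with the conditional structure described in
#' \code{\link{cohort_params}} and returns both the observable data (cohort
#' sheet plus per-sample log2 segments) and the planted ground truth. Every
#' record's histology is consistent with its planted grade and criterion
#' (e.g., a mitotic-count Grade 2 has 4--19 mitoses, no brain invasion and
#' fewer than 3 atypia features), so the grading and scoring stages recover
#' the planted values exactly; arm losses are planted with segment log2
#' values held beyond a noise margin from the -0.1 threshold, so arm calls
#' are also exact.
#'
#' @param params a \code{\link{cohort_params}} list.
#' @param seed integer RNG seed (deterministic output for fixed
#'   params + seed).
#' @param arms,loci annotation tables (defaults: the bundled hg19-style
#'   tables).
#' @param with_segments set FALSE to skip segment emission (fast, for
#'   sheet/truth-level simulation studies; \code{segments} is then NULL).
#' @return list with \code{sheet} (cohort sheet data.frame), \code{segments}
#'   (combined multi-sample segment data.frame, 0-based half-open; use
#'   \code{\link{write_seg}} to export), \code{truth} (planted values and
#'   expected pipeline outputs) and \code{params}.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1,
                            arms = load_arm_definitions(default_arm_table()),
                            loci = load_locus_definitions(default_locus_table()),
                            with_segments = TRUE) {
  stopifnot(inherits(params, "mnr_params"))
  set.seed(seed)
  n <- params$n_samples
  ids <- sprintf("SYN%05d", seq_len(n))
  grade <- sample(names(params$p_grade), n, replace = TRUE,
                  prob = params$p_grade)
  criterion <- rep("none", n)
  is_g2 <- grade == "2"
  criterion[is_g2] <- sample(names(params$p_criterion), sum(is_g2),
                             replace = TRUE, prob = params$p_criterion)
  stratum <- ifelse(grade == "1", "g1",
                    ifelse(grade == "3", "g3", paste0("g2_", criterion)))
  classes <- colnames(params$mc_probs)
  mc_class <- vapply(stratum, function(s)
    sample(classes, 1, prob = params$mc_probs[s, ]), character(1),
    USE.NAMES = FALSE)

  # Grade 3 route: molecular (CDKN2A/B deletion, moderate mitoses) vs
  # mitotic; mitotic route may co-delete CDKN2A/B
  g3_mol <- grade == "3" & runif(n) < params$p_g3_molecular
  cdkn2ab_deleted <- g3_mol |
    (grade == "3" & !g3_mol & runif(n) < params$p_g3_histo_cdkn2ab)

  mitoses <- integer(n)
  mitoses[grade == "1"] <- g1_mitoses(sum(grade == "1"))
  low_mit_g2 <- is_g2 & criterion %in% c("brain_invasion", "histology_type")
  hi_mit_g2 <- is_g2 & !low_mit_g2
  mitoses[low_mit_g2] <- g1_mitoses(sum(low_mit_g2))
  mitoses[hi_mit_g2] <- g2_mitoses(sum(hi_mit_g2))
  mitoses[g3_mol] <- sample(6:19, sum(g3_mol), replace = TRUE)
  g3_hist <- grade == "3" & !g3_mol
  mitoses[g3_hist] <- g3_mitoses(sum(g3_hist))

  invasion <- ifelse(
    criterion %in% c("brain_invasion", "brain_invasion_plus_mitoses"),
    "yes", "no")
  subtype <- rep(NA_character_, n)
  atypia <- matrix(FALSE, n, length(ATYPIA_FEATURES),
                   dimnames = list(NULL, ATYPIA_FEATURES))
  for (i in seq_len(n)) {
    if (criterion[i] == "histology_type") {
      if (mc_class[i] == "SMARCE1_altered") {
        subtype[i] <- "clear_cell"
      } else if (runif(1) < 0.5) {
        subtype[i] <- "chordoid"
      } else {  # atypia route: >= 3 of the 5 features
        subtype[i] <- sample(COMMON_SUBTYPES, 1)
        k <- sample(3:5, 1)
        atypia[i, sample(ATYPIA_FEATURES, k)] <- TRUE
      }
    } else {
      subtype[i] <- sample(COMMON_SUBTYPES, 1)
      k <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
      if (k > 0) atypia[i, sample(ATYPIA_FEATURES, k)] <- TRUE
    }
  }

  # referred cases occasionally carry a second (lower) count; the effective
  # maximum always equals the planted count
  referred <- runif(n) < 0.25
  mit_ref <- ifelse(referred, mitoses, NA_real_)
  mit_loc <- ifelse(referred, pmax(0, mitoses - sample(0:3, n, replace = TRUE)),
                    mitoses)

  masked <- runif(n) < params$p_ungraded
  sex <- ifelse(runif(n) < params$p_female[grade], "F", "M")
  age <- pmin(pmax(round(rnorm(n, params$age_mean[grade], params$age_sd)), 16), 91)
  band <- sample(names(params$cs_mix), n, replace = TRUE, prob = params$cs_mix)
  cs <- ifelse(band == "included", runif(n, 0.9, 1),
               ifelse(band == "low_band", runif(n, 0.3, 0.9),
                      runif(n, 0.05, 0.3)))

  # planted arm losses, conditional on (grade, methylation class)
  arm_keys <- c("1p", "6q", "14q", "22q")
  lost <- matrix(FALSE, n, 4, dimnames = list(NULL, arm_keys))
  for (g in c("1", "2", "3")) {
    for (cl in classes) {
      sel <- grade == g & mc_class == cl
      if (!any(sel)) next
      pr <- params$arm_probs[[g]][cl, arm_keys]
      lost[sel, ] <- matrix(runif(sum(sel) * 4) < rep(pr, each = sum(sel)),
                            ncol = 4)
    }
  }

  # CDKN2A/B locus log2 channel with a target mitoses correlation. The
  # deep-deletion values are fixed first (they are part of the biology and
  # carry most of the leverage); the slope of the continuous channel is then
  # solved so the overall Pearson correlation of (mitoses, locus log2)
  # matches the target.
  no <- params$noise
  del_vals <- pmin(rnorm(sum(cdkn2ab_deleted), no$del_mean, no$del_sd),
                   no$del_ceiling)
  eps <- rnorm(n)
  zm <- if (stats::sd(mitoses) > 0) (mitoses - mean(mitoses)) / stats::sd(mitoses)
        else rep(0, n)
  locus_for <- function(alpha) {
    v <- pmin(pmax(no$locus_mu + no$locus_sigma * (alpha * zm + eps),
                   no$locus_clamp[1]), no$locus_clamp[2])
    v[cdkn2ab_deleted] <- del_vals
    v
  }
  fit_err <- function(alpha) {
    v <- locus_for(alpha)
    if (stats::sd(v) == 0 || stats::sd(mitoses) == 0) return(0)
    stats::cor(mitoses, v) - no$cdkn2ab_cor
  }
  alpha <- if (stats::sd(mitoses) == 0) 0 else {
    lo <- fit_err(-10); hi <- fit_err(10)
    if (sign(lo) == sign(hi)) {  # target unreachable: nearest endpoint
      if (abs(lo) < abs(hi)) -10 else 10
    } else stats::uniroot(fit_err, c(-10, 10))$root
  }
  locus_log2 <- locus_for(alpha)

  sheet <- data.frame(
    sample_id = ids, sex = sex, age = age,
    pathway = ifelse(referred, "external", "local"),
    mitoses_local = ifelse(masked, NA_real_, mit_loc),
    mitoses_referred = ifelse(masked, NA_real_, mit_ref),
    brain_invasion = ifelse(masked, "unassessable", invasion),
    subtype = ifelse(masked, "unspecified", subtype),
    stringsAsFactors = FALSE)
  for (f in ATYPIA_FEATURES)
    sheet[[paste0("atypia_", f)]] <- ifelse(masked, FALSE, atypia[, f])
  sheet$gradeable <- !masked
  sheet$tert_promoter <- "unknown"
  sheet$mc_class <- mc_class
  sheet$calibrated_score <- cs

  expected_grade <- ifelse(masked, "ungraded", grade)
  expected_category <- ifelse(masked | grade != "2", "none", criterion)
  esc <- model_score(expected_grade, mc_class,
                     lost[, "1p"], lost[, "6q"], lost[, "14q"])
  truth <- data.frame(
    sample_id = ids, grade = grade, criterion = criterion,
    mc_class = mc_class, masked_ungraded = masked,
    lost_1p = lost[, "1p"], lost_6q = lost[, "6q"],
    lost_14q = lost[, "14q"], lost_22q = lost[, "22q"],
    cdkn2ab_deleted = cdkn2ab_deleted, cdkn2ab_log2 = locus_log2,
    mitoses = ifelse(masked, NA_integer_, mitoses),
    included = band == "included",
    expected_grade = expected_grade,
    expected_category = expected_category,
    expected_total = esc$total,
    expected_risk = as.character(esc$risk_group),
    stringsAsFactors = FALSE)

  segments <- NULL
  if (with_segments) {
    seg_list <- lapply(seq_len(n), function(i)
      emit_segments(ids[i],
                    lost_arms = arm_keys[lost[i, ]],
                    locus_log2 = locus_log2[i],
                    arms = arms, loci = loci, noise = no))
    segments <- do.call(rbind, seg_list)
  }

  list(sheet = sheet, segments = segments, truth = truth, params = params)
}

#' Emit log2 segments for one synthetic sample
#'
#' The inverse of the arm caller: planted-lost arms receive a telomeric
#' block covering a uniform 30--98\% of the arm at a log2 value held at or
#' below \code{lost_ceiling} (default -0.15, a clear margin beyond the -0.1
#' threshold); intact arms receive neutral segments truncated above
#' \code{neutral_floor} (-0.08). Chromosome 9 carries a dedicated CDKN2A/B
#' locus segment at \code{locus_log2} so the locus minimum is exactly the
#' planted value. Only chromosomes 1, 6, 9, 14 and 22 are emitted.
#'
#' @param sample_id sample identifier.
#' @param lost_arms character vector of arm keys planted as lost (subset of
#'   1p, 6q, 14q, 22q).
#' @param locus_log2 planted CDKN2A/B locus log2 value.
#' @param arms,loci annotation tables.
#' @param noise noise model (see \code{\link{cohort_params}}).
#' @return data.frame of segments (0-based half-open).
#' @export
emit_segments <- function(sample_id, lost_arms, locus_log2,
                          arms = load_arm_definitions(default_arm_table()),
                          loci = load_locus_definitions(default_locus_table()),
                          noise = cohort_params()$noise) {
  rneutral <- function(k) pmax(rnorm(k, noise$neutral_mean, noise$neutral_sd),
                               noise$neutral_floor)
  rlost <- function(k) pmin(rnorm(k, noise$lost_mean, noise$lost_sd),
                            noise$lost_ceiling)
  locus <- loci[loci$name == "CDKN2A/B", , drop = FALSE]
  use <- arms[arms$chrom %in% c("chr1", "chr6", "chr9", "chr14", "chr22"), ,
              drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(use))) {
    a <- use[j, ]
    if (a$chrom == "chr9" && a$arm == "p") {
      # split 9p around the CDKN2A/B locus so its minimum is exact
      out[[length(out) + 1]] <- data.frame(
        sample_id = sample_id, chrom = a$chrom,
        start = c(a$start, locus$start, locus$end),
        end = c(locus$start, locus$end, a$end),
        log2_ratio = c(rneutral(1), locus_log2, rneutral(1)))
      next
    }
    if (a$arm_key %in% lost_arms) {
      f <- runif(1, noise$lost_frac_range[1], noise$lost_frac_range[2])
      len <- round(f * a$length)
      if (a$arm == "p") {          # telomeric block at the arm start
        b <- c(a$start, a$start + len)
        keep <- c(a$start + len, a$end)
      } else {                     # telomeric block at the arm end
        b <- c(a$end - len, a$end)
        keep <- c(a$start, a$end - len)
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = sample_id, chrom = a$chrom,
        start = c(b[1], keep[1]), end = c(b[2], keep[2]),
        log2_ratio = c(rlost(1), rneutral(1)))
    } else {
      out[[length(out) + 1]] <- data.frame(
        sample_id = sample_id, chrom = a$chrom,
        start = a$start, end = a$end, log2_ratio = rneutral(1))
    }
  }
  seg <- do.call(rbind, out)
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Parameter-recovery report for the cohort generator
#'
#' Generates a cohort and compares, for every (grade stratum, methylation
#' class) cell of the conditional allocation table, the planted probability
#' with the observed proportion and its exact (Clopper-Pearson) 95\%
#' binomial confidence interval. With defaults and large n, at least 95\% of
#' cells are expected to cover their planted value.
#'
#' @param params a \code{\link{cohort_params}} list.
#' @param n cohort size (overrides \code{params$n_samples}).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with \code{cells} (one row per cell: stratum, class,
#'   planted, estimate, ci_lo, ci_hi, inside) and \code{prop_inside}.
#' @export
recovery_report <- function(params = cohort_params(), n = NULL, seed = 1,
                            conf = 0.95) {
  if (!is.null(n)) params$n_samples <- as.integer(n)
  sim <- generate_cohort(params, seed = seed, with_segments = FALSE)
  truth <- sim$truth
  stratum <- ifelse(truth$grade == "1", "g1",
                    ifelse(truth$grade == "3", "g3",
                           paste0("g2_", truth$criterion)))
  rows <- list()
  for (s in rownames(params$mc_probs)) {
    in_s <- stratum == s
    n_s <- sum(in_s)
    for (cl in colnames(params$mc_probs)) {
      k <- sum(in_s & truth$mc_class == cl)
      planted <- params$mc_probs[s, cl]
      if (n_s == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          stratum = s, class = cl, n = 0L, planted = planted,
          estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          inside = NA)
        next
      }
      ci <- stats::binom.test(k, n_s, conf.level = conf)$conf.int
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, class = cl, n = n_s, planted = planted,
        estimate = k / n_s, ci_lo = ci[1], ci_hi = ci[2],
        inside = planted >= ci[1] & planted <= ci[2])
    }
  }
  cells <- do.call(rbind, rows)
  list(cells = cells,
       prop_inside = mean(cells$inside, na.rm = TRUE))
}
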