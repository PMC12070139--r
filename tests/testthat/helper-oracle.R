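# Independent oracles and small fixture builders for the test suite.

# Per-base brute-force arm-loss fraction: marks every base of the arm
# (0-based half-open) covered by a segment at or below the loss threshold.
# Intentionally naive and independent of the IRanges-backed implementation;
# only usable on toy arms (<= ~100 kb).
brute_fraction <- function(segments, arm, loss_log2 = -0.1) {
  len <- arm$end - arm$start
  covered <- logical(len)
  for (i in seq_len(nrow(segments))) {
    if (segments$chrom[i] != arm$chrom) next
    if (segments$log2_ratio[i] > loss_log2) next
    s <- max(segments$start[i], arm$start)
    e <- min(segments$end[i], arm$end)
    if (e > s) covered[(s - arm$start + 1):(e - arm$start)] <- TRUE
  }
  sum(covered) / len
}

# one toy arm (chrT p, 0-based half-open)
toy_arm <- function(start = 0, end = 10000, chrom = "chrT", arm = "p") {
  load_arm_definitions(data.frame(chrom = chrom, arm = arm,
                                  start = start, end = end))
}

toy_segments <- function(start, end, log2, chrom = "chrT", sample_id = "S1") {
  n <- length(start)
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             start = start, end = end, log2_ratio = log2,
             stringsAsFactors = FALSE)
}

# random segment set on a toy arm (may extend past its bounds and overlap)
random_toy_case <- function(arm_len = sample(1000:100000, 1),
                            n_seg = sample(0:20, 1)) {
  arm <- toy_arm(end = arm_len)
  if (n_seg == 0) {
    return(list(arm = arm, segments = toy_segments(integer(0), integer(0),
                                                   numeric(0))))
  }
  s <- sample(seq(-200, arm_len + 200), n_seg, replace = TRUE)
  w <- sample(1:round(arm_len / 2), n_seg, replace = TRUE)
  log2 <- round(runif(n_seg, -1.5, 0.5), 3)
  list(arm = arm, segments = toy_segments(s, s + w, log2))
}

# expand a counts matrix into one record per counted unit
expand_counts <- function(counts, row_key = "row", col_key = "col") {
  idx <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(
    rep(rownames(counts)[idx[, 1]], counts[idx]),
    rep(colnames(counts)[idx[, 2]], counts[idx]),
    stringsAsFactors = FALSE)
  names(out) <- c(row_key, col_key)
  out
}

# minimal valid histology feature list, overridable per test
hist_features <- function(...) {
  defaults <- list(mitoses_local = 0, mitoses_referred = NA,
                   brain_invasion = "no", subtype = "transitional",
                   atypia_features = character(0), gradeable = TRUE)
  utils::modifyList(defaults, list(...))
}

mol_flags <- function(cdkn2ab = "no", tert = "no") {
  list(cdkn2ab_deleted = cdkn2ab, tert_promoter_mutant = tert)
}
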