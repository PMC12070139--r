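test_that("arm definitions parse, normalise and validate", {
  tab <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    arm = c("p", "q", "p"),
                    start = c(0, 125e6, 0),
                    end = c(123.4e6, 249e6, 92e6))
  arms <- load_arm_definitions(tab)
  expect_equal(nrow(arms), 3)
  expect_equal(arms$arm_key, c("1p", "1q", "2p"))
  expect_equal(arms$length, arms$end - arms$start)
  expect_equal(arms$start[1], 0)

  # 1-based inclusive input shifts starts down by one
  arms1 <- load_arm_definitions(transform(tab, start = start + 1),
                                one_based = TRUE)
  expect_equal(arms1$start, arms$start)

  # overlapping p/q on one chromosome is a format error
  bad <- data.frame(chrom = "chr1", arm = c("p", "q"),
                    start = c(0, 100e6), end = c(123e6, 249e6))
  expect_error(load_arm_definitions(bad), "overlap")
  expect_error(load_arm_definitions(tab[, -2]), "missing required column")
  expect_error(load_arm_definitions(transform(tab, end = start)), "exceed")
})

test_that("bundled annotation tables load and contain the required entries", {
  arms <- load_arm_definitions(default_arm_table())
  expect_true(all(c("1p", "6q", "14q", "22q", "9p") %in% arms$arm_key))
  expect_true(all(arms$length > 0))
  loci <- load_locus_definitions(default_locus_table())
  expect_true("CDKN2A/B" %in% loci$name)
  cdk <- loci[loci$name == "CDKN2A/B", ]
  p9 <- arms[arms$arm_key == "9p", ]
  expect_true(cdk$start >= p9$start && cdk$end <= p9$end)
})

test_that("SEG round trip preserves segments and converts coordinates", {
  seg <- toy_segments(c(0, 500, 900), c(500, 1000, 1200),
                      c(-0.5, 0.01, -1.2), chrom = "chr1")
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(seg, path)
  # on disk: 1-based inclusive
  raw <- read.delim(path)
  expect_equal(raw$start, seg$start + 1)
  expect_equal(raw$end, seg$end)
  back <- read_seg(path)
  expect_equal(back$start, seg$start)
  expect_equal(back$end, seg$end)
  expect_equal(back$log2_ratio, seg$log2_ratio)

  writeLines(c("a\tb\tc", "x\tchr1\t1"), path)
  expect_error(read_seg(path), "malformed SEG")
})

test_that("arm_loss_fraction: direct arithmetic and union semantics", {
  arm <- toy_arm(end = 10000)
  # one segment covering 10% at log2 -0.5
  expect_equal(arm_loss_fraction(toy_segments(0, 1000, -0.5), arm), 0.10)
  # nothing below threshold
  expect_equal(arm_loss_fraction(toy_segments(0, 1000, 0.2), arm), 0)
  expect_equal(arm_loss_fraction(toy_segments(integer(0), integer(0),
                                              numeric(0)), arm), 0)
  # two overlapping lost segments jointly covering 7%: union, not sum
  seg <- toy_segments(c(0, 300), c(500, 700), c(-0.5, -0.3))
  expect_equal(arm_loss_fraction(seg, arm), 0.07)
  expect_equal(brute_fraction(seg, arm), 0.07)  # oracle agrees
  # threshold is inclusive (log2 == loss_log2 counts as lost)
  expect_equal(arm_loss_fraction(toy_segments(0, 1000, -0.1), arm), 0.10)
  degenerate <- toy_arm(end = 10); degenerate$end <- degenerate$start
  expect_error(arm_loss_fraction(seg, degenerate), "zero-length")
})

test_that("arm_loss_fraction equals the per-base oracle on random cases", {
  set.seed(42)
  for (i in 1:60) {
    cs <- random_toy_case()
    expect_identical(arm_loss_fraction(cs$segments, cs$arm),
                     brute_fraction(cs$segments, cs$arm))
  }
})

test_that("fraction properties: range, monotonicity, boundary clipping", {
  set.seed(7)
  for (i in 1:25) {
    cs <- random_toy_case()
    f0 <- arm_loss_fraction(cs$segments, cs$arm)
    expect_gte(f0, 0); expect_lte(f0, 1)
    # adding a lost segment never decreases the fraction
    extra_lost <- toy_segments(100, 400, -0.9)
    expect_gte(arm_loss_fraction(rbind(cs$segments, extra_lost), cs$arm), f0)
    # adding a neutral segment never changes it
    extra_neutral <- toy_segments(0, cs$arm$end, 0.0)
    expect_identical(arm_loss_fraction(rbind(cs$segments, extra_neutral),
                                       cs$arm), f0)
  }

  # a segment spanning the p/q boundary contributes only its overlap, and
  # pre-splitting it at the boundary changes nothing
  defs <- data.frame(chrom = "chrT", arm = c("p", "q"),
                     start = c(0, 10000), end = c(10000, 30000))
  arms <- load_arm_definitions(defs)
  spanning <- toy_segments(8000, 14000, -0.8)
  split <- toy_segments(c(8000, 10000), c(10000, 14000), c(-0.8, -0.8))
  for (k in c("Tp", "Tq")) {
    arm <- arms[arms$arm_key == k, ]
    expect_identical(arm_loss_fraction(spanning, arm),
                     arm_loss_fraction(split, arm))
  }
  expect_equal(arm_loss_fraction(spanning, arms[arms$arm == "p", ]), 0.2)
  expect_equal(arm_loss_fraction(spanning, arms[arms$arm == "q", ]), 0.2)
})

test_that("call_arm_status applies the strict more-than-5% rule", {
  expect_true(call_arm_status(0.051))
  expect_false(call_arm_status(0.05))   # boundary: not lost
  expect_false(call_arm_status(0))
  expect_true(call_arm_status(1))
  expect_error(call_arm_status(1.2), "\\[0, 1\\]")
  expect_error(call_arm_status(-0.1), "\\[0, 1\\]")
})

test_that("CDKN2A/B call: threshold, minimum, and explicit no-call", {
  loci <- load_locus_definitions(data.frame(
    name = "CDKN2A/B", chrom = "chr9", start = 1000, end = 2000))
  locus <- loci[1, ]
  deep <- toy_segments(500, 1500, -1.2, chrom = "chr9")
  expect_true(call_cdkn2ab(deep, locus)$deleted)
  expect_equal(call_cdkn2ab(deep, locus)$log2, -1.2)
  neutral <- toy_segments(500, 2500, 0.0, chrom = "chr9")
  expect_false(call_cdkn2ab(neutral, locus)$deleted)
  # minimum over overlapping segments wins
  both <- rbind(neutral, deep)
  expect_equal(call_cdkn2ab(both, locus)$log2, -1.2)
  # hemizygous-level loss is not a homozygous deletion
  expect_false(call_cdkn2ab(toy_segments(0, 3000, -0.3, chrom = "chr9"),
                            locus)$deleted)
  # no overlap -> no-call, not an error and not "not deleted"
  away <- toy_segments(5000, 6000, -2, chrom = "chr9")
  nc <- call_cdkn2ab(away, locus)
  expect_identical(nc$call, "no-call")
  expect_true(is.na(nc$deleted))
})

test_that("build_cnv_profile composes the calls per sample", {
  arms <- load_arm_definitions(default_arm_table())
  loci <- load_locus_definitions(default_locus_table())
  a1p <- arms[arms$arm_key == "1p", ]
  seg <- toy_segments(a1p$start, a1p$end, -0.5, chrom = "chr1")
  prof <- build_cnv_profile("S1", seg, arms, loci)
  expect_true(prof$lost_1p)
  expect_equal(prof$frac_1p, 1)
  expect_false(any(prof$lost_6q, prof$lost_14q, prof$lost_22q))
  expect_identical(prof$cdkn2ab_call, "no-call")

  empty <- prof0 <- build_cnv_profile("S2", seg[0, ], arms, loci)
  expect_equal(unlist(empty[paste0("frac_", c("1p", "6q", "14q", "22q"))]),
               c(frac_1p = 0, frac_6q = 0, frac_14q = 0, frac_22q = 0))
  expect_false(any(unlist(empty[paste0("lost_", c("1p", "6q", "14q", "22q"))])))
  expect_identical(empty$cdkn2ab_call, "no-call")

  expect_error(build_cnv_profile("S3", seg, arms[arms$arm_key != "6q", ], loci),
               "missing required arm")
})

test_that("planted losses from the simulator are recovered exactly", {
  arms <- load_arm_definitions(default_arm_table())
  loci <- load_locus_definitions(default_locus_table())
  set.seed(11)
  seg <- emit_segments("S1", lost_arms = c("1p", "14q"), locus_log2 = -0.02,
                       arms = arms, loci = loci)
  prof <- build_cnv_profile("S1", seg, arms, loci)
  expect_true(prof$lost_1p && prof$lost_14q)
  expect_false(prof$lost_6q || prof$lost_22q)
  expect_equal(prof$cdkn2ab_log2, -0.02)
  expect_identical(prof$cdkn2ab_call, "not_deleted")
})
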