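test_that("effective mitotic count takes the higher available value", {
  expect_equal(effective_mitotic_count(3, 6), 6)
  expect_equal(effective_mitotic_count(5, NA), 5)
  expect_equal(effective_mitotic_count(NA, 7), 7)
  expect_equal(effective_mitotic_count(0, 0), 0)
  expect_true(is.na(effective_mitotic_count(NA, NA)))
  expect_error(effective_mitotic_count(-1), "non-negative")
})

test_that("mitoses per mm2 conversion is exact at the standard HPF area", {
  expect_identical(mitoses_per_mm2(4, 0.16), 2.5)
  expect_identical(mitoses_per_mm2(20, 0.16), 12.5)
  expect_identical(mitoses_per_mm2(0, 0.16), 0)
  expect_equal(mitoses_per_mm2(10, 0.25), 4)
  expect_error(mitoses_per_mm2(4, 0), "positive")
})

test_that("grade assignment follows the 2021 criteria", {
  # Grade 1: bland histology
  expect_identical(assign_grade(hist_features(), mol_flags())$grade, "1")

  # Grade 2 via each route, with the reported criterion category
  g <- assign_grade(hist_features(mitoses_local = 5), mol_flags())
  expect_identical(g$grade, "2")
  expect_identical(g$criterion_category, "mitotic_count")

  g <- assign_grade(hist_features(mitoses_local = 2, brain_invasion = "yes"),
                    mol_flags())
  expect_identical(g$grade, "2")
  expect_identical(g$criterion_category, "brain_invasion")

  g <- assign_grade(hist_features(mitoses_local = 6, brain_invasion = "yes"),
                    mol_flags())
  expect_identical(g$criterion_category, "brain_invasion_plus_mitoses")

  g <- assign_grade(hist_features(mitoses_local = 1, subtype = "clear_cell"),
                    mol_flags())
  expect_identical(g$grade, "2")
  expect_identical(g$criterion_category, "histology_type")

  g <- assign_grade(hist_features(atypia_features = c(
    "hypercellularity", "prominent_nucleoli", "spotty_necrosis")), mol_flags())
  expect_identical(g$grade, "2")
  expect_identical(g$criterion_category, "histology_type")

  # two atypia features are not enough
  expect_identical(assign_grade(hist_features(atypia_features = c(
    "hypercellularity", "spotty_necrosis")), mol_flags())$grade, "1")

  # Grade 3 routes: mitoses >= 20, CDKN2A/B deletion, TERT mutation
  expect_identical(assign_grade(hist_features(mitoses_local = 20),
                                mol_flags())$grade, "3")
  expect_identical(assign_grade(hist_features(mitoses_local = 19),
                                mol_flags())$grade, "2")
  g <- assign_grade(hist_features(mitoses_local = 2),
                    mol_flags(cdkn2ab = "yes"))
  expect_identical(g$grade, "3")
  expect_true("molecular_grade3" %in% g$criteria_fired)
  expect_identical(assign_grade(hist_features(), mol_flags(tert = "yes"))$grade,
                   "3")
})

test_that("rhabdoid/papillary floor at Grade 2, other subtypes do not", {
  for (st in c("rhabdoid", "papillary")) {
    g <- assign_grade(hist_features(subtype = st), mol_flags())
    expect_identical(g$grade, "2")
    expect_identical(g$criterion_category, "histology_type")
  }
  # the floor does not cap: criteria can still reach Grade 3
  expect_identical(assign_grade(hist_features(subtype = "rhabdoid",
                                              mitoses_local = 25),
                                mol_flags())$grade, "3")
})

test_that("ungradeable samples and unknown evidence are handled safely", {
  g <- assign_grade(hist_features(gradeable = FALSE, mitoses_local = NA),
                    mol_flags())
  expect_identical(g$grade, "ungraded")
  expect_identical(g$criterion_category, "none")

  # unknown molecular flags never upgrade but are reported as caveats
  g <- assign_grade(hist_features(), mol_flags(cdkn2ab = "unknown",
                                               tert = "unknown"))
  expect_identical(g$grade, "1")
  expect_length(g$caveats, 2)

  # unassessable brain invasion is absent evidence
  g <- assign_grade(hist_features(brain_invasion = "unassessable",
                                  mitoses_local = 5), mol_flags())
  expect_identical(g$criterion_category, "mitotic_count")

  expect_error(assign_grade(hist_features(atypia_features = "necrosis")),
               "unknown atypia")
})

test_that("grading is monotone in the mitotic count and category-consistent", {
  grades <- vapply(0:30, function(m)
    assign_grade(hist_features(mitoses_local = m), mol_flags())$grade,
    character(1))
  expect_true(all(diff(as.integer(grades)) >= 0))
  expect_identical(unique(grades[1:4]), "1")     # 0-3
  expect_identical(unique(grades[5:20]), "2")    # 4-19
  expect_identical(unique(grades[21:31]), "3")   # 20+

  # category brain_invasion_plus_mitoses iff both fired, no molecular upgrade
  set.seed(3)
  for (i in 1:40) {
    m <- sample(0:19, 1)
    inv <- sample(c("yes", "no"), 1)
    g <- assign_grade(hist_features(mitoses_local = m, brain_invasion = inv),
                      mol_flags())
    if (g$grade == "2") {
      both <- inv == "yes" && m >= 4
      expect_identical(g$criterion_category == "brain_invasion_plus_mitoses",
                       both)
      expect_setequal(
        g$criteria_fired,
        c("mitotic_count", "brain_invasion")[c(m >= 4, inv == "yes")])
    }
  }
})

test_that("assign_grades drives the rules over a sheet, using CNV CDKN2A/B", {
  sheet <- data.frame(
    sample_id = c("A", "B", "C"), sex = "F", age = 50,
    mitoses_local = c(1, 5, 2), mitoses_referred = c(NA, 8, NA),
    brain_invasion = c("no", "no", "no"),
    subtype = "transitional",
    atypia_hypercellularity = FALSE, atypia_sheet_like_growth = FALSE,
    atypia_prominent_nucleoli = FALSE, atypia_spotty_necrosis = FALSE,
    atypia_small_cell_change = FALSE,
    gradeable = TRUE, mc_class = "benign", calibrated_score = 0.95,
    stringsAsFactors = FALSE)
  cnv <- data.frame(sample_id = c("A", "B", "C"),
                    cdkn2ab_call = c("not_deleted", "not_deleted", "deleted"))
  out <- assign_grades(sheet, cnv)
  expect_identical(out$grade, c("1", "2", "3"))
  expect_equal(out$mitoses_effective, c(1, 8, 2))  # referred max used for B
})
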