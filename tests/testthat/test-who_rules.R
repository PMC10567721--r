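test_that("the canonical integrated diagnoses come out as stated", {
  # IDH-mutant + 1p/19q codeletion, histologic grade 2 -> oligodendroglioma G2
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = TRUE, codel_1p19q = TRUE, histologic_grade = 2))
  expect_equal(d$category, "O2")
  expect_equal(d$type, "O")

  # IDH-mutant astrocytoma with CDKN2A/B homozygous deletion is grade 4
  # even with low-grade histology and no MVP/necrosis
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = TRUE, codel_1p19q = FALSE, mvp = FALSE, necrosis = FALSE,
    cdkn2ab_homdel = TRUE, histologic_grade = 2))
  expect_equal(d$category, "A4")

  # IDH-wildtype with TERT promoter mutation is molecular GBM despite
  # grade-2 histology
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = FALSE, tert_promoter_mutant = TRUE, egfr_amplified = FALSE,
    plus7_minus10 = FALSE, mvp = FALSE, necrosis = FALSE,
    histologic_grade = 2))
  expect_equal(d$category, "GBM")
  expect_equal(d$grade, 4L)

  # IDH-wildtype with nothing qualifying: indeterminate, not an error
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = FALSE, tert_promoter_mutant = FALSE, egfr_amplified = FALSE,
    plus7_minus10 = FALSE, mvp = FALSE, necrosis = FALSE,
    histologic_grade = 2))
  expect_equal(d$status, "indeterminate")
  expect_true(is.na(d$category))
})

test_that("the exhaustive truth table satisfies the scheme invariants", {
  tf <- c(TRUE, FALSE)
  grid <- expand.grid(idh = tf, codel = tf, cdkn = tf, tert = tf, egfr = tf,
                      p7m10 = tf, mvp = tf, necr = tf, grade = c(2L, 3L))
  cats <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- suppressWarnings(integrate_diagnosis(diagnostic_markers(
      idh_mutant = g$idh, codel_1p19q = g$codel, cdkn2ab_homdel = g$cdkn,
      tert_promoter_mutant = g$tert, egfr_amplified = g$egfr,
      plus7_minus10 = g$p7m10, mvp = g$mvp, necrosis = g$necr,
      histologic_grade = g$grade)))
    expect_true(d$status %in% c("classified", "indeterminate"))
    if (d$status == "classified") {
      # category consistent with (type, grade); GBM always 4; O never 4
      expect_equal(d$category,
                   if (d$type == "GBM") "GBM" else paste0(d$type, d$grade))
      if (d$type == "GBM") expect_equal(d$grade, 4L)
      if (d$type == "O") expect_true(d$grade %in% c(2L, 3L))
      cats <- c(cats, d$category)
    }
  }
  # the six reachable categories are exactly the WHO adult-type set
  expect_setequal(unique(cats), glioma_classes())
})

test_that("CDKN2A/B homozygous deletion never lowers an astrocytoma grade", {
  tf <- c(TRUE, FALSE)
  for (mvp in tf) for (necr in tf) for (gr in c(2L, 3L)) {
    base <- integrate_diagnosis(diagnostic_markers(
      idh_mutant = TRUE, codel_1p19q = FALSE, cdkn2ab_homdel = FALSE,
      mvp = mvp, necrosis = necr, histologic_grade = gr))
    with_del <- integrate_diagnosis(diagnostic_markers(
      idh_mutant = TRUE, codel_1p19q = FALSE, cdkn2ab_homdel = TRUE,
      mvp = mvp, necrosis = necr, histologic_grade = gr))
    expect_gte(with_del$grade, base$grade)
    expect_equal(with_del$grade, 4L)
  }
})

test_that("unknown markers on the decisive path become unresolved outcomes", {
  d <- integrate_diagnosis(diagnostic_markers())
  expect_equal(d$status, "unresolved")
  expect_equal(d$missing, "idh_mutant")

  d <- integrate_diagnosis(diagnostic_markers(idh_mutant = TRUE))
  expect_equal(d$missing, "codel_1p19q")

  # grade-4 qualifier fires even with other qualifiers unknown (monotone)
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = TRUE, codel_1p19q = FALSE, necrosis = TRUE))
  expect_equal(d$category, "A4")

  # but a negative path with unknowns cannot resolve
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = TRUE, codel_1p19q = FALSE, mvp = FALSE, necrosis = FALSE))
  expect_equal(d$status, "unresolved")
  expect_true("cdkn2ab_homdel" %in% d$missing)

  # IDH-wildtype with an unknown molecular qualifier and nothing positive
  d <- integrate_diagnosis(diagnostic_markers(
    idh_mutant = FALSE, mvp = FALSE, necrosis = FALSE,
    tert_promoter_mutant = FALSE, egfr_amplified = NA, plus7_minus10 = FALSE))
  expect_equal(d$status, "unresolved")
  expect_equal(d$missing, "egfr_amplified")
})

test_that("the IDH-wildtype histology switch changes only the MVP/necrosis rule", {
  m <- diagnostic_markers(idh_mutant = FALSE, mvp = TRUE, necrosis = FALSE,
                          tert_promoter_mutant = FALSE, egfr_amplified = FALSE,
                          plus7_minus10 = FALSE, histologic_grade = 3)
  expect_equal(integrate_diagnosis(m, "either")$category, "GBM")
  expect_equal(integrate_diagnosis(m, "both")$status, "indeterminate")
})

test_that("invalid marker records are flagged", {
  expect_warning(diagnostic_markers(idh_mutant = FALSE, codel_1p19q = TRUE),
                 "not a valid")
  expect_error(diagnostic_markers(histologic_grade = 4), "2 or 3")
  expect_error(diagnostic_markers(idh_mutant = "yes"), "TRUE/FALSE/NA")
})

test_that("marker tables round-trip through CSV and classify in bulk", {
  df <- data.frame(patient_id = c("P1", "P2", "P3"),
                   idh_mutant = c(TRUE, TRUE, FALSE),
                   codel_1p19q = c(TRUE, FALSE, FALSE),
                   cdkn2ab_homdel = c(FALSE, TRUE, FALSE),
                   tert_promoter_mutant = c(FALSE, FALSE, TRUE),
                   egfr_amplified = FALSE, plus7_minus10 = FALSE,
                   mvp = c(FALSE, FALSE, NA), necrosis = FALSE,
                   histologic_grade = c(3L, 2L, 2L))
  f <- tempfile(fileext = ".csv")
  write_marker_table(df, f)
  df2 <- read_marker_table(f)
  expect_equal(df2$mvp, df$mvp)                    # unknown survives the trip
  res <- classify_marker_table(df2)
  expect_equal(res$category, c("O3", "A4", "GBM"))
  expect_equal(res$status, rep("classified", 3))
})
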