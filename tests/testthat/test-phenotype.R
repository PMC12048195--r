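test_that("GPV is the maximum of the allelic values", {
  expect_equal(gpv(0, 0), 0)
  expect_equal(gpv(1.5, 0), 1.5)
  expect_equal(gpv(2, 0), 2)
  expect_true(is.na(gpv(NA, 5)))
  expect_error(gpv(11, 0), "\\[0, 10\\]")
  # symmetric and idempotent
  expect_equal(gpv(1.5, 9.7), gpv(9.7, 1.5))
  expect_equal(gpv(6.8, 6.8), 6.8)
})

test_that("GPV bins follow the classic/mild/HPA footnote with gap rounding", {
  expect_equal(classify_gpv(0), "classic_PKU")
  expect_equal(classify_gpv(2), "classic_PKU")
  expect_equal(classify_gpv(2.7), "classic_PKU")
  expect_equal(classify_gpv(2.8), "mild_PKU")
  expect_equal(classify_gpv(6.6), "mild_PKU")
  expect_equal(classify_gpv(6.7), "mild_HPA")
  expect_equal(classify_gpv(6.8), "mild_HPA")
  expect_equal(classify_gpv(10), "mild_HPA")
  # gap values round to one decimal before binning
  expect_equal(classify_gpv(2.74), "classic_PKU")
  expect_equal(classify_gpv(2.76), "mild_PKU")
  expect_equal(classify_gpv(6.64), "mild_PKU")
  expect_equal(classify_gpv(6.66), "mild_HPA")
  expect_error(classify_gpv(10.5), "\\[0, 10\\]")

  # monotone non-decreasing along classic -> mild -> HPA
  lv <- c(classic_PKU = 1, mild_PKU = 2, mild_HPA = 3)
  expect_true(all(diff(lv[classify_gpv(seq(0, 10, by = 0.1))]) >= 0))
})

test_that("clinical type follows the Phe thresholds with inclusive 1200 boundary", {
  expect_equal(phe_to_clinical(2400), "cPKU")
  expect_equal(phe_to_clinical(1074), "mPKU")
  expect_equal(phe_to_clinical(1200), "mPKU")
  expect_equal(phe_to_clinical(1201), "cPKU")
  expect_error(phe_to_clinical(500), "outside the two-class scheme")
  expect_error(phe_to_clinical(NA_real_), "qualitative or missing")
})

test_that("recomputed GPVs match the recorded column except the one known discrepancy", {
  r <- recompute_gpv(fixture_cohort())
  checked <- r[!is.na(r$gpv_recorded), ]
  disagreements <- checked[!checked$agrees, ]
  # patient 7 records APV pair 10/9.7 but GPV 9.7, contradicting GPV = max;
  # the table's value is transcribed as printed and listed here
  expect_equal(nrow(disagreements), 1L)
  expect_equal(disagreements$patient_id, 7L)
  expect_equal(disagreements$gpv_recomputed, 10)
  expect_equal(disagreements$gpv_recorded, 9.7)
})

test_that("predicted classes agree with the majority BioPKU type for GPV-0 genotypes", {
  co <- fixture_cohort()
  patients <- cohort_patients(co)
  zero <- patients[!is.na(patients$gpv) & patients$gpv == 0, ]
  expect_gt(nrow(zero), 0)
  expect_equal(unique(classify_gpv(zero$gpv)), "classic_PKU")
  expect_equal(unique(zero$biopku_type), "classic")
})

test_that("phenotype prediction marks single-heterozygous and unknown-APV genotypes unpredictable", {
  co <- fixture_cohort()
  pred <- predict_phenotype(co)
  expect_equal(nrow(pred), 40L)
  # single-heterozygous: one allele unexplained
  singles <- pred[pred$category == "single_heterozygous", ]
  expect_true(all(is.na(singles$gpv)))
  # homozygous profiles duplicate their variant's APV
  p4 <- pred[pred$patient_id == 4, ]
  expect_equal(c(p4$apv_a, p4$apv_b), c(0, 0))
  expect_equal(p4$predicted_type, "classic_PKU")
  # compound het with both APVs known
  p9 <- pred[pred$patient_id == 9, ]
  expect_equal(p9$gpv, 1.5)
  # compound het with an unknown-APV variant stays unpredictable
  p26 <- pred[pred$patient_id == 26, ]
  expect_true(is.na(p26$gpv))
})

test_that("the APV lookup matches the published per-variant values", {
  apv <- apv_table()
  lut <- setNames(apv$apv, apv$variant)
  expect_equal(unname(lut["c.782G>A"]), 1.5)
  expect_equal(unname(lut["c.1066-11G>A"]), 0)
  expect_equal(unname(lut["c.898G>T"]), 9.7)
  expect_equal(unname(lut["c.1169A>G"]), 6.8)
  expect_equal(unname(lut["c.533A>G"]), 7.5)
  expect_equal(unname(lut["c.143T>C"]), 2)
  expect_equal(unname(lut["c.464G>A"]), 10)
})

test_that("concordance counts under an explicit, echoed mapping", {
  same <- c("cPKU", "mPKU", "cPKU")
  cc <- concordance(same, c("classic", "mild", "classic"))
  expect_equal(cc$rate, 1)

  co <- fixture_cohort()
  patients <- cohort_patients(co)
  cc2 <- concordance(patients$clinical_type, patients$biopku_type)
  expect_equal(cc2$n_evaluable, 34L)  # 6 patients have no BioPKU entry
  expect_equal(cc2$n_concordant, 32L)
  expect_named(cc2$mapping, c("cPKU", "mPKU"))

  expect_warning(empty <- concordance(NA_character_, NA_character_),
                 "no evaluable")
  expect_equal(empty$n_evaluable, 0L)
  expect_true(is.na(empty$rate))

  expect_error(concordance("xPKU", "classic"), "missing from the concordance mapping")
})
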