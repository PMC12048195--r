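test_that("zygosity is called inclusively at the threshold and is monotone", {
  expect_equal(call_zygosity(0.58), "hom")
  expect_equal(call_zygosity(0.56), "het")
  expect_equal(call_zygosity(c(0, 1)), c("het", "hom"))
  expect_error(call_zygosity(1.2), "\\[0, 1\\]")
  expect_error(call_zygosity(-0.1), "\\[0, 1\\]")

  af <- seq(0, 1, by = 0.01)
  z <- call_zygosity(af)
  # monotone: once hom, always hom as the fraction grows
  expect_true(all(diff(z == "hom") >= 0))
})

test_that("genotype profiles follow the 1-2 call assembly rules", {
  co <- fixture_cohort()
  profiles <- assemble_genotypes(co)
  expect_equal(profiles$category[profiles$patient_id == 4], "homozygous")
  expect_equal(profiles$category[profiles$patient_id == 2], "compound_heterozygous")
  expect_equal(profiles$category[profiles$patient_id == 33], "single_heterozygous")
  expect_false(profiles$explained[profiles$patient_id == 33])
  expect_true(all(profiles$assumed_trans ==
                    (profiles$category == "compound_heterozygous")))

  # a hom-classified fraction inside a two-call profile is flagged, not fatal
  expect_equal(sum(profiles$inconsistent), 1L)
  expect_equal(profiles$patient_id[profiles$inconsistent], 7L)
  expect_equal(profiles$category[profiles$patient_id == 7], "compound_heterozygous")

  three <- dplyr::bind_rows(co, dplyr::mutate(co[1, ], variant = "c.999A>G"),
                            dplyr::mutate(co[1, ], variant = "c.998A>G"))
  expect_error(assemble_genotypes(three), "more than 2 calls")
})

test_that("the derived threshold is 0.58 on the cohort with strict separation", {
  co <- fixture_cohort()
  thr <- derive_threshold(co)
  expect_equal(as.numeric(thr), 0.58)
  expect_equal(attr(thr, "max_het_af"), 0.56)

  # the threshold equals the 4th-smallest single-variant fraction
  singles <- co |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  expect_equal(as.numeric(thr), sort(singles$allele_fraction)[4])

  # strict separation among single-variant records under the derived rule
  z <- call_zygosity(singles$allele_fraction, as.numeric(thr))
  expect_lt(max(singles$allele_fraction[z == "het"]),
            min(singles$allele_fraction[z == "hom"]))
  # the only call anywhere contradicting the bi-allelic model is patient 7's
  inc <- attr(thr, "inconsistent_calls")
  expect_equal(inc$patient_id, 7L)
})

test_that("threshold derivation is order-invariant and errors without separation", {
  co <- fixture_cohort()
  shuffled <- co[sample.int(nrow(co)), ]
  expect_equal(as.numeric(derive_threshold(shuffled)),
               as.numeric(derive_threshold(co)))

  # perfect separation: all singles at 1.0, all doubles at 0.5
  toy <- tibble::tibble(
    patient_id = c(1, 2, 3, 3, 4, 4),
    allele_fraction = c(1, 1, 0.5, 0.5, 0.5, 0.5)
  )
  expect_equal(as.numeric(derive_threshold(toy)), 1)

  # an unexplained single above every other single fraction: no valid cutoff
  bad <- tibble::tibble(
    patient_id = c(1, 2),
    allele_fraction = c(0.9, 0.5),
    explained = c(FALSE, TRUE)
  )
  expect_error(derive_threshold(bad), "no valid separating value")
  expect_error(derive_threshold(toy[3:6, ]), "no single-variant patients")
})

test_that("a derived threshold separates simulated truth perfectly when centres are wide", {
  cfg <- sim_config(af_center_hom = 0.95, af_center_het = 0.35,
                    af_concentration = 200)
  sc <- simulate_cohort(200, config = cfg, seed = 11)
  thr <- derive_threshold(sc)
  called <- call_zygosity(sc$allele_fraction, as.numeric(thr))
  expect_equal(mean(called == sc$true_zygosity), 1)
})

test_that("pileup calling filters on depth and fraction with a drop log", {
  obs <- tibble::tibble(
    depth = c(49L, 50L, 600L, 700L),
    alt_count = c(30L, 30L, 60L, 200L)
  )
  out <- pileup_call(obs, min_depth = 50, min_af = 0.15)
  expect_equal(out$depth, c(50L, 700L))  # 600x call has af 0.1 < 0.15
  expect_equal(out$zygosity, c("hom", "het"))
  dropped <- attr(out, "dropped")
  expect_equal(nrow(dropped), 2L)
  expect_setequal(dropped$drop_reason,
                  c("depth below min_depth", "af below min_af"))
})

test_that("deep homozygous pileups are recalled as hom at >= 95%", {
  set.seed(17)
  cfg <- sim_config(depth_min = 500)
  x <- simulate_pileup(rep("hom", 1000), cfg)
  out <- pileup_call(x, min_depth = 50, min_af = 0.15)
  expect_gte(mean(out$zygosity == "hom") * nrow(out) / 1000, 0.95)
})
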