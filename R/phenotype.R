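#' Allelic phenotype value (APV) lookup table
#'
#' Extracts the per-variant APV (a 0-10 severity score, 0 most severe,
#' taken from the BioPKU resource and transcribed with the cohort) as a
#' lookup table keyed by the canonical `c.` string. Variants whose APV is
#' never stated stay out of the table and later yield "unpredictable"
#' phenotypes rather than a default severity.
#'
#' @param cohort Cohort tibble with `variant_key` and `apv` columns
#'   (default: the packaged cohort).
#' @return Tibble with `variant` (canonical key) and `apv`, one row per
#'   variant with a known value.
#' @export
apv_table <- function(cohort = pku_cohort()) {
  tab <- cohort |>
    dplyr::filter(!is.na(.data$apv)) |>
    dplyr::distinct(variant = .data$variant_key, .data$apv)
  conflicts <- dplyr::count(tab, .data$variant) |> dplyr::filter(.data$n > 1)
  if (nrow(conflicts)) {
    abort(paste0("conflicting APV values for: ",
                 paste(conflicts$variant, collapse = ", ")))
  }
  dplyr::arrange(tab, .data$variant)
}

#' Genotypic phenotype value from an APV pair
#'
#' The genotype-level severity score is the maximum of the two allelic
#' values (the milder allele determines residual enzyme activity in a
#' recessive disease). A missing APV on either allele makes the genotype
#' unpredictable (`NA`), never a number.
#'
#' @param apv_a,apv_b Numeric APVs in `[0, 10]` (vectors recycle).
#' @return Numeric vector of GPVs, `NA` where either APV is missing.
#' @examples
#' gpv(1.5, 0)
#' @export
gpv <- function(apv_a, apv_b) {
  ok <- c(apv_a, apv_b)
  if (any(ok < 0 | ok > 10, na.rm = TRUE)) abort("APV values must lie in [0, 10]")
  pmax(apv_a, apv_b)
}

#' Classify a GPV into a predicted PKU type
#'
#' Bins the genotypic phenotype value: 0-2.7 classic PKU, 2.8-6.6 mild
#' PKU, 6.7-10.0 mild hyperphenylalaninemia. Values falling in the gaps
#' between bins are rounded to one decimal first, so the bins tile
#' `[0, 10]`.
#'
#' @param x Numeric GPVs in `[0, 10]` (`NA` passes through).
#' @return Character vector of `"classic_PKU"`, `"mild_PKU"`, `"mild_HPA"`.
#' @examples
#' classify_gpv(c(0, 2, 6.8))
#' @export
classify_gpv <- function(x) {
  if (any(x < 0 | x > 10, na.rm = TRUE)) abort("GPV must lie in [0, 10]")
  r <- round_half_up(x, 1)
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r <= 2.7 ~ "classic_PKU",
    r <= 6.6 ~ "mild_PKU",
    TRUE ~ "mild_HPA"
  )
}

#' Clinical PKU type from pre-treatment phenylalanine
#'
#' The two-class clinical scheme: classic PKU above 1200 micromol/L, mild
#' PKU at 600-1200 micromol/L (both bounds inclusive). Values below 600
#' are outside the scheme and raise an error; qualitative Phe markers are
#' not numbers and must be handled by the caller (the recorded clinical
#' label is used for such patients).
#'
#' @param phe_umol Numeric pre-treatment Phe in micromol/L.
#' @return Character vector of `"cPKU"`/`"mPKU"`.
#' @examples
#' phe_to_clinical(c(2400, 1074, 1200))
#' @export
phe_to_clinical <- function(phe_umol) {
  if (any(is.na(phe_umol))) {
    abort("qualitative or missing Phe entries cannot be classified; use the recorded label")
  }
  if (any(phe_umol < 600)) {
    abort("Phe below 600 micromol/L is outside the two-class scheme")
  }
  ifelse(phe_umol > 1200, "cPKU", "mPKU")
}

#' Predict phenotype from genotype profiles
#'
#' Maps each patient's assembled genotype to an APV pair and a GPV:
#' homozygous profiles duplicate their variant's APV; compound-heterozygous
#' profiles pair their two variants' APVs; single-heterozygous profiles are
#' unpredictable (one allele is unexplained), matching how such patients
#' are reported. Variants absent from the APV table also make the genotype
#' unpredictable.
#'
#' @param cohort Cohort tibble (one row per call).
#' @param threshold Homozygosity cutoff.
#' @param apv APV lookup from [apv_table()].
#' @return Tibble with one row per patient: `patient_id`, `category`,
#'   `apv_a`, `apv_b`, `gpv`, `predicted_type` (`NA` = unpredictable).
#' @export
predict_phenotype <- function(cohort, threshold = 0.58, apv = apv_table()) {
  profiles <- assemble_genotypes(cohort, threshold)
  lut <- setNames(apv$apv, apv$variant)
  per_patient <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      v1 = .data$variant_key[1],
      v2 = if (dplyr::n() == 2) .data$variant_key[2] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::left_join(profiles[c("patient_id", "category")], by = "patient_id")
  out <- per_patient |>
    dplyr::mutate(
      apv_a = unname(lut[.data$v1]),
      apv_b = dplyr::case_when(
        .data$category == "homozygous" ~ unname(lut[.data$v1]),
        .data$category == "compound_heterozygous" ~ unname(lut[.data$v2]),
        TRUE ~ NA_real_
      ),
      apv_a = ifelse(.data$category == "single_heterozygous", NA_real_, .data$apv_a),
      gpv = gpv(.data$apv_a, .data$apv_b),
      predicted_type = classify_gpv(.data$gpv)
    )
  out[c("patient_id", "category", "apv_a", "apv_b", "gpv", "predicted_type")]
}

#' Recompute each patient's GPV from the transcribed APV pair
#'
#' Applies the GPV-is-the-maximum rule to the APV pair exactly as recorded
#' per patient (two-call patients pair their two per-call values;
#' single-call patients duplicate theirs, as the source table does),
#' independent of the zygosity threshold. Used to audit the recorded GPV
#' column against the rule.
#'
#' @param cohort Cohort tibble with per-call `apv` and per-patient `gpv`
#'   columns.
#' @return Tibble with `patient_id`, `apv_a`, `apv_b`, `gpv_recomputed`,
#'   `gpv_recorded`, `agrees`.
#' @export
recompute_gpv <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      apv_a = .data$apv[1],
      apv_b = if (dplyr::n() == 2) .data$apv[2] else .data$apv[1],
      gpv_recorded = .data$gpv[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gpv_recomputed = gpv(.data$apv_a, .data$apv_b),
      agrees = .data$gpv_recomputed == .data$gpv_recorded
    )
}

#' Concordance between predicted and recorded labels
#'
#' Counts agreement between two label vectors under an explicit mapping
#' declaring which (predicted, recorded) pairs count as concordant; the
#' mapping is echoed in the result so the rule is never implicit. Pairs
#' with a missing label on either side are excluded from the evaluable
#' set.
#'
#' @param predicted,recorded Character label vectors of equal length.
#' @param mapping Named list: names are predicted labels, values the
#'   character vectors of recorded labels concordant with them. The
#'   default maps clinical `cPKU` to BioPKU `classic` and clinical `mPKU`
#'   to BioPKU `mild` and `mild_hpa`.
#' @return A list of class `pah_concordance`: `n_concordant`,
#'   `n_evaluable`, `rate` (`NA` when nothing is evaluable, with a
#'   warning), `mapping`.
#' @export
concordance <- function(predicted, recorded,
                        mapping = list(cPKU = "classic",
                                       mPKU = c("mild", "mild_hpa"))) {
  stopifnot(length(predicted) == length(recorded))
  keep <- !is.na(predicted) & !is.na(recorded)
  p <- predicted[keep]; r <- recorded[keep]
  unmapped_p <- setdiff(unique(p), names(mapping))
  unmapped_r <- setdiff(unique(r), unlist(mapping))
  if (length(unmapped_p) || length(unmapped_r)) {
    abort(paste0("labels missing from the concordance mapping: ",
                 paste(c(unmapped_p, unmapped_r), collapse = ", ")))
  }
  hits <- vapply(seq_along(p), function(i) r[i] %in% mapping[[p[i]]],
                 logical(1))
  n_eval <- length(p)
  n_conc <- sum(hits)
  if (n_eval == 0) {
    warn("no evaluable (predicted, recorded) pairs")
  }
  structure(
    list(n_concordant = n_conc, n_evaluable = n_eval,
         rate = if (n_eval > 0) n_conc / n_eval else NA_real_,
         mapping = mapping),
    class = "pah_concordance"
  )
}

#' @export
print.pah_concordance <- function(x, ...) {
  cat("Concordance:", x$n_concordant, "/", x$n_evaluable,
      if (!is.na(x$rate)) sprintf("(%.1f%%)", 100 * x$rate) else "(undefined)", "\n")
  cat("Mapping:\n")
  for (nm in names(x$mapping)) {
    cat("  ", nm, "<->", paste(x$mapping[[nm]], collapse = ", "), "\n")
  }
  invisible(x)
}
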