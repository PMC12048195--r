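cohort_required_cols <- c(
  "patient_id", "phe_pretreatment", "clinical_type", "sex", "birth_year",
  "consanguinity", "variant", "depth", "allele_fraction"
)

cohort_col_types <- readr::cols(
  patient_id = readr::col_integer(),
  phe_pretreatment = readr::col_character(),
  clinical_type = readr::col_character(),
  sex = readr::col_character(),
  birth_year = readr::col_integer(),
  consanguinity = readr::col_character(),
  variant = readr::col_character(),
  depth = readr::col_integer(),
  allele_fraction = readr::col_double(),
  acmg_codes = readr::col_character(),
  acmg_class = readr::col_character(),
  apv = readr::col_double(),
  gpv = readr::col_double(),
  biopku_type = readr::col_character(),
  biopku_votes = readr::col_character()
)

#' Load a PKU cohort table
#'
#' Reads a tab-separated cohort table with one row per (patient, variant)
#' call; patient-level fields (Phe level, clinical type, sex, birth year,
#' consanguinity, GPV, BioPKU type) are repeated on each of a patient's
#' rows. Qualitative pre-treatment Phe entries are kept as the markers
#' `"guthrie_gt_8mgdl"` (historical Guthrie screen, > 8 mg/dL) and
#' `"not_determined"`; they are never converted to micromol/L. Every HGVS
#' string is parsed on load and the canonical `c.` key added as
#' `variant_key`.
#'
#' @param path Path to a tab-separated cohort file.
#' @return A tibble with one row per variant call.
#' @seealso [pku_cohort()] for the packaged 40-patient cohort,
#'   [write_cohort()] for the inverse.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("no such cohort file: ", path))
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = cohort_col_types, na = "NA",
                    progress = FALSE)
  )
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0("malformed cohort file ", path, ": ",
                 paste0("row ", prob$row, " (", prob$expected, ")", collapse = "; ")))
  }
  missing_cols <- setdiff(cohort_required_cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("cohort file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort(paste0("cohort file has no data rows: ", path))
  validate_cohort(x)
}

validate_cohort <- function(x) {
  dup <- which(duplicated(x[c("patient_id", "variant")]))
  if (length(dup)) {
    abort(paste0("duplicate (patient, variant) rows at data row(s): ",
                 paste(dup, collapse = ", ")))
  }
  per_patient <- dplyr::count(x, .data$patient_id)
  too_many <- dplyr::filter(per_patient, .data$n > 2)
  if (nrow(too_many)) {
    abort(paste0("more than 2 variants for patient(s): ",
                 paste(too_many$patient_id, collapse = ", ")))
  }
  if (any(is.na(x$depth)) || any(x$depth < 1)) abort("depth must be >= 1 for every call")
  if (any(is.na(x$allele_fraction)) || any(x$allele_fraction < 0 | x$allele_fraction > 1)) {
    abort("allele_fraction must lie in [0, 1]")
  }
  if ("apv" %in% names(x) && any(!is.na(x$apv) & (x$apv < 0 | x$apv > 10))) {
    abort("APV values must lie in [0, 10]")
  }
  if (any(is.na(x$clinical_type))) abort("clinical_type must be present for every record")
  x$variant_key <- variant_key(x$variant)
  as_tibble(x)
}

#' The packaged 40-patient PKU cohort
#'
#' A transcription of the published 40-patient PAH amplicon-sequencing
#' cohort: pre-treatment Phe, clinical PKU type, demographics,
#' consanguinity, and per-variant ONT calls (HGVS description, read depth,
#' observed allele fraction, ACMG evidence codes, APV) together with the
#' reported per-patient GPV and majority BioPKU class. Decimal commas in
#' APV cells were normalised to points at transcription; `NA` encodes the
#' table's "N/A" entries.
#'
#' @return A tibble with 57 variant-call rows covering 40 patients.
#' @export
pku_cohort <- function() {
  load_cohort(system.file("extdata", "pku_cohort.tsv", package = "pahpanel",
                          mustWork = TRUE))
}

#' Write a cohort table
#'
#' Inverse of [load_cohort()]: writes tab-separated text with `NA` for
#' missing fields, dropping the derived `variant_key` column, so that a
#' write/load round trip reproduces the cohort exactly.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[setdiff(names(cohort), "variant_key")]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Patient-level view of a cohort
#'
#' Collapses the one-row-per-call cohort to one row per patient, keeping the
#' repeated demographic fields and adding the number of calls.
#'
#' @param cohort Cohort tibble from [load_cohort()] or [simulate_cohort()].
#' @return A tibble with one row per patient.
#' @export
cohort_patients <- function(cohort) {
  keep <- intersect(
    c("patient_id", "phe_pretreatment", "clinical_type", "sex", "birth_year",
      "consanguinity", "gpv", "biopku_type", "biopku_votes", "true_category",
      "explained"),
    names(cohort)
  )
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(n_calls = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(keep, "n_calls"))))
}

#' Numeric pre-treatment Phe
#'
#' Converts the cohort's `phe_pretreatment` column to micromol/L numbers;
#' the qualitative markers (`"guthrie_gt_8mgdl"`, `"not_determined"`) become
#' `NA` because no conversion factor to micromol/L is defined for them.
#'
#' @param x Character vector of Phe entries.
#' @return Numeric vector (micromol/L).
#' @export
phe_numeric <- function(x) {
  suppressWarnings(as.numeric(x))
}
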