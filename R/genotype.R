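#' Classify zygosity from an observed allele fraction
#'
#' ONT allele fractions shrink systematically towards intermediate values,
#' so homozygosity is called from a data-derived cutoff rather than the
#' naive 1.0: a call is homozygous iff its allele fraction is greater than
#' or equal to `threshold` (inclusive), heterozygous otherwise.
#'
#' @param allele_fraction Numeric vector in `[0, 1]`.
#' @param threshold Homozygosity cutoff (default 0.58, the value derived
#'   from the packaged cohort; see [derive_threshold()]).
#' @return Character vector of `"hom"`/`"het"`.
#' @examples
#' call_zygosity(c(0.56, 0.58, 1, 0))
#' @export
call_zygosity <- function(allele_fraction, threshold = 0.58) {
  if (any(is.na(allele_fraction)) ||
      any(allele_fraction < 0 | allele_fraction > 1)) {
    abort("allele_fraction must lie in [0, 1]")
  }
  ifelse(allele_fraction >= threshold, "hom", "het")
}

#' Per-call zygosity for a cohort
#'
#' Adds a `zygosity` column to a one-row-per-call cohort tibble.
#'
#' @inheritParams call_zygosity
#' @param cohort Cohort tibble with an `allele_fraction` column.
#' @return The cohort with a `zygosity` column.
#' @export
classify_calls <- function(cohort, threshold = 0.58) {
  cohort$zygosity <- call_zygosity(cohort$allele_fraction, threshold)
  cohort
}

#' Assemble patient-level genotype profiles
#'
#' Combines each patient's 1-2 classified calls into a genotype category:
#' one homozygous call explains both alleles (`homozygous`); two
#' heterozygous calls explain them in trans (`compound_heterozygous`; the
#' assay performs no phasing, so the trans configuration is an assumption,
#' flagged in `assumed_trans`); one heterozygous call leaves the second
#' allele unexplained (`single_heterozygous`, `explained = FALSE`). A
#' two-call profile in which any fraction is hom-classified would imply
#' three or more pathogenic alleles; such profiles keep the
#' compound-heterozygous category but are flagged `inconsistent` rather
#' than raising an error, so batch runs stay alive.
#'
#' @param cohort Cohort tibble (one row per call) with `patient_id` and
#'   `allele_fraction`.
#' @param threshold Homozygosity cutoff on allele fraction.
#' @return Tibble with one row per patient: `patient_id`, `category`,
#'   `n_calls`, `explained`, `inconsistent`, `assumed_trans`.
#' @export
assemble_genotypes <- function(cohort, threshold = 0.58) {
  calls <- classify_calls(cohort, threshold)
  bad <- dplyr::count(calls, .data$patient_id) |> dplyr::filter(.data$n > 2)
  if (nrow(bad)) {
    abort(paste0("patients with more than 2 calls: ",
                 paste(bad$patient_id, collapse = ", ")))
  }
  calls |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      n_hom = sum(.data$zygosity == "hom"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = dplyr::case_when(
        .data$n_calls == 1 & .data$n_hom == 1 ~ "homozygous",
        .data$n_calls == 2 ~ "compound_heterozygous",
        TRUE ~ "single_heterozygous"
      ),
      inconsistent = .data$n_calls == 2 & .data$n_hom > 0,
      explained = .data$category != "single_heterozygous",
      assumed_trans = .data$category == "compound_heterozygous"
    ) |>
    dplyr::select("patient_id", "category", "n_calls", "explained",
                  "inconsistent", "assumed_trans")
}

#' Derive the homozygosity threshold from a cohort
#'
#' Finds the smallest observed allele fraction that can be called
#' homozygous. Only single-variant records are candidates (a patient with
#' two listed variants carries each on one allele, so neither call can be
#' homozygous); among the single-variant records, those whose genotype is
#' recorded as not disease-explaining (no genotypic phenotype value) must
#' stay heterozygous. The threshold is the smallest single-variant fraction
#' strictly above the largest must-stay-heterozygous fraction - the
#' maximal-separation choice. Calls of two-variant patients at or above the
#' derived cutoff contradict the bi-allelic model; they are reported in the
#' `"inconsistent_calls"` attribute instead of moving the cutoff.
#'
#' @param cohort Cohort tibble. If an `explained` logical column is present
#'   (simulated cohorts carry one) it marks disease-explained records;
#'   otherwise a missing `gpv` marks a record as unexplained.
#' @return The threshold as a single number of class `pah_threshold`, with
#'   attributes `n_single` (candidate records), `max_het_af` (largest
#'   fraction constrained heterozygous, `-Inf` when unconstrained) and
#'   `inconsistent_calls`.
#' @examples
#' derive_threshold(pku_cohort())
#' @export
derive_threshold <- function(cohort) {
  explained <- if ("explained" %in% names(cohort)) {
    cohort$explained
  } else if ("gpv" %in% names(cohort)) {
    !is.na(cohort$gpv)
  } else {
    rep(TRUE, nrow(cohort))
  }
  x <- cohort |>
    dplyr::mutate(.explained = explained) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.n_calls = dplyr::n()) |>
    dplyr::ungroup()
  singles <- dplyr::filter(x, .data$.n_calls == 1)
  if (nrow(singles) == 0) {
    abort("cannot derive a threshold: cohort has no single-variant patients")
  }
  must_het <- singles$allele_fraction[!singles$.explained]
  floor_af <- if (length(must_het)) max(must_het) else -Inf
  candidates <- sort(singles$allele_fraction)
  above <- candidates[candidates > floor_af]
  if (!length(above)) {
    abort(paste0("no valid separating value: every single-variant fraction is <= ",
                 "the largest must-stay-heterozygous fraction (", floor_af, ")"))
  }
  thr <- min(above)
  doubles <- dplyr::filter(x, .data$.n_calls == 2, .data$allele_fraction >= thr)
  structure(
    thr, class = "pah_threshold",
    n_single = nrow(singles), max_het_af = floor_af,
    inconsistent_calls = doubles[intersect(
      c("patient_id", "variant", "variant_key", "allele_fraction"),
      names(doubles))]
  )
}

#' @export
print.pah_threshold <- function(x, ...) {
  cat("Homozygosity threshold (allele fraction >=):", as.numeric(x), "\n")
  cat("  derived from", attr(x, "n_single"), "single-variant records;",
      "largest constrained-heterozygous fraction:", attr(x, "max_het_af"), "\n")
  inc <- attr(x, "inconsistent_calls")
  if (!is.null(inc) && nrow(inc)) {
    cat("  note:", nrow(inc), "call(s) of two-variant patients reach the",
        "cutoff (flagged inconsistent):",
        paste0("patient ", inc$patient_id, " (", inc$allele_fraction, ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call variants from simulated pileups
#'
#' The naive pileup caller used to exercise the pipeline on simulated
#' data (it stands in for the assay's external basecalling/alignment/
#' calling chain, which is out of scope here): an observation becomes a
#' call when its depth reaches `min_depth` and its observed fraction
#' reaches `min_af`; zygosity is then assigned with [call_zygosity()].
#' Filtered observations are kept in the `"dropped"` attribute with the
#' reason, not discarded silently.
#'
#' @param observations Tibble with `depth` and `observed_af` (or
#'   `alt_count`, from which the fraction is computed), e.g. from
#'   [simulate_pileup()].
#' @param min_depth Minimum read depth (default 50, the depth regarded as
#'   adequate for molecular analysis of the assay).
#' @param min_af Minimum observed allele fraction (default 0.15, just below
#'   the smallest fraction retained in the cohort, 0.18).
#' @param threshold Homozygosity cutoff.
#' @return The emitted observations with a `zygosity` column; dropped rows
#'   (with a `drop_reason` column) in the `"dropped"` attribute.
#' @export
pileup_call <- function(observations, min_depth = 50L, min_af = 0.15,
                        threshold = 0.58) {
  stopifnot(min_depth >= 1)
  obs <- observations
  if (!"observed_af" %in% names(obs)) {
    obs$observed_af <- obs$alt_count / obs$depth
  }
  keep <- obs$depth >= min_depth & obs$observed_af >= min_af
  dropped <- obs[!keep, ]
  dropped$drop_reason <- ifelse(dropped$depth < min_depth,
                                "depth below min_depth", "af below min_af")
  out <- obs[keep, ]
  out$zygosity <- call_zygosity(out$observed_af, threshold)
  structure(out, dropped = dropped)
}
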