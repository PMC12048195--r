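normalize_variant_key <- function(variant) {
  if (grepl("^c\\.", variant)) variant else variant_key(variant)
}

consanguineous_levels <- c("first_degree_cousin", "second_degree_cousin",
                           "third_degree_cousin", "yes_unknown_degree")

#' Patient frequency of a variant
#'
#' Counts the patients carrying at least one call of the variant,
#' regardless of zygosity, and the percentage of the cohort.
#'
#' @param cohort Cohort tibble.
#' @param variant Variant as canonical `c.` key or full HGVS string.
#' @return One-row tibble: `variant`, `n_carriers`, `percent`.
#' @examples
#' variant_patient_frequency(pku_cohort(), "c.1066-11G>A")
#' @export
variant_patient_frequency <- function(cohort, variant) {
  key <- normalize_variant_key(variant)
  n_patients <- dplyr::n_distinct(cohort$patient_id)
  n <- dplyr::n_distinct(cohort$patient_id[cohort$variant_key == key])
  tibble(variant = key, n_carriers = n,
         percent = if (n == 0) 0 else percent_of(n, n_patients))
}

#' Zygosity breakdown of a variant's carriers
#'
#' Partitions a variant's carriers by their patient-level genotype
#' category: homozygous for the variant, carrying it within a
#' compound-heterozygous genotype, or left single-heterozygous.
#'
#' @inheritParams variant_patient_frequency
#' @param threshold Homozygosity cutoff on allele fraction.
#' @return One-row tibble: `variant`, `n_hom`, `n_compound_het`,
#'   `n_single_het`.
#' @export
zygosity_breakdown <- function(cohort, variant, threshold = 0.58) {
  key <- normalize_variant_key(variant)
  profiles <- assemble_genotypes(cohort, threshold)
  carriers <- unique(cohort$patient_id[cohort$variant_key == key])
  cat_tab <- table(factor(
    profiles$category[profiles$patient_id %in% carriers],
    levels = c("homozygous", "compound_heterozygous", "single_heterozygous")
  ))
  tibble(variant = key,
         n_hom = unname(cat_tab[["homozygous"]]),
         n_compound_het = unname(cat_tab[["compound_heterozygous"]]),
         n_single_het = unname(cat_tab[["single_heterozygous"]]))
}

#' Cohort demographics
#'
#' Sex and clinical-type tallies over all patients, and consanguinity over
#' the evaluable patients only: records whose consanguinity is unknown are
#' excluded from the denominator, while "consanguineous, degree unknown"
#' counts as consanguineous.
#'
#' @param cohort Cohort tibble.
#' @return Long tibble with `statistic`, `level`, `n`, `n_evaluable`,
#'   `percent`.
#' @export
demographics <- function(cohort) {
  p <- cohort_patients(cohort)
  n_pat <- nrow(p)
  tally <- function(col) {
    if (!col %in% names(p)) return(NULL)
    p |>
      dplyr::count(level = .data[[col]]) |>
      dplyr::mutate(statistic = col, n_evaluable = .env$n_pat,
                    percent = percent_of(.data$n, .env$n_pat))
  }
  cons <- NULL
  if ("consanguinity" %in% names(p)) {
    known <- p$consanguinity[p$consanguinity != "unknown"]
    n_yes <- sum(known %in% consanguineous_levels)
    cons <- tibble(
      level = "consanguineous", n = n_yes, statistic = "consanguinity",
      n_evaluable = length(known),
      percent = percent_of(n_yes, length(known))
    )
  }
  out <- dplyr::bind_rows(tally("sex"), tally("clinical_type"), cons)
  if (nrow(out) == 0) {
    return(tibble(statistic = character(), level = character(), n = integer(),
                  n_evaluable = integer(), percent = numeric()))
  }
  out[c("statistic", "level", "n", "n_evaluable", "percent")]
}

#' Allele frequency of a variant over the cohort
#'
#' Standard allele counting over `2 n` chromosomes: a homozygous carrier
#' contributes two copies, any heterozygous carrier one.
#'
#' @inheritParams zygosity_breakdown
#' @return Single numeric allele frequency.
#' @examples
#' allele_frequency(pku_cohort(), "c.1066-11G>A")
#' @export
allele_frequency <- function(cohort, variant, threshold = 0.58) {
  bd <- zygosity_breakdown(cohort, variant, threshold)
  n_patients <- dplyr::n_distinct(cohort$patient_id)
  if (n_patients == 0) return(0)
  (2 * bd$n_hom + bd$n_compound_het + bd$n_single_het) / (2 * n_patients)
}

#' Depth range over all calls
#'
#' @param cohort Cohort tibble with a `depth` column.
#' @return One-row tibble: `min_depth`, `max_depth`.
#' @export
depth_summary <- function(cohort) {
  tibble(min_depth = min(cohort$depth), max_depth = max(cohort$depth))
}

#' Summarise a cohort
#'
#' Assembles every cohort-level figure the assay reports: per-variant
#' patient counts, percentages, zygosity breakdowns and allele
#' frequencies; genotype-category totals; sex, clinical-type and
#' consanguinity tallies; and the depth range. Internal consistency is
#' asserted (per-variant zygosity partitions sum to the carrier count;
#' genotype categories sum to the patient count) so a violated invariant
#' is an error, not a silent misreport.
#'
#' @param cohort Cohort tibble.
#' @param threshold Homozygosity cutoff on allele fraction.
#' @return A list of class `pku_cohort_summary` with elements
#'   `n_patients`, `threshold`, `variants` (per-variant tibble),
#'   `genotype_categories`, `demographics`, `depth`.
#' @examples
#' summarize_cohort(pku_cohort())
#' @export
summarize_cohort <- function(cohort, threshold = 0.58) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    return(structure(
      list(n_patients = 0L, threshold = threshold,
           variants = tibble(), genotype_categories = tibble(),
           demographics = tibble(), depth = tibble(min_depth = NA, max_depth = NA)),
      class = "pku_cohort_summary"
    ))
  }
  n_patients <- dplyr::n_distinct(cohort$patient_id)
  keys <- cohort |> dplyr::count(.data$variant_key, sort = TRUE)
  variants <- purrr::map_dfr(keys$variant_key, function(k) {
    freq <- variant_patient_frequency(cohort, k)
    bd <- zygosity_breakdown(cohort, k, threshold)
    dplyr::bind_cols(freq, bd[c("n_hom", "n_compound_het", "n_single_het")]) |>
      dplyr::mutate(allele_frequency = allele_frequency(cohort, k, threshold))
  })
  stopifnot(all(variants$n_hom + variants$n_compound_het + variants$n_single_het ==
                  variants$n_carriers))
  profiles <- assemble_genotypes(cohort, threshold)
  cats <- profiles |>
    dplyr::count(category = factor(.data$category, levels = c(
      "homozygous", "compound_heterozygous", "single_heterozygous"
    )), .drop = FALSE, name = "n") |>
    dplyr::mutate(category = as.character(.data$category),
                  percent = percent_of(.data$n, n_patients))
  stopifnot(sum(cats$n) == n_patients)
  structure(
    list(n_patients = n_patients, threshold = as.numeric(threshold),
         variants = variants, genotype_categories = cats,
         demographics = demographics(cohort), depth = depth_summary(cohort)),
    class = "pku_cohort_summary"
  )
}

#' @export
print.pku_cohort_summary <- function(x, ...) {
  cat("PKU cohort summary -", x$n_patients, "patients",
      sprintf("(homozygosity at allele fraction >= %.2f)\n", x$threshold))
  if (x$n_patients == 0) return(invisible(x))
  cat("\nGenotype categories:\n")
  for (i in seq_len(nrow(x$genotype_categories))) {
    cat(sprintf("  %-22s %2d (%.1f%%)\n", x$genotype_categories$category[i],
                x$genotype_categories$n[i], x$genotype_categories$percent[i]))
  }
  cat("\nMost frequent variants:\n")
  top <- head(x$variants, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-16s %2d/%d patients (%.1f%%), AF %.4f [%d hom / %d cmpd het / %d single het]\n",
                top$variant[i], top$n_carriers[i], x$n_patients, top$percent[i],
                top$allele_frequency[i], top$n_hom[i], top$n_compound_het[i],
                top$n_single_het[i]))
  }
  d <- x$demographics
  cat("\nDemographics:\n")
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-14s %-14s %2d/%d (%.1f%%)\n", d$statistic[i], d$level[i],
                d$n[i], d$n_evaluable[i], d$percent[i]))
  }
  cat(sprintf("\nPer-call depth: %d-%dx\n", x$depth$min_depth, x$depth$max_depth))
  invisible(x)
}

percent_of_cohort <- function(summary, category) {
  g <- summary$genotype_categories
  g$percent[g$category == category]
}
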