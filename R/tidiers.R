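#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary into a per-variant tibble
#'
#' @param x A `pku_cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return The per-variant tibble (`variant`, `n_carriers`, `percent`,
#'   zygosity breakdown, `allele_frequency`).
#' @export
tidy.pku_cohort_summary <- function(x, ...) {
  x$variants
}

#' One-row overview of a cohort summary
#'
#' @inheritParams tidy.pku_cohort_summary
#' @return A one-row tibble: patient count, threshold, genotype-category
#'   percentages and the depth range.
#' @export
glance.pku_cohort_summary <- function(x, ...) {
  g <- setNames(x$genotype_categories$percent, x$genotype_categories$category)
  tibble(
    n_patients = x$n_patients,
    n_variants = nrow(x$variants),
    threshold = x$threshold,
    pct_homozygous = unname(g["homozygous"]),
    pct_compound_het = unname(g["compound_heterozygous"]),
    pct_single_het = unname(g["single_heterozygous"]),
    min_depth = x$depth$min_depth,
    max_depth = x$depth$max_depth
  )
}

#' Tidy a derived homozygosity threshold
#'
#' @param x A `pah_threshold` from [derive_threshold()].
#' @param ... Unused.
#' @return A one-row tibble: `threshold`, `n_single`, `max_het_af`,
#'   `n_inconsistent_calls`.
#' @export
tidy.pah_threshold <- function(x, ...) {
  tibble(
    threshold = as.numeric(x),
    n_single = attr(x, "n_single"),
    max_het_af = attr(x, "max_het_af"),
    n_inconsistent_calls = nrow(attr(x, "inconsistent_calls"))
  )
}

#' Tidy a concordance result
#'
#' @param x A `pah_concordance` from [concordance()].
#' @param ... Unused.
#' @return A one-row tibble: `n_concordant`, `n_evaluable`, `rate`.
#' @export
glance.pah_concordance <- function(x, ...) {
  tibble(n_concordant = x$n_concordant, n_evaluable = x$n_evaluable,
         rate = x$rate)
}
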