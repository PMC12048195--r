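#' Allele fractions by patient with the homozygosity cutoff
#'
#' Dot plot of every call's observed allele fraction, coloured by the
#' zygosity assigned under `threshold`, with the cutoff drawn as a dashed
#' line. The characteristic separation of the assay - heterozygous calls
#' below, homozygous calls at or above the line - is read directly off the
#' panel.
#'
#' @param cohort Cohort tibble.
#' @param threshold Homozygosity cutoff on allele fraction.
#' @return A ggplot object.
#' @export
plot_allele_fractions <- function(cohort, threshold = 0.58) {
  calls <- classify_calls(cohort, threshold)
  ggplot2::ggplot(calls, ggplot2::aes(
    x = factor(.data$patient_id), y = .data$allele_fraction,
    colour = .data$zygosity
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = as.numeric(threshold), linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "patient", y = "observed allele fraction",
                  colour = "zygosity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' Amplicon tiling against the panel's targets
#'
#' Horizontal segment map of the predicted amplicons (with pool colouring
#' when assigned) over the target intervals, for eyeballing coverage and
#' pool layout.
#'
#' @param amplicons Amplicon tibble, e.g. from [enumerate_amplicons()] or
#'   [assign_pools()].
#' @param targets Target tibble from [toy_targets()].
#' @return A ggplot object.
#' @export
plot_amplicon_map <- function(amplicons, targets) {
  amp <- amplicons
  amp$pool_lab <- if ("pool" %in% names(amp)) factor(amp$pool) else factor(1)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = targets,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$kind,
                   yend = .data$kind),
      linewidth = 3, colour = "grey55"
    ) +
    ggplot2::geom_segment(
      data = amp,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$pair,
                   yend = .data$pair, colour = .data$pool_lab),
      linewidth = 2
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "pool") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort summary
#'
#' Bar chart of per-variant patient frequencies, stacked by the carriers'
#' genotype categories.
#'
#' @param object A `pku_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pku_cohort_summary <- function(object, ...) {
  long <- object$variants |>
    tidyr::pivot_longer(c("n_hom", "n_compound_het", "n_single_het"),
                        names_to = "category", values_to = "n") |>
    dplyr::mutate(category = sub("^n_", "", .data$category))
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$variant, -.data$n_carriers), y = .data$n,
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "patients", fill = "zygosity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
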