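#' Simulation configuration for ONT-like pileups
#'
#' Parameters of the pileup simulator. Depth is drawn log-uniformly over
#' `[depth_min, depth_max]`, reflecting the wide per-amplicon depth spread
#' of long-PCR nanopore assays without modelling per-amplicon bias. The
#' variant-supporting read count is beta-binomial: the latent allele
#' fraction is Beta-distributed around the zygosity-specific centre with
#' concentration `af_concentration` (larger = tighter; `Inf` collapses to
#' the centre exactly). The default centres (0.72 homozygous, 0.38
#' heterozygous) are the empirical means of the cohort's observed
#' fractions, encoding the systematic shrinkage of ONT allele fractions
#' away from 1.0/0.5; the default concentration of 40 puts ~95% of
#' simulated homozygous fractions in 0.58-0.86 and heterozygous ones in
#' 0.23-0.53, matching the observed ranges.
#'
#' @param depth_min,depth_max Depth range (reads); defaults 50 and 2000.
#' @param af_center_hom,af_center_het Mean observed allele fraction per
#'   zygosity; must satisfy `0 < het < hom <= 1`.
#' @param af_concentration Beta concentration (overdispersion) parameter.
#' @param seed Optional integer seed stored for convenience.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth_min = 50L, depth_max = 2000L,
                       af_center_hom = 0.72, af_center_het = 0.38,
                       af_concentration = 40, seed = NULL) {
  if (depth_min < 1) abort("depth_min must be >= 1")
  if (depth_max < depth_min) abort("depth_max must be >= depth_min")
  if (!(0 < af_center_het && af_center_het < af_center_hom && af_center_hom <= 1)) {
    abort("allele-fraction centres must satisfy 0 < af_center_het < af_center_hom <= 1")
  }
  if (af_concentration <= 0) abort("af_concentration must be positive")
  structure(
    list(depth_min = as.integer(depth_min), depth_max = as.integer(depth_max),
         af_center_hom = af_center_hom, af_center_het = af_center_het,
         af_concentration = af_concentration, seed = seed),
    class = "sim_config"
  )
}

#' Simulate per-site pileup observations with known zygosity
#'
#' Draws `(depth, alt_count)` pairs for sites of known true zygosity:
#' depth is log-uniform over the configured range and the variant-read
#' count beta-binomial around the zygosity-specific centre (see
#' [sim_config()]). The unit of observation is the pileup summary, which is
#' what amplicon variant reports contain; no read-level sequence is
#' simulated.
#'
#' @param true_zygosity Character vector of `"hom"`/`"het"` truth labels;
#'   recycled to `n`.
#' @param config A [sim_config()].
#' @param n Number of observations (default `length(true_zygosity)`).
#' @return Tibble with `true_zygosity`, `depth`, `alt_count`,
#'   `observed_af`.
#' @export
simulate_pileup <- function(true_zygosity, config = sim_config(),
                            n = length(true_zygosity)) {
  stopifnot(all(true_zygosity %in% c("hom", "het")))
  zyg <- rep_len(true_zygosity, n)
  depth <- pmin(
    config$depth_max,
    as.integer(floor(exp(runif(n, log(config$depth_min),
                               log(config$depth_max + 1)))))
  )
  center <- ifelse(zyg == "hom", config$af_center_hom, config$af_center_het)
  conc <- config$af_concentration
  p <- if (is.infinite(conc)) center else {
    rbeta(n, center * conc, (1 - center) * conc)
  }
  alt <- rbinom(n, depth, p)
  tibble(true_zygosity = zyg, depth = depth, alt_count = alt,
         observed_af = alt / depth)
}

#' Empirical genotype-frequency table of a cohort
#'
#' Tallies the distinct patient genotypes of a cohort (variant keys plus
#' genotype category under the allele-fraction threshold) into a frequency
#' table usable as the sampling distribution of [simulate_cohort()]. With
#' the packaged cohort this reproduces the published marginals, e.g. a
#' 0.375 patient frequency for the most common intronic variant.
#'
#' @param cohort Cohort tibble (default: the packaged cohort).
#' @param threshold Homozygosity threshold on allele fraction.
#' @return Tibble with `variant_a`, `variant_b` (`NA` for single-variant
#'   genotypes), `category` and `freq` (summing to 1).
#' @export
default_genotype_table <- function(cohort = pku_cohort(), threshold = 0.58) {
  profiles <- assemble_genotypes(cohort, threshold)
  calls <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      variant_a = sort(.data$variant_key)[1],
      variant_b = sort(.data$variant_key)[2],
      .groups = "drop"
    ) |>
    dplyr::left_join(profiles[c("patient_id", "category")], by = "patient_id")
  calls |>
    dplyr::count(.data$variant_a, .data$variant_b, .data$category) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::select(-"n")
}

#' Simulate a cohort with known truth labels
#'
#' Draws `n_patients` genotypes from a genotype-frequency table and
#' simulates a pileup for each carried allele: homozygous genotypes get one
#' homozygous pileup for their variant, compound-heterozygous genotypes one
#' heterozygous pileup per variant, single-heterozygous genotypes one
#' heterozygous pileup. The generating truth (`true_zygosity`,
#' `true_category`) and an `explained` flag (two pathogenic alleles
#' accounted for) are stored alongside, so recovery of zygosity and
#' genotype category can be scored exactly.
#'
#' @param n_patients Number of synthetic patients.
#' @param genotype_table Frequency table as from [default_genotype_table()];
#'   frequencies must sum to 1.
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Tibble with one row per simulated call: `patient_id`, `variant`,
#'   `variant_key`, `depth`, `alt_count`, `allele_fraction`,
#'   `true_zygosity`, `true_category`, `explained`.
#' @export
simulate_cohort <- function(n_patients, genotype_table = default_genotype_table(),
                            config = sim_config(), seed = NULL) {
  if (is.null(genotype_table) || nrow(genotype_table) == 0) {
    abort("genotype_table is empty")
  }
  if (abs(sum(genotype_table$freq) - 1) > 1e-8) {
    abort("genotype frequencies must sum to 1")
  }
  with_preserved_seed(seed, {
    idx <- sample.int(nrow(genotype_table), n_patients, replace = TRUE,
                      prob = genotype_table$freq)
    g <- genotype_table[idx, ]
    g$patient_id <- seq_len(n_patients)
    calls <- g |>
      tidyr::pivot_longer(c("variant_a", "variant_b"), values_to = "variant",
                          values_drop_na = TRUE) |>
      dplyr::select("patient_id", "variant", "category")
    calls$true_zygosity <- ifelse(calls$category == "homozygous", "hom", "het")
    pile <- simulate_pileup(calls$true_zygosity, config)
    tibble(
      patient_id = calls$patient_id,
      variant = calls$variant,
      variant_key = calls$variant,
      depth = pile$depth,
      alt_count = pile$alt_count,
      allele_fraction = pile$observed_af,
      true_zygosity = calls$true_zygosity,
      true_category = calls$category,
      explained = calls$category != "single_heterozygous"
    )
  })
}
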