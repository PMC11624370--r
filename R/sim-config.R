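#' Configuration of the synthetic-population generator
#'
#' Collects every knob of the generator in one validated object. Defaults
#' describe the study conditions the package targets: first-lactation cows
#' recorded twice within a 120-185 days-in-milk window, grouped in
#' herd-test-day classes, with trait (co)variances from
#' [default_components()].
#'
#' @param n_founders total founder animals (generation 0).
#' @param n_founder_males number of male founders; the rest are female.
#' @param n_generations number of offspring generations (0 = founders only).
#' @param n_offspring_per_gen animals born per offspring generation.
#' @param female_fraction expected fraction of female offspring.
#' @param n_snps number of biallelic SNP markers.
#' @param maf_range founder minor-allele-frequency range, in (0, 0.5].
#' @param n_herds number of herds.
#' @param test_days_per_herd distinct test dates per herd; each cow is
#'   recorded on `records_per_cow` of them.
#' @param records_per_cow test-day records per cow (>= 2 so permanent
#'   environment and residual are separable).
#' @param components truth (co)variance components
#'   ([covariance_components()]).
#' @param means phenotypic means per trait (added to every record).
#' @param genotyped_fraction fraction of animals carrying genotypes.
#' @param base_birth_years two-element integer vector: founder birth-year
#'   interval; each later generation is born one year after the previous.
#' @param dim_window days-in-milk window records are sampled in.
#' @param seed integer seed driving all sampling.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_founders = 100,
                       n_founder_males = max(2L, round(n_founders / 10)),
                       n_generations = 1,
                       n_offspring_per_gen = n_founders,
                       female_fraction = 0.5,
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       n_herds = 10,
                       test_days_per_herd = 4,
                       records_per_cow = 2,
                       components = default_components(),
                       means = stats::setNames(trait_parameters()$mean,
                                               trait_parameters()$trait),
                       genotyped_fraction = 0.2,
                       base_birth_years = c(2008L, 2017L),
                       dim_window = c(120L, 185L),
                       seed = 1L) {
  stopifnot(
    n_founders >= 2, n_generations >= 0, n_snps >= 1, n_herds >= 1,
    records_per_cow >= 2, test_days_per_herd >= records_per_cow,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    genotyped_fraction >= 0, genotyped_fraction <= 1,
    length(base_birth_years) == 2,
    base_birth_years[1] <= base_birth_years[2],
    length(dim_window) == 2, dim_window[1] >= 5, dim_window[2] <= 305
  )
  if (!inherits(components, "covariance_components")) {
    stop("`components` must be a covariance_components object")
  }
  if (n_generations >= 1 && n_founder_males < 1) {
    stop("at least one male founder is required to breed offspring")
  }
  structure(
    list(
      n_founders = as.integer(n_founders),
      n_founder_males = as.integer(n_founder_males),
      n_generations = as.integer(n_generations),
      n_offspring_per_gen = as.integer(n_offspring_per_gen),
      female_fraction = female_fraction,
      n_snps = as.integer(n_snps),
      maf_range = maf_range,
      n_herds = as.integer(n_herds),
      test_days_per_herd = as.integer(test_days_per_herd),
      records_per_cow = as.integer(records_per_cow),
      components = components,
      means = means,
      genotyped_fraction = genotyped_fraction,
      base_birth_years = as.integer(base_birth_years),
      dim_window = as.integer(dim_window),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}
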