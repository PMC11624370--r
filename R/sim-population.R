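#' Draw from a multivariate normal with a possibly singular covariance
#' @noRd
rmvn_psd <- function(n, Sigma) {
  k <- ncol(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, k))
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Lhalf <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  matrix(stats::rnorm(n * k), n, k) %*% Lhalf
}

#' Simulate a pedigree
#'
#' Founders form generation 0 (no parents). Each later generation is bred
#' by sampling a sire among earlier-born males and a dam among earlier-born
#' females; when no female exists in the pedigree the dam is recorded as
#' unknown (0). Offspring sex is drawn with probability `female_fraction`
#' of being female. Birth years advance one year per generation, so parents
#' are always born before their offspring.
#'
#' @param config a [sim_config()] object.
#' @return A tibble with columns `animal`, `sire`, `dam` (0 = unknown),
#'   `birth_year`, `sex` ("M"/"F"), `generation`, `genotyped`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_founders
  sex <- c(rep("M", config$n_founder_males),
           rep("F", nf - config$n_founder_males))
  ped <- tibble::tibble(
    animal = seq_len(nf),
    sire = 0L, dam = 0L,
    birth_year = as.integer(sample(
      seq(config$base_birth_years[1], config$base_birth_years[2]),
      nf, replace = TRUE)),
    sex = sex,
    generation = 0L
  )
  year0 <- max(ped$birth_year)
  for (g in seq_len(config$n_generations)) {
    males <- ped$animal[ped$sex == "M"]
    females <- ped$animal[ped$sex == "F"]
    if (length(males) == 0) {
      stop("impossible mating structure: no males available in generation ", g)
    }
    n <- config$n_offspring_per_gen
    off <- tibble::tibble(
      animal = max(ped$animal) + seq_len(n),
      sire = as.integer(sample(males, n, replace = TRUE)),
      dam = if (length(females) > 0) {
        as.integer(sample(females, n, replace = TRUE))
      } else 0L,
      birth_year = year0 + g,
      sex = ifelse(stats::runif(n) < config$female_fraction, "F", "M"),
      generation = g
    )
    ped <- dplyr::bind_rows(ped, off)
  }
  ng <- round(config$genotyped_fraction * nrow(ped))
  ped$genotyped <- FALSE
  if (ng > 0) ped$genotyped[sample(nrow(ped), ng)] <- TRUE
  ped
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele frequencies are drawn uniformly within the configured
#' minor-allele-frequency range; founder genotypes are binomial(2, p) per
#' SNP. Each descendant receives one allele sampled from each parent's
#' genotype; an unknown parent transmits an allele drawn from the founder
#' frequencies.
#'
#' @param pedigree tibble as from [simulate_pedigree()].
#' @param config a [sim_config()] object.
#' @return A list with `genotypes` (animals x SNP matrix of 0/1/2, rownames
#'   = animal ids) and `allele_freqs` (founder frequencies).
#' @export
simulate_genotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  n <- nrow(pedigree)
  geno <- matrix(0L, n, m)
  rownames(geno) <- pedigree$animal
  idx <- stats::setNames(seq_len(n), pedigree$animal)
  gamete <- function(parent) {
    if (parent == 0L) {
      stats::rbinom(m, 1L, p)
    } else {
      g <- geno[idx[as.character(parent)], ]
      # heterozygote transmits either allele with probability 1/2
      stats::rbinom(m, 1L, g / 2)
    }
  }
  ord <- order(pedigree$generation, pedigree$animal)
  for (i in ord) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L && pedigree$generation[i] == 0L) {
      geno[i, ] <- stats::rbinom(m, 2L, p)
    } else {
      geno[i, ] <- gamete(s) + gamete(d)
    }
  }
  list(genotypes = geno, allele_freqs = p)
}

#' Simulate true breeding values, herd-test-day and permanent-environment
#' effects
#'
#' Founder breeding values are multivariate normal with the truth genetic
#' covariance; a non-founder is the mean of its known parents plus a
#' Mendelian-sampling deviation with covariance `0.5 * G` when both parents
#' are known, `0.75 * G` with one known parent, and `G` with none. With
#' `inbreeding_adjust = TRUE` the both-known case is scaled by
#' `1 - (F_sire + F_dam) / 2`. Herd-test-day and permanent-environment
#' effects are i.i.d. multivariate normal.
#'
#' @inheritParams simulate_genotypes
#' @param inbreeding_adjust scale Mendelian-sampling variance by parental
#'   inbreeding (requires computing pedigree inbreeding).
#' @return List with `true_bv` (animals x traits, rownames = animal ids),
#'   `true_htd` (tibble: htd key, herd, test_day, one effect column per
#'   trait) and `true_pe` (animals x traits).
#' @export
simulate_true_values <- function(pedigree, config, inbreeding_adjust = FALSE) {
  set.seed(config$seed + 2L)
  cc <- config$components
  G <- cc$G
  k <- length(cc$traits)
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_len(n), pedigree$animal)
  Fcoef <- if (inbreeding_adjust) {
    inbreeding_coefficients(pedigree)$F
  } else rep(0, n)
  bv <- matrix(0, n, k, dimnames = list(pedigree$animal, cc$traits))
  ord <- order(pedigree$generation, pedigree$animal)
  ms_all <- rmvn_psd(n, G)
  for (i in ord) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    nk <- (s != 0L) + (d != 0L)
    pa <- rep(0, k)
    if (s != 0L) pa <- pa + 0.5 * bv[idx[as.character(s)], ]
    if (d != 0L) pa <- pa + 0.5 * bv[idx[as.character(d)], ]
    msvar <- c(1, 0.75, 0.5)[nk + 1L]
    if (nk == 2L && inbreeding_adjust) {
      msvar <- 0.5 * (1 - (Fcoef[idx[as.character(s)]] +
                             Fcoef[idx[as.character(d)]]) / 2)
    }
    bv[i, ] <- pa + sqrt(msvar) * ms_all[i, ]
  }
  nh <- config$n_herds * config$test_days_per_herd
  htd_eff <- rmvn_psd(nh, cc$HTD)
  colnames(htd_eff) <- cc$traits
  true_htd <- dplyr::bind_cols(
    tidyr::expand_grid(herd = seq_len(config$n_herds),
                       test_day = seq_len(config$test_days_per_herd)),
    tibble::as_tibble(htd_eff)
  )
  true_htd$htd <- paste(true_htd$herd, true_htd$test_day, sep = "_")
  pe <- rmvn_psd(n, cc$P)
  dimnames(pe) <- dimnames(bv)
  list(true_bv = bv, true_htd = true_htd, true_pe = pe)
}

#' Simulate herd-test-day phenotype records
#'
#' Cows are the females of the latest generation (all females if there are
#' no offspring generations), assigned to herds at random. Each herd has a
#' schedule of test dates 28 days apart; each cow is recorded on
#' `records_per_cow` consecutive test dates, with its calving date placed
#' so every record falls inside the days-in-milk window. The phenotype of a
#' record is `trait mean + htd + breeding value + permanent environment +
#' residual`, with the residual drawn fresh per record from the truth
#' residual covariance. Fixed-effect truth values are zero: age-at-calving,
#' days-in-milk and year-season classes are carried on the records as
#' nuisance structure for model fitting.
#'
#' @param pedigree tibble from [simulate_pedigree()].
#' @param truth list from [simulate_true_values()].
#' @param config a [sim_config()] object.
#' @param n_cows optional cap on the number of recorded cows.
#' @param cohort which females carry records: the latest generation only
#'   (default) or all females in the pedigree (giving recorded
#'   parent-offspring pairs).
#' @return A tibble with one row per cow-date record.
#' @export
simulate_phenotypes <- function(pedigree, truth, config, n_cows = NULL,
                                cohort = c("last_generation",
                                           "all_females")) {
  cohort <- match.arg(cohort)
  set.seed(config$seed + 3L)
  cc <- config$components
  k <- length(cc$traits)
  gmax <- max(pedigree$generation)
  cows <- if (cohort == "all_females" || gmax == 0L) {
    pedigree$animal[pedigree$sex == "F"]
  } else {
    pedigree$animal[pedigree$sex == "F" & pedigree$generation == gmax]
  }
  if (!is.null(n_cows) && length(cows) > n_cows) cows <- cows[seq_len(n_cows)]
  nc <- length(cows)
  if (nc == 0) stop("no female animals available to record")
  herd <- sample(rep_len(seq_len(config$n_herds), nc))
  r <- config$records_per_cow
  td_first_max <- config$test_days_per_herd - r + 1L
  td_first <- sample.int(td_first_max, nc, replace = TRUE)
  # herd test-date grid: 28 d apart, common origin
  day0 <- as.Date("2021-01-15")
  gap <- 28L
  span <- gap * (r - 1L)
  dim_max1 <- config$dim_window[2] - span
  if (dim_max1 < config$dim_window[1]) {
    stop("dim_window too narrow for records_per_cow at 28-d test spacing")
  }
  dim1 <- sample(seq(config$dim_window[1], dim_max1), nc, replace = TRUE)
  age_calving <- sample(22:29, nc, replace = TRUE)

  rec <- tidyr::expand_grid(ci = seq_len(nc), rep = seq_len(r))
  rec$animal <- cows[rec$ci]
  rec$herd <- herd[rec$ci]
  rec$test_day <- td_first[rec$ci] + rec$rep - 1L
  rec$htd <- paste(rec$herd, rec$test_day, sep = "_")
  rec$date <- day0 + gap * (rec$test_day - 1L)
  rec$dim <- dim1[rec$ci] + gap * (rec$rep - 1L)
  rec$calving_date <- rec$date - rec$dim
  rec$age_calving_mo <- age_calving[rec$ci]
  rec$ac_class <- paste0("ac", (rec$age_calving_mo - 16L) %/% 2L)
  rec$dim_class <- paste0("dim", rec$dim %/% 5L)
  rec$year_season <- paste0(format(rec$calving_date, "%Y"), "_q",
                            (as.integer(format(rec$calving_date, "%m")) - 1L) %/% 3L + 1L)
  rec$lactation <- 1L

  aidx <- match(as.character(rec$animal), rownames(truth$true_bv))
  hidx <- match(rec$htd, truth$true_htd$htd)
  e <- rmvn_psd(nrow(rec), cc$R)
  y <- matrix(rep(config$means[cc$traits], each = nrow(rec)), nrow(rec), k) +
    as.matrix(truth$true_htd[hidx, cc$traits]) +
    truth$true_bv[aidx, , drop = FALSE] +
    truth$true_pe[aidx, , drop = FALSE] + e
  colnames(y) <- cc$traits
  dplyr::bind_cols(
    rec[, c("animal", "herd", "test_day", "htd", "date", "calving_date",
            "dim", "dim_class", "ac_class", "age_calving_mo", "year_season",
            "lactation")],
    tibble::as_tibble(y)
  )
}

#' Simulate a complete population with known ground truth
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()], [simulate_true_values()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @inheritParams simulate_pedigree
#' @param genotypes generate SNP genotypes (disable to save time when only
#'   phenotypes are needed).
#' @param n_cows optional cap passed to [simulate_phenotypes()].
#' @param cohort recorded-cow cohort, passed to [simulate_phenotypes()].
#' @return A `true_population` list: `pedigree`, `genotypes`,
#'   `allele_freqs`, `true_bv`, `true_htd`, `true_pe`, `records`, `config`.
#' @export
simulate_population <- function(config, genotypes = TRUE, n_cows = NULL,
                                cohort = c("last_generation",
                                           "all_females")) {
  ped <- simulate_pedigree(config)
  gen <- if (genotypes) simulate_genotypes(ped, config) else
    list(genotypes = NULL, allele_freqs = NULL)
  truth <- simulate_true_values(ped, config)
  records <- simulate_phenotypes(ped, truth, config, n_cows = n_cows,
                                 cohort = cohort)
  structure(
    list(pedigree = ped, genotypes = gen$genotypes,
         allele_freqs = gen$allele_freqs,
         true_bv = truth$true_bv, true_htd = truth$true_htd,
         true_pe = truth$true_pe, records = records, config = config),
    class = "true_population"
  )
}
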