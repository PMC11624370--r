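test_that("pedigree simulation is deterministic and structurally valid", {
  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    n_offspring_per_gen = 8, seed = 4)
  ped1 <- simulate_pedigree(cfg)
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped1, ped2)
  # every non-founder has both parents in an earlier generation
  idx <- stats::setNames(ped1$generation, ped1$animal)
  off <- ped1[ped1$generation > 0, ]
  expect_true(all(idx[as.character(off$sire)] < off$generation))
  expect_true(all(off$dam == 0 |
                    idx[as.character(off$dam)] < off$generation))
  # sexes consistent with parent roles
  sex <- stats::setNames(ped1$sex, ped1$animal)
  expect_true(all(sex[as.character(off$sire)] == "M"))
  expect_true(all(sex[as.character(off$dam[off$dam != 0])] == "F"))
  # parents born before offspring
  by <- stats::setNames(ped1$birth_year, ped1$animal)
  expect_true(all(by[as.character(off$sire)] < off$birth_year))
})

test_that("zero offspring generations yield founders only", {
  cfg <- sim_config(n_founders = 6, n_generations = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 6)
  expect_true(all(ped$sire == 0 & ped$dam == 0))
})

test_that("an all-female founder set cannot breed offspring", {
  expect_error(sim_config(n_founders = 5, n_founder_males = 0,
                          n_generations = 1),
               "male founder")
})

test_that("gene dropping is Mendelian-consistent", {
  pop <- small_population()
  ped <- pop$pedigree
  g <- pop$genotypes
  off <- ped[ped$generation > 0, ]
  gs <- g[as.character(off$sire), , drop = FALSE]
  gd <- g[as.character(off$dam), , drop = FALSE]
  go <- g[as.character(off$animal), , drop = FALSE]
  # a homozygous parent pair 0 x 0 can only give 0, and 2 x 2 only 2
  both0 <- gs == 0 & gd == 0
  expect_true(all(go[both0] == 0))
  both2 <- gs == 2 & gd == 2
  expect_true(all(go[both2] == 2))
  # regression of offspring on mid-parent genotype is about 1
  mp <- (gs + gd) / 2
  b <- stats::coef(stats::lm(as.numeric(go) ~ as.numeric(mp)))[2]
  expect_gt(b, 0.9)
  expect_lt(b, 1.1)
})

test_that("founder genotype means match binomial sampling", {
  cfg <- sim_config(n_founders = 500, n_generations = 0, n_snps = 1,
                    maf_range = c(0.3, 0.3), seed = 8)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  m <- mean(gen$genotypes[, 1])
  se <- sqrt(2 * 0.3 * 0.7 / 500)
  expect_lt(abs(m - 0.6), 3 * se)
})

test_that("zero genetic variance gives exactly zero breeding values", {
  cfg <- sim_config(n_founders = 12, n_generations = 1,
                    n_offspring_per_gen = 10, seed = 5)
  cc <- cfg$components
  cc$G[] <- 0
  cfg$components <- cc
  truth <- simulate_true_values(simulate_pedigree(cfg), cfg)
  expect_true(all(truth$true_bv == 0))
})

test_that("founder breeding values converge to the truth covariance", {
  cfg <- sim_config(n_founders = 100000, n_generations = 0, seed = 6)
  ped <- simulate_pedigree(cfg)
  truth <- simulate_true_values(ped, cfg)
  Vemp <- stats::cov(truth$true_bv)
  G <- cfg$components$G
  expect_lt(max(abs(Vemp - G) / (sqrt(diag(G)) %o% sqrt(diag(G)))), 0.02)
})

test_that("relative covariances of breeding values match the numerator relationship", {
  cfg <- sim_config(n_founders = 2000, n_founder_males = 100,
                    n_generations = 1, n_offspring_per_gen = 20000,
                    female_fraction = 1, seed = 7)
  ped <- simulate_pedigree(cfg)
  truth <- simulate_true_values(ped, cfg)
  G <- cfg$components$G["CH4", "CH4"]
  off <- ped[ped$generation == 1, ]
  bo <- truth$true_bv[as.character(off$animal), "CH4"]
  bs <- truth$true_bv[as.character(off$sire), "CH4"]
  # parent-offspring covariance is 0.5 G
  expect_lt(abs(stats::cov(bo, bs) - 0.5 * G) / G, 0.05)
  # paternal half sibs covary at 0.25 G: take two offspring per sire
  first <- off[!duplicated(off$sire), ]
  rest <- off[duplicated(off$sire), ]
  second <- rest[!duplicated(rest$sire), ]
  common <- intersect(first$sire, second$sire)
  b1 <- truth$true_bv[as.character(first$animal[match(common, first$sire)]),
                      "CH4"]
  b2 <- truth$true_bv[as.character(second$animal[match(common,
                                                       second$sire)]),
                      "CH4"]
  # dams are drawn from a large pool, so shared dams are rare
  expect_lt(abs(stats::cov(b1, b2) - 0.25 * G) / G, 0.15)
  # Mendelian sampling variance around the parent average is 0.5 G
  bd <- truth$true_bv[as.character(off$dam), "CH4"]
  ms <- bo - (bs + bd) / 2
  expect_lt(abs(stats::var(ms) - 0.5 * G) / G, 0.05)
})

test_that("phenotypes decompose into the simulated variance components", {
  cfg <- sim_config(n_founders = 20000, n_founder_males = 100,
                    n_generations = 0, n_herds = 500,
                    test_days_per_herd = 4, seed = 9)
  pop <- simulate_population(cfg, genotypes = FALSE)
  vp_true <- sum(purrr::map_dbl(cfg$components[c("HTD", "G", "P", "R")],
                                ~ .x["CH4", "CH4"]))
  vp_emp <- stats::var(pop$records$CH4)
  expect_lt(abs(vp_emp - vp_true) / vp_true, 0.05)
  expect_equal(mean(pop$records$CH4), cfg$means[["CH4"]],
               tolerance = 0.01)
})

test_that("all-zero variances and means give all-zero phenotypes", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 2)
  for (nm in c("HTD", "G", "P", "R")) cfg$components[[nm]][] <- 0
  cfg$means[] <- 0
  pop <- simulate_population(cfg, genotypes = FALSE)
  expect_true(all(abs(pop$records[, cfg$components$traits]) < 1e-12))
})

test_that("records of one cow share breeding value and PE but not residual", {
  pop <- small_population()
  r <- pop$records
  cows <- unique(r$animal)
  a1 <- r[match(cows, r$animal), ]
  # same cow, two records: difference removes a and p, leaving residual
  second <- r[duplicated(r$animal), ]
  second <- second[match(cows, second$animal), ]
  d <- a1$CH4 - second$CH4
  # htd differs too; variance of the difference is bounded by
  # 2 (htd + residual) variance
  vR <- pop$config$components$R["CH4", "CH4"]
  vH <- pop$config$components$HTD["CH4", "CH4"]
  expect_lt(stats::var(d, na.rm = TRUE), 2.6 * (vR + vH))
})
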