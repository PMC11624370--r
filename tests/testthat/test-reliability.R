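test_that("animals without information have zero reliability", {
  ped <- tibble::tibble(animal = 1:6, sire = 0L, dam = 0L,
                        birth_year = 2000L, sex = "F",
                        generation = 0L, genotyped = FALSE)
  # animals 1-4 recorded in shared herd-test-day groups; 5-6 unrecorded
  rec <- tibble::tibble(animal = rep(1:4, each = 2),
                        htd = rep(c("h1", "h2"), 4),
                        ac_class = "a", dim_class = "d",
                        year_season = "y",
                        CH4 = c(480, 500, 460, 455, 520, 530, 490, 485))
  des <- build_design(rec, ped, traits = "CH4")
  cc <- one_trait_components(c(900, 1500, 1000, 3100))
  sol <- solve_mme(assemble_mme(des, cc,
                                numerator_relationship_inverse(ped)))
  rel <- pev_reliability(sol)
  # animals 5 and 6 have no records and no informative relatives
  expect_equal(rel$reliability[rel$animal %in% c("5", "6")], c(0, 0),
               tolerance = 1e-8)
  expect_gt(rel$reliability[rel$animal == "1"], 0)
})

test_that("reliability matches 1 - PEV/var from a dense inverse", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  cc <- pop$config$components
  sys <- assemble_mme(des, cc, numerator_relationship_inverse(des$pedigree))
  sol <- solve_mme(sys)
  rel <- pev_reliability(sol)
  Ci <- solve(as.matrix(sys$C))
  k <- 4
  i <- sample(seq_along(des$levels$animal), 5)
  for (t in 1:k) {
    eq <- (des$ranges$animal[i] - 1) * k + t
    pev <- diag(Ci)[eq]
    got <- rel$pev[rel$trait == des$traits[t]][i]
    expect_equal(got, pev, tolerance = 1e-8)
  }
})

test_that("adding daughters never decreases a sire's reliability", {
  cc <- one_trait_components(c(900, 1500, 1000, 3100))
  rels <- purrr::map_dbl(c(4, 12, 30), function(nd) {
    ped <- tibble::tibble(animal = seq_len(nd + 1),
                          sire = c(0L, rep(1L, nd)),
                          dam = 0L, birth_year = c(2000L, rep(2005L, nd)),
                          sex = c("M", rep("F", nd)),
                          generation = c(0L, rep(1L, nd)),
                          genotyped = FALSE)
    rec <- tibble::tibble(animal = rep(2:(nd + 1), each = 2),
                          htd = rep(c("h1", "h2"), nd),
                          ac_class = "a", dim_class = "d",
                          year_season = "y",
                          CH4 = stats::rnorm(2 * nd, 490, 50))
    des <- build_design(rec, ped, traits = "CH4")
    sol <- solve_mme(assemble_mme(des, cc,
                                  numerator_relationship_inverse(ped)))
    pev_reliability(sol)$reliability[1]
  })
  expect_true(all(diff(rels) > 0))
})

test_that("vanishing non-genetic variances drive reliability toward one", {
  # with many recorded unrelated animals and all non-genetic variances
  # near zero, records reveal breeding values up to the fixed mean, so
  # reliability approaches 1 - 1/n
  n <- 50
  ped <- tibble::tibble(animal = seq_len(n), sire = 0L, dam = 0L,
                        birth_year = 2000L, sex = "F", generation = 0L,
                        genotyped = FALSE)
  set.seed(31)
  rec <- tibble::tibble(animal = rep(seq_len(n), each = 2),
                        htd = rep(c("h1", "h2"), n),
                        ac_class = "a", dim_class = "d", year_season = "y",
                        CH4 = stats::rnorm(2 * n, 490, 40))
  cc <- one_trait_components(c(1e-6, 1500, 1e-6, 1e-6))
  des <- build_design(rec, ped, traits = "CH4")
  sol <- solve_mme(assemble_mme(des, cc,
                                numerator_relationship_inverse(ped)))
  expect_gt(min(pev_reliability(sol)$reliability), 0.95)
})

test_that("the 80:20 reliability blend is applied and validated", {
  expect_equal(blend_reliability(0.9, 0.5), 0.82)
  expect_equal(blend_reliability(0.7, 0.7), 0.7)
  expect_equal(blend_reliability(1, 0), 0.8)
  expect_equal(blend_reliability(c(0.9, 1), c(0.5, 0)), c(0.82, 0.8))
  expect_error(blend_reliability(1.2, 0.5), "0, 1")
  expect_error(blend_reliability(0.5, -0.1), "0, 1")
})
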