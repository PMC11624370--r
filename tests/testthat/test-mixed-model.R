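test_that("design incidence structures count levels and records correctly", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  r <- pop$records
  expect_equal(length(des$levels$htd), length(unique(r$htd)))
  expect_equal(length(des$levels$animal), nrow(pop$pedigree))
  expect_equal(length(des$levels$pe), length(unique(r$animal)))
  # herd-test-day incidence columns sum to the records in that group
  Z1 <- des$W[, des$ranges$htd]
  expect_equal(unname(Matrix::colSums(Z1)),
               unname(as.numeric(table(r$htd)[des$levels$htd])))
  expect_error(build_design(dplyr::mutate(r, animal = animal + 10000L),
                            pop$pedigree),
               "missing from the pedigree")
})

test_that("assembled equations are symmetric and solve correctly", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  cc <- pop$config$components
  sys <- assemble_mme(des, cc, numerator_relationship_inverse(des$pedigree))
  expect_lt(max(abs(sys$C - Matrix::t(sys$C))), 1e-12)
  sol <- solve_mme(sys)
  res <- as.numeric(sys$C %*% as.numeric(t(sol$theta)) - sys$rhs)
  expect_lt(max(abs(res)), 1e-6)
  # direct and conjugate-gradient solutions agree
  sol_cg <- solve_mme(sys, method = "cg", tol = 1e-12)
  expect_lt(max(abs(sol$theta - sol_cg$theta)), 1e-6)
})

test_that("a singular component matrix is reported by name", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  cc <- pop$config$components
  cc$P[] <- 0
  expect_error(assemble_mme(des, cc,
                            numerator_relationship_inverse(des$pedigree)),
               "P")
})

test_that("single-record single-animal system reproduces the hand solution", {
  # one trait, one animal, one record y; all variances 1, no relatives.
  # Equations (intercept absorbed as the only fixed effect):
  # the BLUP of each random effect shrinks y - mu by its variance ratio.
  ped <- tibble::tibble(animal = 1L, sire = 0L, dam = 0L,
                        birth_year = 2000L, sex = "F", generation = 0L,
                        genotyped = FALSE)
  rec <- tibble::tibble(animal = 1L, htd = "h1", ac_class = "a",
                        dim_class = "d", year_season = "y", CH4 = 5)
  des <- build_design(rec, ped, traits = "CH4")
  cc <- one_trait_components(c(1, 1, 1, 1))
  sys <- assemble_mme(des, cc, numerator_relationship_inverse(ped))
  sol <- solve_mme(sys)
  # with a fixed mean soaking the record, all random solutions are 0
  expect_equal(unname(sol$theta[1, 1]), 5, tolerance = 1e-10)
  expect_true(all(abs(sol$theta[-1, 1]) < 1e-10))
})

test_that("solutions are invariant to record ordering", {
  pop <- small_population()
  cc <- pop$config$components
  des1 <- build_design(pop$records, pop$pedigree)
  sol1 <- solve_mme(assemble_mme(des1, cc,
                                 numerator_relationship_inverse(des1$pedigree)))
  set.seed(1)
  shuf <- pop$records[sample(nrow(pop$records)), ]
  des2 <- build_design(shuf, pop$pedigree)
  sol2 <- solve_mme(assemble_mme(des2, cc,
                                 numerator_relationship_inverse(des2$pedigree)))
  e1 <- sol1$ebv[order(sol1$ebv$animal), ]
  e2 <- sol2$ebv[order(sol2$ebv$animal), ]
  expect_equal(e1$CH4, e2$CH4, tolerance = 1e-8)
})

test_that("zero right-hand side gives the zero solution", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  sys <- assemble_mme(des, pop$config$components,
                      numerator_relationship_inverse(des$pedigree))
  sys$rhs[] <- 0
  sol <- solve_mme(sys)
  expect_true(all(abs(sol$theta) < 1e-12))
})

test_that("EBVs track true breeding values with slope near one", {
  pop <- small_population()
  des <- build_design(pop$records, pop$pedigree)
  sol <- solve_mme(assemble_mme(des, pop$config$components,
                                numerator_relationship_inverse(des$pedigree)))
  tb <- pop$true_bv[sol$ebv$animal, "CH4"]
  b <- stats::coef(stats::lm(tb ~ sol$ebv$CH4))[2]
  expect_gt(b, 0.8)
  expect_lt(b, 1.25)
})
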