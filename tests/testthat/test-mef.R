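test_that("structural coefficients solve the conditional regression", {
  G <- matrix(c(4, 2, 2, 4), 2, 2,
              dimnames = list(c("CH4", "MY"), c("CH4", "MY")))
  b <- structural_coefficients(G, production_traits = "MY")
  expect_equal(unname(b), 0.5)
  # diagonal production block: componentwise ratios
  G4 <- default_components()$G
  bd <- structural_coefficients(G4)
  Gd <- G4
  Gd[c("MY", "FY", "PY"), c("MY", "FY", "PY")] <-
    diag(diag(G4[c("MY", "FY", "PY"), c("MY", "FY", "PY")]))
  bdiag <- structural_coefficients(Gd)
  expect_equal(unname(bdiag),
               unname(G4[c("MY", "FY", "PY"), "CH4"] /
                        diag(G4[c("MY", "FY", "PY"), c("MY", "FY", "PY")])))
  # zero covariances give zero coefficients
  G0 <- G4; G0["CH4", -1] <- 0; G0[-1, "CH4"] <- 0
  expect_equal(unname(structural_coefficients(G0)), rep(0, 3))
})

test_that("residual breeding values reverse scale and respect b = 0", {
  gebv <- tibble::tibble(animal = c("a", "b"), CH4 = c(10, -5),
                         MY = c(1, 2), FY = c(0.1, 0), PY = c(0, 0.2))
  b0 <- stats::setNames(rep(0, 3), c("MY", "FY", "PY"))
  r0 <- residual_breeding_value(gebv, b0)
  expect_equal(r0$mef_index, -gebv$CH4)
  # an animal exactly on the regression plane has raw 0
  b1 <- stats::setNames(c(2, 1, 1), c("MY", "FY", "PY"))
  gebv2 <- tibble::tibble(animal = "c", CH4 = 2 * 3 + 1 * 0.5 + 1 * 1,
                          MY = 3, FY = 0.5, PY = 1)
  expect_equal(residual_breeding_value(gebv2, b1)$raw_mef, 0)
  # missing trait values skip the animal with a warning
  gebv3 <- gebv; gebv3$MY[2] <- NA
  expect_warning(r3 <- residual_breeding_value(gebv3, b1), "skipped")
  expect_equal(nrow(r3), 1)
})

test_that("RBV standardization hits mean 100 / SD 5 exactly and is idempotent", {
  set.seed(8)
  x <- stats::rnorm(300, 2, 7)
  base <- seq_len(300) <= 120
  rbv <- rbv_standardize(x, base)
  expect_equal(mean(rbv[base]), 100, tolerance = 1e-12)
  expect_equal(stats::sd(rbv[base]), 5, tolerance = 1e-12)
  expect_equal(rbv_standardize(rbv, base), rbv, tolerance = 1e-12)
  # one base SD above the mean maps to 105
  x2 <- c(mean(x[base]), mean(x[base]) + stats::sd(x[base]))
  rbv2 <- rbv_standardize(c(x, x2), c(base, FALSE, FALSE))
  expect_equal(utils::tail(rbv2, 2), c(100, 105), tolerance = 1e-10)
  expect_error(rbv_standardize(c(1, 1), c(TRUE, TRUE)), "nonzero")
})

test_that("selection-index reliability collapses correctly at the limits", {
  G <- default_components()$G
  b <- structural_coefficients(G)
  traits <- c("CH4", "MY", "FY", "PY")
  r1 <- stats::setNames(rep(1, 4), traits)
  expect_equal(mef_reliability(r1, G, b), 1)
  r0 <- stats::setNames(rep(0, 4), traits)
  expect_equal(mef_reliability(r0, G, b), 0)
  # with b = 0 the index is methane alone
  b0 <- stats::setNames(rep(0, 3), c("MY", "FY", "PY"))
  rm <- stats::setNames(c(0.49, 0.2, 0.3, 0.4), traits)
  expect_equal(mef_reliability(rm, G, b0), 0.49)
  expect_error(mef_reliability(stats::setNames(c(2, 0, 0, 0), traits),
                               G, b), "0, 1")
})

test_that("official status applies inclusive thresholds", {
  expect_true(official_status(20, 5, 0.70))
  expect_false(official_status(19, 10, 0.99))
  expect_false(official_status(100, 4, 0.99))
  expect_false(official_status(100, 10, 0.69))
  expect_equal(official_status(c(20, 19), c(5, 5), c(0.7, 0.7)),
               c(TRUE, FALSE))
})

test_that("raw MEF is genetically independent of production in simulation", {
  cfg <- sim_config(n_founders = 20000, n_generations = 0, seed = 77)
  ped <- simulate_pedigree(cfg)
  truth <- simulate_true_values(ped, cfg)
  G <- cfg$components$G
  b <- structural_coefficients(G)
  gebv <- dplyr::bind_cols(tibble::tibble(animal = rownames(truth$true_bv)),
                           tibble::as_tibble(truth$true_bv))
  mef <- residual_breeding_value(gebv, b)
  for (tr in c("MY", "FY", "PY")) {
    expect_lt(abs(stats::cor(mef$raw_mef, truth$true_bv[, tr])), 0.05)
  }
  # higher index = genetically lower methane after conditioning
  expect_lt(stats::cor(mef$mef_index, truth$true_bv[, "CH4"]), 0)
})
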