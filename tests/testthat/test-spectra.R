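test_that("pin selection extracts exactly the printed regions", {
  expect_length(mir_informative_pins(), 241)
  expect_equal(mir_informative_pins(),
               c(260:402, 442:472, 701:767))
  v <- numeric(1060)
  v[mir_informative_pins()] <- seq_len(241)
  expect_equal(select_informative_pins(v), as.numeric(seq_len(241)))
  # projection: padding the selection back into pin space re-extracts it
  pad <- numeric(1060)
  pad[mir_informative_pins()] <- select_informative_pins(v)
  expect_equal(select_informative_pins(pad), select_informative_pins(v))
  # excluded boundary pin
  v2 <- numeric(1060); v2[403] <- 1
  expect_true(all(select_informative_pins(v2) == 0))
  expect_error(select_informative_pins(numeric(500)), "at least")
})

test_that("subset detection finds an injected level shift and not clean data", {
  set.seed(11)
  n <- 240
  sp <- matrix(stats::rnorm(n * 60, sd = 0.05), n, 60)
  dates <- as.Date("2021-01-01") + seq_len(n)
  clean <- detect_homogeneous_subsets(sp, dates)
  expect_equal(length(unique(clean$subset)), 1L)
  shift <- sp
  shift[121:240, ] <- shift[121:240, ] +
    matrix(rep(seq(0.4, 0.05, length.out = 60), each = 120), 120, 60)
  found <- detect_homogeneous_subsets(shift, dates)
  expect_equal(length(unique(found$subset)), 2L)
  brk <- max(found$index[found$subset == 1])
  expect_lt(abs(brk - 120), 12)
  # a 100% variance threshold monitors nothing
  none <- detect_homogeneous_subsets(shift, dates, variance_threshold = 1)
  expect_equal(length(unique(none$subset)), 1L)
})

test_that("standardization recovers affine maps and aligns moments", {
  set.seed(3)
  ref <- matrix(stats::rnorm(800), 40, 20)
  st0 <- standardize_subset(ref, ref)
  expect_equal(st0$map$slope, rep(1, 20), tolerance = 1e-10)
  expect_equal(st0$map$offset, rep(0, 20), tolerance = 1e-10)
  sub <- ref * 2 + 1
  st <- standardize_subset(sub, ref)
  expect_equal(st$map$slope, rep(0.5, 20), tolerance = 1e-10)
  expect_equal(st$map$offset, rep(-0.5, 20), tolerance = 1e-10)
  sub2 <- matrix(stats::rnorm(800, mean = 3, sd = 2), 40, 20)
  st2 <- standardize_subset(sub2, ref)
  expect_lt(max(abs(colMeans(st2$spectra) - colMeans(ref))), 1e-10)
  # zero-variance pin falls back to an offset-only map
  sub3 <- sub2; sub3[, 1] <- 7
  expect_warning(st3 <- standardize_subset(sub3, ref), "zero-variance")
  expect_equal(st3$map$slope[1], 1)
})

test_that("Mahalanobis QC flags planted outliers and spares the centroid", {
  set.seed(5)
  sp <- matrix(stats::rnorm(400 * 15), 400, 15)
  sp[400, ] <- colMeans(sp[-400, ])  # at the centroid
  qc <- mahalanobis_qc(sp)
  expect_true(qc$qc_pass[400])
  sp2 <- sp
  sp2[1, ] <- sp2[1, ] + 10
  qc2 <- mahalanobis_qc(sp2)
  expect_false(qc2$qc_pass[1])
  # the planted distance exceeds an independently tabulated quantile
  expect_gt(qc2$distance2[1], stats::qchisq(0.999, df = qc2$df[1]))
  # all-identical-but-one flags exactly that one
  sp3 <- matrix(1, 60, 10) + matrix(stats::rnorm(600, sd = 1e-3), 60, 10)
  sp3[7, ] <- sp3[7, ] + 1
  qc3 <- mahalanobis_qc(sp3)
  expect_false(qc3$qc_pass[7])
  expect_true(all(qc3$qc_pass[-7]))
})

test_that("QC flag rate on clean spectra is near the nominal 0.001", {
  set.seed(9)
  sp <- matrix(stats::rnorm(6000 * 20), 6000, 20)
  qc <- mahalanobis_qc(sp)
  rate <- mean(!qc$qc_pass)
  se <- sqrt(0.001 * 0.999 / 6000)
  expect_lt(abs(rate - 0.001), 4 * se)
})

test_that("Savitzky-Golay is exact on cubics and validates parameters", {
  x <- seq_len(80)
  y <- 1 - 2 * x + 0.03 * x^2 - 1e-4 * x^3
  sm <- savitzky_golay(y)
  interior <- 6:75
  expect_lt(max(abs(sm[interior] - y[interior])), 1e-9)
  expect_equal(savitzky_golay(rep(3, 50)), rep(3, 50), tolerance = 1e-12)
  # interior point equals a local cubic least-squares fit
  set.seed(2)
  z <- stats::rnorm(51)
  i <- 26
  win <- (i - 5):(i + 5)
  fit <- stats::lm(z[win] ~ poly(win, 3, raw = TRUE))
  expect_equal(savitzky_golay(z)[i], unname(stats::predict(
    fit, newdata = data.frame(win = i))), tolerance = 1e-8)
  expect_error(savitzky_golay(z, width = 10), "odd")
  expect_error(savitzky_golay(z, order = 11, width = 11), "odd|order")
  expect_error(savitzky_golay(numeric(5)), "shorter")
})
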