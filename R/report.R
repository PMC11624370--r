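#' Summaries of predicted and recorded methane by RBV class
#'
#' Cows are classed by their methane-efficiency RBV: low (< 95, more than
#' one SD below the base mean), medium ([95, 105], boundaries included)
#' and high (> 105). Per class, the mean and standard error (sample
#' SD / sqrt(n)) of predicted and recorded methane are reported; empty
#' classes keep n = 0 with NA means.
#'
#' @param cows tibble with columns `rbv`, `predicted_ch4`, `recorded_ch4`.
#' @param bounds the two class boundaries on the RBV scale.
#' @return A `mef_class_summary` tibble: one row per class with `n`,
#'   means and SEs.
#' @export
rbv_class_summary <- function(cows, bounds = c(95, 105)) {
  lv <- c("low", "medium", "high")
  cls <- dplyr::case_when(
    cows$rbv < bounds[1] ~ "low",
    cows$rbv > bounds[2] ~ "high",
    TRUE ~ "medium"
  )
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else
    NA_real_
  got <- cows |>
    dplyr::mutate(class = factor(cls, levels = lv)) |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$predicted_ch4),
      se_predicted = se(.data$predicted_ch4),
      mean_recorded = mean(.data$recorded_ch4),
      se_recorded = se(.data$recorded_ch4),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with(c("mean_", "se_")),
                                ~ ifelse(.data$n == 0, NA_real_, .x)))
  structure(got, class = c("mef_class_summary", class(got)),
            bounds = bounds)
}

#' Regress daughter methane averages on sire RBV
#'
#' Least-squares regression of per-sire daughter methane means on the
#' sires' RBV, translating RBV points into an expected change in daughter
#' methane (g/d). The per-5-point step (one RBV standard deviation) is
#' reported with the sign convention that a positive step means fewer
#' grams per day.
#'
#' @param sires tibble with columns `rbv` and `daughter_ch4` (per-sire
#'   daughter mean, g/d); at least 3 sires.
#' @return Tibble with `slope_per_point` (g/d per RBV point),
#'   `reduction_per_5_points` (g/d, positive = reduction), `intercept`,
#'   `r_squared`, `n_sires`.
#' @export
daughter_regression <- function(sires) {
  if (nrow(sires) < 3) stop("at least 3 sires with daughters are required")
  if (stats::sd(sires$rbv) == 0) {
    stop("sire RBVs have zero variance; slope undefined")
  }
  fit <- stats::lm(daughter_ch4 ~ rbv, data = sires)
  slope <- unname(stats::coef(fit)[2])
  tibble::tibble(
    slope_per_point = slope,
    reduction_per_5_points = -5 * slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_sires = nrow(sires)
  )
}

#' Correlations of MEF proofs with other trait proofs
#'
#' Pairwise-complete Pearson correlations between the methane-efficiency
#' RBV and any number of other proof vectors over a common animal set.
#' Constant proof vectors yield an NA correlation and are flagged.
#'
#' @param mef_rbv numeric vector of MEF RBVs.
#' @param proofs data frame/tibble of other proof columns (same animals,
#'   same order).
#' @return Tibble with `proof`, `r`, `n`, `flagged`.
#' @export
proof_correlations <- function(mef_rbv, proofs) {
  if (length(mef_rbv) < 3) stop("at least 3 animals are required")
  purrr::map_dfr(names(proofs), function(nm) {
    p <- proofs[[nm]]
    ok <- stats::complete.cases(mef_rbv, p)
    flagged <- sum(ok) < 3 || stats::sd(p[ok]) == 0 ||
      stats::sd(mef_rbv[ok]) == 0
    tibble::tibble(
      proof = nm,
      r = if (flagged) NA_real_ else stats::cor(mef_rbv[ok], p[ok]),
      n = sum(ok),
      flagged = flagged
    )
  })
}
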