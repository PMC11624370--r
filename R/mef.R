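#' Genetic regression coefficients of methane on the production traits
#'
#' Methane efficiency is the part of genetic methane production
#' independent of milk, fat and protein yield. The conditional genetic
#' regression vector is `b = G_pp^-1 g_p`, where `G_pp` is the production
#' block of the genetic covariance matrix and `g_p` the genetic
#' covariances of the production traits with methane.
#'
#' @param G genetic covariance matrix with the methane trait and the
#'   production traits among its dimnames.
#' @param ch4_trait name of the methane trait column.
#' @param production_traits names of the production trait columns.
#' @return Named numeric vector `b` (one coefficient per production
#'   trait).
#' @export
structural_coefficients <- function(G, ch4_trait = "CH4",
                                    production_traits = c("MY", "FY", "PY")) {
  Gpp <- G[production_traits, production_traits, drop = FALSE]
  gp <- G[production_traits, ch4_trait]
  if (rcond(Gpp) < 1e-12) stop("production-trait genetic block is singular")
  stats::setNames(as.numeric(solve(Gpp, gp)), production_traits)
}

#' Residual-genetic methane breeding values (raw MEF)
#'
#' For each animal, `raw = EBV_CH4 - b' (EBV_MY, EBV_FY, EBV_PY)`; the
#' index value is `-raw`, so a higher value means genetically lower
#' methane after accounting for production.
#'
#' @param gebv tibble of per-animal breeding values with an `animal`
#'   column and one column per trait (as `solve_mme()$ebv`).
#' @param b coefficients from [structural_coefficients()].
#' @param ch4_trait methane trait column name.
#' @return Tibble with `animal`, `raw_mef` (g/d, lower = better) and
#'   `mef_index` (reversed scale, higher = better). Animals missing a
#'   trait are dropped with a warning.
#' @export
residual_breeding_value <- function(gebv, b, ch4_trait = "CH4") {
  prod_traits <- names(b)
  need <- c(ch4_trait, prod_traits)
  missing_col <- setdiff(need, names(gebv))
  if (length(missing_col) > 0) {
    stop("gebv lacks trait columns: ", paste(missing_col, collapse = ", "))
  }
  ok <- stats::complete.cases(gebv[, need])
  if (any(!ok)) {
    warning(sum(!ok), " animal(s) skipped: missing trait breeding values")
  }
  g <- gebv[ok, ]
  raw <- g[[ch4_trait]] - as.matrix(g[, prod_traits]) %*% b
  tibble::tibble(animal = g$animal, raw_mef = as.numeric(raw),
                 mef_index = -as.numeric(raw))
}

#' Express an index as a relative breeding value (mean 100, SD 5)
#'
#' `RBV = 100 + 5 * (x - mean_base) / sd_base`, where the base statistics
#' come from a designated base group (bulls born in a reference window
#' with an official evaluation). After the transform, the base group has
#' mean exactly 100 and standard deviation exactly 5.
#'
#' @param values index values for all animals.
#' @param base logical vector marking the base animals.
#' @param mean_target,sd_target the published scale (defaults 100 and 5).
#' @return Numeric vector of RBVs.
#' @export
rbv_standardize <- function(values, base, mean_target = 100, sd_target = 5) {
  stopifnot(length(base) == length(values))
  vb <- values[base]
  if (length(vb) < 2 || stats::sd(vb) == 0) {
    stop("base set must contain at least 2 animals with nonzero variance")
  }
  mean_target + sd_target * (values - mean(vb)) / stats::sd(vb)
}

#' Selection-index reliability of the MEF linear combination
#'
#' MEF is the linear combination `w = (1, -b)` of the four trait breeding
#' values. Its reliability is approximated by the selection-index method:
#' the true-index variance is `w' G w`; the variance of the predicted
#' index replaces each trait's genetic (co)variance by its reliability-
#' scaled counterpart, `cov(EBV_i, EBV_j) = sqrt(r_i r_j) G_ij` (the
#' standard approximation treating EBV accuracy as trait-wise scaling), so
#' `rel_MEF = (w' D G D w) / (w' G w)` with `D = diag(sqrt(r))`. Results
#' are clipped to [0, 1].
#'
#' @param reliabilities tibble with `animal` and one reliability column
#'   per trait, or a named numeric vector for a single animal.
#' @param G genetic covariance matrix.
#' @param b coefficients from [structural_coefficients()].
#' @param ch4_trait methane trait column name.
#' @return Tibble with `animal` and `reliability` (or a scalar for vector
#'   input).
#' @export
mef_reliability <- function(reliabilities, G, b, ch4_trait = "CH4") {
  traits <- c(ch4_trait, names(b))
  w <- c(1, -unname(b))
  Gw <- G[traits, traits]
  denom <- as.numeric(t(w) %*% Gw %*% w)
  one <- function(r) {
    if (any(r < -1e-9 | r > 1 + 1e-9)) stop("reliabilities must be in [0, 1]")
    D <- sqrt(pmin(pmax(r[traits], 0), 1))
    num <- as.numeric(t(w * D) %*% Gw %*% (w * D))
    min(max(num / denom, 0), 1)
  }
  if (is.numeric(reliabilities) && !is.null(names(reliabilities))) {
    return(one(reliabilities))
  }
  tibble::tibble(
    animal = reliabilities$animal,
    reliability = purrr::pmap_dbl(reliabilities[, traits], function(...) {
      one(stats::setNames(c(...), traits))
    })
  )
}

#' Official-status rule for sire evaluations
#'
#' A sire's evaluation is official when it has at least `min_daughters`
#' daughters, distributed over at least `min_herds` herds, and a
#' reliability of at least `min_reliability` (boundaries inclusive).
#'
#' @param n_daughters,n_herds,reliability vectors of sire summaries.
#' @param min_daughters,min_herds,min_reliability the thresholds (20, 5
#'   and 0.70).
#' @return Logical vector.
#' @export
official_status <- function(n_daughters, n_herds, reliability,
                            min_daughters = 20, min_herds = 5,
                            min_reliability = 0.70) {
  n_daughters >= min_daughters & n_herds >= min_herds &
    reliability >= min_reliability
}

#' Full methane-efficiency evaluation table
#'
#' Combines the residual breeding value, RBV standardization against a
#' base of official bulls born in a reference year window, the
#' selection-index reliability, and the official-status rule into one
#' per-animal evaluation.
#'
#' @param gebv per-animal trait breeding values (`animal` + trait
#'   columns).
#' @param reliabilities per-animal per-trait reliabilities (wide tibble,
#'   `animal` + trait columns).
#' @param G genetic covariance matrix.
#' @param pedigree pedigree tibble (for sex and birth year).
#' @param records optional record tibble to count daughters and daughter
#'   herds per sire.
#' @param base_years birth-year window defining base bulls.
#' @param ch4_trait,production_traits trait names.
#' @return A `mef_evaluation` tibble: `animal`, `raw_mef`, `mef_index`,
#'   `rbv`, `reliability`, `n_daughters`, `n_daughter_herds`, `official`,
#'   `is_base`.
#' @export
mef_evaluation <- function(gebv, reliabilities, G, pedigree, records = NULL,
                           base_years = c(2008L, 2017L),
                           ch4_trait = "CH4",
                           production_traits = c("MY", "FY", "PY")) {
  b <- structural_coefficients(G, ch4_trait, production_traits)
  rbv0 <- residual_breeding_value(gebv, b, ch4_trait)
  rel <- mef_reliability(reliabilities, G, b, ch4_trait)
  out <- dplyr::left_join(rbv0, rel, by = "animal")
  ped <- pedigree[match(out$animal, pedigree$animal), ]
  if (!is.null(records)) {
    dtr <- records |>
      dplyr::distinct(.data$animal, .data$herd) |>
      dplyr::left_join(pedigree[, c("animal", "sire")], by = "animal") |>
      dplyr::filter(.data$sire != 0) |>
      dplyr::group_by(.data$sire) |>
      dplyr::summarise(n_daughters = dplyr::n_distinct(.data$animal),
                       n_daughter_herds = dplyr::n_distinct(.data$herd),
                       .groups = "drop")
    out$n_daughters <- dtr$n_daughters[match(out$animal, dtr$sire)]
    out$n_daughter_herds <- dtr$n_daughter_herds[match(out$animal, dtr$sire)]
    out$n_daughters[is.na(out$n_daughters)] <- 0L
    out$n_daughter_herds[is.na(out$n_daughter_herds)] <- 0L
  } else {
    out$n_daughters <- 0L
    out$n_daughter_herds <- 0L
  }
  out$official <- official_status(out$n_daughters, out$n_daughter_herds,
                                  out$reliability)
  out$is_base <- ped$sex == "M" &
    ped$birth_year >= base_years[1] & ped$birth_year <= base_years[2] &
    out$official
  if (sum(out$is_base, na.rm = TRUE) < 2) {
    # fall back to all base-window bulls when too few officials exist
    out$is_base <- ped$sex == "M" &
      ped$birth_year >= base_years[1] & ped$birth_year <= base_years[2]
  }
  out$rbv <- rbv_standardize(out$mef_index, out$is_base)
  class(out) <- c("mef_evaluation", class(out))
  out[, c("animal", "raw_mef", "mef_index", "rbv", "reliability",
          "n_daughters", "n_daughter_herds", "official", "is_base")]
}
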