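#' Prediction-error-variance reliabilities
#'
#' Exact per-animal per-trait reliabilities from the diagonal trait blocks
#' of the inverted mixed-model equations:
#' `rel = 1 - PEV / ((1 + F) * sigma2_a)`, clipped to [0, 1]. The inverse
#' blocks come from the Takahashi selected inverse of the system's sparse
#' Cholesky factor.
#'
#' @param solution an `mme_solution` from [solve_mme()] (direct method, so
#'   the factor is available; it is recomputed otherwise).
#' @param components (co)variance components used in the system; defaults
#'   to those stored in the system.
#' @return Tibble with columns `animal`, `trait`, `pev`, `reliability`.
#' @export
pev_reliability <- function(solution,
                            components = solution$system$components) {
  sys <- solution$system
  design <- sys$design
  k <- length(design$traits)
  bperm <- mme_block_ordering(mme_scalar_pattern(design, sys$rel_inverse))
  bf <- mme_block_factor(sys$C, k, bperm)
  sel <- block_selected_inverse(bf)
  lev <- design$ranges$animal
  bl <- selected_inverse_blocks(sel, lev, lev, k)
  Fv <- attr(sys$rel_inverse, "F")
  if (is.null(Fv)) Fv <- inbreeding_coefficients(design$pedigree)$F
  vg <- diag(components$G)
  out <- purrr::map_dfr(seq_len(k), function(t) {
    pev <- bl[, t, t]
    denom <- (1 + Fv) * vg[t]
    rel <- 1 - pev / denom
    if (any(rel < -1e-8)) {
      warning("PEV exceeded (1 + F) * sigma2_a for some animals; ",
              "reliabilities clipped to 0")
    }
    tibble::tibble(animal = design$levels$animal,
                   trait = design$traits[t],
                   pev = pev,
                   reliability = pmin(pmax(rel, 0), 1))
  })
  out
}

#' Blend direct-genomic and animal-model reliabilities
#'
#' The reliability of a genomically enhanced breeding value is approximated
#' by a weighted 80:20 average of the direct genomic value reliability and
#' the animal-model reliability.
#'
#' @param dgv_rel direct genomic value reliabilities, in [0, 1].
#' @param animal_model_rel animal-model reliabilities, in [0, 1].
#' @param weights the two blending weights (must sum to 1).
#' @return Numeric vector of blended reliabilities.
#' @export
blend_reliability <- function(dgv_rel, animal_model_rel,
                              weights = c(0.8, 0.2)) {
  if (any(dgv_rel < 0 | dgv_rel > 1, na.rm = TRUE) ||
      any(animal_model_rel < 0 | animal_model_rel > 1, na.rm = TRUE)) {
    stop("reliabilities must lie in [0, 1]")
  }
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-8)
  weights[1] * dgv_rel + weights[2] * animal_model_rel
}
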