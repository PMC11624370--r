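#' Trait (co)variance components of the four-trait model
#'
#' The herd-test-day animal model for methane predicted from milk MIR
#' (`CH4`), milk yield (`MY`), fat yield (`FY`) and protein yield (`PY`)
#' carries four 4x4 (co)variance matrices: `HTD` (herd-test-day), `G`
#' (additive genetic), `P` (permanent environment) and `R` (residual).
#' `covariance_components()` bundles and validates them;
#' `default_components()` builds the package default truth used by the
#' synthetic-data generator.
#'
#' @param HTD,G,P,R symmetric positive semi-definite 4x4 matrices (or k x k
#'   for a k-trait model), all with identical dimnames.
#' @return An object of class `covariance_components`: a named list of the
#'   four matrices plus the trait names.
#' @examples
#' cc <- default_components()
#' heritability(cc)
#' @export
covariance_components <- function(HTD, G, P, R) {
  mats <- list(HTD = HTD, G = G, P = P, R = R)
  k <- ncol(G)
  traits <- colnames(G)
  if (is.null(traits)) {
    traits <- paste0("trait", seq_len(k))
    mats <- lapply(mats, function(m) {
      dimnames(m) <- list(traits, traits)
      m
    })
  }
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
      stop(sprintf("component '%s' must be a %dx%d matrix", nm, k, k))
    }
    if (max(abs(m - t(m))) > 1e-8) {
      stop(sprintf("component '%s' is not symmetric", nm))
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop(sprintf("component '%s' is not positive semi-definite", nm))
    }
  }
  structure(c(mats, list(traits = traits)), class = "covariance_components")
}

#' @export
print.covariance_components <- function(x, ...) {
  cat("<covariance_components>", length(x$traits), "traits:",
      paste(x$traits, collapse = ", "), "\n")
  cat("heritabilities:", paste(sprintf("%s=%.3f", x$traits, heritability(x)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Default trait summary used to construct truth components
#'
#' Phenotypic means and standard deviations of weekly methane production
#' (g/d) and test-day milk, fat and protein yields (kg/d) typical of
#' first-lactation Holsteins, with heritabilities, genetic correlations and
#' phenotypic correlations of the four traits.
#'
#' @return A tibble with one row per trait.
#' @export
trait_parameters <- function() {
  tibble::tibble(
    trait = c("CH4", "MY", "FY", "PY"),
    mean = c(490.4, 33.3, 1.3, 1.1),
    sd = c(81.2, 5.0, 0.2, 0.2),
    h2 = c(0.23, 0.38, 0.27, 0.28)
  )
}

#' Default genetic correlation matrix of the four traits
#' @return 4x4 correlation matrix (order CH4, MY, FY, PY).
#' @export
genetic_correlations_default <- function() {
  rg <- diag(4)
  rg[1, 2] <- rg[2, 1] <- -0.13 # CH4-MY
  rg[1, 3] <- rg[3, 1] <- 0.38  # CH4-FY
  rg[1, 4] <- rg[4, 1] <- -0.11 # CH4-PY
  rg[2, 3] <- rg[3, 2] <- 0.48  # MY-FY
  rg[2, 4] <- rg[4, 2] <- 0.83  # MY-PY
  rg[3, 4] <- rg[4, 3] <- 0.71  # FY-PY
  rg
}

#' Default phenotypic correlation matrix of the four traits
#' @return 4x4 correlation matrix (order CH4, MY, FY, PY).
#' @export
phenotypic_correlations_default <- function() {
  rp <- diag(4)
  rp[1, 2] <- rp[2, 1] <- -0.06
  rp[1, 3] <- rp[3, 1] <- -0.18
  rp[1, 4] <- rp[4, 1] <- 0.01
  rp[2, 3] <- rp[3, 2] <- 0.66
  rp[2, 4] <- rp[4, 2] <- 0.90
  rp[3, 4] <- rp[4, 3] <- 0.74
  rp
}

#' Default truth (co)variance components
#'
#' Builds the four 4x4 matrices from published-scale trait summaries: the
#' phenotypic variance of each trait is its squared SD; the genetic variance
#' is `h2 * Vp`; herd-test-day and permanent-environment variances default
#' to 15% of `Vp` each; the residual takes the remainder. Genetic
#' covariances follow the genetic correlations; the part of each phenotypic
#' covariance not attributed to the genetic component is shared among HTD,
#' PE and residual in proportion to the geometric mean of their variances,
#' so the implied total phenotypic correlation matrix is honoured.
#'
#' @param htd_share,pe_share fractions of phenotypic variance assigned to
#'   the herd-test-day and permanent-environment effects (defaults 0.15).
#' @param params trait summary tibble as from [trait_parameters()].
#' @param rg,rp genetic and phenotypic correlation matrices.
#' @return A [covariance_components()] object.
#' @export
default_components <- function(htd_share = 0.15, pe_share = 0.15,
                               params = trait_parameters(),
                               rg = genetic_correlations_default(),
                               rp = phenotypic_correlations_default()) {
  k <- nrow(params)
  vp <- params$sd^2
  vg <- params$h2 * vp
  vhtd <- htd_share * vp
  vpe <- pe_share * vp
  vr <- vp - vg - vhtd - vpe
  if (any(vr <= 0)) stop("variance partition leaves non-positive residual")

  cov_from <- function(v, r) {
    s <- sqrt(v)
    m <- r * (s %o% s)
    diag(m) <- v
    m
  }
  G <- cov_from(vg, rg)
  Pmat_phen <- cov_from(vp, rp)
  # split the non-genetic phenotypic covariance proportionally
  s_htd <- sqrt(vhtd) %o% sqrt(vhtd)
  s_pe <- sqrt(vpe) %o% sqrt(vpe)
  s_r <- sqrt(vr) %o% sqrt(vr)
  tot <- s_htd + s_pe + s_r
  E <- Pmat_phen - G
  diag(E) <- 0
  HTD <- E * s_htd / tot; diag(HTD) <- vhtd
  P <- E * s_pe / tot; diag(P) <- vpe
  R <- E * s_r / tot; diag(R) <- vr
  tr <- params$trait
  dn <- list(tr, tr)
  dimnames(HTD) <- dimnames(G) <- dimnames(P) <- dimnames(R) <- dn
  covariance_components(HTD = HTD, G = G, P = P, R = R)
}

#' Heritability implied by a set of components
#'
#' Heritability per trait is the genetic variance over the sum of all four
#' variance components (herd-test-day included); set `include_htd = FALSE`
#' to drop the HTD variance from the denominator.
#'
#' @param components a [covariance_components()] object.
#' @param include_htd logical; include the HTD variance in the denominator.
#' @return Named numeric vector of heritabilities.
#' @export
heritability <- function(components, include_htd = TRUE) {
  d <- diag(components$G) + diag(components$P) + diag(components$R)
  if (include_htd) d <- d + diag(components$HTD)
  stats::setNames(diag(components$G) / d, components$traits)
}

#' Genetic correlation matrix implied by a set of components
#'
#' @inheritParams heritability
#' @return Correlation matrix of the genetic component.
#' @export
genetic_correlation <- function(components) {
  stats::cov2cor(components$G)
}
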