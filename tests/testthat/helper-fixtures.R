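# Shared fixtures, built in code. Sizes are kept small; statistical checks
# use seeds fixed here so the suite is deterministic.

small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = 40, n_founder_males = 10,
                        n_generations = 1, n_offspring_per_gen = 160,
                        female_fraction = 1, n_herds = 6, n_snps = 300,
                        genotyped_fraction = 0.3, seed = 101)
      cache <<- simulate_population(cfg)
    }
    cache
  }
})

random_pedigree <- function(n_founders, n_extra, seed) {
  cfg <- sim_config(n_founders = n_founders,
                    n_founder_males = max(2, n_founders %/% 3),
                    n_generations = 3,
                    n_offspring_per_gen = ceiling(n_extra / 3),
                    female_fraction = 0.5, seed = seed)
  simulate_pedigree(cfg)
}

# Dense restricted log-likelihood for a single-trait animal model --
# the brute-force oracle the sparse implementation is checked against.
dense_reml_logL_1trait <- function(records, pedigree, varcomp) {
  design <- build_design(records, pedigree, traits = "CH4")
  W <- as.matrix(design$W)
  rg <- design$ranges
  A <- solve(as.matrix(numerator_relationship_inverse(design$pedigree)))
  Z1 <- W[, rg$htd, drop = FALSE]
  Z2 <- W[, rg$animal, drop = FALSE]
  Z3 <- W[, rg$pe, drop = FALSE]
  X <- W[, rg$fixed, drop = FALSE]
  n <- nrow(W)
  V <- varcomp[1] * tcrossprod(Z1) + varcomp[2] * Z2 %*% A %*% t(Z2) +
    varcomp[3] * tcrossprod(Z3) + varcomp[4] * diag(n)
  y <- design$Y[, 1]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
                      t(y) %*% P %*% y)
}

one_trait_components <- function(v, trait = "CH4") {
  m <- function(x) matrix(x, 1, 1, dimnames = list(trait, trait))
  covariance_components(HTD = m(v[1]), G = m(v[2]), P = m(v[3]),
                        R = m(v[4]))
}
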