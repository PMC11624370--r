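#' Build the incidence structures of the herd-test-day animal model
#'
#' Constructs the sparse scalar (single-trait) design `W = [X Z1 Z2 Z3]`
#' for fixed effects (age-at-calving class, days-in-milk class,
#' year-season of calving), herd-test-day, additive animal and permanent
#' environment, plus the record-by-trait response matrix. The fixed-effect
#' model matrix is reduced to full column rank (aliased columns dropped).
#' Animal equations cover the whole pedigree so relatives without records
#' receive breeding values through the relationship matrix.
#'
#' @param records test-day record tibble (as from [simulate_phenotypes()]):
#'   must carry `animal`, `htd`, the fixed-effect class columns and one
#'   column per trait.
#' @param pedigree pedigree tibble; all record animals must appear in it.
#' @param traits character vector of trait columns (default the four-trait
#'   model).
#' @param fixed character vector of fixed-effect class columns.
#' @return A `mme_design` list: `W` (sparse n x m), `Y` (n x k), `ranges`
#'   (per-effect column index lists), `levels` (per-effect level keys),
#'   `traits`, and the sorted pedigree.
#' @export
build_design <- function(records, pedigree,
                         traits = c("CH4", "MY", "FY", "PY"),
                         fixed = c("ac_class", "dim_class", "year_season")) {
  ped <- sort_pedigree(pedigree)
  unknown <- setdiff(records$animal, ped$animal)
  if (length(unknown) > 0) {
    stop("records reference animals missing from the pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  n <- nrow(records)
  fixed <- fixed[purrr::map_lgl(fixed, function(f) {
    length(unique(records[[f]])) >= 2
  })]
  if (length(fixed) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
    X <- stats::model.matrix(fml, data = records)
  }
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")

  htd_lev <- sort(unique(records$htd))
  anim_lev <- as.character(ped$animal)
  pe_lev <- as.character(sort(unique(records$animal)))
  Z1 <- Matrix::sparseMatrix(i = seq_len(n),
                             j = match(records$htd, htd_lev),
                             x = 1, dims = c(n, length(htd_lev)))
  Z2 <- Matrix::sparseMatrix(i = seq_len(n),
                             j = match(as.character(records$animal), anim_lev),
                             x = 1, dims = c(n, length(anim_lev)))
  Z3 <- Matrix::sparseMatrix(i = seq_len(n),
                             j = match(as.character(records$animal), pe_lev),
                             x = 1, dims = c(n, length(pe_lev)))
  W <- cbind(Xs, Z1, Z2, Z3)
  p <- ncol(Xs)
  ranges <- list(
    fixed = seq_len(p),
    htd = p + seq_along(htd_lev),
    animal = p + length(htd_lev) + seq_along(anim_lev),
    pe = p + length(htd_lev) + length(anim_lev) + seq_along(pe_lev)
  )
  Y <- as.matrix(records[, traits])
  structure(
    list(W = W, Y = Y, ranges = ranges,
         levels = list(fixed = colnames(X), htd = htd_lev,
                       animal = anim_lev, pe = pe_lev),
         traits = traits, pedigree = ped, n_records = n),
    class = "mme_design"
  )
}

#' Assemble the multi-trait mixed-model equations
#'
#' Standard Henderson MME with the residual-inverse on the data blocks and
#' `HTD^-1 x I`, `G^-1 x K^-1` (K = A or H), `P^-1 x I` added to the
#' herd-test-day, animal and permanent-environment blocks. Equations are
#' ordered scalar-level major, trait minor.
#'
#' @param design an `mme_design` from [build_design()].
#' @param components a [covariance_components()] object.
#' @param rel_inverse sparse relationship inverse (A or H) over the design's
#'   animal levels, in the same order ([numerator_relationship_inverse()] or
#'   [h_inverse()]).
#' @return An `mme_system` list: `C` (sparse symmetric LHS), `rhs`,
#'   `design`, `components`, `rel_inverse`.
#' @export
assemble_mme <- function(design, components, rel_inverse) {
  k <- length(design$traits)
  for (nm in c("HTD", "G", "P", "R")) {
    m <- components[[nm]][design$traits, design$traits, drop = FALSE]
    if (rcond(m) < 1e-14) stop("component matrix ", nm, " is singular")
  }
  cc <- lapply(components[c("HTD", "G", "P", "R")], function(m) {
    m[design$traits, design$traits, drop = FALSE]
  })
  Rinv <- solve(cc$R)
  WtW <- Matrix::crossprod(design$W)
  Cdat <- Matrix::kronecker(WtW, Rinv)
  p <- length(design$ranges$fixed)
  q1 <- length(design$ranges$htd)
  q2 <- length(design$ranges$animal)
  q3 <- length(design$ranges$pe)
  if (nrow(rel_inverse) != q2) {
    stop("rel_inverse dimension does not match the animal equations")
  }
  Crand <- Matrix::bdiag(
    Matrix::Matrix(0, p * k, p * k, sparse = TRUE),
    Matrix::kronecker(Matrix::Diagonal(q1), solve(cc$HTD)),
    Matrix::kronecker(rel_inverse, solve(cc$G)),
    Matrix::kronecker(Matrix::Diagonal(q3), solve(cc$P))
  )
  C <- Matrix::forceSymmetric(Matrix::drop0(Cdat + Crand))
  rhs_mat <- as.matrix(Matrix::crossprod(design$W, design$Y) %*% Rinv)
  structure(
    list(C = C, rhs = as.numeric(t(rhs_mat)), design = design,
         components = covariance_components(HTD = cc$HTD, G = cc$G,
                                            P = cc$P, R = cc$R),
         rel_inverse = rel_inverse, WtW = WtW),
    class = "mme_system"
  )
}

#' Solve the mixed-model equations
#'
#' Direct solution via a sparse Cholesky factorization, or a Jacobi
#' preconditioned conjugate-gradient iteration. Both return identical
#' solutions within tolerance; the factorization is kept for reuse
#' (prediction-error variances, REML traces).
#'
#' @param system an `mme_system` from [assemble_mme()].
#' @param method `"cholesky"` (direct, default) or `"cg"`.
#' @param tol residual tolerance for the iterative method.
#' @param max_iter iteration cap for the iterative method.
#' @return An `mme_solution` list: per-effect solution tibbles (`fixed`,
#'   `htd`, `ebv`, `pe`), the full solution matrix `theta` (scalar levels x
#'   traits), residual tibble, convergence info and (for the direct
#'   method) the Cholesky factor.
#' @export
solve_mme <- function(system, method = c("cholesky", "cg"), tol = 1e-10,
                      max_iter = 2000) {
  method <- match.arg(method)
  C <- system$C
  b <- system$rhs
  factor <- NULL
  iterations <- NA_integer_
  if (method == "cholesky") {
    factor <- Matrix::Cholesky(C, LDL = FALSE, super = FALSE, perm = TRUE)
    x <- as.numeric(Matrix::solve(factor, b))
  } else {
    d <- Matrix::diag(C)
    x <- numeric(length(b))
    r <- b - as.numeric(C %*% x)
    z <- r / d
    pdir <- z
    rz <- sum(r * z)
    bn <- sqrt(sum(b^2))
    if (bn == 0) bn <- 1
    for (it in seq_len(max_iter)) {
      Ap <- as.numeric(C %*% pdir)
      alpha <- rz / sum(pdir * Ap)
      x <- x + alpha * pdir
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) / bn < tol) break
      z <- r / d
      rz_new <- sum(r * z)
      pdir <- z + (rz_new / rz) * pdir
      rz <- rz_new
    }
    iterations <- it
    if (sqrt(sum(r^2)) / bn >= tol) {
      warning("conjugate gradient did not reach tolerance ", tol,
              " in ", max_iter, " iterations")
    }
  }
  k <- length(system$design$traits)
  theta <- matrix(x, ncol = k, byrow = TRUE)
  colnames(theta) <- system$design$traits
  rg <- system$design$ranges
  lv <- system$design$levels
  as_tbl <- function(range, levels, keycol) {
    out <- tibble::as_tibble(theta[range, , drop = FALSE])
    out <- dplyr::bind_cols(tibble::tibble("{keycol}" := levels), out)
    out
  }
  resid <- system$design$Y - as.matrix(system$design$W %*% theta)
  structure(
    list(
      theta = theta,
      fixed = as_tbl(rg$fixed, lv$fixed, "term"),
      htd = as_tbl(rg$htd, lv$htd, "htd"),
      ebv = as_tbl(rg$animal, lv$animal, "animal"),
      pe = as_tbl(rg$pe, lv$pe, "animal"),
      residuals = tibble::as_tibble(resid),
      method = method, iterations = iterations,
      factor = factor, system = system
    ),
    class = "mme_solution"
  )
}
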