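vech_index <- function(k) {
  ij <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
}

mats_to_par <- function(mats, k) {
  idx <- vech_index(k)
  unlist(lapply(mats, function(m) m[idx]))
}

par_to_mats <- function(par, k, names) {
  idx <- vech_index(k)
  nper <- nrow(idx)
  out <- list()
  for (h in seq_along(names)) {
    m <- matrix(0, k, k)
    v <- par[(h - 1) * nper + seq_len(nper)]
    m[idx] <- v
    m[idx[, c(2, 1), drop = FALSE]] <- v
    out[[names[h]]] <- m
  }
  out
}

is_pd <- function(m, tol = 1e-10) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

#' Multi-trait REML for the herd-test-day animal model
#'
#' Estimates the four (co)variance matrices (herd-test-day, additive
#' genetic, permanent environment, residual) of the multi-trait animal
#' model by restricted maximum likelihood. The default algorithm takes a
#' few expectation-maximization (EM) steps and then switches to
#' average-information (AI) updates with step-halving back toward the EM
#' update whenever a proposed step leaves the positive-definite cone;
#' `method = "em"` runs pure EM, whose restricted likelihood is
#' non-decreasing by construction. All trace terms come from a Takahashi
#' selected inverse of the sparse mixed-model-equation factor.
#'
#' @param records test-day records (see [build_design()]).
#' @param pedigree pedigree tibble.
#' @param traits trait columns to analyse.
#' @param start optional [covariance_components()] starting values; by
#'   default the phenotypic covariance is split 15/25/15/45% over
#'   HTD/G/P/R.
#' @param method `"ai"` (EM-warmed average information, default) or
#'   `"em"`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the relative parameter change.
#' @param em_iterations EM warm-up iterations before AI steps.
#' @param rel_inverse optional relationship inverse (A or H) over the
#'   pedigree; built from the pedigree when `NULL`.
#' @param verbose print the iteration trace.
#' @return A `reml_fit` object: estimated `components`, `trace` tibble
#'   (iteration, restricted log-likelihood, step type, criterion),
#'   `converged`, approximate sampling covariance of the estimates from
#'   the AI matrix (`ai_inverse`), and the final solutions.
#' @export
reml_estimate <- function(records, pedigree,
                          traits = c("CH4", "MY", "FY", "PY"),
                          start = NULL, method = c("ai", "em"),
                          max_iter = 100, tol = 1e-4, em_iterations = 2,
                          rel_inverse = NULL, verbose = FALSE) {
  method <- match.arg(method)
  design <- build_design(records, pedigree, traits = traits)
  k <- length(traits)
  if (is.null(rel_inverse)) {
    rel_inverse <- numerator_relationship_inverse(design$pedigree)
  }
  logdet_K <- attr(rel_inverse, "logdet_A")
  if (is.null(logdet_K)) {
    ch <- Matrix::Cholesky(methods::as(rel_inverse, "symmetricMatrix"),
                           LDL = FALSE, super = FALSE, perm = TRUE)
    logdet_K <- -2 * sum(log(Matrix::diag(methods::as(
      Matrix::expand(ch)$L, "CsparseMatrix"))))
  }
  if (is.null(start)) {
    Vp <- stats::cov(design$Y)
    mats <- list(HTD = 0.15 * Vp, G = 0.25 * Vp, P = 0.15 * Vp,
                 R = 0.45 * Vp)
  } else {
    mats <- lapply(start[c("HTD", "G", "P", "R")], function(m) {
      unname(m[traits, traits, drop = FALSE])
    })
  }
  mat_names <- c("HTD", "G", "P", "R")
  n <- design$n_records
  rg <- design$ranges
  q <- c(HTD = length(rg$htd), G = length(rg$animal), P = length(rg$pe))

  # record-level scalar indices for AI working vectors
  ridx <- list(
    HTD = match(records$htd, design$levels$htd),
    G = match(as.character(records$animal), design$levels$animal),
    P = match(as.character(records$animal), design$levels$pe)
  )
  # lower-triangle weight triplets for the trace matrices
  Ktri <- methods::as(Matrix::tril(methods::as(rel_inverse, "generalMatrix")),
                      "TsparseMatrix")
  bperm <- mme_block_ordering(mme_scalar_pattern(design, rel_inverse))
  ij <- vech_index(k)
  npar_m <- nrow(ij)
  par_names <- unlist(lapply(mat_names, function(nm) {
    paste0(nm, "[", traits[ij[, 1]], ",", traits[ij[, 2]], "]")
  }))

  trace_tbl <- tibble::tibble(iteration = integer(), logL = numeric(),
                              step = character(), criterion = numeric())
  converged <- FALSE
  ai_mat <- NULL
  delta_prev <- NULL

  eval_state <- function(mats) {
    mats <- lapply(mats, function(m) {
      dimnames(m) <- list(traits, traits)
      m
    })
    cc <- covariance_components(HTD = mats$HTD, G = mats$G, P = mats$P,
                                R = mats$R)
    sys <- assemble_mme(design, cc, rel_inverse)
    bf <- mme_block_factor(sys$C, k, bperm)
    x <- block_solve(bf, sys$rhs)
    theta <- matrix(x, ncol = k, byrow = TRUE)
    E <- design$Y - as.matrix(design$W %*% theta)
    Rinv <- solve(mats$R)
    logdet_C <- bf$logdet
    yPy <- sum((design$Y %*% Rinv) * design$Y) - sum(x * sys$rhs)
    m2logL <- n * determinant(mats$R)$modulus +
      q["HTD"] * determinant(mats$HTD)$modulus +
      q["G"] * determinant(mats$G)$modulus + k * logdet_K +
      q["P"] * determinant(mats$P)$modulus + logdet_C + yPy
    sel <- block_selected_inverse(bf)
    WtWt <- methods::as(Matrix::tril(methods::as(sys$WtW, "generalMatrix")),
                        "TsparseMatrix")
    S <- list()
    bl <- selected_inverse_blocks(sel, rg$htd, rg$htd, k)
    S$HTD <- trace_matrix_from_blocks(bl, rep(1, q["HTD"]),
                                      rep(FALSE, q["HTD"]), k)
    bl <- selected_inverse_blocks(sel, rg$animal[Ktri@i + 1L],
                                  rg$animal[Ktri@j + 1L], k)
    S$G <- trace_matrix_from_blocks(bl, Ktri@x, Ktri@i != Ktri@j, k)
    bl <- selected_inverse_blocks(sel, rg$pe, rg$pe, k)
    S$P <- trace_matrix_from_blocks(bl, rep(1, q["P"]),
                                    rep(FALSE, q["P"]), k)
    bl <- selected_inverse_blocks(sel, WtWt@i + 1L, WtWt@j + 1L, k)
    S$R <- trace_matrix_from_blocks(bl, WtWt@x, WtWt@i != WtWt@j, k)

    U <- list(HTD = theta[rg$htd, , drop = FALSE],
              G = theta[rg$animal, , drop = FALSE],
              P = theta[rg$pe, , drop = FALSE])
    UKU <- list(
      HTD = crossprod(U$HTD),
      G = as.matrix(Matrix::crossprod(U$G, rel_inverse %*% U$G)),
      P = crossprod(U$P)
    )
    list(mats = mats, sys = sys, bf = bf, theta = theta, E = E,
         Rinv = Rinv, logL = -0.5 * as.numeric(m2logL), S = S, U = U,
         UKU = UKU)
  }

  em_update <- function(st) {
    list(
      HTD = (st$UKU$HTD + st$S$HTD) / q["HTD"],
      G = (st$UKU$G + st$S$G) / q["G"],
      P = (st$UKU$P + st$S$P) / q["P"],
      R = (crossprod(st$E) + st$S$R) / n
    )
  }

  score_vector <- function(st) {
    sc <- numeric(0)
    for (nm in mat_names) {
      if (nm == "R") {
        Minv <- st$Rinv
        Q <- Minv %*% crossprod(st$E) %*% Minv
        Sm <- st$S$R
        qq <- n
      } else {
        Minv <- solve(st$mats[[nm]])
        Q <- Minv %*% st$UKU[[nm]] %*% Minv
        Sm <- st$S[[nm]]
        qq <- q[nm]
      }
      for (r in seq_len(npar_m)) {
        i <- ij[r, 1]; j <- ij[r, 2]
        mult <- if (i == j) 1 else 2
        trJMinv <- mult * Minv[i, j]
        MJM <- Minv[, i] %o% Minv[j, ] + (if (i == j) 0 else
          Minv[, j] %o% Minv[i, ])
        trPdV <- qq * trJMinv - sum(MJM * Sm)
        ydVy <- mult * Q[i, j]
        sc <- c(sc, -0.5 * (trPdV - ydVy))
      }
    }
    sc
  }

  ai_matrix <- function(st) {
    npar <- npar_m * 4
    Flist <- vector("list", npar)
    pidx <- 1L
    for (nm in mat_names) {
      if (nm == "R") {
        M <- st$E %*% st$Rinv
        for (r in seq_len(npar_m)) {
          i <- ij[r, 1]; j <- ij[r, 2]
          f <- matrix(0, n, k)
          if (i == j) {
            f[, i] <- M[, i]
          } else {
            f[, j] <- f[, j] + M[, i]
            f[, i] <- f[, i] + M[, j]
          }
          Flist[[pidx]] <- f
          pidx <- pidx + 1L
        }
      } else {
        M <- (st$U[[nm]] %*% solve(st$mats[[nm]]))[ridx[[nm]], ,
                                                   drop = FALSE]
        for (r in seq_len(npar_m)) {
          i <- ij[r, 1]; j <- ij[r, 2]
          f <- matrix(0, n, k)
          if (i == j) {
            f[, i] <- M[, i]
          } else {
            f[, j] <- f[, j] + M[, i]
            f[, i] <- f[, i] + M[, j]
          }
          Flist[[pidx]] <- f
          pidx <- pidx + 1L
        }
      }
    }
    RHS <- vapply(Flist, function(f) {
      as.numeric(t(as.matrix(Matrix::crossprod(design$W, f %*% st$Rinv))))
    }, numeric(nrow(st$sys$C)))
    TH <- block_solve(st$bf, RHS)
    PF <- vector("list", npar)
    for (p in seq_len(npar)) {
      th <- matrix(TH[, p], ncol = k, byrow = TRUE)
      PF[[p]] <- (Flist[[p]] - as.matrix(design$W %*% th)) %*% st$Rinv
    }
    AI <- matrix(0, npar, npar)
    for (p in seq_len(npar)) {
      for (s2 in p:npar) {
        AI[p, s2] <- AI[s2, p] <- 0.5 * sum(Flist[[p]] * PF[[s2]])
      }
    }
    AI
  }

  st <- eval_state(mats)
  for (iter in seq_len(max_iter)) {
    use_em <- method == "em" || iter <= em_iterations
    em_mats <- em_update(st)
    step_type <- "em"
    new_mats <- em_mats
    if (use_em) delta_prev <- NULL
    if (!use_em) {
      sc <- score_vector(st)
      AI <- ai_matrix(st)
      ai_mat <- AI
      delta <- tryCatch(solve(AI + diag(1e-10 * max(diag(AI)),
                                        nrow(AI)), sc),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        # geometric step decay in a stable direction: extrapolate the
        # remaining tail of the series (Aitken-style boost)
        boost <- 1
        if (!is.null(delta_prev)) {
          n1 <- sqrt(sum(delta^2)); n0 <- sqrt(sum(delta_prev^2))
          if (n1 > 0 && n0 > 0) {
            cosang <- sum(delta * delta_prev) / (n1 * n0)
            ratio <- n1 / n0
            if (cosang > 0.9 && ratio < 0.95) {
              boost <- min(1 / (1 - ratio), 20)
            }
          }
        }
        delta_prev <- delta
        par_cur <- mats_to_par(st$mats[mat_names], k)
        for (step in unique(c(boost, 1, 0.5, 0.25, 0.125, 0.0625,
                              0.03125, 0.015625))) {
          cand <- par_to_mats(par_cur + step * delta, k, mat_names)
          if (all(vapply(cand, is_pd, logical(1)))) {
            new_mats <- cand
            step_type <- if (step > 1) "ai-boost" else
              if (step == 1) "ai" else "ai-halved"
            break
          }
        }
      }
    }
    par_old <- mats_to_par(st$mats[mat_names], k)
    par_new <- mats_to_par(new_mats, k)
    crit <- sqrt(sum((par_new - par_old)^2) / max(sum(par_old^2), 1e-12))
    st_new <- eval_state(new_mats)
    if (method == "em" && st_new$logL < st$logL - 1e-6) {
      warning("EM restricted log-likelihood decreased; check conditioning")
    }
    st <- st_new
    trace_tbl <- dplyr::bind_rows(trace_tbl, tibble::tibble(
      iteration = iter, logL = st$logL, step = step_type, criterion = crit))
    if (verbose) {
      message(sprintf("iter %3d [%9s] logL = %.4f crit = %.3e", iter,
                      step_type, st$logL, crit))
    }
    if (crit < tol && iter > em_iterations) {
      converged <- TRUE
      break
    }
  }

  cc <- covariance_components(
    HTD = structure(st$mats$HTD, dimnames = list(traits, traits)),
    G = structure(st$mats$G, dimnames = list(traits, traits)),
    P = structure(st$mats$P, dimnames = list(traits, traits)),
    R = structure(st$mats$R, dimnames = list(traits, traits))
  )
  se <- NULL
  if (!is.null(ai_mat)) {
    V <- tryCatch(solve(ai_mat), error = function(e) NULL)
    if (!is.null(V)) se <- stats::setNames(sqrt(pmax(diag(V), 0)), par_names)
  }
  structure(
    list(components = cc, trace = trace_tbl, converged = converged,
         iterations = nrow(trace_tbl), method = method, se = se,
         ai_inverse = if (!is.null(ai_mat)) tryCatch(solve(ai_mat),
                                                     error = function(e) NULL),
         par_names = par_names, traits = traits,
         n_records = n, n_levels = q, logL = st$logL,
         theta = st$theta, design = design, rel_inverse = rel_inverse),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", x$method, "| traits:", paste(x$traits, collapse = ", "),
      "\n")
  cat(sprintf("records: %d | converged: %s after %d iterations | logL = %.3f\n",
              x$n_records, x$converged, x$iterations, x$logL))
  cat("heritabilities:",
      paste(sprintf("%s=%.3f", x$traits, heritability(x$components)),
            collapse = ", "), "\n")
  invisible(x)
}
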