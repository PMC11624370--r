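#' Validate and topologically sort a pedigree
#'
#' Ensures every parent id is either 0 (unknown) or present in the table,
#' that no animal is its own ancestor, and returns the table ordered so
#' parents precede offspring.
#'
#' @param pedigree tibble/data frame with columns `animal`, `sire`, `dam`
#'   (0 = unknown parent).
#' @return The pedigree tibble in topological order, with an integer
#'   `.depth` column (founders = 0) removed before return.
#' @export
sort_pedigree <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  ids <- ped$animal
  if (anyDuplicated(ids)) stop("duplicate animal ids in pedigree")
  idx <- stats::setNames(seq_along(ids), ids)
  par_idx <- function(p) ifelse(p == 0, 0L, idx[as.character(p)])
  si <- par_idx(ped$sire)
  di <- par_idx(ped$dam)
  if (anyNA(si) || anyNA(di)) {
    stop("pedigree references parents that are not listed as animals")
  }
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  state <- integer(n) # 0 = unvisited, 1 = in progress, 2 = done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      if (state[i] == 2L) {
        stack <- stack[-length(stack)]
        next
      }
      state[i] <- 1L
      pend <- c(si[i], di[i])
      pend <- pend[pend != 0L & state[pend] != 2L]
      if (any(state[pend] == 1L)) {
        stop("pedigree contains a cycle (an animal is its own ancestor)")
      }
      if (length(pend) == 0) {
        dpar <- c(si[i], di[i])
        dpar <- dpar[dpar != 0L]
        depth[i] <- if (length(dpar) == 0) 0L else max(depth[dpar]) + 1L
        state[i] <- 2L
        stack <- stack[-length(stack)]
      } else {
        stack <- c(stack, pend)
      }
    }
  }
  ped[order(depth, seq_len(n)), , drop = FALSE]
}

recoded_pedigree <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  list(
    ped = ped,
    sire = ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)]),
    dam = ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)]),
    ids = as.character(ped$animal)
  )
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F for every animal by the Meuwissen-Luo ancestor-traversal
#' algorithm: the diagonal of the numerator relationship matrix is
#' accumulated from the Cholesky column of each animal over its ancestors,
#' using the within-family (Mendelian sampling) variances, so F =
#' 0.5 a(sire, dam) without ever forming A. Animals with an unknown parent
#' have F = 0.
#'
#' @inheritParams sort_pedigree
#' @return Tibble with columns `animal` and `F`, in the input order of
#'   `pedigree`.
#' @export
inbreeding_coefficients <- function(pedigree) {
  rp <- recoded_pedigree(pedigree)
  n <- nrow(rp$ped)
  sire <- rp$sire; dam <- rp$dam
  Fc <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (sire[i] > 0) Fc[sire[i]] else -1
    Fd <- if (dam[i] > 0) Fc[dam[i]] else -1
    d[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (sire[i] == 0L || dam[i] == 0L) {
      Fc[i] <- 0
    } else {
      L <- numeric(i)
      L[i] <- 1
      acc <- -1
      for (j in i:1) {
        if (L[j] != 0) {
          acc <- acc + L[j]^2 * d[j]
          if (sire[j] > 0) L[sire[j]] <- L[sire[j]] + 0.5 * L[j]
          if (dam[j] > 0) L[dam[j]] <- L[dam[j]] + 0.5 * L[j]
        }
      }
      Fc[i] <- acc
    }
  }
  out <- tibble::tibble(animal = rp$ped$animal, F = Fc)
  out[match(pedigree$animal, out$animal), ]
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive genetic relationship matrix A, intended for small
#' pedigrees (oracles, genotyped subsets for H construction). The diagonal
#' equals 1 + F.
#'
#' @inheritParams sort_pedigree
#' @return Dense symmetric matrix with animal ids as dimnames, rows in
#'   topological order.
#' @export
numerator_relationship <- function(pedigree) {
  rp <- recoded_pedigree(pedigree)
  n <- nrow(rp$ped)
  sire <- rp$sire; dam <- rp$dam
  A <- matrix(0, n, n, dimnames = list(rp$ids, rp$ids))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    a_sd <- if (s > 0 && d > 0) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * a_sd
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (s > 0) aj <- aj + 0.5 * A[j, s]
      if (d > 0) aj <- aj + 0.5 * A[j, d]
      A[j, i] <- aj
      A[i, j] <- aj
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from pedigree contributions without forming
#' A, using inbreeding-adjusted Mendelian-sampling variances: for animal i
#' with parents s, d the within-family variance is
#' `0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F with one known parent, 1 with
#' none) and its reciprocal is scattered over the (i, s, d) block.
#'
#' @inheritParams sort_pedigree
#' @param F optional tibble from [inbreeding_coefficients()]; computed when
#'   missing.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with animal ids
#'   as dimnames, in topological order. Attribute `logdet_A` carries
#'   log|A| (the sum of log Mendelian-sampling variances), and attribute
#'   `F` the inbreeding coefficients in matrix order.
#' @export
numerator_relationship_inverse <- function(pedigree, F = NULL) {
  rp <- recoded_pedigree(pedigree)
  n <- nrow(rp$ped)
  sire <- rp$sire; dam <- rp$dam
  if (is.null(F)) F <- inbreeding_coefficients(rp$ped)
  Fv <- F$F[match(rp$ped$animal, F$animal)]
  Fs <- ifelse(sire > 0, Fv[pmax(sire, 1L)], -1)
  Fd <- ifelse(dam > 0, Fv[pmax(dam, 1L)], -1)
  m <- 0.5 - 0.25 * (Fs + Fd)
  alpha <- 1 / m
  anim <- seq_len(n)
  add <- function(a, b, v) list(i = pmax(a, b), j = pmin(a, b), x = v)
  tri <- list(list(i = anim, j = anim, x = alpha))
  for (p in list(sire, dam)) {
    k <- which(p > 0)
    if (length(k)) {
      tri <- c(tri, list(add(anim[k], p[k], -0.5 * alpha[k])),
               list(list(i = p[k], j = p[k], x = 0.25 * alpha[k])))
    }
  }
  both <- which(sire > 0 & dam > 0)
  if (length(both)) {
    tri <- c(tri, list(add(sire[both], dam[both], 0.25 * alpha[both])))
  }
  i <- unlist(lapply(tri, `[[`, "i"))
  j <- unlist(lapply(tri, `[[`, "j"))
  x <- unlist(lapply(tri, `[[`, "x"))
  Ainv <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                               symmetric = TRUE,
                               dimnames = list(rp$ids, rp$ids))
  attr(Ainv, "logdet_A") <- sum(log(m))
  attr(Ainv, "F") <- Fv
  Ainv
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` with `Z = M - 2p`. Optionally tunes the
#' mean diagonal and mean off-diagonal of G to those of the pedigree
#' relationships among genotyped animals (A22) by a scalar affine map, and
#' blends `G* = (1 - w) G + w A22` to guarantee invertibility.
#'
#' @param genotypes animals x SNP matrix of 0/1/2 with animal ids as
#'   rownames.
#' @param allele_freqs optional per-SNP frequencies; computed from the
#'   genotyped set when `NULL`.
#' @param A22 pedigree relationship matrix of the genotyped animals (same
#'   order); required when `tune` or `blend_weight > 0`.
#' @param blend_weight pedigree blending weight w in [0, 1].
#' @param tune logical; tune mean diagonal/off-diagonal to A22 first.
#' @return Dense symmetric matrix over genotyped animals.
#' @export
genomic_relationship <- function(genotypes, allele_freqs = NULL, A22 = NULL,
                                 blend_weight = 0.05, tune = !is.null(A22)) {
  M <- as.matrix(genotypes)
  if (nrow(M) < 2) stop("at least 2 genotyped animals are required")
  p <- if (is.null(allele_freqs)) colMeans(M) / 2 else allele_freqs
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs are monomorphic; G is undefined")
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  Z <- sweep(M[, keep, drop = FALSE], 2, 2 * p[keep])
  G <- tcrossprod(Z) / denom
  if ((tune || blend_weight > 0) && is.null(A22)) {
    stop("A22 is required for tuning or blending")
  }
  if (tune) {
    n <- nrow(G)
    off <- row(G) != col(G)
    md_g <- mean(diag(G)); mo_g <- mean(G[off])
    md_a <- mean(diag(A22)); mo_a <- mean(A22[off])
    # solve b + a * mean = target for diagonal and off-diagonal means
    a <- (md_a - mo_a) / (md_g - mo_g)
    b <- md_a - a * md_g
    G <- a * G + b
  }
  if (blend_weight > 0) {
    G <- (1 - blend_weight) * G + blend_weight * A22
  }
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Inverse of the single-step H matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]` on the genotyped block: the
#' pedigree relationship inverse is corrected where genomic information is
#' available, which is all single-step GBLUP needs.
#'
#' @param A_inv sparse pedigree relationship inverse
#'   ([numerator_relationship_inverse()]) with animal ids as dimnames.
#' @param A22 dense pedigree relationships among genotyped animals.
#' @param G_blended blended genomic relationship matrix (same order as
#'   `A22`).
#' @param genotyped_ids animal ids of the genotyped block, matching the
#'   rows of `A22`/`G_blended`.
#' @return Sparse symmetric matrix with the same dimnames as `A_inv`.
#' @export
h_inverse <- function(A_inv, A22, G_blended, genotyped_ids) {
  ids <- rownames(A_inv)
  pos <- match(as.character(genotyped_ids), ids)
  if (anyNA(pos)) stop("genotyped ids missing from the pedigree: ",
                       paste(genotyped_ids[is.na(pos)], collapse = ", "))
  H <- methods::as(A_inv, "generalMatrix")
  if (length(pos) > 0) {
    corr <- solve(G_blended) - solve(A22)
    n <- nrow(A_inv)
    C <- Matrix::sparseMatrix(
      i = rep(pos, times = length(pos)),
      j = rep(pos, each = length(pos)),
      x = as.numeric(corr), dims = c(n, n)
    )
    H <- H + C
  }
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  dimnames(H) <- dimnames(A_inv)
  H
}
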