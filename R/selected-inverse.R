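# Selected inversion of multi-trait MME coefficient matrices.
#
# The coefficient matrix has dense k x k trait blocks on a scalar-level
# sparsity pattern. A fill-reducing ordering is computed at block level so
# the Cholesky factor stays block-aligned; the Takahashi recurrences then
# run blockwise in compiled code, yielding every inverse entry on the
# factor pattern -- which covers all trace terms REML needs and all
# prediction-error-variance blocks.

#' Scalar-level sparsity pattern of an assembled MME
#' @noRd
mme_scalar_pattern <- function(design, rel_inverse) {
  m <- ncol(design$W)
  P0 <- methods::as(abs(Matrix::crossprod(design$W)), "generalMatrix")
  an <- design$ranges$animal
  Ka <- methods::as(abs(rel_inverse), "TsparseMatrix")
  add <- Matrix::sparseMatrix(i = an[Ka@i + 1L], j = an[Ka@j + 1L],
                              x = Ka@x, dims = c(m, m))
  Matrix::forceSymmetric(P0 + add + Matrix::t(add) + Matrix::Diagonal(m))
}

#' Block-aligned fill-reducing ordering from the scalar pattern
#' @noRd
mme_block_ordering <- function(pattern) {
  m <- nrow(pattern)
  spd <- pattern + Matrix::Diagonal(m, Matrix::rowSums(abs(pattern)))
  ch <- Matrix::Cholesky(methods::as(spd, "symmetricMatrix"), LDL = FALSE,
                         super = FALSE, perm = TRUE)
  ch@perm + 1L # factor position -> original block
}

#' Factor an MME coefficient matrix under a block-aligned ordering
#'
#' @param C assembled coefficient matrix (equations = blocks x traits,
#'   trait minor).
#' @param k traits per block.
#' @param bperm block ordering from [mme_block_ordering()].
#' @return A `block_factor` list with the CHOLMOD factor of the permuted
#'   matrix, the equation-level permutation and the log-determinant.
#' @noRd
mme_block_factor <- function(C, k, bperm) {
  nb <- length(bperm)
  pp <- as.integer(rep((bperm - 1L) * k, each = k) + seq_len(k))
  Cp <- Matrix::forceSymmetric(C[pp, pp])
  ch <- Matrix::Cholesky(Cp, LDL = FALSE, super = FALSE, perm = FALSE)
  L <- methods::as(Matrix::expand(ch)$L, "CsparseMatrix")
  list(chol = ch, L = L, pp = pp, k = k, nb = nb,
       bperm_inv = Matrix::invPerm(bperm),
       logdet = 2 * sum(log(Matrix::diag(L))))
}

#' Solve against a block factor (vector or matrix right-hand side)
#' @noRd
block_solve <- function(bf, b) {
  if (is.matrix(b)) {
    x <- as.matrix(Matrix::solve(bf$chol, b[bf$pp, , drop = FALSE]))
    out <- x
    out[bf$pp, ] <- x
    out
  } else {
    x <- as.numeric(Matrix::solve(bf$chol, b[bf$pp]))
    out <- numeric(length(b))
    out[bf$pp] <- x
    out
  }
}

#' Takahashi selected inverse over the block factor pattern
#' @noRd
block_selected_inverse <- function(bf) {
  z <- cpp_block_takahashi(bf$L@p, bf$L@i, bf$L@x, bf$nb, bf$k)
  c(z, list(k = bf$k, bf = bf))
}

#' Trait-block entries of the inverse for scalar level pairs
#'
#' Levels are original (unpermuted) scalar indices; for each pair the full
#' k x k trait block of the inverse of C is returned. Entries outside the
#' factor pattern (possible only if structural zeros were dropped during
#' assembly) are recomputed by direct solves.
#'
#' @param sel result of [block_selected_inverse()].
#' @param level_i,level_j 1-based scalar level indices.
#' @param ntrait number of traits (must equal the factor's block size).
#' @return Array `length(level_i) x ntrait x ntrait`.
#' @noRd
selected_inverse_blocks <- function(sel, level_i, level_j, ntrait) {
  stopifnot(ntrait == sel$k)
  bi <- sel$bf$bperm_inv[level_i] - 1L
  bj <- sel$bf$bperm_inv[level_j] - 1L
  out <- cpp_block_lookup(sel$Bp, sel$Bi, sel$Zx, as.integer(bi),
                          as.integer(bj), as.integer(ntrait))
  dim(out) <- c(length(level_i), ntrait, ntrait)
  if (anyNA(out)) {
    bad <- which(apply(is.na(out), 1, any))
    n_eq <- sel$bf$nb * sel$k
    for (p in bad) {
      ej <- (level_j[p] - 1L) * ntrait + seq_len(ntrait)
      Emat <- matrix(0, n_eq, ntrait)
      Emat[cbind(ej, seq_len(ntrait))] <- 1
      sol <- block_solve(sel$bf, Emat)
      ei <- (level_i[p] - 1L) * ntrait + seq_len(ntrait)
      out[p, , ] <- sol[ei, , drop = FALSE]
    }
  }
  out
}

#' Accumulate a trait-space trace matrix over weighted scalar pairs
#'
#' Computes `S[a, b] = sum_{l,m} K[l, m] * Cinv[(l, a), (m, b)]` from the
#' lower triangle of the weight matrix K, using symmetry of the inverse.
#'
#' @param blocks array from [selected_inverse_blocks()] over the lower
#'   triplets of K.
#' @param w triplet weights.
#' @param strict logical vector: triplet is strictly below the diagonal.
#' @param ntrait number of traits.
#' @noRd
trace_matrix_from_blocks <- function(blocks, w, strict, ntrait) {
  S <- matrix(0, ntrait, ntrait)
  for (a in seq_len(ntrait)) {
    for (b in seq_len(ntrait)) {
      S[a, b] <- sum(w * blocks[, a, b]) + sum(w[strict] * blocks[strict, b, a])
    }
  }
  (S + t(S)) / 2
}
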