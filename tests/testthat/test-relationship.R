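trio_pedigree <- function() {
  tibble::tibble(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                 birth_year = c(2000L, 2000L, 2001L),
                 sex = c("M", "F", "F"), generation = c(0L, 0L, 1L),
                 genotyped = FALSE)
}

test_that("founders have zero inbreeding and full sibs' offspring 0.25", {
  ped <- tibble::tibble(
    animal = 1:5,
    sire = c(0L, 0L, 1L, 1L, 3L),
    dam = c(0L, 0L, 2L, 2L, 4L),
    birth_year = c(2000L, 2000L, 2001L, 2001L, 2002L),
    sex = c("M", "F", "M", "F", "F"),
    generation = c(0L, 0L, 1L, 1L, 2L), genotyped = FALSE
  )
  Fc <- inbreeding_coefficients(ped)
  expect_equal(Fc$F[1:4], rep(0, 4))
  expect_equal(Fc$F[5], 0.25)
})

test_that("inbreeding matches the tabular-A oracle on a random pedigree", {
  ped <- random_pedigree(12, 40, seed = 33)
  A <- numerator_relationship(ped)
  Fc <- inbreeding_coefficients(ped)
  expect_equal(Fc$F[match(colnames(A), Fc$animal)], unname(diag(A) - 1),
               tolerance = 1e-12)
})

test_that("tabular A has textbook entries and is PSD", {
  A <- numerator_relationship(trio_pedigree())
  expect_equal(unname(A[1:2, 1:2]), diag(2))
  expect_equal(A["3", "1"], 0.5)
  ped <- random_pedigree(10, 30, seed = 12)
  A <- numerator_relationship(ped)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  Fc <- inbreeding_coefficients(ped)
  expect_equal(unname(diag(A)), 1 + Fc$F[match(colnames(A), Fc$animal)])
})

test_that("Henderson A-inverse matches dense inversion, trio pattern included", {
  Ai <- as.matrix(numerator_relationship_inverse(trio_pedigree()))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2))
  expect_equal(Ai["1", "2"], 0.5)
  expect_equal(Ai["1", "3"], -1)
  for (s in 1:5) {
    ped <- random_pedigree(10, 30, seed = s)
    Ai <- numerator_relationship_inverse(ped)
    A <- numerator_relationship(ped)
    expect_lt(max(abs(as.matrix(Ai) - solve(A))), 1e-10)
    expect_equal(attr(Ai, "logdet_A"),
                 as.numeric(determinant(A)$modulus), tolerance = 1e-8)
  }
})

test_that("cyclic pedigrees are rejected", {
  ped <- tibble::tibble(animal = 1:2, sire = c(2L, 1L), dam = c(0L, 0L),
                        birth_year = 2000L, sex = "M", generation = 0L,
                        genotyped = FALSE)
  expect_error(inbreeding_coefficients(ped), "cycle")
})

test_that("VanRaden G matches the hand-computed example and its properties", {
  M <- matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  G <- genomic_relationship(M, allele_freqs = c(0.5, 0.5),
                            blend_weight = 0, tune = FALSE)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2, 2))
  # identical genotype rows give G entries equal to the diagonal
  pop <- small_population()
  gids <- as.character(utils::head(pop$pedigree$animal, 20))
  M2 <- pop$genotypes[gids, ]
  M2[2, ] <- M2[1, ]
  G2 <- genomic_relationship(M2, blend_weight = 0, tune = FALSE)
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-12)
  expect_equal(G2[2, 2], G2[1, 1], tolerance = 1e-12)
  # observed-frequency G has mean diagonal about 1
  G3 <- genomic_relationship(pop$genotypes, blend_weight = 0, tune = FALSE)
  expect_lt(abs(mean(diag(G3)) - 1), 0.1)
  # monomorphic-only SNP sets are rejected
  expect_error(genomic_relationship(matrix(2, 3, 4)), "monomorphic")
})

test_that("blending with weight 1 returns A22 exactly", {
  pop <- small_population()
  ped <- sort_pedigree(pop$pedigree)
  gids <- as.character(ped$animal[ped$genotyped])
  A22 <- numerator_relationship(ped)[gids, gids]
  G <- genomic_relationship(pop$genotypes[gids, ], A22 = A22,
                            blend_weight = 1, tune = FALSE)
  expect_equal(unname(G), unname(A22), tolerance = 1e-12)
})

test_that("H-inverse equals the dense joint-distribution construction", {
  for (s in 1:3) {
    ped <- random_pedigree(10, 30, seed = 100 + s)
    cfg <- sim_config(n_founders = 10, seed = 100 + s, n_snps = 300)
    gen <- simulate_genotypes(ped, cfg)
    ped <- sort_pedigree(ped)
    A <- numerator_relationship(ped)
    gids <- as.character(sample(ped$animal, 8))
    nids <- setdiff(rownames(A), gids)
    A22 <- A[gids, gids]
    G <- genomic_relationship(gen$genotypes[gids, ], A22 = A22,
                              blend_weight = 0.05)
    Ainv <- numerator_relationship_inverse(ped)
    Hinv <- h_inverse(Ainv, A22, G, gids)
    # dense H from the conditional (joint) distribution
    A12 <- A[nids, gids]
    A22i <- solve(A22)
    H <- A
    H[gids, gids] <- G
    H[nids, gids] <- A12 %*% A22i %*% G
    H[gids, nids] <- t(H[nids, gids])
    H[nids, nids] <- A[nids, nids] +
      A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
    expect_lt(max(abs(as.matrix(Hinv) - solve(H))), 1e-8)
  }
})

test_that("H-inverse reduces to A-inverse when genomics agrees with pedigree", {
  ped <- random_pedigree(8, 20, seed = 55)
  ped <- sort_pedigree(ped)
  A <- numerator_relationship(ped)
  gids <- as.character(ped$animal[1:5])
  A22 <- A[gids, gids]
  Ainv <- numerator_relationship_inverse(ped)
  Hinv <- h_inverse(Ainv, A22, A22, gids)
  expect_lt(max(abs(as.matrix(Hinv) - as.matrix(Ainv))), 1e-10)
  # unknown genotyped ids are an error
  expect_error(h_inverse(Ainv, A22, A22, c("999999")), "missing")
})
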