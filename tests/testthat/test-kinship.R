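test_that("tabular A reproduces textbook identities", {
  ped <- data.frame(id = c("P1", "P2", "O"), sire = c("0", "0", "P1"),
                    dam = c("0", "0", "P2"))
  A <- build_A(ped)
  expect_equal(A["O", "P1"], 0.5)
  expect_equal(A["O", "O"], 1.0)

  # full sibs and their inbred offspring
  ped2 <- data.frame(id = c("S", "D", "F1", "F2", "X"),
                     sire = c("0", "0", "S", "S", "F1"),
                     dam = c("0", "0", "D", "D", "F2"))
  A2 <- build_A(ped2)
  expect_equal(A2["F1", "F2"], 0.5)
  expect_equal(A2["X", "X"], 1.25)
  expect_equal(inbreeding_coeff(ped2)[["X"]], 0.25)
})

test_that("A matches the recursive-definition oracle on random pedigrees", {
  for (seed in 1:3) {
    ped <- random_pedigree(12, seed = seed)
    A <- build_A(ped)
    Aref <- relationship_oracle(ped)
    expect_lt(max(abs(A[rownames(Aref), rownames(Aref)] - Aref)), 1e-12)
  }
})

test_that("A is PSD with unit-plus-inbreeding diagonal; A inverse is exact", {
  for (seed in 4:6) {
    ped <- random_pedigree(25, seed = seed)
    A <- build_A(ped)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
    expect_true(all(diag(A) >= 1 - 1e-12))
    ai <- build_A_inverse(ped)
    expect_lt(max(abs(as.matrix(ai$A_inv) %*% A[ai$ids, ai$ids] -
                        diag(nrow(A)))), 1e-8)
    expect_equal(ai$logdet_A, as.numeric(determinant(A)$modulus))
    expect_equal(ai$f, diag(A)[ai$ids] - 1, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("pedigree cycles are rejected with the members named", {
  ped <- data.frame(id = c("A", "B"), sire = c("B", "A"), dam = c("0", "0"))
  expect_error(build_A(ped), "cycle")
  ped2 <- data.frame(id = "A", sire = "A", dam = "0")
  expect_error(build_A(ped2), "own parent")
})

test_that("A22 block extraction equals the dense A sub-block", {
  ped <- random_pedigree(30, seed = 8)
  A <- build_A(ped)
  ids <- sample(ped$id, 7)
  expect_equal(build_A22(ped, ids), A[ids, ids], tolerance = 1e-12)
})

test_that("SNP QC applies call-rate, MAF, autosome and HWE rules", {
  set.seed(21)
  n <- 100
  p <- c(0.4, 0.3, 0.25, 0.35, 0.45, 0.3)
  geno <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  colnames(geno) <- paste0("snp", 1:6)
  # snp1 fine; snp2 monomorphic; snp3 10% missing; snp4 X chromosome;
  # snp5 gross HWE failure (all heterozygote-free); snp6 fine
  geno[, 2] <- 0L
  geno[sample(n, 10), 3] <- NA
  geno[, 5] <- ifelse(stats::runif(n) < 0.5, 0L, 2L)
  map <- data.frame(snp = colnames(geno),
                    chrom = c("1", "2", "3", "X", "5", "12"),
                    pos = 1:6 * 1000)
  qc <- snp_qc(geno, map)
  expect_setequal(colnames(qc$geno), c("snp1", "snp6"))
  rep <- stats::setNames(qc$report$n, qc$report$criterion)
  expect_equal(rep[["call_rate"]], 1L)
  expect_gte(rep[["maf"]], 1L)
  expect_equal(rep[["non_autosomal"]], 1L)
  expect_gte(rep[["hwe"]], 1L)
  expect_error(snp_qc(geno[, 2, drop = FALSE], map[2, ]), "all SNPs removed")
})

test_that("HWE chi-square equals the hand-computed statistic", {
  # counts (50, 0, 50): p = 0.5, expected (25, 50, 25), chi-square = n = 100
  pval <- hwe_chisq_p(50, 0, 50)
  expect_equal(pval, stats::pchisq(100, df = 1, lower.tail = FALSE))
  # perfect HWE proportions give statistic 0
  expect_equal(hwe_chisq_p(25, 50, 25), 1)
  expect_true(is.na(hwe_chisq_p(100, 0, 0)))  # monomorphic: no test
})

test_that("G follows VanRaden method 1 on hand-worked examples", {
  # one SNP, genotypes (2, 0): p = 0.5, Z = (1, -1), denom = 0.5
  M <- matrix(c(2, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(build_G(M), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  # identical genotypes: off-diagonal equals both diagonals
  set.seed(5)
  M2 <- matrix(stats::rbinom(40, 2, 0.3), 2, 20, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:20)))
  M2[2, ] <- M2[1, ]
  G2 <- build_G(M2)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(G2[1, 2], G2[2, 2])
  expect_error(build_G(matrix(2, 3, 2)), "monomorphic")
})

test_that("G is invariant to allele-coding swaps and centres near 1", {
  set.seed(31)
  n <- 200; m <- 800
  p <- stats::runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(M) <- paste0("i", seq_len(n))
  G <- build_G(M)
  # swap coding of a random subset of SNPs (0 <-> 2)
  sw <- sample(m, 300)
  M2 <- M
  M2[, sw] <- 2 - M2[, sw]
  expect_equal(build_G(M2), build_G(M), tolerance = 1e-12,
               ignore_attr = TRUE)
  # HWE population: mean diagonal within 1 +- 0.05
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("pruning removes exactly one of each duplicate pair", {
  set.seed(41)
  p <- stats::runif(500, 0.2, 0.5)
  M <- sapply(p, function(pp) stats::rbinom(20, 2, pp))
  rownames(M) <- sprintf("i%02d", 1:20)
  # a minor-allele-rich individual has a self-relationship well above 1;
  # entering it twice makes a clear duplicate pair
  dup <- ifelse(p < 0.35, 2L, 0L)
  M <- rbind(M, i21 = dup, i22 = dup)
  G <- build_G(M)
  expect_gt(G["i21", "i22"], 0.95)
  pr <- prune_high_relationship(G, 0.95)
  expect_equal(pr$dropped, "i22")  # higher id of the pair dropped
  expect_equal(pr$n_violations, 1)
  # no violations: identity mapping
  pr2 <- prune_high_relationship(G[1:20, 1:20], 10)
  expect_equal(pr2$keep, sprintf("i%02d", 1:20))
  expect_length(pr2$dropped, 0)
})

test_that("pruning matches minimal removal on a two-duplicate-pair toy", {
  set.seed(42)
  p <- stats::runif(400, 0.2, 0.5)
  M <- sapply(p, function(pp) stats::rbinom(12, 2, pp))
  rownames(M) <- letters[1:12]
  M <- rbind(M, w = ifelse(p < 0.35, 2L, 0L), x = ifelse(p < 0.35, 2L, 0L),
             y = ifelse(p > 0.4, 2L, 0L), z = ifelse(p > 0.4, 2L, 0L))
  G <- build_G(M)
  pr <- prune_high_relationship(G, 0.95)
  # exhaustive check: kept set has no violating pair and removal is minimal
  keep <- pr$keep
  expect_true(all(G[keep, keep][upper.tri(diag(length(keep)))] <= 0.95))
  expect_equal(length(pr$dropped), 2L)
})

test_that("H inverse reduces to A inverse in the degenerate cases", {
  ped <- random_pedigree(15, seed = 10)
  hb0 <- blend_and_H_inverse(NULL, ped, character(0))
  ai <- build_A_inverse(ped)
  expect_equal(as.matrix(hb0$H_inv), as.matrix(ai$A_inv), tolerance = 1e-12)
  # blend weight 0: Gw = A22 so the genomic correction vanishes
  set.seed(10)
  gids <- sample(ped$id, 5)
  G <- build_A22(ped, gids) + 0.5  # arbitrary "genomic" matrix
  hb <- blend_and_H_inverse(G, ped, gids, blend_w = 0)
  expect_equal(as.matrix(hb$H_inv), as.matrix(ai$A_inv), tolerance = 1e-9)
})

test_that("H from inverting H^-1 matches the joint-distribution formula", {
  ped <- random_pedigree(8, seed = 12)
  gids <- ped$id[c(3, 6, 8)]
  set.seed(2)
  M <- matrix(stats::rbinom(3 * 150, 2, 0.4), 3, 150,
              dimnames = list(gids, paste0("s", 1:150)))
  G <- build_G(M)
  hb <- blend_and_H_inverse(G, ped, gids, blend_w = 0.95)
  H <- solve(as.matrix(hb$H_inv))
  ids <- hb$ids
  A <- build_A(ped)[ids, ids]
  g_idx <- match(gids, ids)
  n_idx <- setdiff(seq_along(ids), g_idx)
  A22 <- A[g_idx, g_idx]
  A12 <- A[n_idx, g_idx]
  A22i <- solve(A22)
  Gw <- hb$Gw
  # direct single-step formula for H
  H_ref <- A
  H_ref[g_idx, g_idx] <- Gw
  H_ref[n_idx, g_idx] <- A12 %*% A22i %*% Gw
  H_ref[g_idx, n_idx] <- t(H_ref[n_idx, g_idx])
  H_ref[n_idx, n_idx] <- A[n_idx, n_idx] +
    A12 %*% A22i %*% (Gw - A22) %*% A22i %*% t(A12)
  expect_equal(H, H_ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(hb$logdet_H, as.numeric(determinant(H_ref)$modulus),
               tolerance = 1e-8)
})

test_that("ungenotyped animals without genotyped descendants keep A rows", {
  ped <- data.frame(id = c("U1", "U2", "Gn", "U3"),
                    sire = c("0", "0", "0", "U1"),
                    dam = c("0", "0", "0", "U2"))
  set.seed(3)
  M <- matrix(stats::rbinom(2 * 100, 2, 0.3), 1, 200)
  G <- matrix(1.02, 1, 1, dimnames = list("Gn", "Gn"))
  hb <- blend_and_H_inverse(G, ped, "Gn")
  H <- solve(as.matrix(hb$H_inv))
  A <- build_A(ped)[hb$ids, hb$ids]
  un <- c("U1", "U2", "U3")
  expect_equal(H[un, un], A[un, un], tolerance = 1e-10)
})
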