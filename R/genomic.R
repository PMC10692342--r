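#' SNP quality control
#'
#' Filters a biallelic genotype matrix (0/1/2 allele dosages, `NA` missing)
#' by the usual marker criteria: call rate strictly above `call_rate_min`,
#' minor allele frequency strictly above `maf_min`, autosomal location, and
#' no significant deviation from Hardy-Weinberg equilibrium (one-degree
#' chi-square test on genotype counts, removed when p < `hwe_alpha`).
#'
#' @param geno Numeric matrix, individuals x SNPs, entries in `{0,1,2,NA}`.
#'   Columns must be named by SNP id.
#' @param map data.frame with columns `snp`, `chrom`, `pos`. Chromosomes
#'   with purely numeric labels are treated as autosomes.
#' @param call_rate_min,maf_min,hwe_alpha Thresholds; defaults 0.95, 0.05
#'   and 1e-6.
#' @return A list with `geno` (the retained columns), `map` (matching rows)
#'   and `report`, a data.frame of per-criterion failure counts (criteria
#'   evaluated independently on the input; a SNP can fail several).
#' @export
snp_qc <- function(geno, map, call_rate_min = 0.95, maf_min = 0.05,
                   hwe_alpha = 1e-6) {
  stopifnot(is.matrix(geno), !is.null(colnames(geno)))
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)))
  map <- map[match(colnames(geno), map$snp), , drop = FALSE]
  if (anyNA(map$snp)) stop("map is missing SNP(s) present in the genotype matrix")
  ok_vals <- geno %in% c(0, 1, 2) | is.na(geno)
  if (!all(ok_vals)) stop("genotypes must be coded 0/1/2 or NA")

  n <- nrow(geno)
  n_obs <- colSums(!is.na(geno))
  call_rate <- n_obs / n
  p <- colSums(geno, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(p, 1 - p)

  autosomal <- grepl("^[0-9]+$", as.character(map$chrom)) &
    suppressWarnings(as.integer(as.character(map$chrom))) > 0

  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  fail_cr <- call_rate <= call_rate_min
  fail_maf <- maf <= maf_min
  fail_auto <- !autosomal
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  keep <- !(fail_cr | fail_maf | fail_auto | fail_hwe)
  if (!any(keep)) stop("all SNPs removed by quality control")

  report <- data.frame(
    criterion = c("call_rate", "maf", "non_autosomal", "hwe", "retained"),
    n = c(sum(fail_cr), sum(fail_maf), sum(fail_auto), sum(fail_hwe),
          sum(keep)),
    stringsAsFactors = FALSE
  )
  list(geno = geno[, keep, drop = FALSE], map = map[keep, , drop = FALSE],
       report = report)
}

#' Hardy-Weinberg chi-square p-values from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts
#' (AA, Aa, aa) against Hardy-Weinberg expectations at the observed allele
#' frequency. Monomorphic SNPs return `NA` (no test possible).
#'
#' @param n0,n1,n2 Integer vectors of genotype counts for dosages 0, 1, 2.
#' @return Numeric vector of p-values.
#' @export
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- 2 * n * p * q
  e2 <- n * p^2
  out <- rep(NA_real_, length(n))
  ok <- n > 0 & p > 0 & p < 1
  chi <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  out[ok] <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z = M - 2p`, allele
#' frequencies computed from the genotyped set itself, and missing entries
#' mean-imputed (to `2 p_j`, i.e. zero after centring).
#'
#' @param M Numeric matrix, individuals x SNPs, dosages 0/1/2 with `NA`
#'   allowed. Rows must be named by individual id.
#' @return Dense symmetric matrix with individual ids as dimnames; allele
#'   frequencies in attribute `p`.
#' @export
build_G <- function(M) {
  stopifnot(is.matrix(M))
  n_obs <- colSums(!is.na(M))
  if (any(n_obs == 0)) stop("SNP(s) with no observed genotypes")
  p <- colSums(M, na.rm = TRUE) / (2 * n_obs)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero denominator for G")
  Z <- sweep(M, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(G, p = p)
}

#' Prune individuals with near-duplicate genomic relationships
#'
#' Greedily removes individuals until no off-diagonal genomic relationship
#' exceeds `threshold`. At each step the individual involved in most
#' remaining violations is dropped; ties are broken by dropping the
#' higher id (sort order), so the lowest id of a duplicate pair is kept.
#'
#' @param G Symmetric genomic relationship matrix with dimnames.
#' @param threshold Relationship above which a pair is considered redundant
#'   (default 0.95).
#' @return A list with `keep` (retained ids), `dropped` (removed ids) and
#'   `n_violations` (violating pairs in the input).
#' @export
prune_high_relationship <- function(G, threshold = 0.95) {
  stopifnot(is.matrix(G), !is.null(rownames(G)))
  ids <- rownames(G)
  V <- G > threshold
  diag(V) <- FALSE
  n_viol <- sum(V) / 2
  active <- rep(TRUE, length(ids))
  repeat {
    counts <- rowSums(V[active, active, drop = FALSE])
    if (!any(counts > 0)) break
    cand <- which(counts == max(counts))
    victim_local <- cand[order(ids[active][cand], decreasing = TRUE)][1L]
    victim <- which(active)[victim_local]
    active[victim] <- FALSE
  }
  list(keep = ids[active], dropped = ids[!active], n_violations = n_viol)
}

#' Blended genomic matrix and single-step H inverse
#'
#' Builds the weighted genomic relationship matrix
#' `Gw = w G + (1 - w) A22` and the inverse of the single-step relationship
#' matrix,
#' `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`
#' on the genotyped block, which lets genotyped and ungenotyped animals be
#' evaluated jointly. The blend keeps Gw positive definite and accounts for
#' the polygenic fraction not captured by the markers.
#'
#' @param G Genomic relationship matrix over the genotyped animals
#'   (dimnames = ids), e.g. from [build_G()].
#' @param ped Pedigree data.frame (`id`, `sire`, `dam`).
#' @param genotyped_ids Ids of the genotyped animals (must be rows of `G`
#'   and in the pedigree). May be empty, in which case `H^-1 = A^-1`.
#' @param blend_w Weight on G in the blend (default 0.95).
#' @param A_inv,A22 Optional precomputed pieces (from [build_A_inverse()]
#'   and [build_A22()]) to avoid recomputation.
#' @return A list with `H_inv` (sparse symmetric), `ids` (pedigree order),
#'   `Gw`, `A22`, `A_inv`, `f` (inbreeding), and `logdet_H` (log
#'   determinant of H, used by the REML likelihood).
#' @export
blend_and_H_inverse <- function(G, ped, genotyped_ids, blend_w = 0.95,
                                A_inv = NULL, A22 = NULL) {
  ai <- if (is.null(A_inv)) build_A_inverse(ped) else A_inv
  ids <- ai$ids
  genotyped_ids <- as.character(genotyped_ids)
  if (!length(genotyped_ids)) {
    return(list(H_inv = ai$A_inv, ids = ids, Gw = NULL, A22 = NULL,
                A_inv = ai, f = ai$f, logdet_H = ai$logdet_A))
  }
  if (is.null(A22)) A22 <- build_A22(ped, genotyped_ids)
  if (!all(genotyped_ids %in% rownames(G))) {
    stop("genotyped id(s) missing from G")
  }
  Gg <- G[genotyped_ids, genotyped_ids, drop = FALSE]
  Gw <- blend_w * Gg + (1 - blend_w) * A22
  chG <- tryCatch(chol(Gw), error = function(e) NULL)
  if (is.null(chG)) {
    stop("blended genomic matrix Gw is singular; lower blend_w to put more ",
         "weight on the pedigree block")
  }
  Gw_inv <- chol2inv(chG)
  chA22 <- chol(A22)
  A22_inv <- chol2inv(chA22)
  idx <- match(genotyped_ids, ids)
  delta <- Gw_inv - A22_inv
  ng <- length(idx)
  D <- sparseMatrix(i = rep(idx, each = ng), j = rep(idx, times = ng),
                    x = as.numeric(t(delta)), dims = dim(ai$A_inv),
                    dimnames = dimnames(ai$A_inv))
  H_inv <- forceSymmetric(ai$A_inv + D)
  # |H| = |A| * |Gw| / |A22|
  logdet_H <- ai$logdet_A + 2 * sum(log(Matrix::diag(chG))) -
    2 * sum(log(Matrix::diag(chA22)))
  list(H_inv = H_inv, ids = ids, Gw = Gw, A22 = A22, A_inv = ai, f = ai$f,
       logdet_H = logdet_H)
}
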