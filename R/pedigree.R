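#' @importFrom Matrix sparseMatrix Diagonal t solve crossprod tcrossprod
#'   determinant diag bdiag drop0 forceSymmetric
NULL

# Canonical indexed pedigree: ids as character, parents as row indices
# (0 = unknown), topologically sorted so parents precede offspring.
# Parents that appear only in the sire/dam columns are added as founders.
ped_index <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) {
    stop("duplicated animal id(s) in pedigree: ",
         paste(utils::head(unique(id[duplicated(id)]), 5L), collapse = ", "))
  }
  unk <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  sire <- unk(ped$sire)
  dam <- unk(ped$dam)
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  if (any(si == seq_len(n) & si > 0L) || any(di == seq_len(n) & di > 0L)) {
    stop("pedigree cycle: animal is its own parent: ",
         paste(id[which(si == seq_len(n) | di == seq_len(n))], collapse = ", "))
  }
  # Kahn-style topological sort in rounds
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed & (si == 0L | placed[pmax(si, 1L)]) &
      (di == 0L | placed[pmax(di, 1L)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree cycle detected involving: ",
         paste(utils::head(id[!placed], 10L), collapse = ", "))
  }
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  list(id = id[ord],
       sire = ifelse(si[ord] == 0L, 0L, pos[pmax(si[ord], 1L)]),
       dam = ifelse(di[ord] == 0L, 0L, pos[pmax(di[ord], 1L)]))
}

# Meuwissen & Luo inbreeding coefficients and Mendelian-sampling variances
# d_i for an indexed pedigree. Unknown parents contribute F = -1 to d_i
# (so d = 1 with both parents unknown, 0.75 - 0.25 F_s with one known).
ped_inbreeding <- function(px) {
  n <- length(px$id)
  sire <- px$sire
  dam <- px$dam
  f <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]
    dd <- dam[i]
    fs <- if (s == 0L) -1 else f[s]
    fd <- if (dd == 0L) -1 else f[dd]
    d[i] <- 0.5 - 0.25 * (fs + fd)
    if (s == 0L || dd == 0L) next
    # ancestors of i (including i), processed in decreasing index order
    anc <- i
    frontier <- i
    while (length(frontier)) {
      par <- c(sire[frontier], dam[frontier])
      par <- par[par > 0L]
      par <- setdiff(unique(par), anc)
      anc <- c(anc, par)
      frontier <- par
    }
    anc <- sort(anc, decreasing = TRUE)
    L <- numeric(n)
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * d[j]
      if (sire[j] > 0L) L[sire[j]] <- L[sire[j]] + 0.5 * L[j]
      if (dam[j] > 0L) L[dam[j]] <- L[dam[j]] + 0.5 * L[j]
    }
    f[i] <- aii - 1
  }
  list(f = f, d = d)
}

#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen-Luo evaluation of Wright's inbreeding coefficient for every
#' animal in the pedigree.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`; unknown parents
#'   coded 0, `NA` or `""`. Parents appearing only as sire/dam are added as
#'   founders.
#' @return Named numeric vector of inbreeding coefficients (pedigree order
#'   after topological sorting).
#' @export
inbreeding_coeff <- function(ped) {
  px <- ped_index(ped)
  f <- ped_inbreeding(px)$f
  names(f) <- px$id
  f
}

#' Numerator relationship matrix (A)
#'
#' Wright's numerator relationship matrix by the tabular method, with
#' inbreeding. Animals are returned in topological order (parents before
#' offspring).
#'
#' @inheritParams inbreeding_coeff
#' @return Dense symmetric matrix with dimnames set to the animal ids.
#' @export
build_A <- function(ped) {
  px <- ped_index(ped)
  n <- length(px$id)
  A <- matrix(0, n, n, dimnames = list(px$id, px$id))
  for (i in seq_len(n)) {
    s <- px$sire[i]
    d <- px$dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, prev]
      if (d > 0L) row <- row + 0.5 * A[d, prev]
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via the
#' Mendelian-sampling variances from the Meuwissen-Luo algorithm.
#'
#' @inheritParams inbreeding_coeff
#' @return A list with `A_inv` (sparse symmetric `Matrix`), `ids` (row
#'   order), `f` (inbreeding coefficients) and `logdet_A` (log determinant
#'   of A, i.e. the sum of log Mendelian-sampling variances).
#' @export
build_A_inverse <- function(ped) {
  px <- ped_index(ped)
  n <- length(px$id)
  fd <- ped_inbreeding(px)
  alpha <- 1 / fd$d
  i_idx <- seq_len(n)
  s <- px$sire
  d <- px$dam
  hs <- s > 0L
  hd <- d > 0L
  both <- hs & hd
  ii <- c(i_idx,
          i_idx[hs], s[hs],
          s[hs],
          i_idx[hd], d[hd],
          d[hd],
          s[both], d[both])
  jj <- c(i_idx,
          s[hs], i_idx[hs],
          s[hs],
          d[hd], i_idx[hd],
          d[hd],
          d[both], s[both])
  xx <- c(alpha,
          -alpha[hs] / 2, -alpha[hs] / 2,
          alpha[hs] / 4,
          -alpha[hd] / 2, -alpha[hd] / 2,
          alpha[hd] / 4,
          alpha[both] / 4, alpha[both] / 4)
  A_inv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                        dimnames = list(px$id, px$id))
  A_inv <- forceSymmetric(drop0(A_inv))
  list(A_inv = A_inv, ids = px$id, f = fd$f, logdet_A = sum(log(fd$d)))
}

#' Pedigree relationships among a subset of animals (A22)
#'
#' Extracts the block of the numerator relationship matrix for a set of
#' (typically genotyped) animals without forming the full dense A. Uses the
#' factorisation `A = (I - P)^-1 D (I - P)^-T`, where P holds the 0.5
#' parent contributions, via two sparse triangular solves per animal.
#'
#' @inheritParams inbreeding_coeff
#' @param ids Character vector of animal ids for the block.
#' @return Dense symmetric matrix over `ids` (in the order given).
#' @export
build_A22 <- function(ped, ids) {
  px <- ped_index(ped)
  ids <- as.character(ids)
  idx <- match(ids, px$id)
  if (anyNA(idx)) {
    stop("id(s) not in pedigree: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  n <- length(px$id)
  fd <- ped_inbreeding(px)
  hs <- px$sire > 0L
  hd <- px$dam > 0L
  P <- sparseMatrix(i = c(seq_len(n)[hs], seq_len(n)[hd]),
                    j = c(px$sire[hs], px$dam[hd]),
                    x = rep(0.5, sum(hs) + sum(hd)), dims = c(n, n))
  Tm <- Diagonal(n) - P          # unit lower triangular (topological order)
  E <- sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                    dims = c(n, length(idx)))
  W <- solve(t(Tm), E)           # (I - P)^-T e_j
  V <- solve(Tm, Diagonal(x = fd$d) %*% W)
  A22 <- as.matrix(crossprod(E, V))
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ids, ids)
  A22
}
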