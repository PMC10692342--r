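# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (recursions, dense algebra, explicit
# loops) rather than calling the package's own implementations.

# recursive definition of the numerator relationship:
# a(i,j) = 0.5 * (a(sire_i, j) + a(dam_i, j)) for i later-born than j,
# a(i,i) = 1 + 0.5 * a(sire_i, dam_i)
relationship_oracle <- function(ped) {
  id <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  sire[sire %in% c("0", "") | is.na(sire)] <- NA
  dam[dam %in% c("0", "") | is.na(dam)] <- NA
  pos <- stats::setNames(seq_along(id), id)
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (pos[[i]] < pos[[j]]) return(a(j, i))
    si <- sire[pos[[i]]]
    di <- dam[pos[[i]]]
    if (i == j) return(1 + 0.5 * a_safe(si, di))
    0.5 * (a_safe(si, j) + a_safe(di, j))
  }
  a_safe <- function(i, j) if (is.na(i) || is.na(j)) 0 else a(i, j)
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- a(id[i], id[j])
  }
  A
}

# random pedigree generator: founders first, then animals with parents
# drawn from earlier animals (possibly unknown)
random_pedigree <- function(n, n_founders = 4, seed = 1) {
  set.seed(seed)
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    prev <- id[seq_len(i - 1L)]
    sire[i] <- if (stats::runif(1) < 0.9) sample(prev, 1) else "0"
    dam[i] <- if (stats::runif(1) < 0.9) sample(prev, 1) else "0"
    if (sire[i] == dam[i]) dam[i] <- "0"
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# dense REML log-likelihood from the standard matrix identities
dense_reml_oracle <- function(y, X, Vlist, v_e) {
  n <- length(y)
  V <- diag(v_e, n)
  for (Vk in Vlist) V <- V + Vk
  Xd <- as.matrix(X)
  p <- ncol(Xd)
  Vi <- solve(V)
  XVX <- t(Xd) %*% Vi %*% Xd
  P <- Vi - Vi %*% Xd %*% solve(XVX, t(Xd) %*% Vi)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# small calf record table with valid factors, for design/editing tests
toy_records <- function(n = 40, n_dams = 10, n_sires = 4, n_herds = 2,
                        seed = 1) {
  set.seed(seed)
  dams <- paste0("D", seq_len(n_dams))
  data.frame(
    calf_id = paste0("C", seq_len(n)),
    dam_id = sample(dams, n, replace = TRUE),
    sire_id = sample(paste0("S", seq_len(n_sires)), n, replace = TRUE),
    herd_id = sample(paste0("H", seq_len(n_herds)), n, replace = TRUE),
    birth_date = as.Date("2010-01-01") + sample.int(720, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_type = sample(c("singleton", "twin"), n, replace = TRUE,
                        prob = c(0.95, 0.05)),
    biw_kg = round(stats::rnorm(n, 43, 4), 1),
    gestation_len_d = sample(262:298, n, replace = TRUE),
    dam_parity = sample(1:9, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# tiny simulation config for fast end-to-end tests (defaults overridable)
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_herds = 3L, n_stations = 2L, n_years = 3L, n_dams = 60L,
         n_sires = 15L, n_genotyped_sires = 8L, n_snps = 80L),
    list(...))
  do.call(sim_config, c(list(seed = seed), args))
}
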