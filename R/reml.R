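#' Random-term constructors for the REML machinery
#'
#' A mixed model here is `y = X b + sum_k Z_k u_k + e`,
#' `u_k ~ N(0, Gamma_k)`, `e ~ N(0, I v_e)`. Three covariance structures
#' cover all models in this package:
#' \describe{
#'   \item{`rand_iid(Z)`}{`Gamma = I v` — e.g. sire, dam or herd-year-month
#'     effects.}
#'   \item{`rand_struct(Z, V_inv, logdet_V)`}{`Gamma = V v` with a known
#'     relationship structure `V` supplied through its sparse inverse — e.g.
#'     a pedigree or single-step structured additive effect.}
#'   \item{`rand_rr2(Z_int, Z_slope, V_inv, logdet_V)`}{a random-regression
#'     (reaction-norm) pair of intercept and slope effects per individual
#'     with 2x2 covariance `K`, i.e. `Gamma = K %x% V` (V = I when `V_inv`
#'     is `NULL`). Parameters are `k11` (intercept variance), `k22` (slope
#'     variance) and `k12` (their covariance).}
#' }
#'
#' @param Z,Z_int,Z_slope Sparse design matrices (records x levels).
#' @param V_inv Sparse symmetric inverse of the structure matrix (`NULL`
#'   for identity).
#' @param logdet_V Log-determinant of the structure matrix `V`.
#' @param name Term label used in parameter names and output.
#' @return A term object (list) for [reml_fit()].
#' @export
rand_iid <- function(Z, name) {
  list(type = "iid", Z = Z, q = ncol(Z), name = name, npar = 1L,
       par_names = paste0(name, ".v"))
}

#' @rdname rand_iid
#' @export
rand_struct <- function(Z, V_inv, logdet_V, name) {
  stopifnot(ncol(Z) == nrow(V_inv))
  list(type = "struct", Z = Z, q = ncol(Z), V_inv = forceSymmetric(V_inv),
       logdet_V = logdet_V, name = name, npar = 1L,
       par_names = paste0(name, ".v"))
}

#' @rdname rand_iid
#' @export
rand_rr2 <- function(Z_int, Z_slope, V_inv = NULL, logdet_V = 0, name) {
  stopifnot(ncol(Z_int) == ncol(Z_slope))
  if (!is.null(V_inv)) {
    stopifnot(ncol(Z_int) == nrow(V_inv))
    V_inv <- forceSymmetric(V_inv)
  }
  list(type = "rr2", Z1 = Z_int, Z2 = Z_slope, q = ncol(Z_int),
       V_inv = V_inv, logdet_V = logdet_V, name = name, npar = 3L,
       par_names = paste0(name, c(".k11", ".k22", ".k12")))
}

# upper-triangle triplets of a symmetric sparse/dense matrix embedded at
# diagonal offset o (0-based)
ut_triplets <- function(B, o) {
  Bt <- as(as(as(B, "generalMatrix"), "CsparseMatrix"), "TsparseMatrix")
  keep <- Bt@i <= Bt@j
  list(i = Bt@i[keep] + o + 1L, j = Bt@j[keep] + o + 1L, x = Bt@x[keep])
}

# all triplets of B embedded at row offset oi, col offset oj (oi < oj)
full_triplets <- function(B, oi, oj) {
  Bt <- as(as(as(B, "generalMatrix"), "CsparseMatrix"), "TsparseMatrix")
  list(i = Bt@i + oi + 1L, j = Bt@j + oj + 1L, x = Bt@x)
}

# Precompute everything reusable across likelihood evaluations: the stacked
# design, its cross-products, and a fixed-pattern triplet template for the
# mixed-model-equation coefficient matrix
# M(theta) = W'W / v_e + blockdiag(0, Gamma_k^-1).
reml_setup <- function(y, X, terms) {
  stopifnot(length(terms) >= 1L, !is.null(names(terms)) || TRUE)
  n <- length(y)
  X <- as(X, "CsparseMatrix")
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  Zs <- lapply(terms, function(tm) {
    if (tm$type == "rr2") cbind(tm$Z1, tm$Z2) else tm$Z
  })
  W <- do.call(cbind, c(list(X), Zs))
  m <- ncol(W)
  WtW <- forceSymmetric(crossprod(W))
  Wty <- as.numeric(crossprod(W, y))
  yty <- sum(y^2)

  # block offsets of each term inside W
  offs <- p + c(0L, cumsum(vapply(Zs, ncol, 0L)))[seq_along(terms)]

  tw <- ut_triplets(WtW, 0L)
  tmpl_i <- tw$i; tmpl_j <- tw$j; tmpl_x <- tw$x
  tmpl_g <- rep(1L, length(tw$x))
  ngroup <- 1L
  group_of <- list()          # per term, the template group ids
  ch_V <- list()              # Cholesky of V_inv per structured term
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    o <- offs[k]
    if (tm$type == "iid") {
      ngroup <- ngroup + 1L
      tmpl_i <- c(tmpl_i, o + seq_len(tm$q))
      tmpl_j <- c(tmpl_j, o + seq_len(tm$q))
      tmpl_x <- c(tmpl_x, rep(1, tm$q))
      tmpl_g <- c(tmpl_g, rep(ngroup, tm$q))
      group_of[[k]] <- ngroup
    } else if (tm$type == "struct") {
      ngroup <- ngroup + 1L
      tt <- ut_triplets(tm$V_inv, o)
      tmpl_i <- c(tmpl_i, tt$i); tmpl_j <- c(tmpl_j, tt$j)
      tmpl_x <- c(tmpl_x, tt$x)
      tmpl_g <- c(tmpl_g, rep(ngroup, length(tt$x)))
      group_of[[k]] <- ngroup
      ch_V[[k]] <- Matrix::Cholesky(tm$V_inv, LDL = FALSE)
    } else { # rr2: three groups scaled by Kinv[1,1], Kinv[2,2], Kinv[1,2]
      Vi <- if (is.null(tm$V_inv)) Diagonal(tm$q) else tm$V_inv
      t11 <- ut_triplets(Vi, o)
      t22 <- ut_triplets(Vi, o + tm$q)
      t12 <- full_triplets(Vi, o, o + tm$q)
      gs <- ngroup + 1:3
      ngroup <- ngroup + 3L
      tmpl_i <- c(tmpl_i, t11$i, t22$i, t12$i)
      tmpl_j <- c(tmpl_j, t11$j, t22$j, t12$j)
      tmpl_x <- c(tmpl_x, t11$x, t22$x, t12$x)
      tmpl_g <- c(tmpl_g, rep(gs[1], length(t11$x)),
                  rep(gs[2], length(t22$x)), rep(gs[3], length(t12$x)))
      group_of[[k]] <- gs
      if (!is.null(tm$V_inv)) ch_V[[k]] <- Matrix::Cholesky(tm$V_inv, LDL = FALSE)
    }
  }
  par_names <- c(unlist(lapply(terms, `[[`, "par_names")), "v_e")
  list(y = y, X = X, W = W, n = n, p = p, m = m, WtW = WtW, Wty = Wty,
       yty = yty, terms = terms, offs = offs,
       tmpl = list(i = tmpl_i, j = tmpl_j, x = tmpl_x, g = tmpl_g,
                   ngroup = ngroup),
       group_of = group_of, ch_V = ch_V, par_names = par_names,
       npar = sum(vapply(terms, `[[`, 0L, "npar")) + 1L)
}

# split a parameter vector into per-term pieces + residual variance
split_theta <- function(setup, theta) {
  stopifnot(length(theta) == setup$npar)
  out <- vector("list", length(setup$terms))
  pos <- 1L
  for (k in seq_along(setup$terms)) {
    np <- setup$terms[[k]]$npar
    out[[k]] <- theta[pos:(pos + np - 1L)]
    pos <- pos + np
  }
  list(term_par = out, v_e = theta[setup$npar])
}

theta_feasible <- function(setup, theta, lb = 0) {
  sp <- split_theta(setup, theta)
  if (!is.finite(sp$v_e) || sp$v_e <= lb) return(FALSE)
  for (k in seq_along(setup$terms)) {
    tp <- sp$term_par[[k]]
    if (setup$terms[[k]]$npar == 1L) {
      if (!is.finite(tp) || tp <= lb) return(FALSE)
    } else {
      if (any(!is.finite(tp))) return(FALSE)
      if (tp[1] <= lb || tp[2] <= lb) return(FALSE)
      if (tp[3]^2 >= tp[1] * tp[2]) return(FALSE)
    }
  }
  TRUE
}

# Evaluate the restricted log-likelihood at theta. Returns the factorisation
# and MME solution for reuse. chol_cache: a CHMfactor from a previous call
# with the same template (pattern is identical by construction).
reml_eval <- function(setup, theta, chol_cache = NULL) {
  sp <- split_theta(setup, theta)
  v_e <- sp$v_e
  coefs <- numeric(setup$tmpl$ngroup)
  coefs[1L] <- 1 / v_e
  sum_logdet_gamma <- 0
  for (k in seq_along(setup$terms)) {
    tm <- setup$terms[[k]]
    tp <- sp$term_par[[k]]
    g <- setup$group_of[[k]]
    if (tm$type == "iid") {
      coefs[g] <- 1 / tp
      sum_logdet_gamma <- sum_logdet_gamma + tm$q * log(tp)
    } else if (tm$type == "struct") {
      coefs[g] <- 1 / tp
      sum_logdet_gamma <- sum_logdet_gamma + tm$q * log(tp) + tm$logdet_V
    } else {
      K <- matrix(c(tp[1], tp[3], tp[3], tp[2]), 2L, 2L)
      detK <- tp[1] * tp[2] - tp[3]^2
      Kinv <- matrix(c(tp[2], -tp[3], -tp[3], tp[1]), 2L, 2L) / detK
      coefs[g[1]] <- Kinv[1, 1]
      coefs[g[2]] <- Kinv[2, 2]
      coefs[g[3]] <- Kinv[1, 2]
      sum_logdet_gamma <- sum_logdet_gamma + tm$q * log(detK) +
        2 * tm$logdet_V
    }
  }
  xs <- setup$tmpl$x * coefs[setup$tmpl$g]
  M <- sparseMatrix(i = setup$tmpl$i, j = setup$tmpl$j, x = xs,
                    dims = c(setup$m, setup$m), symmetric = TRUE)
  # CHMfactor objects are updated in place; a failed update can leave the
  # shared factor in a broken state, so any failure falls back to a fresh
  # symbolic factorisation and the old object is abandoned
  ch <- NULL
  if (!is.null(chol_cache)) {
    ch <- tryCatch(Matrix::update(chol_cache, M),
                   error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(ch)) {
    ch <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, super = NA),
                   error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(ch)) {
    return(list(logL = -Inf, ok = FALSE, ch = NULL))
  }
  logdet_M <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  rhs <- setup$Wty / v_e
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  yPy <- (setup$yty - sum(sol * setup$Wty)) / v_e
  logL <- -0.5 * ((setup$n - setup$p) * log(2 * pi) + setup$n * log(v_e) +
                    sum_logdet_gamma + logdet_M + yPy)
  list(logL = logL, ok = TRUE, ch = ch, sol = sol, v_e = v_e, yPy = yPy)
}

#' Restricted log-likelihood of a mixed model
#'
#' Evaluates the REML log-likelihood (including the `-(n-p)/2 log(2 pi)`
#' constant) for a given set of variance parameters, via a sparse Cholesky
#' factorisation of the mixed-model-equation coefficient matrix. Used for
#' model comparison and as the objective that [reml_fit()] maximises.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (full column rank).
#' @param terms List of random terms from [rand_iid()], [rand_struct()],
#'   [rand_rr2()].
#' @param theta Parameter vector: the concatenated per-term parameters
#'   (variance for iid/struct terms; `k11, k22, k12` for rr2 terms) followed
#'   by the residual variance.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, X, terms, theta) {
  setup <- reml_setup(y, X, terms)
  if (!theta_feasible(setup, theta)) stop("infeasible variance parameters")
  ev <- reml_eval(setup, theta)
  if (!ev$ok) stop("singular mixed-model equations at the given parameters")
  ev$logL
}

# multiply the derivative of V wrt each parameter by a vector:
# returns n x npar matrix F with columns dV/dtheta_i %*% v
vdot_products <- function(setup, v) {
  out <- matrix(0, setup$n, setup$npar)
  col <- 1L
  for (k in seq_along(setup$terms)) {
    tm <- setup$terms[[k]]
    if (tm$type == "iid") {
      out[, col] <- as.numeric(tm$Z %*% crossprod(tm$Z, v))
      col <- col + 1L
    } else if (tm$type == "struct") {
      w <- crossprod(tm$Z, v)
      Hw <- Matrix::solve(setup$ch_V[[k]], w, system = "A")
      out[, col] <- as.numeric(tm$Z %*% Hw)
      col <- col + 1L
    } else {
      w1 <- crossprod(tm$Z1, v)
      w2 <- crossprod(tm$Z2, v)
      if (!is.null(tm$V_inv)) {
        w1 <- Matrix::solve(setup$ch_V[[k]], w1, system = "A")
        w2 <- Matrix::solve(setup$ch_V[[k]], w2, system = "A")
      }
      out[, col] <- as.numeric(tm$Z1 %*% w1)                      # k11
      out[, col + 1L] <- as.numeric(tm$Z2 %*% w2)                 # k22
      out[, col + 2L] <- as.numeric(tm$Z1 %*% w2 + tm$Z2 %*% w1)  # k12
      col <- col + 3L
    }
  }
  out[, setup$npar] <- v  # residual variance: dV/dv_e = I
  out
}

# P v = (v - W M^-1 W' v / v_e) / v_e using the current factorisation
apply_P <- function(setup, ev, V) {
  V <- as.matrix(V)
  rhs <- crossprod(setup$W, V) / ev$v_e
  sol <- Matrix::solve(ev$ch, rhs, system = "A")
  (V - as.matrix(setup$W %*% sol)) / ev$v_e
}

# Average-information matrix: AI[i,j] = 0.5 * (dV_i P y)' P (dV_j P y)
ai_matrix <- function(setup, ev) {
  Py <- as.numeric(apply_P(setup, ev, setup$y))
  Fm <- vdot_products(setup, Py)
  PF <- apply_P(setup, ev, Fm)
  ai <- 0.5 * crossprod(Fm, PF)
  ai <- (ai + t(ai)) / 2
  dimnames(ai) <- list(setup$par_names, setup$par_names)
  ai
}

# forward-difference gradient of the restricted log-likelihood; the
# factorisation is threaded through the evaluations so a failed update
# never leaves a broken factor in use
fd_gradient <- function(setup, theta, logL0, ch, scale_typ) {
  g <- numeric(setup$npar)
  for (i in seq_len(setup$npar)) {
    h <- 1e-5 * max(abs(theta[i]), 1e-3 * scale_typ)
    th <- theta
    th[i] <- th[i] + h
    if (!theta_feasible(setup, th)) {
      h <- -h
      th <- theta
      th[i] <- th[i] + h
    }
    ev <- reml_eval(setup, th, chol_cache = ch)
    if (!is.null(ev$ch)) ch <- ev$ch
    g[i] <- if (ev$ok) (ev$logL - logL0) / h else NA_real_
  }
  if (anyNA(g)) stop("likelihood evaluation failed during gradient computation")
  g
}

#' Control options for AI-REML
#'
#' @param max_iter Maximum number of average-information iterations.
#' @param tol_logl Convergence threshold on the change in restricted
#'   log-likelihood between accepted iterations.
#' @param tol_par Convergence threshold on the maximum relative parameter
#'   change.
#' @param min_var_frac Lower bound on every variance, as a fraction of the
#'   phenotypic variance (keeps components strictly inside the parameter
#'   space).
#' @param verbose Print per-iteration progress.
#' @return List of control values.
#' @export
reml_control <- function(max_iter = 200L, tol_logl = 1e-6, tol_par = 1e-8,
                         min_var_frac = 1e-8, verbose = FALSE) {
  list(max_iter = max_iter, tol_logl = tol_logl, tol_par = tol_par,
       min_var_frac = min_var_frac, verbose = verbose)
}

#' Fit a mixed model by average-information REML
#'
#' Maximises the restricted log-likelihood over the variance parameters by
#' Newton steps using the average-information (AI) matrix, the standard
#' second-order REML algorithm for animal-breeding models. The gradient is
#' obtained by numerical differentiation of the exactly-computed restricted
#' log-likelihood; the AI matrix is computed exactly from the quadratic
#' forms `0.5 * (dV_i P y)' P (dV_j P y)`. Steps are halved until they both
#' stay inside the parameter space (positive variances, positive-definite
#' 2x2 covariance blocks) and do not decrease the log-likelihood, so the
#' log-likelihood is non-decreasing over accepted iterations.
#'
#' @inheritParams restricted_loglik
#' @param start Optional start values (same layout as `theta` in
#'   [restricted_loglik()]). Default: residual variance = half the
#'   phenotypic variance, the remainder spread equally over all variance
#'   slots, covariances 0 (2x2 blocks start diagonal).
#' @param control See [reml_control()].
#' @param se_cols Indices of fixed-effect columns for which standard errors
#'   are computed (default: all when there are at most 60, otherwise none;
#'   callers typically request just the heat-load covariate).
#' @return An object of class `heatnorm_fit`: a list with elements `theta`
#'   (named parameter vector), `vc` (per-term variance components; 2x2
#'   blocks as matrices), `beta`, `beta_se`, `logL`, `ai` (average
#'   information matrix at the optimum), `grad`, `trace` (per-iteration
#'   log-likelihood and parameters), `converged`, `n_iter`, `n`, `p`,
#'   `par_names`, `sol` (all MME solutions), and `term_names`.
#' @export
reml_fit <- function(y, X, terms, start = NULL, control = reml_control(),
                     se_cols = NULL) {
  setup <- reml_setup(y, X, terms)
  vy <- stats::var(y)
  lb <- control$min_var_frac * vy
  if (is.null(start)) {
    nslot <- sum(vapply(setup$terms, function(tm)
      if (tm$npar == 3L) 2L else 1L, 0L))
    fill <- 0.5 * vy / nslot
    start <- numeric(setup$npar)
    pos <- 1L
    for (tm in setup$terms) {
      if (tm$npar == 1L) {
        start[pos] <- fill
        pos <- pos + 1L
      } else {
        start[pos:(pos + 2L)] <- c(fill, fill, 0)
        pos <- pos + 3L
      }
    }
    start[setup$npar] <- 0.5 * vy
  }
  if (!theta_feasible(setup, start, lb = 0)) {
    warning("non-positive-definite start values; projecting into the parameter space")
    start <- pmax(start, lb)
  }
  theta <- start
  ev <- reml_eval(setup, theta)
  if (!ev$ok) stop("mixed-model equations singular at the starting values; ",
                   "check that X has full column rank")
  trace <- data.frame(iter = 0L, logL = ev$logL, lambda = NA_real_)
  trace_theta <- matrix(theta, nrow = 1L)
  converged <- FALSE
  g <- NULL
  # Newton steps are taken on an unconstrained scale: log variances and
  # atanh correlations for the 2x2 blocks. The positive-definite boundary
  # is then at infinity, so steps toward a boundary optimum (e.g. a
  # correlation near 1 or a vanishing slope variance) stay well behaved.
  tcap <- t_caps(setup, vy, lb)
  tv <- theta_to_t(setup, theta)
  lambda <- 0
  n_small <- 0L
  n_rescue <- 0L
  for (iter in seq_len(control$max_iter)) {
    # AI first: it must see the factorisation at the current theta, which
    # the in-place finite-difference evaluations would otherwise perturb
    ai <- ai_matrix(setup, ev)
    g <- fd_gradient(setup, theta, ev$logL, ev$ch, vy)
    J <- t_jacobian(setup, theta)
    gt <- as.numeric(crossprod(J, g))
    ait <- crossprod(J, ai %*% J)
    ait <- (ait + t(ait)) / 2
    # active set: parameters pinned at a cap with an outward gradient
    free <- !((tv <= tcap$lo + 1e-9 & gt < 0) | (tv >= tcap$hi - 1e-9 & gt > 0))
    if (!any(free)) {
      converged <- TRUE
      break
    }
    # expected gain of a full (undamped) Newton step in the free subspace;
    # used to distinguish a plateau from true convergence
    exp_gain <- tryCatch({
      d0 <- solve(ait[free, free, drop = FALSE], gt[free])
      0.5 * sum(gt[free] * d0)
    }, error = function(e) NA_real_)
    accepted <- FALSE
    for (damp_try in 1:25) {
      dscale <- diag(ait)[free]
      dscale[dscale <= 0] <- max(abs(dscale), 1e-8)
      Hm <- ait[free, free, drop = FALSE] + lambda * diag(dscale, sum(free))
      delta_f <- tryCatch(solve(Hm, gt[free]), error = function(e) NULL)
      if (!is.null(delta_f)) {
        delta <- numeric(setup$npar)
        delta[free] <- delta_f
        tv_new <- pmin(tcap$hi, pmax(tcap$lo, tv + delta))
        th_new <- t_to_theta(setup, tv_new)
        ev_new <- reml_eval(setup, th_new, chol_cache = ev$ch)
        if (ev_new$ok && ev_new$logL >= ev$logL - 1e-10) {
          accepted <- TRUE
          break
        }
      }
      lambda <- if (lambda == 0) 1e-4 else lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) {
      # no uphill step even under heavy damping: gradient is numerically
      # zero along every free direction
      converged <- TRUE
      break
    }
    dl <- ev_new$logL - ev$logL
    dpar <- max(abs(th_new - theta) / pmax(abs(theta), 1e-8))
    if (control$verbose) {
      message(sprintf("iter %3d logL %.6f dlogL %.2e lambda %.2g", iter,
                      ev_new$logL, dl, lambda))
    }
    theta <- th_new
    tv <- tv_new
    ev <- ev_new
    trace <- rbind(trace, data.frame(iter = iter, logL = ev$logL,
                                     lambda = lambda))
    trace_theta <- rbind(trace_theta, theta)
    # converge when the step gained essentially nothing AND either the
    # projected Newton step promises essentially nothing more or the gain
    # has been negligible for three consecutive iterations (plateau); a
    # vanishing parameter change also terminates
    small_dl <- abs(dl) < control$tol_logl
    n_small <- if (small_dl) n_small + 1L else 0L
    if ((small_dl && !is.na(exp_gain) && exp_gain < 1e-3) ||
        n_small >= 3L || dpar < control$tol_par) {
      # before stopping, probe along the raw gradient: the average
      # information can understate the attainable gain on flat stretches
      probe <- NULL
      if (n_rescue < 10L) {
        gn <- sqrt(sum(gt[free]^2))
        if (gn > 0) {
          dirv <- numeric(setup$npar)
          dirv[free] <- gt[free] / gn
          for (sstep in c(1, 0.3, 0.1, 0.03, 0.01)) {
            tv_try <- pmin(tcap$hi, pmax(tcap$lo, tv + 0.3 * sstep * dirv))
            ev_try <- reml_eval(setup, t_to_theta(setup, tv_try),
                                chol_cache = ev$ch)
            if (ev_try$ok && ev_try$logL > ev$logL + 100 * control$tol_logl) {
              probe <- list(tv = tv_try, ev = ev_try)
              break
            }
          }
        }
      }
      if (is.null(probe)) {
        converged <- TRUE
        break
      }
      n_rescue <- n_rescue + 1L
      n_small <- 0L
      tv <- probe$tv
      theta <- t_to_theta(setup, tv)
      ev <- probe$ev
      trace <- rbind(trace, data.frame(iter = iter, logL = ev$logL,
                                       lambda = NA_real_))
      trace_theta <- rbind(trace_theta, theta)
      next
    }
    lambda <- max(0, lambda / 25)
    if (lambda < 1e-6) lambda <- 0
  }
  if (!converged) {
    stop("AI-REML did not converge in ", control$max_iter,
         " iterations; final logL = ", format(ev$logL),
         " (see trace attribute)", call. = FALSE)
  }
  # refresh the factorisation at the final theta (gradient evaluations
  # update the shared factor in place), then compute the reported AI
  # matrix, gradient and standard errors from it
  ev <- reml_eval(setup, theta, chol_cache = ev$ch)
  ai <- ai_matrix(setup, ev)
  g <- fd_gradient(setup, theta, ev$logL, ev$ch, vy)
  ev <- reml_eval(setup, theta, chol_cache = ev$ch)
  names(theta) <- setup$par_names
  colnames(trace_theta) <- setup$par_names

  sp <- split_theta(setup, theta)
  vc <- list()
  for (k in seq_along(setup$terms)) {
    tm <- setup$terms[[k]]
    vc[[tm$name]] <- if (tm$npar == 1L) unname(sp$term_par[[k]]) else {
      tp <- sp$term_par[[k]]
      matrix(c(tp[1], tp[3], tp[3], tp[2]), 2L, 2L,
             dimnames = list(c("int", "slope"), c("int", "slope")))
    }
  }
  vc$v_e <- sp$v_e

  beta <- ev$sol[seq_len(setup$p)]
  names(beta) <- colnames(setup$X)
  if (is.null(se_cols)) se_cols <- if (setup$p <= 60L) seq_len(setup$p) else integer(0)
  beta_se <- rep(NA_real_, setup$p)
  names(beta_se) <- colnames(setup$X)
  if (length(se_cols)) {
    E <- sparseMatrix(i = se_cols, j = seq_along(se_cols), x = 1,
                      dims = c(setup$m, length(se_cols)))
    Cinv_cols <- as.matrix(Matrix::solve(ev$ch, E, system = "A"))
    beta_se[se_cols] <- sqrt(pmax(Cinv_cols[cbind(se_cols, seq_along(se_cols))], 0))
  }

  structure(list(theta = theta, vc = vc, beta = beta, beta_se = beta_se,
                 logL = ev$logL, ai = ai, grad = g, trace = trace,
                 trace_theta = trace_theta, converged = converged,
                 n_iter = max(trace$iter), n = setup$n, p = setup$p,
                 par_names = setup$par_names, sol = ev$sol,
                 term_names = vapply(setup$terms, `[[`, "", "name")),
            class = "heatnorm_fit")
}

# --- transformed (unconstrained) parameter scale -------------------------
# variances -> log(v); 2x2 block covariance -> atanh of the correlation.

theta_to_t <- function(setup, theta) {
  tv <- theta
  pos <- 1L
  for (tm in setup$terms) {
    if (tm$npar == 1L) {
      tv[pos] <- log(theta[pos])
      pos <- pos + 1L
    } else {
      r <- theta[pos + 2L] / sqrt(theta[pos] * theta[pos + 1L])
      tv[pos] <- log(theta[pos])
      tv[pos + 1L] <- log(theta[pos + 1L])
      tv[pos + 2L] <- atanh(min(0.999999, max(-0.999999, r)))
      pos <- pos + 3L
    }
  }
  tv[setup$npar] <- log(theta[setup$npar])
  tv
}

t_to_theta <- function(setup, tv) {
  theta <- tv
  pos <- 1L
  for (tm in setup$terms) {
    if (tm$npar == 1L) {
      theta[pos] <- exp(tv[pos])
      pos <- pos + 1L
    } else {
      k11 <- exp(tv[pos])
      k22 <- exp(tv[pos + 1L])
      theta[pos] <- k11
      theta[pos + 1L] <- k22
      theta[pos + 2L] <- tanh(tv[pos + 2L]) * sqrt(k11 * k22)
      pos <- pos + 3L
    }
  }
  theta[setup$npar] <- exp(tv[setup$npar])
  theta
}

# Jacobian d theta / d t (npar x npar)
t_jacobian <- function(setup, theta) {
  J <- matrix(0, setup$npar, setup$npar)
  pos <- 1L
  for (tm in setup$terms) {
    if (tm$npar == 1L) {
      J[pos, pos] <- theta[pos]
      pos <- pos + 1L
    } else {
      k11 <- theta[pos]; k22 <- theta[pos + 1L]; k12 <- theta[pos + 2L]
      r <- k12 / sqrt(k11 * k22)
      J[pos, pos] <- k11
      J[pos + 1L, pos + 1L] <- k22
      J[pos + 2L, pos] <- k12 / 2
      J[pos + 2L, pos + 1L] <- k12 / 2
      J[pos + 2L, pos + 2L] <- (1 - r^2) * sqrt(k11 * k22)
      pos <- pos + 3L
    }
  }
  J[setup$npar, setup$npar] <- theta[setup$npar]
  J
}

# caps on the transformed scale: variances in [lb, 1e4 * var(y)],
# correlations within tanh(+-6) (|r| <= 0.99999)
t_caps <- function(setup, vy, lb) {
  lo <- numeric(setup$npar)
  hi <- numeric(setup$npar)
  pos <- 1L
  for (tm in setup$terms) {
    if (tm$npar == 1L) {
      lo[pos] <- log(lb); hi[pos] <- log(1e4 * vy)
      pos <- pos + 1L
    } else {
      lo[pos:(pos + 1L)] <- log(lb); hi[pos:(pos + 1L)] <- log(1e4 * vy)
      lo[pos + 2L] <- -6; hi[pos + 2L] <- 6
      pos <- pos + 3L
    }
  }
  lo[setup$npar] <- log(lb); hi[setup$npar] <- log(1e4 * vy)
  list(lo = lo, hi = hi)
}

clamp_theta <- function(setup, theta, lb) {
  sp <- split_theta(setup, theta)
  pos <- 1L
  for (k in seq_along(setup$terms)) {
    tm <- setup$terms[[k]]
    if (tm$npar == 1L) {
      theta[pos] <- max(theta[pos], lb)
      pos <- pos + 1L
    } else {
      theta[pos] <- max(theta[pos], lb)
      theta[pos + 1L] <- max(theta[pos + 1L], lb)
      # shrink covariance inside the PSD cone if needed
      bound <- sqrt(theta[pos] * theta[pos + 1L])
      if (abs(theta[pos + 2L]) >= bound) {
        theta[pos + 2L] <- sign(theta[pos + 2L]) * 0.999 * bound
      }
      pos <- pos + 3L
    }
  }
  theta[setup$npar] <- max(theta[setup$npar], lb)
  theta
}

#' @export
print.heatnorm_fit <- function(x, ...) {
  cat("AI-REML fit:", x$n, "records,", x$p, "fixed-effect columns\n")
  cat("logL =", format(x$logL, digits = 10), " (", x$n_iter, "iterations )\n")
  cat("variance components:\n")
  for (nm in names(x$vc)) {
    v <- x$vc[[nm]]
    if (is.matrix(v)) {
      cat("  ", nm, ": K = [", paste(signif(c(v[1, 1], v[2, 2], v[1, 2]), 5),
                                     collapse = ", "),
          "] (int var, slope var, covariance)\n")
    } else {
      cat("  ", nm, ":", signif(v, 5), "\n")
    }
  }
  invisible(x)
}
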