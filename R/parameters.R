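#' Reaction-norm variance along the gradient
#'
#' For an intercept+slope random effect with 2x2 covariance `K`, the
#' variance at gradient value `x` is the quadratic form
#' `Var(x) = v_int + 2 x c_is + x^2 v_slope = (1, x) K (1, x)'`.
#'
#' @param K Either a 2x2 covariance matrix (intercept first) or a numeric
#'   vector `c(v_int, v_slope, c_is)`.
#' @param x Gradient value(s) on the scaled \[-1, 1\] axis (vectorised).
#' @return Numeric vector of variances.
#' @export
variance_at <- function(K, x) {
  k <- cf2(K)
  k[["v_int"]] + 2 * x * k[["c_is"]] + x^2 * k[["v_slope"]]
}

cf2 <- function(K) {
  if (is.matrix(K)) {
    stopifnot(all(dim(K) == c(2L, 2L)))
    c(v_int = K[1, 1], v_slope = K[2, 2], c_is = K[1, 2])
  } else {
    stopifnot(is.numeric(K), length(K) == 3L)
    k <- unname(K)
    c(v_int = k[1], v_slope = k[2], c_is = k[3])
  }
}

#' Correlation between a reaction-norm effect at two gradient values
#'
#' `r(x1, x2) = (v_int + (x1 + x2) c_is + x1 x2 v_slope) /
#' sqrt(Var(x1) Var(x2))`; symmetric in its arguments and exactly 1 when
#' `x1 == x2` or when the slope variance is zero.
#'
#' @inheritParams variance_at
#' @param x1,x2 Gradient values (vectorised together).
#' @return Numeric vector of correlations.
#' @export
correlation_between_envs <- function(K, x1, x2) {
  k <- cf2(K)
  v1 <- variance_at(k, x1)
  v2 <- variance_at(k, x2)
  if (any(v1 <= 0) || any(v2 <= 0)) {
    stop("zero or negative reaction-norm variance at a requested gradient ",
         "value; correlation undefined")
  }
  cv <- k[["v_int"]] + (x1 + x2) * k[["c_is"]] + x1 * x2 * k[["v_slope"]]
  pmin(1, pmax(-1, cv / sqrt(v1 * v2)))
}

# canonical component list from a fit or a plain list
as_components <- function(object) {
  if (inherits(object, "heatnorm_fit")) {
    vc <- object$vc
    list(v_d = vc$d, K_m = vc$m, K_pe = vc$pe, v_hym = vc$hym, v_e = vc$v_e)
  } else {
    stopifnot(all(c("v_d", "K_m", "K_pe", "v_e") %in% names(object)))
    if (is.null(object$v_hym)) object$v_hym <- 0
    object
  }
}

#' Heritabilities and variance ratios along the heat-load gradient
#'
#' The phenotypic variance at gradient value `x` is
#' `v_p(x) = v_d + v_m(x) + v_pe(x) + v_hym + v_e` (the herd-year-month
#' variance is part of the denominator by default, being a random model
#' term). Direct heritability is `v_d / v_p(x)`, maternal heritability
#' `v_m(x) / v_p(x)`, and the maternal permanent-environmental proportion
#' `v_pe(x) / v_p(x)`.
#'
#' @param components A `heatnorm_fit` from [fit_model2()] or a list with
#'   `v_d`, `K_m`, `K_pe`, `v_hym`, `v_e`.
#' @param x Gradient value(s), vectorised.
#' @param include_hym Include the herd-year-month variance in the
#'   phenotypic denominator (default `TRUE`).
#' @return data.frame with columns `x`, `v_m`, `v_pe`, `v_p`, `h2_d`,
#'   `h2_m`, `pe_prop`.
#' @export
heritabilities_at <- function(components, x, include_hym = TRUE) {
  cp <- as_components(components)
  v_m <- variance_at(cp$K_m, x)
  v_pe <- variance_at(cp$K_pe, x)
  v_p <- cp$v_d + v_m + v_pe + (if (include_hym) cp$v_hym else 0) + cp$v_e
  if (any(v_p <= 0)) stop("non-positive phenotypic variance")
  data.frame(x = x, v_m = v_m, v_pe = v_pe, v_p = v_p,
             h2_d = cp$v_d / v_p, h2_m = v_m / v_p, pe_prop = v_pe / v_p)
}

# map a REML parameter vector (named as in fit$par_names) to components
theta_components <- function(theta) {
  list(v_d = theta[["d.v"]],
       K_m = matrix(c(theta[["m.k11"]], theta[["m.k12"]],
                      theta[["m.k12"]], theta[["m.k22"]]), 2L, 2L),
       K_pe = matrix(c(theta[["pe.k11"]], theta[["pe.k12"]],
                       theta[["pe.k12"]], theta[["pe.k22"]]), 2L, 2L),
       v_hym = theta[["hym.v"]], v_e = theta[["v_e"]])
}

# delta-method SE of scalar functions of the variance parameters, using the
# inverse average-information matrix as the asymptotic covariance
delta_se <- function(fit, fun_list) {
  Sigma <- tryCatch(solve(fit$ai), error = function(e) NULL)
  if (is.null(Sigma)) {
    warning("average-information matrix is singular; standard errors ",
            "reported as missing")
    return(rep(NA_real_, length(fun_list)))
  }
  theta <- fit$theta
  vapply(fun_list, function(fun) {
    g0 <- fun(theta)
    grad <- vapply(seq_along(theta), function(i) {
      h <- 1e-6 * max(abs(theta[i]), 1e-6)
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- dn[i] - h
      (fun(up) - fun(dn)) / (2 * h)
    }, 0)
    v <- drop(t(grad) %*% Sigma %*% grad)
    sqrt(max(v, 0))
  }, 0)
}

#' Gradient-dependent genetic parameters with standard errors
#'
#' Evaluates the maternal genetic and permanent-environmental variance
#' functions, phenotypic variance, direct and maternal heritabilities and
#' the permanent-environmental proportion over a grid of the scaled
#' gradient, with delta-method standard errors propagated from the inverse
#' average-information matrix of the REML fit.
#'
#' @param fit A `heatnorm_fit` from [fit_model2()].
#' @param grid Gradient values (default `seq(-1, 1, by = 0.1)`).
#' @param se Compute standard errors (default `TRUE`).
#' @param include_hym See [heritabilities_at()].
#' @return data.frame with the parameter values and (optionally) `se_`
#'   columns.
#' @export
gradient_parameters <- function(fit, grid = seq(-1, 1, by = 0.1), se = TRUE,
                                include_hym = TRUE) {
  stopifnot(inherits(fit, "heatnorm_fit"))
  out <- heritabilities_at(fit, grid, include_hym = include_hym)
  if (se) {
    mk <- function(what, x) {
      force(x)
      switch(what,
        v_m = function(th) variance_at(theta_components(th)$K_m, x),
        v_pe = function(th) variance_at(theta_components(th)$K_pe, x),
        h2_d = function(th) heritabilities_at(theta_components(th), x,
                                              include_hym)$h2_d,
        h2_m = function(th) heritabilities_at(theta_components(th), x,
                                              include_hym)$h2_m,
        pe_prop = function(th) heritabilities_at(theta_components(th), x,
                                                 include_hym)$pe_prop)
    }
    for (what in c("v_m", "v_pe", "h2_d", "h2_m", "pe_prop")) {
      funs <- lapply(grid, function(x) mk(what, x))
      out[[paste0("se_", what)]] <- delta_se(fit, funs)
    }
  }
  out
}

#' Correlation matrix of a reaction-norm effect over a gradient grid
#'
#' @param fit A `heatnorm_fit` from [fit_model2()], or a 2x2 covariance
#'   matrix.
#' @param grid Gradient values.
#' @param which `"m"` (maternal genetic) or `"pe"` (maternal permanent
#'   environmental); ignored when `fit` is a matrix.
#' @param se Also return delta-method SEs (only available from a fit).
#' @return A list with `r` (correlation matrix over the grid) and, when
#'   requested, `se` (same shape).
#' @export
correlation_grid <- function(fit, grid = seq(-1, 1, by = 0.1),
                             which = c("m", "pe"), se = FALSE) {
  which <- match.arg(which)
  K <- if (inherits(fit, "heatnorm_fit")) fit$vc[[which]] else fit
  ng <- length(grid)
  r <- outer(grid, grid, function(a, b) correlation_between_envs(K, a, b))
  dimnames(r) <- list(format(grid), format(grid))
  out <- list(r = r)
  if (se) {
    stopifnot(inherits(fit, "heatnorm_fit"))
    pairs <- expand.grid(i = seq_len(ng), j = seq_len(ng))
    key <- if (which == "m") "K_m" else "K_pe"
    funs <- lapply(seq_len(nrow(pairs)), function(k) {
      x1 <- grid[pairs$i[k]]
      x2 <- grid[pairs$j[k]]
      function(th) correlation_between_envs(theta_components(th)[[key]],
                                            x1, x2)
    })
    out$se <- matrix(delta_se(fit, funs), ng, ng, dimnames = dimnames(r))
  }
  out
}

#' Delta-method standard errors for gradient parameters
#'
#' Convenience wrapper returning only the standard errors of the gradient
#' parameters (see [gradient_parameters()]).
#'
#' @inheritParams gradient_parameters
#' @return data.frame of the grid and `se_` columns.
#' @export
parameter_ses <- function(fit, grid = seq(-1, 1, by = 0.1),
                          include_hym = TRUE) {
  gp <- gradient_parameters(fit, grid, se = TRUE, include_hym = include_hym)
  gp[, c("x", grep("^se_", names(gp), value = TRUE))]
}
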