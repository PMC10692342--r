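#' Fixed-effect design matrix for the birth-weight models
#'
#' Builds the sparse full-rank fixed-effect design: overall mean,
#' herd-birth-year, sex-by-birth-type, gestation-length class, parity class
#' (treatment contrasts) and one linear heat-load covariate.
#'
#' @param records Edited records with factor columns from
#'   [assign_classes()] and the covariate column present.
#' @param covariate Name of the heat-load covariate column (e.g. `"s_wk8"`
#'   or `"s_pc1"`).
#' @return Sparse design matrix; the covariate is the last column, named
#'   after `covariate`.
#' @export
fixed_design <- function(records, covariate) {
  stopifnot(covariate %in% names(records))
  d <- droplevels(records[, c("hy", "sex_bt", "gl_class", "parity_class")])
  d$heat <- records[[covariate]]
  stopifnot(!anyNA(d$heat))
  X <- Matrix::sparse.model.matrix(
    ~ hy + sex_bt + gl_class + parity_class + heat, data = d)
  colnames(X)[ncol(X)] <- covariate
  drop_aliased(X, protect = covariate)
}

# drop linearly dependent fixed-effect columns (pivoted Cholesky of X'X),
# so the mixed-model equations stay positive definite; aliasing among
# treatment-coded factors does occur in small or unbalanced data sets
drop_aliased <- function(X, protect = character(0)) {
  XtX <- as.matrix(crossprod(X))
  ch <- suppressWarnings(chol(XtX, pivot = TRUE, tol = 1e-9))
  r <- attr(ch, "rank")
  if (r < ncol(X)) {
    keep <- sort(attr(ch, "pivot")[seq_len(r)])
    dropped <- colnames(X)[-keep]
    if (any(protect %in% dropped)) {
      stop("fixed-effect covariate ", paste(intersect(protect, dropped),
                                            collapse = ", "),
           " is aliased with the factor effects and cannot be estimated")
    }
    warning("dropping ", length(dropped), " aliased fixed-effect column(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

# records x levels indicator for a factor/id vector over a given level list
indicator_matrix <- function(ids, levels) {
  j <- match(as.character(ids), levels)
  if (anyNA(j)) {
    stop("unknown level(s): ",
         paste(utils::head(unique(as.character(ids)[is.na(j)]), 5L),
               collapse = ", "))
  }
  sparseMatrix(i = seq_along(j), j = j, x = 1,
               dims = c(length(j), length(levels)),
               dimnames = list(NULL, levels))
}

#' Design matrices for the two birth-weight models
#'
#' Model 1 (`y = Xb + Ks + Mh + Q c_hym + e`) regresses birth weight on one
#' scaled heat-load covariate with independent random sire, dam and
#' herd-year-month effects. Model 2
#' (`y = Xb + Zd + Wm + S p_m + Q c_hym + e`) is the maternal reaction-norm
#' model: a direct additive effect per calf plus maternal genetic and
#' maternal permanent-environmental intercept+slope pairs per dam, the
#' covariate nested within the maternal terms.
#'
#' @inheritParams fixed_design
#' @param model 1 or 2.
#' @param animal_ids Ordered ids carrying the direct additive effect
#'   (model 2; typically the full pedigree order).
#' @param maternal_ids Ordered ids carrying the maternal genetic
#'   intercept/slope pair (model 2; typically dams plus their ancestors).
#' @return A named list of sparse matrices: model 1 `X, K, M, Q`; model 2
#'   `X, Z, W_int, W_slope, S_int, S_slope, Q`, plus `hym_levels`,
#'   `sire_levels`/`dam_levels` (model 1) or `pe_levels` (model 2).
#' @export
build_design <- function(records, covariate, model = 1L, animal_ids = NULL,
                         maternal_ids = NULL) {
  X <- fixed_design(records, covariate)
  hym_levels <- sort(unique(as.character(records$hym)))
  Q <- indicator_matrix(records$hym, hym_levels)
  if (model == 1L) {
    sire_levels <- sort(unique(as.character(records$sire_id)))
    dam_levels <- sort(unique(as.character(records$dam_id)))
    list(X = X,
         K = indicator_matrix(records$sire_id, sire_levels),
         M = indicator_matrix(records$dam_id, dam_levels),
         Q = Q,
         sire_levels = sire_levels, dam_levels = dam_levels,
         hym_levels = hym_levels)
  } else {
    stopifnot(!is.null(animal_ids), !is.null(maternal_ids))
    x <- records[[covariate]]
    Z <- indicator_matrix(records$calf_id, animal_ids)
    W <- indicator_matrix(records$dam_id, maternal_ids)
    pe_levels <- sort(unique(as.character(records$dam_id)))
    S <- indicator_matrix(records$dam_id, pe_levels)
    list(X = X, Z = Z,
         W_int = W, W_slope = W * x,
         S_int = S, S_slope = S * x,
         Q = Q, pe_levels = pe_levels, hym_levels = hym_levels)
  }
}

#' Fit the fixed-regression model (model 1)
#'
#' Estimates the regression of birth weight on one scaled prenatal
#' heat-load covariate with independent random sire, dam and
#' herd-year-month effects, by AI-REML. The heat-load coefficient, its
#' model-based standard error and the Wald p-value are attached.
#'
#' @inheritParams fixed_design
#' @param control See [reml_control()].
#' @param start Optional starting values (`v_sire, v_dam, v_hym, v_e`).
#' @return A `heatnorm_fit` with an additional `covariate` element
#'   (`name`, `estimate`, `se`, `p_value`).
#' @export
fit_model1 <- function(records, covariate, control = reml_control(),
                       start = NULL) {
  records <- records[!is.na(records[[covariate]]), , drop = FALSE]
  ds <- build_design(records, covariate, model = 1L)
  terms <- list(rand_iid(ds$K, "sire"),
                rand_iid(ds$M, "dam"),
                rand_iid(ds$Q, "hym"))
  cov_col <- ncol(ds$X)
  fit <- reml_fit(records$biw_kg, ds$X, terms, start = start,
                  control = control, se_cols = cov_col)
  est <- unname(fit$beta[cov_col])
  se <- unname(fit$beta_se[cov_col])
  fit$covariate <- list(name = covariate, estimate = est, se = se,
                        p_value = 2 * stats::pnorm(-abs(est / se)))
  fit$model <- 1L
  fit
}

#' Run the model-1 regression battery over all heat-load covariates
#'
#' Fits model 1 once per covariate (the 12 weekly scaled THI means and the
#' scaled PC1, i.e. 13 consecutive runs) and collects the regression
#' coefficients. A failed run is reported, not propagated.
#'
#' @inheritParams fit_model1
#' @param covariates Covariate columns to sweep (default
#'   `s_wk1..s_wk12, s_pc1`).
#' @return A list with `report` (data.frame: covariate, estimate, se,
#'   p_value, logL, converged, error) and `fits` (the individual fits,
#'   `NULL` where a run failed).
#' @export
run_model1_battery <- function(records,
                               covariates = c(paste0("s_wk", 1:12), "s_pc1"),
                               control = reml_control()) {
  fits <- vector("list", length(covariates))
  names(fits) <- covariates
  rows <- lapply(covariates, function(cv) {
    f <- tryCatch(fit_model1(records, cv, control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      data.frame(covariate = cv, estimate = NA_real_, se = NA_real_,
                 p_value = NA_real_, logL = NA_real_, converged = FALSE,
                 error = conditionMessage(f), stringsAsFactors = FALSE)
    } else {
      fits[[cv]] <<- f
      data.frame(covariate = cv, estimate = f$covariate$estimate,
                 se = f$covariate$se, p_value = f$covariate$p_value,
                 logL = f$logL, converged = f$converged, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  list(report = do.call(rbind, rows), fits = fits)
}

#' Pedigree subset: ids plus all their ancestors
#'
#' @param ped Pedigree data.frame (`id`, `sire`, `dam`).
#' @param ids Ids whose ancestral closure is wanted.
#' @return The pedigree rows for `ids` and all their ancestors.
#' @export
prune_pedigree <- function(ped, ids) {
  id <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  sire[sire %in% c("0", "") | is.na(sire)] <- NA
  dam[dam %in% c("0", "") | is.na(dam)] <- NA
  keep <- unique(as.character(ids))
  frontier <- keep
  while (length(frontier)) {
    rows <- match(frontier, id)
    par <- unique(stats::na.omit(c(sire[rows], dam[rows])))
    par <- setdiff(par, keep)
    keep <- c(keep, par)
    frontier <- par
  }
  ped[id %in% keep, , drop = FALSE]
}

#' Fit the maternal reaction-norm model (model 2)
#'
#' Estimates the (co)variance components of the maternal reaction-norm
#' model by AI-REML: a direct additive genetic effect per calf and, per
#' dam, maternal genetic and maternal permanent-environmental
#' intercept+slope pairs in the scaled heat-load covariate, plus a random
#' herd-year-month effect. The additive structures are the single-step H
#' matrix when genotypes are supplied, otherwise the pedigree A matrix. The
#' direct effect is intercept-only; no direct-maternal covariance is
#' fitted. The maternal genetic term uses the pedigree restricted to dams
#' and their ancestors (animals without records or descendants in that role
#' marginalise out exactly).
#'
#' @inheritParams fit_model1
#' @param ped Pedigree data.frame (`id`, `sire`, `dam`).
#' @param G Genomic relationship matrix over genotyped animals, or `NULL`
#'   for a pedigree-only (A matrix) fit.
#' @param genotyped_ids Ids of genotyped animals (ignored when `G` is
#'   `NULL`).
#' @param blend_w Weight on G in the Gw blend (see
#'   [blend_and_H_inverse()]).
#' @return A `heatnorm_fit` with `vc` elements `d` (direct variance), `m`
#'   (2x2 maternal genetic covariance), `pe` (2x2 maternal
#'   permanent-environmental covariance), `hym`, `v_e`, plus `covariate`
#'   info as in [fit_model1()].
#' @export
fit_model2 <- function(records, covariate, ped, G = NULL,
                       genotyped_ids = NULL, blend_w = 0.95,
                       control = reml_control(), start = NULL) {
  records <- records[!is.na(records[[covariate]]), , drop = FALSE]
  gids <- if (is.null(G)) character(0) else as.character(genotyped_ids)
  hb_d <- blend_and_H_inverse(G, ped, gids, blend_w = blend_w)

  ped_m <- prune_pedigree(ped, unique(records$dam_id))
  gids_m <- intersect(gids, as.character(ped_m$id))
  hb_m <- blend_and_H_inverse(G, ped_m, gids_m, blend_w = blend_w)

  ds <- build_design(records, covariate, model = 2L,
                     animal_ids = hb_d$ids, maternal_ids = hb_m$ids)
  terms <- list(
    rand_struct(ds$Z, hb_d$H_inv, hb_d$logdet_H, "d"),
    rand_rr2(ds$W_int, ds$W_slope, V_inv = hb_m$H_inv,
             logdet_V = hb_m$logdet_H, name = "m"),
    rand_rr2(ds$S_int, ds$S_slope, V_inv = NULL, name = "pe"),
    rand_iid(ds$Q, "hym")
  )
  cov_col <- ncol(ds$X)
  fit <- reml_fit(records$biw_kg, ds$X, terms, start = start,
                  control = control, se_cols = cov_col)
  est <- unname(fit$beta[cov_col])
  se <- unname(fit$beta_se[cov_col])
  fit$covariate <- list(name = covariate, estimate = est, se = se,
                        p_value = 2 * stats::pnorm(-abs(est / se)))
  fit$model <- 2L
  fit
}
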