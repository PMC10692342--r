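library(Matrix)

test_that("design matrices have the documented structure", {
  recs <- assign_classes(edit_phenotypes(toy_records(100, 12, seed = 2))$records)
  recs$s_pc1 <- stats::runif(nrow(recs), -1, 1)
  ds1 <- build_design(recs, "s_pc1", model = 1L)
  expect_equal(nrow(ds1$X), nrow(recs))
  expect_equal(colnames(ds1$X)[ncol(ds1$X)], "s_pc1")
  expect_equal(ncol(ds1$K), length(unique(recs$sire_id)))
  expect_equal(unname(Matrix::rowSums(ds1$Q)), rep(1, nrow(recs)))

  # 3 records of one dam with covariates (-1, 0, 1): W rows are
  # (1,-1), (1,0), (1,1) split over the intercept and slope blocks
  r3 <- recs[1:3, ]
  r3$dam_id <- "DD"
  r3$calf_id <- c("X1", "X2", "X3")
  r3$s_pc1 <- c(-1, 0, 1)
  ds2 <- build_design(r3, "s_pc1", model = 2L,
                      animal_ids = c("X1", "X2", "X3", "DD"),
                      maternal_ids = "DD")
  expect_equal(as.numeric(ds2$W_int), c(1, 1, 1))
  expect_equal(as.numeric(ds2$W_slope), c(-1, 0, 1))
  expect_equal(dim(ds2$Z), c(3L, 4L))
})

test_that("two herds by two years enumerate four herd-year levels", {
  recs <- toy_records(60, 10, n_herds = 2, seed = 3)
  recs$birth_date <- as.Date("2010-06-01") +
    ifelse(seq_len(60) %% 2 == 0, 0, 400)
  recs <- assign_classes(edit_phenotypes(recs)$records)
  expect_equal(nlevels(droplevels(recs$hy)), 4L)
  recs$s_pc1 <- seq(-1, 1, length.out = nrow(recs))
  X <- fixed_design(recs, "s_pc1")
  # intercept + 3 herd-year contrasts
  expect_equal(sum(grepl("^hy", colnames(X))) + 1L, 4L)
})

test_that("REML equals the closed-form ANOVA estimator on balanced one-way data", {
  s <- 5; nrep <- 4
  set.seed(13)
  g <- factor(rep(seq_len(s), each = nrep))
  y <- 20 + stats::rnorm(s, 0, 2)[g] + stats::rnorm(s * nrep, 0, 1.5)
  ms <- anova(stats::lm(y ~ g))
  v_between <- (ms["g", "Mean Sq"] - ms["Residuals", "Mean Sq"]) / nrep
  Z <- t(as(g, "sparseMatrix")) * 1
  fit <- reml_fit(y, matrix(1, s * nrep, 1), list(rand_iid(Z, "grp")),
                  control = reml_control(tol_logl = 1e-10))
  expect_equal(unname(fit$theta[1]), v_between, tolerance = 1e-4)
  expect_equal(unname(fit$theta[2]), ms["Residuals", "Mean Sq"],
               tolerance = 1e-4)
})

test_that("a pure-noise model drives the group variance to the boundary", {
  set.seed(17)
  n <- 400
  g <- factor(rep(1:40, each = 10))
  y <- 5 + stats::rnorm(n, 0, 2)
  Z <- t(as(g, "sparseMatrix")) * 1
  fit <- reml_fit(y, matrix(1, n, 1), list(rand_iid(Z, "grp")))
  # MC standard error of the between-group variance under the null is
  # about sqrt(2 * ve^2 * (1/m)(1/n_rep^2) ...); 3 SE ~ 0.6 here
  expect_lt(unname(fit$theta[1]), 0.6)
  expect_equal(unname(fit$theta[2]), 4, tolerance = 0.6)
})

test_that("AI-REML lands within one grid cell of a restricted-likelihood grid search", {
  for (seed in c(101, 202)) {
    set.seed(seed)
    q <- 30; nrep <- 10; n <- q * nrep
    g <- factor(rep(seq_len(q), each = nrep))
    x <- stats::rnorm(n)
    y <- 1 + 0.5 * x + stats::rnorm(q, 0, sqrt(3))[g] + stats::rnorm(n, 0, 1.4)
    X <- cbind(1, x)
    Z <- t(as(g, "sparseMatrix")) * 1
    terms <- list(rand_iid(Z, "grp"))
    fit <- reml_fit(y, X, terms, control = reml_control(tol_logl = 1e-9))
    v1 <- seq(0.5, 6, length.out = 51)
    v2 <- seq(0.5, 6, length.out = 51)
    setup <- heatnorm:::reml_setup(y, X, terms)
    ll <- matrix(-Inf, 51, 51)
    ch <- NULL
    for (i in seq_along(v1)) for (j in seq_along(v2)) {
      ev <- heatnorm:::reml_eval(setup, c(v1[i], v2[j]), chol_cache = ch)
      ch <- ev$ch
      ll[i, j] <- ev$logL
    }
    best <- which(ll == max(ll), arr.ind = TRUE)
    cell <- c(diff(v1)[1], diff(v2)[1])
    expect_lt(abs(fit$theta[1] - v1[best[1]]), cell[1] + 1e-9)
    expect_lt(abs(fit$theta[2] - v2[best[2]]), cell[2] + 1e-9)
  }
})

test_that("restricted log-likelihood matches the dense-formula oracle", {
  set.seed(23)
  n <- 20
  g <- factor(sample(1:6, n, TRUE))
  h <- factor(sample(1:4, n, TRUE))
  x <- stats::runif(n, -1, 1)
  y <- stats::rnorm(n, 30, 3)
  X <- cbind(1, x)
  Zg <- t(as(g, "sparseMatrix")) * 1
  Zh <- t(as(h, "sparseMatrix")) * 1
  terms <- list(rand_iid(Zg, "g"), rand_iid(Zh, "h"))
  theta <- c(2.5, 1.2, 3.1)
  ll <- restricted_loglik(y, X, terms, theta)
  ll_ref <- dense_reml_oracle(y, X, list(
    2.5 * as.matrix(Zg %*% t(Zg)), 1.2 * as.matrix(Zh %*% t(Zh))), 3.1)
  expect_equal(ll, ll_ref, tolerance = 1e-8)
})

test_that("scaling the response shifts the restricted log-likelihood exactly", {
  set.seed(29)
  n <- 60
  g <- factor(sample(1:10, n, TRUE))
  y <- stats::rnorm(n, 40, 4)
  X <- matrix(1, n, 1)
  Z <- t(as(g, "sparseMatrix")) * 1
  terms <- list(rand_iid(Z, "g"))
  theta <- c(3, 8)
  cc <- 2.7
  l1 <- restricted_loglik(y, X, terms, theta)
  l2 <- restricted_loglik(cc * y, X, terms, cc^2 * theta)
  expect_equal(l2, l1 - (n - 1) * log(cc), tolerance = 1e-9)
})

test_that("REML estimates are invariant to a constant shift of the response", {
  recs <- assign_classes(edit_phenotypes(toy_records(150, 20, seed = 5))$records)
  recs$s_pc1 <- stats::runif(nrow(recs), -1, 1)
  f1 <- fit_model1(recs, "s_pc1")
  recs2 <- recs
  recs2$biw_kg <- recs2$biw_kg + 7
  f2 <- fit_model1(recs2, "s_pc1")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
  expect_equal(f1$covariate$estimate, f2$covariate$estimate, tolerance = 1e-5)
})

test_that("a maternal-slope model dominates its slope-free reduction", {
  # data with genuine maternal slopes: the reaction-norm model must reach a
  # restricted likelihood at least as high as the nested slope-free model
  wins <- 0L
  for (seed in 1:3) {
    cfg <- tiny_config(seed = seed, K_m = c(1.4, 0.6, 0.2),
                       K_pe = c(0.6, 0.5, 0.1))
    d <- simulate_dataset(cfg)
    recs <- merge(assign_classes(edit_phenotypes(d$calves)$records),
                  d$covariates, by = "calf_id")
    fit <- fit_model2(recs, "s_pc1", d$pedigree)
    # slope-free reduction: freeze slope variances/covariances near zero
    th0 <- fit$theta
    th0[c("m.k22", "m.k12", "pe.k22", "pe.k12")] <- c(1e-8, 0, 1e-8, 0)
    ll0 <- with(fit, {
      recs2 <- recs[!is.na(recs$s_pc1), ]
      hb_d <- blend_and_H_inverse(NULL, d$pedigree, character(0))
      ped_m <- prune_pedigree(d$pedigree, unique(recs2$dam_id))
      hb_m <- blend_and_H_inverse(NULL, ped_m, character(0))
      ds <- build_design(recs2, "s_pc1", model = 2L,
                         animal_ids = hb_d$ids, maternal_ids = hb_m$ids)
      terms <- list(
        rand_struct(ds$Z, hb_d$H_inv, hb_d$logdet_H, "d"),
        rand_rr2(ds$W_int, ds$W_slope, V_inv = hb_m$H_inv,
                 logdet_V = hb_m$logdet_H, name = "m"),
        rand_rr2(ds$S_int, ds$S_slope, V_inv = NULL, name = "pe"),
        rand_iid(ds$Q, "hym"))
      restricted_loglik(recs2$biw_kg, fixed_design(recs2, "s_pc1"),
                        terms, th0)
    })
    if (fit$logL >= ll0 - 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("the model-1 battery sweeps all covariates and reports 13 rows", {
  cfg <- tiny_config(seed = 31)
  d <- simulate_dataset(cfg)
  recs <- merge(assign_classes(edit_phenotypes(d$calves)$records),
                d$covariates, by = "calf_id")
  bat <- run_model1_battery(recs)
  expect_equal(nrow(bat$report), 13L)
  expect_equal(bat$report$covariate, c(paste0("s_wk", 1:12), "s_pc1"))
  expect_true(all(bat$report$converged))
  # an identical covariate column gives an identical coefficient
  recs$s_wk1 <- recs$s_wk2
  b2 <- run_model1_battery(recs, covariates = c("s_wk1", "s_wk2"))
  expect_equal(b2$report$estimate[1], b2$report$estimate[2], tolerance = 1e-6)
})

test_that("a simulated fixed heat-load slope is recovered by model 1", {
  cfg <- tiny_config(seed = 37, n_dams = 150L, n_herds = 4L,
                     covariate = "s_wk4", beta_heat = -0.8)
  d <- simulate_dataset(cfg)
  recs <- merge(assign_classes(edit_phenotypes(d$calves)$records),
                d$covariates, by = "calf_id")
  fit <- fit_model1(recs, "s_wk4")
  expect_lt(abs(fit$covariate$estimate - (-0.8)), 2.5 * fit$covariate$se)
  expect_gt(fit$covariate$se, 0)
})
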