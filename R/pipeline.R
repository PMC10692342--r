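#' Plot gradient-dependent parameters
#'
#' Base-graphics summaries of a model-2 fit: heritabilities and variance
#' functions along the gradient, and the correlations of the maternal
#' effects between the gradient maximum and every other grid point.
#'
#' @param fit A `heatnorm_fit` from [fit_model2()].
#' @param grid Gradient grid.
#' @param which `"heritability"` or `"correlation"`.
#' @return Invisibly, the plotted data.
#' @export
plot_gradient_parameters <- function(fit, grid = seq(-1, 1, by = 0.1),
                                     which = c("heritability", "correlation")) {
  which <- match.arg(which)
  if (which == "heritability") {
    gp <- gradient_parameters(fit, grid, se = TRUE)
    graphics::plot(gp$x, gp$h2_d, type = "l", ylim = c(0, max(gp$h2_d) * 1.3),
                   xlab = "scaled heat-load gradient", ylab = "ratio",
                   main = "Direct and maternal heritability")
    graphics::lines(gp$x, gp$h2_m, lty = 2)
    graphics::lines(gp$x, gp$pe_prop, lty = 3)
    graphics::legend("topright", c("h2 direct", "h2 maternal", "pe proportion"),
                     lty = 1:3, bty = "n")
    invisible(gp)
  } else {
    r_m <- correlation_between_envs(fit$vc$m, 1, grid)
    r_pe <- correlation_between_envs(fit$vc$pe, 1, grid)
    graphics::plot(grid, r_m, type = "l", ylim = c(0, 1),
                   xlab = "scaled heat-load gradient x",
                   ylab = "correlation with effect at x = 1",
                   main = "Maternal effect correlations")
    graphics::lines(grid, r_pe, lty = 2)
    graphics::legend("bottomleft", c("maternal genetic", "maternal pe"),
                     lty = 1:2, bty = "n")
    invisible(data.frame(x = grid, r_mg = r_m, r_mpe = r_pe))
  }
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages end to end on synthetic data: simulate (weather,
#' population, phenotypes), heat-load covariates, phenotype edits, the
#' 13-run model-1 regression battery, the model-2 reaction-norm fit, and
#' the gradient parameters, writing CSV/JSON outputs, figures and a run
#' manifest into `out_dir`. Stages already present in `out_dir` are not
#' recomputed unless `overwrite = TRUE`, so a failed run can be resumed.
#'
#' @param config A [sim_config()] (or a YAML/JSON file path containing its
#'   arguments).
#' @param out_dir Output directory (created if absent).
#' @param battery_covariates Covariates for the model-1 sweep; defaults to
#'   all 13. Use fewer for quick runs.
#' @param use_genotypes Use the single-step H matrix in model 2 (default
#'   `TRUE`); otherwise pedigree only.
#' @param control REML control, see [reml_control()].
#' @param overwrite Recompute stages whose outputs already exist.
#' @return Invisibly, a list with the main in-memory results (`data`,
#'   `battery`, `fit2`, `params`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir,
                         battery_covariates = c(paste0("s_wk", 1:12), "s_pc1"),
                         use_genotypes = TRUE,
                         control = reml_control(),
                         overwrite = FALSE) {
  if (is.character(config)) config <- do.call(sim_config, read_config(config))
  stopifnot(inherits(config, "heatnorm_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] stage %-12s %.1fs", format(Sys.time(), "%H:%M:%S"),
                    name, timings[[name]]))
    res
  }

  data <- stage("simulate", simulate_dataset(config))
  write_csv_plain(data$stations, file.path(out_dir, "stations.csv"))
  write_csv_plain(data$herds, file.path(out_dir, "herds.csv"))
  write_csv_plain(data$pedigree, file.path(out_dir, "pedigree.csv"))
  write_csv_plain(data$covariates, file.path(out_dir, "covariates.csv"))

  edited <- stage("edit", {
    ed <- edit_phenotypes(data$calves)
    list(records = assign_classes(ed$records), log = ed$log)
  })
  write_csv_plain(edited$log, file.path(out_dir, "edit_log.csv"))
  recs <- merge(edited$records, data$covariates, by = "calf_id")
  write_csv_plain(recs[, c("calf_id", "biw_kg", paste0("s_wk", 1:12),
                           "s_pc1")],
                  file.path(out_dir, "edited_records.csv"))

  battery_file <- file.path(out_dir, "model1_battery.csv")
  battery <- NULL
  if (overwrite || !file.exists(battery_file)) {
    battery <- stage("model1", run_model1_battery(recs, battery_covariates,
                                                  control = control))
    write_csv_plain(battery$report, battery_file)
  }

  fit2_file <- file.path(out_dir, "model2_fit.json")
  fit2 <- NULL
  params <- NULL
  if (overwrite || !file.exists(fit2_file)) {
    fit2 <- stage("model2", fit_model2(
      recs, config$covariate, data$pedigree,
      G = if (use_genotypes) build_G(data$genotypes) else NULL,
      genotyped_ids = data$genotyped_ids, control = control))
    jsonlite::write_json(
      list(covariate = fit2$covariate, theta = as.list(fit2$theta),
           logL = fit2$logL, n_iter = fit2$n_iter,
           converged = fit2$converged),
      fit2_file, auto_unbox = TRUE, digits = NA)
    params <- stage("params", gradient_parameters(fit2))
    write_csv_plain(params, file.path(out_dir, "gradient_parameters.csv"))
    write_csv_plain(as.data.frame(correlation_grid(fit2, which = "m")$r),
                    file.path(out_dir, "correlations_maternal_genetic.csv"))
    write_csv_plain(as.data.frame(correlation_grid(fit2, which = "pe")$r),
                    file.path(out_dir, "correlations_maternal_pe.csv"))
    grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
    plot_gradient_parameters(fit2, which = "heritability")
    plot_gradient_parameters(fit2, which = "correlation")
    grDevices::dev.off()
  }

  manifest <- list(
    tool = paste0("heatnorm ", as.character(utils::packageVersion("heatnorm"))),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = config_hash(config),
    n_records = nrow(recs),
    stage_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, edited = edited, battery = battery,
                 fit2 = fit2, params = params, manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

read_config <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
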