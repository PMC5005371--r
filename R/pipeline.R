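#' Run configuration for the end-to-end pipeline
#'
#' Accepts a list or a YAML file with (all optional except `out_dir`):
#' `seed`, `out_dir`, `response` ("cwsi" or "ig"), `scenarios` (deficit
#' fractions for the provenance contrasts), `experiment` (overrides passed
#' to [experiment_params()]), and `imaging` (`enabled`, `n_scenes`) to
#' demonstrate the image chain on a few synthetic scenes. All randomness
#' flows from the single top-level seed.
#'
#' @param config list or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  defaults <- list(seed = 1L, response = "cwsi", scenarios = c(0, 0.5, 1),
                   experiment = list(), imaging = list(enabled = FALSE,
                                                       n_scenes = 3L))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!config$response %in% c("cwsi", "ig"))
    stop("response must be 'cwsi' or 'ig'")
  if (isTRUE(config$imaging$enabled) &&
      (is.null(config$imaging$n_scenes) || config$imaging$n_scenes < 1))
    stop("imaging.n_scenes must be >= 1 when imaging is enabled")
  structure(config, class = c("run_config", "list"))
}

fit_to_list <- function(fit, deletions = NULL) {
  vc <- variance_components(fit)
  r2 <- r2_glmm(fit)
  out <- list(response = fit$spec$response,
              model_type = fit$spec$model_type,
              terms = fit$spec$terms,
              coefficients = fixef_table(fit),
              sigma0_sq = vc$sigma0_sq, sigma_eps_sq = vc$sigma_eps_sq,
              logLik = as.numeric(stats::logLik(fit$lme)),
              AIC = stats::AIC(fit$lme),
              r2_marginal = r2[["marginal"]],
              r2_conditional = r2[["conditional"]],
              variance_structure = fit$spec$variance_structure,
              centering = as.list(fit$spec$centering),
              pswd_center = fit$spec$pswd_center,
              time_scale_note = "time in days since study start / 42")
  if (!is.null(deletions)) out$deletions = deletions
  out
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages: simulate an experiment table (and optionally a few
#' thermal scenes to exercise the imaging chain), validate and write the
#' observations, fit and simplify the soil-water-deficit model (with
#' AIC-based meteorology selection, scenario contrasts and curvature
#' tests), fit the stress- and recovery-window treatment models with their
#' contrast families and effect-reduction summary, compute response
#' magnitudes with the Kruskal-Wallis/Dunn comparison, and write a summary
#' report plus a manifest (seed, config hash, artifact checksums). A rerun
#' with the same config reproduces identical artifact hashes. A failing
#' stage aborts with the stage named; artifacts written so far are moved
#' under `failed/`.
#'
#' @param config a [run_config()], list, or YAML path.
#' @return (invisibly) list with the key results and artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  fail <- function(stage, e) {
    fdir <- file.path(out_dir, "failed")
    dir.create(fdir, showWarnings = FALSE)
    for (f in written) if (file.exists(f))
      file.rename(f, file.path(fdir, basename(f)))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, code) tryCatch(code, error = function(e)
    fail(name, e))

  # -- simulate ------------------------------------------------------------
  exp <- stage("simulate", {
    params <- do.call(experiment_params,
                      c(config$experiment, list(seed = config$seed)))
    generate_experiment(params, model = "pswd", response = config$response)
  })
  obs <- exp$observations

  # -- imaging demonstration (optional) ------------------------------------
  if (isTRUE(config$imaging$enabled)) {
    stage("process-images", {
      rows <- lapply(seq_len(config$imaging$n_scenes), function(i) {
        sc <- generate_thermal_scene(scene_params(seed = config$seed * 1000L + i))
        seg <- segment_scene(sc, sc$layout,
                             segmentation_config(emissivities = list(
                               canopy = 1, wet = 1, dry = 1)))
        data.frame(scene = i,
                   canopy_median = seg$median_temps[["canopy"]],
                   canopy_truth = sc$true_temps[["canopy"]],
                   wet_median = seg$median_temps[["wet"]],
                   dry_median = seg$median_temps[["dry"]],
                   threshold = seg$threshold_used,
                   n_canopy_px = seg$n_pixels[["canopy"]])
      })
      utils::write.csv(do.call(rbind, rows),
                       emit(file.path(out_dir, "scenes.csv")),
                       row.names = FALSE)
    })
  }

  # -- compute indices / write observations --------------------------------
  stage("compute-indices", {
    if (!"vpd" %in% names(obs)) obs$vpd <- vpd(obs$air_temp, obs$rh)
    write_observations(obs, emit(file.path(out_dir, "obs.csv")))
  })

  # -- soil-water-deficit model --------------------------------------------
  resp <- if (config$response == "cwsi") "cwsi" else "sqrt_ig"
  pswd_res <- stage("fit-pswd", {
    sel <- select_meteo_covariates(obs, resp)
    simp <- simplify_model(sel$spec, obs)
    final <- fit_lmm(simp$spec, obs, "REML")
    scen <- lapply(config$scenarios, function(s)
      provenance_contrasts(final, at_pswd = s))
    names(scen) <- sprintf("pswd_%g", config$scenarios)
    curv <- if (all(c("provenance:pswd", "provenance:pswd2") %in%
                      simp$spec$terms)) test_interaction_curvature(final)
      else NULL
    write_json_artifact(c(fit_to_list(final, simp$deletions),
                          list(meteo_choice = sel$chosen,
                               meteo_aic = as.list(sel$aic))),
                        emit(file.path(out_dir, "fit_pswd.json")))
    utils::write.csv(do.call(rbind, scen),
                     emit(file.path(out_dir, "contrasts_pswd.csv")),
                     row.names = FALSE)
    if (!is.null(curv))
      utils::write.csv(curv, emit(file.path(out_dir, "curvature.csv")),
                       row.names = FALSE)
    list(fit = final, scenarios = scen, curvature = curv,
         deletions = simp$deletions)
  })

  # -- treatment models ----------------------------------------------------
  treat_res <- stage("fit-treatment", {
    fits <- lapply(c("stress", "recovery"), function(p) {
      spec <- build_treatment_model(obs, period_window(p), resp)
      simp <- simplify_model(spec, obs)
      fit <- fit_lmm(simp$spec, obs, "REML")
      write_json_artifact(fit_to_list(fit, simp$deletions),
                          emit(file.path(out_dir,
                                         sprintf("fit_%s.json", p))))
      utils::write.csv(treatment_contrasts(fit),
                       emit(file.path(out_dir,
                                      sprintf("contrasts_%s.csv", p))),
                       row.names = FALSE)
      fit
    })
    names(fits) <- c("stress", "recovery")
    red <- treatment_effect_reduction(fits$stress, fits$recovery)
    list(fits = fits, reduction = red)
  })

  # -- response magnitudes -------------------------------------------------
  mag_res <- stage("response-magnitude", {
    deltas <- response_magnitude(obs, config$response)
    utils::write.csv(deltas, emit(file.path(out_dir, "deltas.csv")),
                     row.names = FALSE)
    kd <- kruskal_dunn(split(deltas$delta, deltas$provenance))
    write_json_artifact(kd, emit(file.path(out_dir, "magnitude_tests.json")))
    list(deltas = deltas, tests = kd)
  })

  # -- report + manifest ---------------------------------------------------
  stage("report", {
    period <- ifelse(obs$day %in% period_window("stress")$days, "stress",
                     ifelse(obs$day %in% period_window("recovery")$days,
                            "recovery", "pre"))
    dist <- stats::aggregate(obs[[config$response]],
                             by = list(provenance = obs$provenance,
                                       treatment = obs$treatment,
                                       period = period),
                             FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    dist <- data.frame(dist[1:3], mean = dist$x[, "mean"], sd = dist$x[, "sd"])
    summary <- list(
      response = config$response,
      seed = config$seed,
      index_distribution = dist,
      treatment_effect_stress =
        unname(coef(treat_res$fits$stress)["treatmentcontrol"]),
      treatment_effect_recovery =
        unname(coef(treat_res$fits$recovery)["treatmentcontrol"]),
      treatment_effect_reduction_pct = treat_res$reduction$percent,
      r2_pswd = as.list(r2_glmm(pswd_res$fit)))
    write_json_artifact(summary, emit(file.path(out_dir, "summary.json")))
    cfg_path <- emit(file.path(out_dir, "config.json"))
    cfg <- unclass(config)
    cfg$out_dir <- NULL        # location must not change the manifest hash
    write_json_artifact(cfg, cfg_path)
    hashes <- as.list(tools::md5sum(sort(written)))
    names(hashes) <- basename(sort(written))
    manifest <- list(package = "conitherm",
                     version = as.character(utils::packageVersion("conitherm")),
                     seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     artifacts = hashes)
    write_json_artifact(manifest, file.path(out_dir, "manifest.json"))
  })

  invisible(list(observations = obs, pswd = pswd_res, treatment = treat_res,
                 magnitude = mag_res,
                 artifacts = c(written, file.path(out_dir, "manifest.json"))))
}
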