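PROVENANCES <- c("F3", "PL9", "ES1", "D8", "BG10", "I4")
TREATMENTS <- c("drought", "control")

#' Default experimental design
#'
#' Replicate counts per provenance and treatment for the 48-seedling,
#' six-provenance, two-treatment greenhouse layout: 27 control and 21
#' drought individuals, unbalanced across provenances.
#'
#' @return data.frame with columns `provenance`, `treatment`, `n`.
#' @export
default_design <- function() {
  data.frame(
    provenance = rep(PROVENANCES, 2),
    treatment = rep(c("control", "drought"), each = 6),
    n = c(4L, 3L, 5L, 5L, 5L, 5L,    # control
          4L, 5L, 3L, 3L, 3L, 3L))   # drought
}

#' Default percent-soil-water-deficit schedule
#'
#' Per-treatment target PSWD (deficit-positive fraction) for each measuring
#' day. Both treatments start saturated (PSWD 0) and are identical before
#' the divergence day; from there the drought targets ramp to a plateau
#' near 0.88 (soil around the permanent wilting point) while the control
#' plateaus near 0.30 (mild deficit even under regular watering). In the
#' recovery window (measuring days 14 onward for the default 17-day
#' schedule) all pots are re-saturated, but a residual deficit difference
#' persists.
#'
#' @param n_days number of measuring days; default 17.
#' @param divergence_day first measuring day on which the treatment targets
#'   differ; default 4 (one week into the treatment).
#' @return data.frame with columns `day`, `control`, `drought` and
#'   attribute `divergence_day`.
#' @export
default_pswd_schedule <- function(n_days = 17L, divergence_day = 4L) {
  stopifnot(n_days >= 2L, divergence_day >= 2L, divergence_day <= n_days)
  recovery_start <- if (n_days >= 14L) 14L else n_days + 1L
  ctrl <- numeric(n_days)
  for (j in seq_len(n_days)) {
    ctrl[j] <- if (j >= recovery_start) 0.15
      else if (j == 1L) 0 else min(0.30, 0.30 * (j - 1) / 3)
  }
  drt <- ctrl
  ramp_days <- 3L
  for (j in seq_len(n_days)) {
    if (j < divergence_day) next
    drt[j] <- if (j >= recovery_start) 0.45
      else min(0.88, ctrl[divergence_day - 1L] +
                 (0.88 - ctrl[divergence_day - 1L]) *
                 (j - divergence_day + 1L) / ramp_days)
  }
  structure(data.frame(day = seq_len(n_days), control = ctrl, drought = drt),
            divergence_day = as.integer(divergence_day))
}

#' Per-tree soil-water-deficit trajectories
#'
#' Each tree follows its treatment's target schedule plus a tree-level
#' offset drawn once per tree from N(0, `jitter_sd`), emulating unequal
#' water depletion between individuals. Control and drought series are
#' identical in distribution before the schedule's divergence day.
#'
#' @param schedule data.frame with columns `day`, `control`, `drought` (see
#'   [default_pswd_schedule()]).
#' @param n_trees named integer vector `c(control = ..., drought = ...)`.
#' @param jitter_sd standard deviation of the per-tree offset; >= 0.
#' @param seed integer RNG seed.
#' @return data.frame with columns `tree_id`, `treatment`, `day`, `pswd`.
#' @export
generate_pswd_trajectories <- function(schedule, n_trees, jitter_sd = 0.03,
                                       seed = 1L) {
  stopifnot(all(c("day", "control", "drought") %in% names(schedule)))
  stopifnot(all(c("control", "drought") %in% names(n_trees)))
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  with_seed(seed, {
    out <- lapply(c("control", "drought"), function(tr) {
      n <- n_trees[[tr]]
      offs <- stats::rnorm(n, 0, jitter_sd)
      do.call(rbind, lapply(seq_len(n), function(i)
        data.frame(tree_id = sprintf("%s_%02d", tr, i), treatment = tr,
                   day = schedule$day, pswd = schedule[[tr]] + offs[i])))
    })
    do.call(rbind, out)
  })
}

# ---- coefficient vocabulary ----------------------------------------------

coef_names_for <- function(model) {
  switch(model,
    pswd = c("intercept", "provenance", "pswd", "pswd2", "height", "diameter",
             "vpd", "radiation", "airT", "rh", "provenance_pswd",
             "provenance_pswd2", "vpd_pswd", "airT_pswd", "rh_pswd"),
    treatment = c("intercept", "provenance", "treatment", "time", "time2",
                  "height", "diameter", "airT", "rh", "radiation",
                  "provenance_treatment", "treatment_time", "treatment_time2",
                  "treatment_height", "treatment_diameter", "treatment_airT",
                  "treatment_rh"),
    stop("unknown model: ", model))
}

#' Default generating coefficients
#'
#' Named coefficient sets for the soil-water-deficit response model
#' (`model = "pswd"`) and the treatment/recovery model
#' (`model = "treatment"`), on the fitting scale of the chosen index (raw
#' CWSI; square-root scale for Ig). The soil-water-deficit and
#' meteorological coefficients use the magnitudes characteristic of potted
#' conifer seedlings under greenhouse drought (e.g. CWSI: PSWD -2.49,
#' PSWD^2 1.61, VPD 0.044, radiation 0.00032; treatment model: treatment
#' -0.23 during stress). Provenance entries are named vectors over the
#' non-reference provenance levels (reference: first level alphabetically).
#'
#' @param model `"pswd"` or `"treatment"`.
#' @param response `"cwsi"` or `"ig"`.
#' @return named list of coefficients.
#' @export
default_coefficients <- function(model = c("pswd", "treatment"),
                                 response = c("cwsi", "ig")) {
  model <- match.arg(model); response <- match.arg(response)
  lv <- sort(PROVENANCES)                      # BG10 D8 ES1 F3 I4 PL9
  nonref <- lv[-1]
  pv <- function(x) stats::setNames(x, nonref)
  if (model == "pswd") {
    if (response == "cwsi")
      list(intercept = 0.9, pswd = -2.49, pswd2 = 1.61,
           vpd = 0.044, radiation = 0.00032,
           provenance = pv(c(0.05, -0.06, 0.02, 0.04, 0.03)),
           provenance_pswd = pv(c(0.15, -0.30, 0.10, 0.20, 0.12)),
           provenance_pswd2 = pv(c(-0.10, 0.25, -0.06, -0.12, -0.08)))
    else
      list(intercept = 1.6, pswd = 4.39, pswd2 = -2.91,
           vpd = -0.081, radiation = -0.00061,
           provenance = pv(c(-0.08, 0.10, -0.04, -0.06, -0.05)),
           provenance_pswd = pv(c(-0.25, 0.50, -0.15, -0.30, -0.20)),
           provenance_pswd2 = pv(c(0.18, -0.40, 0.10, 0.20, 0.14)))
  } else {
    if (response == "cwsi")
      list(intercept = 0.45, treatment = -0.23, time = 0.42, time2 = -0.42,
           height = -0.000034, treatment_height = 0.00074, diameter = -0.03,
           airT = 0.0086, treatment_airT = -0.012,
           rh = -0.0007, treatment_rh = -0.01, radiation = 0.00025,
           provenance = pv(c(0.03, -0.05, -0.02, 0.08, 0.04)),
           provenance_treatment = pv(c(-0.02, 0.04, 0.01, 0.10, -0.03)))
    else
      list(intercept = 1.1, treatment = 0.43, time = -0.54, time2 = 0.68,
           height = 0.00014, treatment_height = -0.0013, diameter = 0.056,
           airT = -0.013, treatment_airT = 0.02,
           rh = 0.0002, treatment_rh = 0.02,
           provenance = pv(c(-0.05, 0.08, 0.03, -0.12, -0.06)),
           provenance_treatment = pv(c(0.03, -0.06, -0.02, -0.15, 0.05)))
  }
}

#' Parameters of a synthetic greenhouse drought experiment
#'
#' Bundles the design (replicates per provenance and treatment), the
#' measuring-day calendar, generating coefficients, variance components,
#' meteorological sampling ranges, the soil-water-deficit schedule and
#' seedling-dimension distributions.
#'
#' @param design data.frame with columns `provenance`, `treatment`, `n`;
#'   default [default_design()].
#' @param n_days number of measuring days; default 17 (roughly twice weekly
#'   over a nine-week study).
#' @param coefficients named list of generating coefficients, or `NULL` to
#'   use [default_coefficients()] for the chosen model and response.
#'   Unnamed terms default to 0.
#' @param random_intercept_sd,residual_sd standard deviations of the
#'   per-tree random intercept (>= 0) and the residual (> 0), on the
#'   fitting scale of the response.
#' @param meteo_ranges list of `c(min, max)` for `air_temp` (degrees C),
#'   `rh` (percent, within (0, 100]) and `radiation` (W/m^2); defaults are
#'   the measuring-day envelope of a shaded summer greenhouse
#'   (20.4--37.1 degrees C, 29--66%, 24--234 W/m^2).
#' @param pswd_schedule per-treatment target trajectory; default
#'   [default_pswd_schedule()].
#' @param pswd_jitter_sd per-tree deficit offset SD; default 0.03.
#' @param height_mean,height_sd,diameter_mean,diameter_sd seedling
#'   dimension distributions (mm).
#' @param seed integer RNG seed.
#' @return object of class `experiment_params`.
#' @export
experiment_params <- function(design = default_design(), n_days = 17L,
                              coefficients = NULL,
                              random_intercept_sd = 0.1, residual_sd = 0.15,
                              meteo_ranges = list(air_temp = c(20.4, 37.1),
                                                  rh = c(29, 66),
                                                  radiation = c(24, 234)),
                              pswd_schedule = default_pswd_schedule(n_days),
                              pswd_jitter_sd = 0.03,
                              height_mean = 370, height_sd = 70,
                              diameter_mean = 8.2, diameter_sd = 1.2,
                              seed = 1L) {
  stopifnot(all(c("provenance", "treatment", "n") %in% names(design)))
  if (random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  stopifnot(all(c("air_temp", "rh", "radiation") %in% names(meteo_ranges)))
  if (meteo_ranges$rh[1] <= 0 || meteo_ranges$rh[2] > 100)
    stop("rh range must lie within (0, 100]")
  if (meteo_ranges$air_temp[1] <= -40) stop("air_temp range below -40 C")
  dd <- attr(pswd_schedule, "divergence_day")
  if (!is.null(dd) && dd > 1L) {
    pre <- seq_len(dd - 1L)
    if (any(pswd_schedule$control[pre] != pswd_schedule$drought[pre]))
      stop("pswd_schedule: treatments must be identical before the divergence day")
  }
  structure(list(design = design, n_days = as.integer(n_days),
                 coefficients = coefficients,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, meteo_ranges = meteo_ranges,
                 pswd_schedule = pswd_schedule,
                 pswd_jitter_sd = pswd_jitter_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 seed = as.integer(seed)),
            class = "experiment_params")
}

canonical_coefficients <- function(coefficients, model) {
  valid <- coef_names_for(model)
  if (is.null(coefficients)) coefficients <- list()
  bad <- setdiff(names(coefficients), valid)
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "),
         "; valid names for the ", model, " model are: ",
         paste(valid, collapse = ", "))
  lv <- sort(PROVENANCES); nonref <- lv[-1]
  out <- list()
  for (nm in valid) {
    v <- coefficients[[nm]]
    if (startsWith(nm, "provenance")) {
      full <- stats::setNames(numeric(length(nonref)), nonref)
      if (!is.null(v)) {
        if (is.null(names(v)) && length(v) == length(nonref)) names(v) <- nonref
        badlv <- setdiff(names(v), nonref)
        if (length(badlv))
          stop(nm, ": unknown provenance level(s) ",
               paste(badlv, collapse = ", "),
               " (reference level ", lv[1], " carries no coefficient)")
        full[names(v)] <- v
      }
      out[[nm]] <- full
    } else {
      out[[nm]] <- if (is.null(v)) 0 else as.numeric(v)
    }
  }
  out
}

#' Generate a synthetic experiment table with known truth
#'
#' Simulates per-tree, per-measuring-day observations: design factors,
#' seedling dimensions, meteorology sampled within the stated ranges (a
#' uniformly drawn daily mean plus a small within-day deviation, since
#' trees are measured sequentially in a random order that is recorded),
#' soil-water-deficit trajectories, and a thermal-index response built as
#' fixed part + per-tree random intercept + Gaussian residual from the
#' chosen model equation. For `response = "cwsi"` the linear predictor is
#' the CWSI itself; for `response = "ig"` it is sqrt(Ig) (the fitting
#' scale), and the table's `ig` column is its square. Reference and canopy
#' temperatures consistent with each index value are back-computed so the
#' index algebra holds row by row. Covariates are NOT centered here; the
#' modelling stage centers.
#'
#' @param params an [experiment_params()].
#' @param model `"pswd"` (index vs. soil water deficit) or `"treatment"`
#'   (index vs. irrigation treatment over time).
#' @param response `"cwsi"` or `"ig"`.
#' @return object of class `ct_experiment`: `observations` (data.frame),
#'   `truth` (canonical coefficients, variance components, per-tree random
#'   intercepts), and `params`.
#' @export
generate_experiment <- function(params, model = c("pswd", "treatment"),
                                response = c("cwsi", "ig")) {
  stopifnot(inherits(params, "experiment_params"))
  model <- match.arg(model); response <- match.arg(response)
  cf <- canonical_coefficients(params$coefficients %||%
                                 default_coefficients(model, response), model)
  lv <- sort(unique(params$design$provenance))
  sched <- params$pswd_schedule
  n_days <- params$n_days
  if (nrow(sched) < n_days) stop("pswd_schedule shorter than n_days")

  with_seed(params$seed, {
    # trees
    des <- params$design[params$design$n > 0, ]
    trees <- do.call(rbind, lapply(seq_len(nrow(des)), function(k)
      data.frame(provenance = des$provenance[k], treatment = des$treatment[k],
                 idx = seq_len(des$n[k]))))
    trees$tree_id <- sprintf("%s_%s_%d", trees$provenance, trees$treatment,
                             trees$idx)
    n_tree <- nrow(trees)
    trees$height <- stats::rnorm(n_tree, params$height_mean, params$height_sd)
    trees$diameter <- stats::rnorm(n_tree, params$diameter_mean,
                                   params$diameter_sd)
    trees$b0 <- stats::rnorm(n_tree, 0, params$random_intercept_sd)
    trees$pswd_off <- stats::rnorm(n_tree, 0, params$pswd_jitter_sd)

    days_since_start <- round(seq(0, 61, length.out = n_days))
    mr <- params$meteo_ranges
    rows <- vector("list", n_days)
    for (j in seq_len(n_days)) {
      day_mean <- vapply(mr, function(r) stats::runif(1, r[1], r[2]),
                         numeric(1))
      ord <- sample.int(n_tree)
      d <- trees
      d$day <- j
      d$days_since_start <- days_since_start[j]
      d$time <- days_since_start[j] / 42
      d$measure_order <- order(ord)
      for (v in names(mr)) {
        width <- diff(mr[[v]])
        x <- day_mean[[v]] + stats::runif(n_tree, -0.05, 0.05) * width
        d[[if (v == "air_temp") "air_temp" else v]] <-
          pmin(mr[[v]][2], pmax(mr[[v]][1], x))
      }
      d$pswd <- ifelse(d$treatment == "control", sched$control[j],
                       sched$drought[j]) + d$pswd_off
      d$t_wet <- stats::runif(1, 20, 24) + stats::rnorm(n_tree, 0, 0.1)
      d$t_dry <- d$t_wet + stats::runif(1, 12, 18)
      rows[[j]] <- d
    }
    obs <- do.call(rbind, rows)
    obs$vpd <- vpd(obs$air_temp, obs$rh)
    tr01 <- as.numeric(obs$treatment == "control")   # 0 drought, 1 control
    pvec <- function(nm) {
      v <- cf[[nm]]
      ifelse(obs$provenance == lv[1], 0, v[obs$provenance])
    }
    lp <- cf$intercept + pvec("provenance")
    if (model == "pswd") {
      lp <- lp + cf$pswd * obs$pswd + cf$pswd2 * obs$pswd^2 +
        cf$height * obs$height + cf$diameter * obs$diameter +
        cf$vpd * obs$vpd + cf$radiation * obs$radiation +
        cf$airT * obs$air_temp + cf$rh * obs$rh +
        pvec("provenance_pswd") * obs$pswd +
        pvec("provenance_pswd2") * obs$pswd^2 +
        cf$vpd_pswd * obs$vpd * obs$pswd +
        cf$airT_pswd * obs$air_temp * obs$pswd +
        cf$rh_pswd * obs$rh * obs$pswd
    } else {
      lp <- lp + cf$treatment * tr01 + cf$time * obs$time +
        cf$time2 * obs$time^2 + cf$height * obs$height +
        cf$diameter * obs$diameter + cf$airT * obs$air_temp +
        cf$rh * obs$rh + cf$radiation * obs$radiation +
        pvec("provenance_treatment") * tr01 +
        cf$treatment_time * tr01 * obs$time +
        cf$treatment_time2 * tr01 * obs$time^2 +
        cf$treatment_height * tr01 * obs$height +
        cf$treatment_diameter * tr01 * obs$diameter +
        cf$treatment_airT * tr01 * obs$air_temp +
        cf$treatment_rh * tr01 * obs$rh
    }
    y <- lp + obs$b0 + stats::rnorm(nrow(obs), 0, params$residual_sd)
    if (response == "cwsi") {
      obs$cwsi <- y
      obs$t_canopy <- obs$t_wet + y * (obs$t_dry - obs$t_wet)
    } else {
      obs$ig <- y^2
      obs$t_canopy <- (obs$t_dry + obs$ig * obs$t_wet) / (1 + obs$ig)
    }
    obs$b0 <- NULL; obs$pswd_off <- NULL; obs$idx <- NULL
    rownames(obs) <- NULL
    structure(list(observations = obs,
                   truth = list(model = model, response = response,
                                coefficients = cf,
                                random_intercept_sd = params$random_intercept_sd,
                                residual_sd = params$residual_sd,
                                random_intercepts = stats::setNames(trees$b0,
                                                                    trees$tree_id),
                                seed = params$seed),
                   params = params),
              class = "ct_experiment")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
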