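# Term vocabulary shared by the two model families. Terms are named by what
# they are in the science (airT = air temperature), and mapped to formula
# syntax on mean-centered columns at fit time.
TERM_FORMULA <- c(
  "provenance" = "provenance",
  "treatment" = "treatment",
  "pswd" = "pswd_s",
  "pswd2" = "I(pswd_s^2)",
  "height" = "height_c",
  "diameter" = "diameter_c",
  "airT" = "airT_c",
  "rh" = "rh_c",
  "vpd" = "vpd_c",
  "radiation" = "radiation_c",
  "time" = "time",
  "time2" = "I(time^2)",
  "provenance:pswd" = "provenance:pswd_s",
  "provenance:pswd2" = "provenance:I(pswd_s^2)",
  "vpd:pswd" = "vpd_c:pswd_s",
  "airT:pswd" = "airT_c:pswd_s",
  "rh:pswd" = "rh_c:pswd_s",
  "provenance:treatment" = "provenance:treatment",
  "treatment:time" = "treatment:time",
  "treatment:time2" = "treatment:I(time^2)",
  "treatment:height" = "treatment:height_c",
  "treatment:diameter" = "treatment:diameter_c",
  "treatment:airT" = "treatment:airT_c",
  "treatment:rh" = "treatment:rh_c")

# marginality: which terms a term requires to stay in the model
TERM_REQUIRES <- list(
  "pswd2" = "pswd",
  "time2" = "time",
  "provenance:pswd" = c("provenance", "pswd"),
  "provenance:pswd2" = c("provenance:pswd", "pswd2"),
  "vpd:pswd" = c("vpd", "pswd"),
  "airT:pswd" = c("airT", "pswd"),
  "rh:pswd" = c("rh", "pswd"),
  "provenance:treatment" = c("provenance", "treatment"),
  "treatment:time" = c("treatment", "time"),
  "treatment:time2" = c("treatment:time", "time2"),
  "treatment:height" = c("treatment", "height"),
  "treatment:diameter" = c("treatment", "diameter"),
  "treatment:airT" = c("treatment", "airT"),
  "treatment:rh" = c("treatment", "rh"))

# observation columns each term reads
TERM_COLUMNS <- list(
  provenance = "provenance", treatment = "treatment",
  pswd = "pswd", pswd2 = "pswd", height = "height", diameter = "diameter",
  airT = "air_temp", rh = "rh", vpd = "vpd", radiation = "radiation",
  time = "time", time2 = "time")

CENTERED_COVARIATES <- c(height = "height", diameter = "diameter",
                         airT = "air_temp", rh = "rh", vpd = "vpd",
                         radiation = "radiation")

new_model_spec <- function(model_type, response, terms, centering,
                           pswd_center = 0,
                           variance_structure = "homoscedastic",
                           window = NULL) {
  stopifnot(response %in% c("cwsi", "sqrt_ig"),
            variance_structure %in% c("homoscedastic", "per_treatment",
                                      "power_of_fitted"))
  unknown <- setdiff(terms, names(TERM_FORMULA))
  if (length(unknown))
    stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  structure(list(model_type = model_type, response = response, terms = terms,
                 centering = centering, pswd_center = pswd_center,
                 variance_structure = variance_structure, window = window),
            class = "ct_model_spec")
}

#' @export
print.ct_model_spec <- function(x, ...) {
  cat(sprintf("ct_model_spec (%s model, response %s)\n", x$model_type,
              x$response))
  cat("  fixed terms:", paste(x$terms, collapse = " + "), "\n")
  cat("  random: ~1 | tree_id\n")
  if (x$model_type == "pswd")
    cat(sprintf("  PSWD centered at %.2f\n", x$pswd_center))
  if (!is.null(x$window))
    cat("  window: days", paste(range(x$window), collapse = "-"), "\n")
  cat("  variance structure:", x$variance_structure, "\n")
  invisible(x)
}

check_columns <- function(obs, cols) {
  miss <- setdiff(cols, names(obs))
  if (length(miss))
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
}

response_column <- function(response) {
  if (response == "cwsi") "cwsi" else "ig"
}

#' Build the full soil-water-deficit model specification
#'
#' The full random-intercept model of a thermal index against percent soil
#' water deficit: provenance dummies, PSWD as linear plus quadratic terms
#' (uncentered, so scenario contrasts can re-center it), seedling height
#' and diameter, a meteorological set — either vapor pressure deficit or
#' air temperature plus relative humidity (the two are strongly correlated,
#' so exactly one set enters; see [select_meteo_covariates()]) — solar
#' radiation, the provenance interactions with both PSWD terms, and the
#' meteorology-by-PSWD interaction. All covariates besides PSWD are
#' centered on their means, which are stored in the spec so a refit is
#' exact. No time variable enters (time and PSWD are collinear). The random
#' structure is a per-tree intercept, which requires at least two trees.
#'
#' @param obs observation table (see [generate_experiment()] or
#'   [read_observations()]).
#' @param response `"cwsi"` or `"sqrt_ig"` (Ig is fit on the square-root
#'   scale).
#' @param meteo `"vpd"` (default) or `"airT_rh"`.
#' @param variance_structure `"homoscedastic"` (default),
#'   `"per_treatment"` (separate residual variances by treatment), or
#'   `"power_of_fitted"` (residual SD a power of the fitted value).
#' @return a `ct_model_spec`.
#' @export
build_pswd_model <- function(obs, response = c("cwsi", "sqrt_ig"),
                             meteo = c("vpd", "airT_rh"),
                             variance_structure = "homoscedastic") {
  response <- match.arg(response); meteo <- match.arg(meteo)
  meteo_terms <- if (meteo == "vpd") c("vpd", "vpd:pswd")
    else c("airT", "rh", "airT:pswd", "rh:pswd")
  terms <- c("provenance", "pswd", "pswd2", "height", "diameter",
             meteo_terms[!grepl(":", meteo_terms)], "radiation",
             "provenance:pswd", "provenance:pswd2",
             meteo_terms[grepl(":", meteo_terms)])
  main_terms <- terms[!grepl(":", terms)]
  cols <- unique(c("tree_id", response_column(response),
                   unlist(TERM_COLUMNS[main_terms], use.names = FALSE)))
  check_columns(obs, cols)
  if (length(unique(obs$provenance)) < 2L)
    stop("need at least two provenances")
  if (length(unique(obs$tree_id)) < 2L)
    stop("single tree: the random intercept is unidentifiable")
  centering <- centering_means(obs, terms)
  new_model_spec("pswd", response, terms, centering,
                 variance_structure = variance_structure)
}

centering_means <- function(obs, terms) {
  base <- sub(":.*", "", terms)
  used <- union(base, sub(".*:", "", terms))
  used <- intersect(used, names(CENTERED_COVARIATES))
  vapply(CENTERED_COVARIATES[used], function(col) mean(obs[[col]]),
         numeric(1))
}

#' Measuring-day windows for the treatment analysis
#'
#' The stress window spans measuring days 4--13 (soil-water deficits
#' clearly separated between treatments) and the recovery window days
#' 14--17 (after re-saturation of all pots). Windows are disjoint.
#'
#' @param name `"stress"` or `"recovery"`, or supply `days` directly.
#' @param days optional integer vector of measuring days within 1--17.
#' @return object of class `period_window`.
#' @export
period_window <- function(name = c("stress", "recovery"), days = NULL) {
  name <- match.arg(name)
  if (is.null(days)) days <- if (name == "stress") 4:13 else 14:17
  days <- as.integer(days)
  if (length(days) == 0 || any(days < 1L | days > 17L))
    stop("window days must lie within 1-17")
  structure(list(name = name, days = days), class = "period_window")
}

#' Build the full treatment/recovery model specification
#'
#' The full random-intercept model of a thermal index against the water
#' supply treatment within one period window: a treatment dummy (0 =
#' drought, 1 = control), time since the study start as linear plus
#' quadratic terms (scaled to days/42, the length of the treatment window),
#' provenance dummies, seedling height and diameter, air temperature,
#' relative humidity and radiation, and the treatment interactions with
#' provenance, both time terms, height, diameter, air temperature and
#' relative humidity. Continuous covariates other than time are centered on
#' their within-window means.
#'
#' @param obs observation table.
#' @param window a [period_window()].
#' @inheritParams build_pswd_model
#' @return a `ct_model_spec` carrying the window.
#' @export
build_treatment_model <- function(obs, window = period_window("stress"),
                                  response = c("cwsi", "sqrt_ig"),
                                  variance_structure = "homoscedastic") {
  response <- match.arg(response)
  stopifnot(inherits(window, "period_window"))
  check_columns(obs, c("tree_id", "day", "treatment", "provenance",
                       response_column(response), "time", "height",
                       "diameter", "air_temp", "rh", "radiation"))
  sub <- obs[obs$day %in% window$days, , drop = FALSE]
  if (nrow(sub) == 0L) stop("window contains no observations")
  if (length(unique(sub$treatment)) < 2L)
    stop("window contains a single treatment; treatment effect unidentifiable")
  terms <- c("provenance", "treatment", "time", "time2", "height", "diameter",
             "airT", "rh", "radiation", "provenance:treatment",
             "treatment:time", "treatment:time2", "treatment:height",
             "treatment:diameter", "treatment:airT", "treatment:rh")
  if (length(unique(sub$provenance)) < 2L)
    terms <- setdiff(terms, c("provenance", "provenance:treatment"))
  centering <- centering_means(sub, terms)
  new_model_spec("treatment", response, terms, centering,
                 variance_structure = variance_structure,
                 window = window$days)
}

# Build the analysis frame: factors, centered columns, response transform.
prepare_model_frame <- function(spec, obs) {
  if (!is.null(spec$window)) obs <- obs[obs$day %in% spec$window, , drop = FALSE]
  d <- obs
  d$provenance <- factor(d$provenance)
  if ("treatment" %in% names(d))
    d$treatment <- factor(d$treatment, levels = c("drought", "control"))
  if (spec$response == "sqrt_ig") {
    if (!"ig" %in% names(d)) stop("observation table is missing column(s): ig")
    neg <- which(d$ig < 0)
    if (length(neg))
      stop("Ig must be nonnegative for the square-root transform; offending row(s): ",
           paste(utils::head(neg, 10), collapse = ", "))
    d$sqrt_ig <- sqrt(d$ig)
  }
  for (nm in names(spec$centering))
    d[[paste0(nm, "_c")]] <- d[[CENTERED_COVARIATES[[nm]]]] -
      spec$centering[[nm]]
  if ("pswd" %in% names(d)) d$pswd_s <- d$pswd - spec$pswd_center
  d
}

spec_formula <- function(spec) {
  lhs <- if (spec$response == "sqrt_ig") "sqrt_ig" else "cwsi"
  stats::as.formula(paste(lhs, "~", paste(TERM_FORMULA[spec$terms],
                                          collapse = " + ")))
}
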