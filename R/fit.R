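#' Fit a random-intercept mixed model from a specification
#'
#' Fits the specified fixed structure with a per-tree random intercept by
#' `nlme::lme`. Use maximum likelihood (`method = "ML"`) for AIC-based
#' comparisons and term deletion, and REML for the reported final fit. The
#' three supported variance structures are homoscedastic residuals,
#' separate residual variances per treatment (`nlme::varIdent`), and a
#' power-of-fitted-values variance function (`nlme::varPower`).
#'
#' @param spec a `ct_model_spec` from [build_pswd_model()] or
#'   [build_treatment_model()].
#' @param obs observation table; if the spec carries a period window the
#'   table is subset to it.
#' @param method `"REML"` (default) or `"ML"`.
#' @return object of class `ct_model_fit` wrapping the `lme` fit together
#'   with the spec and the (unsubset) observations, so scenario refits can
#'   re-center and refit exactly.
#' @export
fit_lmm <- function(spec, obs, method = c("REML", "ML")) {
  stopifnot(inherits(spec, "ct_model_spec"))
  method <- match.arg(method)
  frame <- prepare_model_frame(spec, obs)
  w <- switch(spec$variance_structure,
              homoscedastic = NULL,
              per_treatment = nlme::varIdent(form = ~ 1 | treatment),
              power_of_fitted = nlme::varPower(form = ~ fitted(.)))
  args <- list(fixed = spec_formula(spec), data = frame,
               random = ~ 1 | tree_id, method = method,
               na.action = stats::na.fail,
               control = nlme::lmeControl(maxIter = 100L, msMaxIter = 200L,
                                          returnObject = FALSE))
  if (!is.null(w)) args$weights <- w
  # nlminb resolves boundary (zero-variance) cases sharply; fall back to
  # optim on the rare fits where it fails to converge
  lme_fit <- tryCatch(do.call(nlme::lme, args), error = function(e1) {
    args$control$opt <- "optim"
    tryCatch(do.call(nlme::lme, args), error = function(e2)
      stop("mixed-model fit failed: ", conditionMessage(e2), call. = FALSE))
  })
  structure(list(spec = spec, method = method, lme = lme_fit, frame = frame,
                 obs = obs),
            class = "ct_model_fit")
}

#' @export
coef.ct_model_fit <- function(object, ...) nlme::fixef(object$lme)

#' @export
vcov.ct_model_fit <- function(object, ...) vcov(object$lme)

#' @export
logLik.ct_model_fit <- function(object, ...) stats::logLik(object$lme)

#' @export
AIC.ct_model_fit <- function(object, ..., k = 2) stats::AIC(object$lme)

#' Variance components of a fitted model
#'
#' @param fit a `ct_model_fit`.
#' @return list with `sigma0_sq` (random-intercept variance) and
#'   `sigma_eps_sq` (residual variance; under a variance-function structure
#'   the average of the per-observation residual variances).
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "ct_model_fit"))
  vc <- nlme::VarCorr(fit$lme)
  sigma0_sq <- as.numeric(vc["(Intercept)", "Variance"])
  sigma <- fit$lme$sigma
  vs <- fit$lme$modelStruct$varStruct
  sigma_eps_sq <- if (is.null(vs)) sigma^2
    else mean((sigma / nlme::varWeights(vs))^2)
  list(sigma0_sq = sigma0_sq, sigma_eps_sq = sigma_eps_sq)
}

#' Fixed-effect coefficient table
#'
#' @param fit a `ct_model_fit`.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p` (normal
#'   reference).
#' @export
fixef_table <- function(fit) {
  b <- nlme::fixef(fit$lme)
  se <- sqrt(diag(vcov(fit$lme)))
  z <- b / se
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
             row.names = NULL)
}

#' @export
print.ct_model_fit <- function(x, ...) {
  cat(sprintf("ct_model_fit (%s model, response %s, %s)\n",
              x$spec$model_type, x$spec$response, x$method))
  vc <- variance_components(x)
  r2 <- r2_glmm(x)
  cat(sprintf("  AIC %.2f | sigma0^2 %.4g | sigma_eps^2 %.4g | R2m %.3f R2c %.3f\n",
              stats::AIC(x$lme), vc$sigma0_sq, vc$sigma_eps_sq,
              r2[["marginal"]], r2[["conditional"]]))
  print(utils::head(fixef_table(x), 20))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Nakagawa--Schielzeth decomposition for a Gaussian identity-link mixed
#' model: the marginal R-squared is the variance of the fixed-effect
#' predictor over the total (fixed + random-intercept + residual) variance;
#' the conditional R-squared adds the random-intercept variance to the
#' numerator.
#'
#' @param fit a `ct_model_fit`.
#' @return named numeric vector `c(marginal = ..., conditional = ...)`.
#' @export
r2_glmm <- function(fit) {
  stopifnot(inherits(fit, "ct_model_fit"))
  var_f <- stats::var(stats::fitted(fit$lme, level = 0))
  vc <- variance_components(fit)
  tot <- var_f + vc$sigma0_sq + vc$sigma_eps_sq
  c(marginal = var_f / tot, conditional = (var_f + vc$sigma0_sq) / tot)
}

#' Choose the meteorological covariate set by AIC
#'
#' Air temperature plus relative humidity on the one hand and vapor
#' pressure deficit on the other are strongly correlated, so only one set
#' enters the soil-water-deficit model. Both full-model variants are fitted
#' under maximum likelihood and the lower-AIC one is returned; an exact tie
#' goes to the VPD variant (fewer parameters).
#'
#' @inheritParams build_pswd_model
#' @return list with the chosen `spec`, the `aic` of both variants, and
#'   `chosen` (`"vpd"` or `"airT_rh"`).
#' @export
select_meteo_covariates <- function(obs, response = c("cwsi", "sqrt_ig"),
                                    variance_structure = "homoscedastic") {
  response <- match.arg(response)
  spec_v <- build_pswd_model(obs, response, meteo = "vpd",
                             variance_structure = variance_structure)
  spec_t <- build_pswd_model(obs, response, meteo = "airT_rh",
                             variance_structure = variance_structure)
  aic <- c(vpd = stats::AIC(fit_lmm(spec_v, obs, "ML")$lme),
           airT_rh = stats::AIC(fit_lmm(spec_t, obs, "ML")$lme))
  chosen <- if (aic[["vpd"]] <= aic[["airT_rh"]]) "vpd" else "airT_rh"
  list(spec = if (chosen == "vpd") spec_v else spec_t, aic = aic,
       chosen = chosen)
}

droppable_terms <- function(terms) {
  needed <- unique(unlist(TERM_REQUIRES[intersect(terms, names(TERM_REQUIRES))]))
  setdiff(terms, needed)
}

#' Backward AIC simplification of a model specification
#'
#' Single-term backward deletion under maximum likelihood: at each step
#' every term whose removal respects marginality (no retained interaction
#' or higher-order term depends on it) is tentatively dropped, and the
#' deletion that most lowers the AIC is accepted; iteration stops when no
#' deletion lowers the AIC. Terms that add no explanatory power are thereby
#' excluded.
#'
#' @param spec a `ct_model_spec` (the full model).
#' @param obs observation table.
#' @return list with the simplified `spec` and `deletions`, a data.frame
#'   logging each dropped term and the AIC before/after.
#' @export
simplify_model <- function(spec, obs) {
  stopifnot(inherits(spec, "ct_model_spec"))
  cur <- spec
  cur_aic <- stats::AIC(fit_lmm(cur, obs, "ML")$lme)
  log <- data.frame(step = integer(), dropped = character(),
                    aic_before = numeric(), aic_after = numeric())
  step <- 0L
  repeat {
    cands <- droppable_terms(cur$terms)
    if (length(cands) == 0L) break
    aics <- vapply(cands, function(tm) {
      red <- cur; red$terms <- setdiff(cur$terms, tm)
      tryCatch(stats::AIC(fit_lmm(red, obs, "ML")$lme),
               error = function(e) Inf)
    }, numeric(1))
    if (min(aics) >= cur_aic) break
    drop <- cands[which.min(aics)]
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, dropped = drop,
                                 aic_before = cur_aic,
                                 aic_after = min(aics)))
    cur$terms <- setdiff(cur$terms, drop)
    cur_aic <- min(aics)
  }
  list(spec = cur, deletions = log)
}
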