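sim_pswd <- function(seed, coefficients = NULL, sigma0 = 0.1, sigma = 0.15,
                     design = default_design()) {
  p <- experiment_params(design = design, coefficients = coefficients,
                         random_intercept_sd = sigma0, residual_sd = sigma,
                         seed = seed)
  generate_experiment(p, "pswd", "cwsi")$observations
}

test_that("the full deficit model carries the expected term structure", {
  obs <- sim_pswd(1)
  spec <- build_pswd_model(obs, "cwsi")
  expect_setequal(spec$terms,
                  c("provenance", "pswd", "pswd2", "height", "diameter",
                    "vpd", "radiation", "provenance:pswd", "provenance:pswd2",
                    "vpd:pswd"))
  spec_t <- build_pswd_model(obs, "cwsi", meteo = "airT_rh")
  expect_true(all(c("airT", "rh", "airT:pswd", "rh:pswd") %in% spec_t$terms))
  expect_false("vpd" %in% spec_t$terms)
  # centering map records the means actually used
  expect_equal(spec$centering[["vpd"]], mean(obs$vpd))
  expect_equal(spec$centering[["height"]], mean(obs$height))
  expect_false("pswd" %in% names(spec$centering))  # PSWD left uncentered
})

test_that("missing columns and degenerate designs are rejected with names", {
  obs <- sim_pswd(1)
  expect_error(build_pswd_model(obs[, setdiff(names(obs), "diameter")]),
               "diameter")
  one_tree <- obs[obs$tree_id == obs$tree_id[1], ]
  one_tree$provenance <- rep(c("F3", "PL9"), length.out = nrow(one_tree))
  expect_error(build_pswd_model(one_tree), "random intercept")
  expect_error(build_pswd_model(obs[obs$provenance == "F3", ]),
               "two provenances")
})

test_that("noise-free data returns the generating coefficients", {
  obs <- sim_pswd(11, coefficients = list(intercept = 0.9, pswd = -2.49,
                                          pswd2 = 1.61, vpd = 0.044,
                                          radiation = 0.00032),
                  sigma0 = 0, sigma = 1e-6)
  fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "ML")
  b <- coef(fit)
  expect_equal(unname(b["pswd_s"]), -2.49, tolerance = 1e-4)
  expect_equal(unname(b["I(pswd_s^2)"]), 1.61, tolerance = 1e-4)
  expect_equal(unname(b["vpd_c"]), 0.044, tolerance = 1e-3)
})

test_that("with no tree-level variance the mixed fit collapses to least squares", {
  obs <- sim_pswd(1, sigma0 = 0)
  spec <- build_pswd_model(obs, "cwsi")
  fit <- fit_lmm(spec, obs, "ML")
  # the variance estimate collapses to the boundary ...
  expect_lt(variance_components(fit)$sigma0_sq, 1e-8)
  # ... and the fixed effects coincide with ordinary least squares
  frame <- conitherm:::prepare_model_frame(spec, obs)
  ols <- stats::lm(conitherm:::spec_formula(spec), data = frame)
  expect_lt(max(abs(coef(fit) - stats::coef(ols))), 1e-6)
})

test_that("conditional minus marginal R2 grows with the random-intercept variance", {
  r2_gap <- function(sigma0) {
    obs <- sim_pswd(17, sigma0 = sigma0)
    r2 <- r2_glmm(fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML"))
    r2[["conditional"]] - r2[["marginal"]]
  }
  expect_gt(r2_gap(0.2), r2_gap(0) + 0.05)
})

test_that("R2 components match their closed forms in limiting cases", {
  # pure noise: marginal near zero, conditional near sigma0^2/(sigma0^2+sigma^2)
  obs <- sim_pswd(19, coefficients = list(), sigma0 = 0.1, sigma = 0.15)
  fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML")
  r2 <- r2_glmm(fit)
  expect_lt(r2[["marginal"]], 0.1)  # small overfit inflation from ~23 params
  expect_equal(unname(r2[["conditional"]] - r2[["marginal"]]),
               0.01 / (0.01 + 0.0225), tolerance = 0.25)
  # near-noise-free strong signal: marginal close to 1
  obs2 <- sim_pswd(23, sigma0 = 0, sigma = 1e-3)
  r2b <- r2_glmm(fit_lmm(build_pswd_model(obs2, "cwsi"), obs2, "REML"))
  expect_gt(r2b[["marginal"]], 0.999)
})

test_that("AIC chooses the meteorological set that generated the data", {
  # pure VPD effect
  vpd_wins <- vapply(1:10, function(s) {
    obs <- sim_pswd(100 + s,
                    coefficients = list(intercept = 0.5, pswd = -1,
                                        pswd2 = 0.6, vpd = 0.15))
    select_meteo_covariates(obs, "cwsi")$chosen == "vpd"
  }, logical(1))
  expect_gte(sum(vpd_wins), 9)
  # independent T and RH effects of opposite sign
  trh_wins <- vapply(1:10, function(s) {
    obs <- sim_pswd(200 + s,
                    coefficients = list(intercept = 0.5, pswd = -1,
                                        pswd2 = 0.6, airT = 0.02, rh = 0.01))
    select_meteo_covariates(obs, "cwsi")$chosen == "airT_rh"
  }, logical(1))
  expect_gte(sum(trh_wins), 9)
})

test_that("backward AIC deletion prunes inert terms and respects marginality", {
  small <- small_design(2L)
  dropped_height <- vapply(1:30, function(s) {
    obs <- sim_pswd(300 + s, design = small)   # defaults: height coef 0
    simp <- simplify_model(build_pswd_model(obs, "cwsi"), obs)
    !("height" %in% simp$spec$terms)
  }, logical(1))
  # AIC drops a true-zero term when its LR statistic is below 2 (about 84%)
  expect_gte(sum(dropped_height), 20)

  # a strong interaction is retained together with its main effects
  obs <- sim_pswd(31, coefficients = list(
    intercept = 0.6, pswd = -1.5, pswd2 = 1.0,
    provenance_pswd = c(BG10 = 0, D8 = 1.5, ES1 = -1.2, F3 = 0.8, I4 = 1.0,
                        PL9 = -0.9)[-1]))
  simp <- simplify_model(build_pswd_model(obs, "cwsi"), obs)
  expect_true("provenance:pswd" %in% simp$spec$terms)
  expect_true(all(c("provenance", "pswd") %in% simp$spec$terms))
  # every remaining term has its marginality requirements present
  for (tm in simp$spec$terms) {
    req <- conitherm:::TERM_REQUIRES[[tm]]
    if (!is.null(req)) expect_true(all(req %in% simp$spec$terms))
  }
  # the deletion log matches the removed terms
  expect_setequal(simp$deletions$dropped,
                  setdiff(build_pswd_model(obs, "cwsi")$terms, simp$spec$terms))
})

test_that("an already-minimal strong model is returned unchanged", {
  obs <- sim_pswd(41, coefficients = list(intercept = 0.5, pswd = -2.49,
                                          pswd2 = 1.61))
  spec <- build_pswd_model(obs, "cwsi")
  spec$terms <- c("pswd", "pswd2")
  simp <- simplify_model(spec, obs)
  expect_identical(simp$spec$terms, c("pswd", "pswd2"))
  expect_identical(nrow(simp$deletions), 0L)
})

test_that("re-centering the deficit leaves the likelihood invariant", {
  obs <- sim_pswd(43)
  spec <- build_pswd_model(obs, "cwsi")
  f0 <- fit_lmm(spec, obs, "ML")
  spec5 <- spec; spec5$pswd_center <- 0.5
  f5 <- fit_lmm(spec5, obs, "ML")
  expect_equal(as.numeric(logLik(f0)), as.numeric(logLik(f5)),
               tolerance = 1e-6)
})

test_that("scenario contrasts re-center exactly and adjust by the BH step-up", {
  obs <- sim_pswd(47)
  fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML")
  c0a <- provenance_contrasts(fit, 0)
  c0b <- provenance_contrasts(fit, 0)   # idempotent at the current center
  expect_equal(c0a$estimate, c0b$estimate)
  expect_identical(nrow(c0a), 15L)
  expect_true(all(c0a$p_adj >= c0a$p) && all(c0a$p_adj <= 1))
  expect_equal(c0a$p_adj, oracle_bh(c0a$p))
  c50 <- provenance_contrasts(fit, 0.5)
  expect_false(isTRUE(all.equal(c0a$estimate, c50$estimate)))
})

test_that("a strongly deviant provenance is flagged by scenario contrasts", {
  obs <- sim_pswd(53, coefficients = list(
    intercept = 0.5, pswd = -1, pswd2 = 0.5,
    provenance = c(D8 = 0, ES1 = 0.75, F3 = 0, I4 = 0, PL9 = 0)),
    sigma0 = 0.05, sigma = 0.15)
  fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML")
  cc <- provenance_contrasts(fit, 0)
  involves <- cc$level_a == "ES1" | cc$level_b == "ES1"
  expect_true(all(cc$p_adj[involves] < 0.05))
})

test_that("curvature tests flag a provenance with a different quadratic response", {
  obs <- sim_pswd(59, coefficients = list(
    intercept = 0.5, pswd = -2.49, pswd2 = 1.61,
    provenance_pswd2 = c(D8 = 0, ES1 = 1.61, F3 = 0, I4 = 0, PL9 = 0)),
    sigma0 = 0.05, sigma = 0.15)
  fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML")
  cv <- test_interaction_curvature(fit)
  involves <- cv$level_a == "ES1" | cv$level_b == "ES1"
  expect_true(all(cv$p_adj[involves] < 0.05))
  expect_true(all(cv$df == 2))
  # error path when the interactions are absent
  spec <- build_pswd_model(obs, "cwsi")
  spec$terms <- setdiff(spec$terms, c("provenance:pswd", "provenance:pswd2"))
  fit2 <- fit_lmm(spec, obs, "REML")
  expect_error(test_interaction_curvature(fit2), "no interaction to test")
})

test_that("the square-root scale for Ig is enforced and fit on that scale", {
  p <- experiment_params(seed = 61)
  obs <- generate_experiment(p, "pswd", "ig")$observations
  fit <- fit_lmm(build_pswd_model(obs, "sqrt_ig"), obs, "REML")
  expect_identical(fit$spec$response, "sqrt_ig")
  expect_true(is.finite(AIC(fit)))
  obs$ig[3] <- -0.1
  expect_error(fit_lmm(build_pswd_model(obs, "sqrt_ig"), obs), "row")
})

test_that("per-treatment and power variance structures fit and report components", {
  obs <- sim_pswd(67)
  f1 <- fit_lmm(build_pswd_model(obs, "cwsi",
                                 variance_structure = "per_treatment"),
                obs, "REML")
  vc <- variance_components(f1)
  expect_gt(vc$sigma_eps_sq, 0)
  expect_gte(vc$sigma0_sq, 0)
  expect_true(is.finite(AIC(f1)))
})
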