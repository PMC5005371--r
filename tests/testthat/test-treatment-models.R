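sim_treat <- function(seed, coefficients = NULL, sigma0 = 0.1, sigma = 0.15) {
  p <- experiment_params(coefficients = coefficients,
                         random_intercept_sd = sigma0, residual_sd = sigma,
                         seed = seed)
  generate_experiment(p, "treatment", "cwsi")$observations
}

test_that("period windows are disjoint and bounded", {
  st <- period_window("stress"); rc <- period_window("recovery")
  expect_identical(st$days, 4:13)
  expect_identical(rc$days, 14:17)
  expect_length(intersect(st$days, rc$days), 0)
  expect_error(period_window("stress", days = 0:5), "within 1-17")
})

test_that("the full treatment model carries the expected interaction structure", {
  obs <- sim_treat(1)
  spec <- build_treatment_model(obs, period_window("stress"), "cwsi")
  expect_setequal(spec$terms,
                  c("provenance", "treatment", "time", "time2", "height",
                    "diameter", "airT", "rh", "radiation",
                    "provenance:treatment", "treatment:time",
                    "treatment:time2", "treatment:height",
                    "treatment:diameter", "treatment:airT", "treatment:rh"))
  expect_identical(spec$window, 4:13)
  # centering computed within the window
  sub <- obs[obs$day %in% 4:13, ]
  expect_equal(spec$centering[["airT"]], mean(sub$air_temp))

  expect_error(build_treatment_model(obs[obs$day > 20, ]), "no observations")
  drought_only <- obs[obs$treatment == "drought", ]
  expect_error(build_treatment_model(drought_only), "single treatment")
})

test_that("flipping the treatment dummy flips the coefficient sign, not the evidence", {
  obs <- sim_treat(3)
  fit <- fit_lmm(build_treatment_model(obs, period_window("stress"), "cwsi"),
                 obs, "REML")
  flipped <- obs
  flipped$treatment <- ifelse(obs$treatment == "control", "drought", "control")
  spec_f <- build_treatment_model(flipped, period_window("stress"), "cwsi")
  fit_f <- fit_lmm(spec_f, flipped, "REML")
  t1 <- fixef_table(fit); t2 <- fixef_table(fit_f)
  b1 <- t1[t1$term == "treatmentcontrol", ]
  b2 <- t2[t2$term == "treatmentcontrol", ]
  expect_equal(b1$estimate, -b2$estimate, tolerance = 1e-9)
  expect_equal(abs(b1$z), abs(b2$z), tolerance = 1e-9)
})

test_that("treatment contrasts split into three BH-adjusted families", {
  obs <- sim_treat(5)
  fit <- fit_lmm(build_treatment_model(obs, period_window("stress"), "cwsi"),
                 obs, "REML")
  tc <- treatment_contrasts(fit)
  expect_identical(sum(tc$family == "treatment_within_provenance"), 6L)
  expect_identical(sum(tc$family == "provenance_within_drought"), 15L)
  expect_identical(sum(tc$family == "provenance_within_control"), 15L)
  for (fam in unique(tc$family)) {
    sub <- tc[tc$family == fam, ]
    expect_equal(sub$p_adj, oracle_bh(sub$p))
  }
})

test_that("a provenance with no treatment response is the one left non-significant", {
  # strong control-vs-drought effect everywhere except I4, where the
  # interaction cancels it (the pattern of a provenance already stressed
  # under regular watering)
  hits <- vapply(1:8, function(s) {
    obs <- sim_treat(100 + s, coefficients = list(
      intercept = 0.6, treatment = -0.45, time = 0.3,
      provenance_treatment = c(D8 = 0, ES1 = 0, F3 = 0, I4 = 0.45, PL9 = 0)),
      sigma0 = 0.05, sigma = 0.12)
    fit <- fit_lmm(build_treatment_model(obs, period_window("stress"), "cwsi"),
                   obs, "REML")
    tc <- treatment_contrasts(fit)
    tw <- tc[tc$family == "treatment_within_provenance", ]
    i4 <- tw$p_adj[tw$level_b == "I4"] >= 0.05
    rest <- all(tw$p_adj[tw$level_b != "I4"] < 0.05)
    i4 && rest
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("with one provenance only the treatment contrast is returned", {
  obs <- sim_treat(7)
  obs <- obs[obs$provenance == "F3", ]
  fit <- fit_lmm(build_treatment_model(obs, period_window("stress"), "cwsi"),
                 obs, "REML")
  tc <- treatment_contrasts(fit)
  expect_identical(unique(tc$family), "treatment")
  expect_identical(nrow(tc), 1L)
})

test_that("the stress-to-recovery reduction is computed from the treatment coefficients", {
  red <- treatment_effect_reduction(-0.23, -0.11)
  expect_equal(red$percent, 100 * (1 - 0.11 / 0.23), tolerance = 1e-9)
  expect_identical(red$percent_rounded_10, 50)
  expect_equal(treatment_effect_reduction(-0.3, -0.3)$percent, 0)
  expect_equal(treatment_effect_reduction(-0.3, 0)$percent, 100)
  expect_error(treatment_effect_reduction(0, -0.1), "zero")

  obs <- sim_treat(9)
  fs <- fit_lmm(build_treatment_model(obs, period_window("stress"), "cwsi"),
                obs, "REML")
  fr <- fit_lmm(build_treatment_model(obs, period_window("recovery"), "cwsi"),
                obs, "REML")
  red2 <- treatment_effect_reduction(fs, fr)
  bs <- coef(fs)[["treatmentcontrol"]]; br <- coef(fr)[["treatmentcontrol"]]
  expect_equal(red2$percent, 100 * (1 - abs(br) / abs(bs)))
})

test_that("response magnitudes pair every drought tree with every control tree within provenance", {
  obs <- sim_treat(11)
  rm_ <- response_magnitude(obs, "cwsi")
  # default design: 4x4 + 3x5 + 5x3 + 5x3 + 5x3 + 5x3 pairings
  expect_identical(nrow(rm_), 4L * 4L + 3L * 5L + 4L * (5L * 3L))
  expect_identical(anyDuplicated(rm_[c("drought_tree_id", "control_tree_id")]), 0L)

  # identical series in both groups give all-zero deltas
  flat <- obs
  flat$cwsi <- 1
  expect_equal(response_magnitude(flat, "cwsi")$delta, rep(0, nrow(rm_)))

  # a provenance lacking one treatment is excluded with a warning
  part <- obs[!(obs$provenance == "F3" & obs$treatment == "drought"), ]
  expect_warning(rm2 <- response_magnitude(part, "cwsi"), "F3")
  expect_false("F3" %in% rm2$provenance)
})

test_that("rank tests separate provenances with opposite response magnitudes", {
  hits <- vapply(1:5, function(s) {
    obs <- sim_treat(200 + s, coefficients = list(
      intercept = 0.6, treatment = -0.25,
      provenance_treatment = c(D8 = 0, ES1 = -0.35, F3 = 0, I4 = 0.25,
                               PL9 = 0)),
      sigma0 = 0.05, sigma = 0.12)
    deltas <- response_magnitude(obs, "cwsi")
    kd <- kruskal_dunn(split(deltas$delta, deltas$provenance))
    pw <- kd$pairwise
    extreme <- (pw$level_a == "ES1" & pw$level_b == "I4") |
      (pw$level_a == "I4" & pw$level_b == "ES1")
    kd$kruskal$p_value < 0.05 && pw$p_adj[extreme] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("Kruskal-Wallis reduces to the squared rank-sum statistic for two tie-free groups", {
  set.seed(8)
  x <- rnorm(12); y <- rnorm(15) + 0.5
  kd <- kruskal_dunn(list(a = x, b = y))
  # closed-form equivalence: H = z^2 of the standardized rank sum
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r1 <- sum(rank(c(x, y))[1:n1])
  z <- (r1 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kd$kruskal$statistic, z^2, tolerance = 1e-9)
  expect_equal(abs(kd$pairwise$z), abs(z), tolerance = 1e-9)

  # rank statistics are invariant under monotone transforms
  kd2 <- kruskal_dunn(list(a = exp(x), b = exp(y)))
  expect_equal(kd2$kruskal$statistic, kd$kruskal$statistic)
  expect_equal(kd2$pairwise$z, kd$pairwise$z)

  expect_error(kruskal_dunn(list(a = 1, b = c(1, 2))), "at least 2")
})
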