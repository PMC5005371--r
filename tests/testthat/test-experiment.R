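test_that("deficit trajectories follow the schedule with per-tree jitter", {
  sched <- default_pswd_schedule(17, divergence_day = 4)
  expect_true(all(sched$control[1:3] == sched$drought[1:3]))
  expect_true(all(sched$drought[4:13] > sched$control[4:13]))

  # jitter 0: every tree equals its treatment target
  tr <- generate_pswd_trajectories(sched, c(control = 3, drought = 3),
                                   jitter_sd = 0, seed = 1)
  for (d in c(1, 5, 17)) {
    sub <- tr[tr$day == d, ]
    expect_equal(sub$pswd[sub$treatment == "control"],
                 rep(sched$control[d], 3))
    expect_equal(sub$pswd[sub$treatment == "drought"],
                 rep(sched$drought[d], 3))
  }
  # reproducibility and error path
  expect_identical(generate_pswd_trajectories(sched, c(control = 3, drought = 3),
                                              seed = 7),
                   generate_pswd_trajectories(sched, c(control = 3, drought = 3),
                                              seed = 7))
  expect_error(generate_pswd_trajectories(sched, c(control = 3, drought = 3),
                                          jitter_sd = -1), "jitter_sd")
})

test_that("treatments separate by rank test only after the divergence day", {
  sched <- default_pswd_schedule(17, divergence_day = 7)
  tr <- generate_pswd_trajectories(sched, c(control = 10, drought = 10),
                                   jitter_sd = 0.03, seed = 5)
  p_for_day <- function(d) {
    sub <- tr[tr$day == d, ]
    stats::wilcox.test(pswd ~ treatment, data = sub, exact = FALSE)$p.value
  }
  expect_true(all(vapply(2:6, p_for_day, numeric(1)) > 0.05))
  expect_true(all(vapply(7:13, p_for_day, numeric(1)) < 0.001))
})

test_that("experiment generation is deterministic and validates coefficient names", {
  p <- experiment_params(seed = 9)
  a <- generate_experiment(p, "pswd", "cwsi")
  b <- generate_experiment(p, "pswd", "cwsi")
  expect_identical(a$observations, b$observations)
  expect_identical(nrow(a$observations), 48L * 17L)
  expect_identical(sum(a$observations$treatment == "control"), 27L * 17L)

  bad <- experiment_params(coefficients = list(pswd = 1, banana = 2), seed = 1)
  expect_error(generate_experiment(bad, "pswd", "cwsi"),
               "banana.*valid names")
  badlv <- experiment_params(coefficients = list(provenance = c(XX = 1)),
                             seed = 1)
  expect_error(generate_experiment(badlv, "pswd", "cwsi"), "provenance level")
})

test_that("in the noise-free limit the response is the exact deficit polynomial", {
  p <- experiment_params(
    coefficients = list(intercept = 0.9, pswd = -2.49, pswd2 = 1.61),
    random_intercept_sd = 0, residual_sd = 1e-9, seed = 3)
  sim <- generate_experiment(p, "pswd", "cwsi")
  obs <- sim$observations
  expect_equal(obs$cwsi, 0.9 - 2.49 * obs$pswd + 1.61 * obs$pswd^2,
               tolerance = 1e-6)
  # back-computed temperatures reproduce the index through the algebra
  expect_equal(cwsi(obs$t_canopy, obs$t_wet, obs$t_dry,
                    warn_out_of_range = FALSE),
               obs$cwsi, tolerance = 1e-9)
})

test_that("with all coefficients zero the response is centered noise", {
  p <- experiment_params(coefficients = list(), random_intercept_sd = 0,
                         residual_sd = 0.15, seed = 21)
  obs <- generate_experiment(p, "pswd", "cwsi")$observations
  expect_lt(abs(mean(obs$cwsi)), 3 * 0.15 / sqrt(nrow(obs)) + 0.01)
  expect_equal(stats::sd(obs$cwsi), 0.15, tolerance = 0.1)
})

test_that("tree-mean variance matches sigma0^2 + sigma_eps^2 / n_days", {
  des <- data.frame(provenance = "F3", treatment = c("control", "drought"),
                    n = c(250L, 250L))
  p <- experiment_params(design = des, coefficients = list(),
                         random_intercept_sd = 0.1, residual_sd = 0.15,
                         seed = 77)
  obs <- generate_experiment(p, "pswd", "cwsi")$observations
  tree_means <- tapply(obs$cwsi, obs$tree_id, mean)
  expected <- 0.1^2 + 0.15^2 / 17
  expect_equal(unname(stats::var(tree_means)), expected, tolerance = 0.15)
})

test_that("meteorology stays inside the stated measuring-day envelope", {
  obs <- generate_experiment(experiment_params(seed = 2), "pswd", "cwsi")$observations
  expect_true(all(obs$air_temp >= 20.4 & obs$air_temp <= 37.1))
  expect_true(all(obs$rh >= 29 & obs$rh <= 66))
  expect_true(all(obs$radiation >= 24 & obs$radiation <= 234))
  expect_equal(obs$vpd, vpd(obs$air_temp, obs$rh))
  # the within-day measuring order is recorded as a permutation
  d1 <- obs[obs$day == 1, ]
  expect_setequal(d1$measure_order, seq_len(nrow(d1)))
})

test_that("simulated coefficients are recovered without bias at study scale", {
  ests <- vapply(1:30, function(s) {
    p <- experiment_params(seed = 1000 + s)
    obs <- generate_experiment(p, "pswd", "cwsi")$observations
    fit <- fit_lmm(build_pswd_model(obs, "cwsi"), obs, "REML")
    coef(fit)[c("pswd_s", "I(pswd_s^2)")]
  }, numeric(2))
  se_mc <- apply(ests, 1, stats::sd) / sqrt(ncol(ests))
  expect_lt(abs(mean(ests[1, ]) - (-2.49)), 4 * se_mc[1])
  expect_lt(abs(mean(ests[2, ]) - 1.61), 4 * se_mc[2])
})
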