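test_that("zscore standardizes to sample mean 0 and SD 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(c(5, 5, 5)), "zero variance")
  expect_error(zscore(7), "at least 2")
  set.seed(3)
  z <- zscore(rnorm(1000, 40, 13))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
})

test_that("stimulus-response fit recovers gain, bias and error statistics", {
  t5 <- c(-60, -30, 0, 30, 60)
  f <- fit_stimulus_response(t5, c(-50, -40, -30, -20, -10))
  expect_equal(f$gain, 1 / 3)
  expect_equal(f$bias_deg, -30)

  targets <- seq(-60, 60, by = 10)
  f_id <- fit_stimulus_response(targets, targets)
  expect_equal(f_id$gain, 1)
  expect_equal(f_id$bias_deg, 0)
  expect_equal(f_id$r2, 1)
  expect_equal(f_id$mae_deg, 0)
  expect_equal(unname(coef(f_id)), c(0, 1))
  expect_equal(predict(f_id, c(-5, 5)), c(-5, 5))
  expect_equal(residuals(f_id), rep(0, length(targets)))

  f_const <- fit_stimulus_response(t5, rep(-35, 5))
  expect_equal(f_const$gain, 0)
  expect_equal(f_const$bias_deg, -35)
  expect_equal(f_const$mae_deg, mean(abs(-35 - t5)))

  expect_error(fit_stimulus_response(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_stimulus_response(rep(5, 6), rnorm(6)), "targets do not vary")
})

test_that("r2 equals r squared and residual stats are nonnegative", {
  set.seed(10)
  for (i in 1:10) {
    t <- runif(20, -60, 60)
    r <- 0.7 * t + rnorm(20, 0, 8)
    f <- fit_stimulus_response(t, r)
    expect_lt(abs(f$r2 - f$r^2), 1e-10)
    expect_gte(f$residual_sd_deg, 0)
    expect_gte(f$mae_deg, 0)
  }
})

test_that("fits match a brute-force normal-equations oracle", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    t <- runif(n, -70, 70)
    r <- runif(1, -1, 2) * t + rnorm(n, 0, 10)
    f <- fit_stimulus_response(t, r)
    X <- cbind(1, t)
    beta <- solve(t(X) %*% X, t(X) %*% r)
    expect_lt(abs(f$bias_deg - beta[1]), 1e-8)
    expect_lt(abs(f$gain - beta[2]), 1e-8)
  }
})

test_that("azimuth cue regression is self-consistent on its own generative model", {
  w <- make_weighted_trials(400, az_weights = c(p = -0.42, q = 0.85), seed = 2)
  f <- fit_azimuth_cues(w$trials)
  # refitting the re-standardized response rescales the weights by 1/sd(resp)
  expect_equal(f$coefs[["p"]], -0.42 / w$resp_az_sd, tolerance = 1e-6)
  expect_equal(f$coefs[["q"]], 0.85 / w$resp_az_sd, tolerance = 1e-6)
})

test_that("an ideal localizer yields p = 0, q = 1 and [p, q, s] = [0, 0, 1]", {
  tr <- simulate_session(noiseless_ideal_model(), "pre_test", seed = 4)
  f1a <- fit_stimulus_response(tr$target_az_deg, tr$resp_az_deg)
  f1e <- fit_stimulus_response(tr$target_el_deg, tr$resp_el_deg)
  expect_equal(f1a$gain, 1, tolerance = 1e-6)
  expect_equal(f1a$bias_deg, 0, tolerance = 1e-6)
  expect_equal(f1e$gain, 1, tolerance = 1e-6)
  f2 <- fit_azimuth_cues(tr)
  expect_equal(f2$coefs[["p"]], 0, tolerance = 1e-6)
  expect_equal(f2$coefs[["q"]], 1, tolerance = 1e-6)
  f4 <- fit_elevation_cues(tr)
  expect_equal(unname(f4$coefs), c(0, 0, 1), tolerance = 1e-6)
})

test_that("elevation cue regression is self-consistent and splits hemifields", {
  w <- make_weighted_trials(600, el_weights = c(p = 0, q = -0.3, s = 0.5), seed = 5)
  f <- fit_elevation_cues(w$trials)
  expect_equal(f$coefs[["s"]], 0.5 / w$resp_el_sd, tolerance = 1e-6)
  expect_equal(f$coefs[["q"]], -0.3 / w$resp_el_sd, tolerance = 1e-6)
  expect_equal(f$coefs[["p"]], 0, tolerance = 1e-6)

  # midline targets belong to neither hemifield
  tr <- w$trials
  tr$target_az_deg[1:50] <- 0
  n_l <- fit_elevation_cues(tr, hemifield = "left")$n
  n_r <- fit_elevation_cues(tr, hemifield = "right")$n
  expect_identical(n_l + n_r + 50L, nrow(tr))

  few <- w$trials[1:12, ]
  few$target_az_deg <- abs(few$target_az_deg)  # empty left hemifield
  expect_error(fit_elevation_cues(few, hemifield = "left"), "'left'")
})

test_that("single-level designs are refused and near-collinearity is warned", {
  w <- make_weighted_trials(100, seed = 6)
  tr <- w$trials
  tr$level_dBA <- 60
  expect_error(fit_azimuth_cues(tr), "single sound level")
  expect_error(fit_elevation_cues(tr), "two")

  # a narrow azimuth range makes the head-shadow sine locally linear, so a
  # near-constant level renders the proximal level collinear with azimuth
  tr2 <- tr[1:50, ]
  tr2$target_az_deg <- seq(-1, 1, length.out = 50)
  tr2$level_dBA <- 60 + rep(c(0, 1e-8), 25)
  expect_warning(f <- fit_azimuth_cues(tr2), "near-collinear")
  expect_false(is.null(f$warning))
})

test_that("with orthogonal predictors the weights equal simple correlations", {
  # hse = 0 makes the proximal level equal the (balanced) free-field level,
  # orthogonal to target azimuth by construction
  set.seed(9)
  az <- rep(seq(-60, 60, length.out = 30), each = 2)
  lev <- rep(c(50, 70), 30)
  resp <- 0.5 * az - 0.8 * lev + rnorm(60, 0, 10)
  tr <- data.frame(
    trial_index = 1:60, phase = "pre", condition = "plugged",
    stimulus_type = "HP", level_dBA = lev, target_az_deg = az,
    target_el_deg = 0, resp_az_deg = resp, resp_el_deg = 0, rt_ms = NA
  )
  f <- fit_azimuth_cues(tr, hse_db = 0)
  expect_equal(f$coefs[["q"]], cor(az, resp), tolerance = 1e-10)
  expect_equal(f$coefs[["p"]], cor(lev, resp), tolerance = 1e-10)
  # and the azimuth weight equals the Pearson r of the simple fit
  expect_equal(f$coefs[["q"]], fit_stimulus_response(az, resp)$r, tolerance = 1e-10)
})

test_that("generative weights are recovered within 3 SEs", {
  for (seed in 1:5) {
    w <- make_weighted_trials(2000, az_weights = c(p = -0.35, q = 0.7),
                              el_weights = c(p = 0.1, q = -0.2, s = 0.6),
                              noise_sd = 0.6, seed = seed)
    fa <- fit_azimuth_cues(w$trials)
    expect_lt(abs(fa$coefs[["p"]] - (-0.35 / w$resp_az_sd)), 3 * fa$se[["p"]])
    expect_lt(abs(fa$coefs[["q"]] - (0.7 / w$resp_az_sd)), 3 * fa$se[["q"]])
    fe <- fit_elevation_cues(w$trials)
    expect_lt(abs(fe$coefs[["s"]] - (0.6 / w$resp_el_sd)), 3 * fe$se[["s"]])
  }
})
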