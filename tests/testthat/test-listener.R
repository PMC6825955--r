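test_that("proximal level follows the sinusoidal head-shadow model", {
  expect_equal(proximal_level(0, 60, 10), 60)
  expect_equal(proximal_level(90, 60, 10), 70)
  expect_equal(proximal_level(30, 55, 10), 60)  # 55 + 10*sin(30 deg)
  expect_equal(proximal_level(-90, 60, 10), 50)
  expect_error(proximal_level(95, 60, 10), "\\[-90, 90\\]")
})

test_that("posterior response matches the closed forms", {
  # equal reliabilities: midpoint
  d <- posterior_response(gaussian_prior(0, 7), gaussian_prior(20, 7), "map")
  expect_equal(d$mean_deg, 10)

  # hand computation: shrinkage 1/2, map var 25, sampling var 50
  d_map <- posterior_response(gaussian_prior(0, 10), gaussian_prior(20, 10), "map")
  d_smp <- posterior_response(gaussian_prior(0, 10), gaussian_prior(20, 10),
                              "posterior_sample")
  expect_equal(d_map$sd_deg^2, 25)
  expect_equal(d_smp$sd_deg^2, 50)
  expect_equal(d_smp$mean_deg, d_map$mean_deg)

  # uniform-prior limit: the likelihood
  d_u <- posterior_response(gaussian_prior(5, Inf), gaussian_prior(-40, 12), "map")
  expect_equal(d_u$mean_deg, -40)
  expect_equal(d_u$sd_deg, 12)

  expect_error(posterior_response(gaussian_prior(0, 10),
                                  list(mean_deg = 0, sd_deg = -1), "map"),
               "positive")
  expect_error(gaussian_prior(0, 0), "positive")
})

test_that("closed-form moments agree with Monte-Carlo posterior sampling", {
  set.seed(41)
  n_draws <- 2e4
  for (i in 1:15) {
    mu_p <- runif(1, -50, 50); sd_p <- runif(1, 3, 60)
    mu_s <- runif(1, -50, 50); sd_s <- runif(1, 3, 60)
    prior <- gaussian_prior(mu_p, sd_p)
    lik <- gaussian_prior(mu_s, sd_s)
    d_map <- posterior_response(prior, lik, "map")
    d_smp <- posterior_response(prior, lik, "posterior_sample")

    k <- sd_p^2 / (sd_p^2 + sd_s^2)
    # MAP readout under trial-to-trial sensory noise
    x <- rnorm(n_draws, mu_s, sd_s)
    y_map <- k * x + (1 - k) * mu_p
    # a random draw from the product-Gaussian posterior
    post_sd <- sqrt(sd_s^2 * sd_p^2 / (sd_s^2 + sd_p^2))
    y_smp <- rnorm(n_draws, d_map$mean_deg, post_sd)

    se_mean <- sd(y_map) / sqrt(n_draws)
    expect_lt(abs(mean(y_map) - d_map$mean_deg), 4 * se_mean)
    se_var <- var(y_map) * sqrt(2 / (n_draws - 1))
    expect_lt(abs(var(y_map) - d_map$sd_deg^2), 4 * se_var)
    se_var2 <- var(y_smp) * sqrt(2 / (n_draws - 1))
    expect_lt(abs(var(y_smp) - d_smp$sd_deg^2), 4 * se_var2)
  }
})

test_that("posterior-sampling inflates variance by exactly 1 + sdS^2/sdP^2", {
  set.seed(7)
  for (i in 1:50) {
    sd_p <- runif(1, 0.5, 100); sd_s <- runif(1, 0.5, 100)
    prior <- gaussian_prior(runif(1, -80, 80), sd_p)
    lik <- gaussian_prior(runif(1, -80, 80), sd_s)
    ratio <- posterior_response(prior, lik, "posterior_sample")$sd_deg^2 /
      posterior_response(prior, lik, "map")$sd_deg^2
    expected <- 1 + sd_s^2 / sd_p^2
    expect_lt(abs(ratio - expected), 1e-12 * expected)
  }
})

test_that("response gain is monotone in the prior and sensory widths", {
  gain <- function(sd_p, sd_s)
    (posterior_response(gaussian_prior(0, sd_p), gaussian_prior(1, sd_s), "map"))$mean_deg
  sd_grid <- c(1, 2, 5, 10, 30, 90)
  for (sd_s in c(2, 10, 40)) {
    g <- vapply(sd_grid, gain, numeric(1), sd_s = sd_s)
    expect_true(all(diff(g) > 0))  # increasing in prior width
  }
  for (sd_p in c(2, 10, 40)) {
    g <- vapply(sd_grid, function(s) gain(sd_p, s), numeric(1))
    expect_true(all(diff(g) < 0))  # decreasing in sensory width
  }
})

test_that("noiseless veridical and prior-dominated limits hold", {
  tr <- simulate_trial(noiseless_ideal_model(), double_polar(30, 20), "HP", 60)
  expect_equal(tr$resp_az_deg, 30)
  expect_equal(tr$resp_el_deg, 20)

  captured <- listener_model(
    "plugged_pre",
    azimuth_prior = gaussian_prior(-40, 0.01),
    azimuth_sensory_sd_deg = c(BB = 500, LP = 500, HP = 500),
    motor_noise_sd_deg = 0
  )
  set.seed(2)
  for (az in c(-60, 0, 60)) {
    tr <- simulate_trial(captured, double_polar(az, 0), "HP", 60)
    expect_lt(abs(tr$resp_az_deg - (-40)), 1)
  }
})

test_that("sessions are deterministic under a fixed seed", {
  m <- listener_model("plugged_pre")
  a <- simulate_session(m, "pre_test", seed = 99)
  b <- simulate_session(m, "pre_test", seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, simulate_session(m, "pre_test", seed = 100)))
})

test_that("session designs deliver the prescribed stimulus menus", {
  tt <- simulate_session(listener_model("plugged_training"), "training", seed = 5)
  expect_identical(nrow(tt), 500L)
  expect_true(all(tt$target_el_deg == 0))
  counts <- table(tt$target_az_deg)
  expect_identical(sort(as.numeric(names(counts))),
                   c(-60, -48, -36, -24, -12, 12, 24, 36, 48, 60))
  expect_true(all(counts == 50))
  expect_true(all(tt$level_dBA == 60) && all(tt$stimulus_type == "HP"))

  te <- simulate_session(listener_model("plugged_pre"), "pre_test", seed = 6)
  expect_identical(nrow(te), 180L)
  expect_identical(as.vector(table(te$level_dBA)), rep(60L, 3))
  expect_true(all(te$level_dBA %in% c(50, 60, 70)))
  expect_true(all(abs(te$target_az_deg) <= 60))
  expect_true(all(te$target_el_deg >= -40 & te$target_el_deg <= 50))
  trained <- te$target_el_deg == 0 &
    te$target_az_deg %in% c(-60, -48, -36, -24, -12, 12, 24, 36, 48, 60)
  expect_false(any(trained))

  ct <- simulate_session(listener_model("binaural"), "control_binaural", seed = 7)
  expect_identical(nrow(ct), 300L)
  expect_identical(sum(ct$stimulus_type == "HP"), 180L)
  expect_identical(sum(ct$stimulus_type == "BB"), 60L)
  expect_identical(sum(ct$stimulus_type == "LP"), 60L)
  expect_true(all(ct$level_dBA[ct$stimulus_type == "HP"] %in% seq(45, 70, 5)))
  expect_true(all(ct$level_dBA[ct$stimulus_type != "HP"] %in% c(50, 65)))
  expect_true(all(abs(ct$target_az_deg) <= 80))
})

test_that("simulate() method returns reproducible session lists", {
  m <- listener_model("binaural")
  s1 <- simulate(m, nsim = 2, seed = 3, design = "pre_test")
  expect_length(s1, 2)
  expect_identical(s1[[1]], simulate_session(m, "pre_test", seed = 3))
})

test_that("plugged simulations show the monaural signatures under regression", {
  m <- listener_model("plugged_pre")
  tr <- simulate_session(m, "pre_test", seed = 8, n_trials = 2000)
  az <- fit_azimuth_cues(tr)
  expect_lt(az$coefs[["p"]], 0)
  expect_gt(az$coefs[["q"]], 0)
  expect_lt(az$coefs[["q"]], 1)
  s_left <- fit_elevation_cues(tr, hemifield = "left")$coefs[["s"]]
  s_right <- fit_elevation_cues(tr, hemifield = "right")$coefs[["s"]]
  expect_gt(s_left, s_right)
})
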