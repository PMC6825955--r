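# Shared fixtures, all generated in code.

# A hand-buildable valid trial table (not simulated), n rows.
make_manual_trials <- function(n = 12, seed = 1) {
  set.seed(seed)
  az <- runif(n, -60, 60)
  el <- vapply(az, function(a) runif(1, max(-40, abs(a) - 90), min(50, 90 - abs(a))),
               numeric(1))
  data.frame(
    trial_index = seq_len(n),
    phase = sample(c("control", "pre", "post"), n, replace = TRUE),
    condition = sample(c("binaural", "plugged"), n, replace = TRUE),
    stimulus_type = sample(c("BB", "LP", "HP"), n, replace = TRUE),
    level_dBA = sample(c(45, 50, 60, 65, 70), n, replace = TRUE),
    target_az_deg = az,
    target_el_deg = el,
    resp_az_deg = az + rnorm(n, 0, 5),
    resp_el_deg = el + rnorm(n, 0, 5),
    rt_ms = ifelse(runif(n) < 0.2, NA, 200 + rexp(n, 1 / 50))
  )
}

# Trial table whose responses follow known standardized weights, for
# regression self-consistency and recovery tests. Returns the table plus the
# realized response SDs needed to express the generative weights on the
# fitted (re-standardized) scale.
make_weighted_trials <- function(n, az_weights = c(p = -0.4, q = 0.6),
                                 el_weights = c(p = 0, q = -0.3, s = 0.5),
                                 noise_sd = 0, hse_db = 10, seed = 1) {
  set.seed(seed)
  az <- runif(n, -60, 60)
  el <- vapply(az, function(a) runif(1, max(-40, abs(a) - 90), min(50, 90 - abs(a))),
               numeric(1))
  level <- sample(c(50, 60, 70), n, replace = TRUE)
  iprox <- proximal_level(az, level, hse_db)
  zI <- zscore(iprox); zT <- zscore(az); zE <- zscore(el)
  resp_az <- az_weights[["p"]] * zI + az_weights[["q"]] * zT + rnorm(n, 0, noise_sd)
  resp_el <- el_weights[["p"]] * zI + el_weights[["q"]] * zT +
    el_weights[["s"]] * zE + rnorm(n, 0, noise_sd)
  trials <- data.frame(
    trial_index = seq_len(n), phase = "pre", condition = "plugged",
    stimulus_type = "HP", level_dBA = level,
    target_az_deg = az, target_el_deg = el,
    resp_az_deg = resp_az, resp_el_deg = resp_el, rt_ms = 300
  )
  list(trials = trials, resp_az_sd = sd(resp_az), resp_el_sd = sd(resp_el))
}

# Listener with no sensory or motor noise and flat priors: the veridical
# ideal localizer.
noiseless_ideal_model <- function() {
  listener_model(
    "binaural",
    azimuth_prior = gaussian_prior(0, Inf),
    elevation_prior = gaussian_prior(0, Inf),
    azimuth_sensory_sd_deg = c(BB = 0, LP = 0, HP = 0),
    elevation_sensory_sd_hearing_deg = 0,
    motor_noise_sd_deg = 0,
    rt_lognorm_sdlog = 0
  )
}
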