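#' Gaussian spatial prior
#'
#' A one-dimensional Gaussian prior over a spatial angle. An infinite
#' `sd_deg` denotes the uniform (flat) limit, under which the percept is
#' governed by the sensory likelihood alone.
#'
#' @param mean_deg prior mean, degrees.
#' @param sd_deg prior standard deviation, degrees; strictly positive, may be
#'   `Inf`.
#' @return An object of class `gaussian_prior` with fields `mean_deg`,
#'   `sd_deg`.
#' @examples
#' gaussian_prior(0, 12)
#' gaussian_prior(0, Inf)  # uniform limit
#' @export
gaussian_prior <- function(mean_deg, sd_deg) {
  if (!is.finite(mean_deg)) stop("prior mean must be finite")
  if (is.na(sd_deg) || sd_deg <= 0) stop("prior sd must be strictly positive")
  structure(list(mean_deg = mean_deg, sd_deg = sd_deg), class = "gaussian_prior")
}

#' @export
print.gaussian_prior <- function(x, ...) {
  cat(sprintf("Gaussian prior: mean %.3g deg, sd %s deg\n", x$mean_deg,
              if (is.infinite(x$sd_deg)) "Inf (uniform limit)" else
                sprintf("%.3g", x$sd_deg)))
  invisible(x)
}

#' Proximal sound level at the free ear
#'
#' Approximates the head-shadow effect (HSE) on the level perceived at the
#' free ear as a sinusoidal modulation of the free-field level:
#' \deqn{I_{prox}(\alpha) = I_{snd} + HSE \cdot \sin(\pi \alpha / 180)}
#' with the target azimuth \eqn{\alpha} in degrees and both levels in dB.
#' The default head-shadow magnitude is 10 dB for broadband sounds. The sine
#' approximation is only meaningful in the frontal hemifield, so azimuths
#' outside \eqn{\pm 90}° are rejected.
#'
#' @param target_azimuth_deg target azimuth, degrees, within \[-90, 90\].
#' @param free_field_level_dBA free-field sound level, dBA.
#' @param hse_db head-shadow magnitude, dB (default 10).
#' @return Proximal level in dBA (vectorized over azimuth/level).
#' @examples
#' proximal_level(0, 60)    # 60: no head shadow on the midline
#' proximal_level(90, 60)   # 70: full head shadow laterally
#' proximal_level(30, 55)   # 60 = 55 + 10 * sin(30 deg)
#' @export
proximal_level <- function(target_azimuth_deg, free_field_level_dBA, hse_db = 10) {
  if (any(!is.finite(target_azimuth_deg)) || any(abs(target_azimuth_deg) > 90))
    stop("target azimuth must lie within [-90, 90] degrees for the head-shadow model")
  free_field_level_dBA + hse_db * sin(pi * target_azimuth_deg / 180)
}

#' Bayesian response distribution for one spatial channel
#'
#' Combines a Gaussian prior with a Gaussian sensory likelihood and returns
#' the distribution of localization responses under one of two decision
#' rules. Both rules share the posterior mean
#' \deqn{\mu_{RESP} = \frac{\sigma_P^2 \mu_S + \sigma_S^2 \mu_P}{\sigma_P^2 + \sigma_S^2},}
#' i.e. the sensory estimate shrunk toward the prior. Under the
#' maximum-a-posteriori (`"map"`) rule the response variance is
#' \deqn{\sigma^2_{RESP} = \frac{\sigma_S^2}{(1 + \sigma_S^2/\sigma_P^2)^2},}
#' the variance of the posterior peak under trial-to-trial sensory noise.
#' Under posterior sampling (`"posterior_sample"`), where the response is a
#' random draw from the posterior, the variance inflates to
#' \deqn{\sigma^2_{RESP} = \frac{\sigma_S^2}{1 + \sigma_S^2/\sigma_P^2},}
#' exactly \eqn{1 + \sigma_S^2/\sigma_P^2} times the MAP variance. With an
#' infinite prior sd both rules reduce to the likelihood
#' (\eqn{\mu_{RESP}=\mu_S}, \eqn{\sigma_{RESP}=\sigma_S}).
#'
#' @param prior a [gaussian_prior()] (fields `mean_deg`, `sd_deg`; `sd_deg`
#'   may be `Inf`).
#' @param likelihood the sensory likelihood, any list with finite `mean_deg`
#'   and strictly positive finite `sd_deg` (e.g. a [gaussian_prior()]).
#' @param rule `"map"` or `"posterior_sample"`.
#' @return An object of class `response_distribution` with fields `mean_deg`,
#'   `sd_deg`, `rule`.
#' @examples
#' posterior_response(gaussian_prior(0, 10), gaussian_prior(20, 10), "map")
#' @export
posterior_response <- function(prior, likelihood,
                               rule = c("map", "posterior_sample")) {
  rule <- match.arg(rule)
  mu_p <- prior$mean_deg; sd_p <- prior$sd_deg
  mu_s <- likelihood$mean_deg; sd_s <- likelihood$sd_deg
  if (is.na(sd_p) || sd_p <= 0) stop("prior sd must be strictly positive")
  if (!is.finite(sd_s) || sd_s <= 0)
    stop("likelihood sd must be strictly positive and finite")
  if (!is.finite(mu_s)) stop("likelihood mean must be finite")

  if (is.infinite(sd_p)) {
    shrink <- 1
  } else {
    shrink <- sd_p^2 / (sd_p^2 + sd_s^2)  # response gain d(mu_RESP)/d(mu_S)
  }
  mean_resp <- shrink * mu_s + (1 - shrink) * mu_p
  var_resp <- switch(rule,
    map = shrink^2 * sd_s^2,
    posterior_sample = shrink * sd_s^2
  )
  structure(
    list(mean_deg = mean_resp, sd_deg = sqrt(var_resp), rule = rule),
    class = "response_distribution"
  )
}

#' @export
print.response_distribution <- function(x, ...) {
  cat(sprintf("Response distribution (%s): mean %.4g deg, sd %.4g deg\n",
              x$rule, x$mean_deg, x$sd_deg))
  invisible(x)
}

#' Generative Bayesian listener model
#'
#' Constructs the generative model of a listener localizing brief sounds in
#' the frontal hemifield. Each spatial channel (azimuth, elevation) combines
#' a noisy sensory estimate with a Gaussian spatial prior under a MAP or
#' posterior-sampling decision rule ([posterior_response()]).
#'
#' The azimuth channel encodes the target azimuth with stimulus-type-specific
#' sensory noise. Under plugged hearing the encoding acquires a
#' level-dependent bias toward the free (left) ear: the perceived interaural
#' level difference pulls the estimate by
#' `perceived_ild_bias_deg + ild_level_slope_deg_per_db * (I_prox - level_reference_dBA)`,
#' so louder sounds are heard further toward the hearing side (the ambiguous
#' head-shadow cue). Under binaural hearing the encoding is unbiased.
#'
#' The elevation channel models the azimuth-dependent binaural weighting of
#' the spectral (pinna) cues: under plugged hearing its sensory sd
#' interpolates logistically (midpoint 0°, slope `binaural_weight_slope` per
#' degree) between `elevation_sensory_sd_hearing_deg` far on the free side
#' and `elevation_sensory_sd_plugged_deg` far on the plugged side; under
#' binaural hearing it is constant at the hearing-side value.
#'
#' Condition presets (`"binaural"`, `"plugged_pre"`, `"plugged_training"`,
#' `"plugged_post"`) set priors and sensory reliabilities appropriate for the
#' experimental epoch; every field can be overridden through `...`.
#'
#' @param condition hearing/epoch preset.
#' @param ... named overrides of any model field (see Details and the field
#'   list in the returned object).
#' @return An object of class `listener_model`.
#' @examples
#' m <- listener_model("plugged_pre")
#' print(m)
#' tr <- simulate_session(m, "pre_test", seed = 7)
#' head(tr)
#' @export
listener_model <- function(condition = c("binaural", "plugged_pre",
                                         "plugged_training", "plugged_post"),
                           ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    binaural = list(
      azimuth_prior = gaussian_prior(0, 180),     # near-uniform azimuth prior
      elevation_prior = gaussian_prior(3, 12),    # slight upward default prior
      azimuth_sensory_sd_deg = c(BB = 4, LP = 4, HP = 4),
      perceived_ild_bias_deg = 0,
      ild_level_slope_deg_per_db = 0
    ),
    plugged_pre = list(
      azimuth_prior = gaussian_prior(-40, 15),    # narrow prior at the free ear
      elevation_prior = gaussian_prior(3, 12),
      azimuth_sensory_sd_deg = c(BB = 30, LP = 12, HP = 30),  # LP keeps ITDs
      perceived_ild_bias_deg = -10,
      ild_level_slope_deg_per_db = -1.5
    ),
    plugged_training = list(
      azimuth_prior = gaussian_prior(-40, 15),
      elevation_prior = gaussian_prior(3, 12),
      azimuth_sensory_sd_deg = c(BB = 30, LP = 12, HP = 30),
      perceived_ild_bias_deg = -10,
      ild_level_slope_deg_per_db = -1.5
    ),
    plugged_post = list(
      azimuth_prior = gaussian_prior(-10, 60),    # relaxed, recentred
      elevation_prior = gaussian_prior(0, 5),     # trained horizon prior
      azimuth_sensory_sd_deg = c(BB = 15, LP = 12, HP = 15),  # remapped cues
      perceived_ild_bias_deg = -10,
      ild_level_slope_deg_per_db = -1.5
    )
  )
  model <- c(list(condition = condition), base, list(
    elevation_sensory_sd_hearing_deg = 5,
    elevation_sensory_sd_plugged_deg = 50,
    binaural_weight_slope = 0.05,   # logistic slope, per degree azimuth
    hse_db = 10,
    plug_attenuation_hp_db = 25,
    plug_attenuation_lp_db = 20,
    level_reference_dBA = 60,
    decision_rule = "map",
    motor_noise_sd_deg = 3,
    rt_base_ms = 150,
    rt_ms_per_deg = 5,              # affine penalty per degree of sensory sd
    rt_lognorm_sdlog = 0.1
  ))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(model))
  if (length(unknown))
    stop("unknown listener_model field(s): ", paste(unknown, collapse = ", "))
  model[names(dots)] <- dots
  validate_listener_model(structure(model, class = "listener_model"))
}

validate_listener_model <- function(model) {
  stopifnot(inherits(model$azimuth_prior, "gaussian_prior"),
            inherits(model$elevation_prior, "gaussian_prior"))
  pos <- c("hse_db", "plug_attenuation_hp_db", "plug_attenuation_lp_db")
  for (f in pos)
    if (!is.finite(model[[f]]) || model[[f]] <= 0)
      stop("listener_model field '", f, "' must be positive")
  # sensory sds may be exactly zero (the noiseless veridical limit)
  nneg <- c("elevation_sensory_sd_hearing_deg", "elevation_sensory_sd_plugged_deg")
  for (f in nneg)
    if (!is.finite(model[[f]]) || model[[f]] < 0)
      stop("listener_model field '", f, "' must be nonnegative")
  if (any(!is.finite(model$azimuth_sensory_sd_deg)) ||
      any(model$azimuth_sensory_sd_deg < 0))
    stop("azimuth sensory sds must be nonnegative")
  if (model$motor_noise_sd_deg < 0) stop("motor noise sd must be nonnegative")
  if (!model$decision_rule %in% c("map", "posterior_sample"))
    stop("decision_rule must be 'map' or 'posterior_sample'")
  model
}

#' @export
print.listener_model <- function(x, ...) {
  cat("Bayesian listener model (", x$condition, ")\n", sep = "")
  cat(sprintf("  azimuth prior:    mean %6.1f deg, sd %s deg\n",
              x$azimuth_prior$mean_deg,
              format(x$azimuth_prior$sd_deg)))
  cat(sprintf("  elevation prior:  mean %6.1f deg, sd %s deg\n",
              x$elevation_prior$mean_deg, format(x$elevation_prior$sd_deg)))
  cat("  azimuth sensory sd (deg): ",
      paste(names(x$azimuth_sensory_sd_deg), x$azimuth_sensory_sd_deg,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  elevation sensory sd: %.3g (hearing) -> %.3g (plugged) deg\n",
              x$elevation_sensory_sd_hearing_deg,
              x$elevation_sensory_sd_plugged_deg))
  cat(sprintf("  decision rule: %s; motor noise %.3g deg; HSE %.3g dB\n",
              x$decision_rule, x$motor_noise_sd_deg, x$hse_db))
  invisible(x)
}

is_plugged <- function(model) model$condition != "binaural"

# One spatial channel of simulate_trial. A zero sensory sd is the noiseless
# limit (the posterior collapses onto the sensory estimate); otherwise the
# closed-form posterior_response applies.
channel_response <- function(prior, mean_deg, sd_deg, rule) {
  if (sd_deg == 0)
    return(list(mean_deg = mean_deg, sd_deg = 0, rule = rule))
  posterior_response(prior, list(mean_deg = mean_deg, sd_deg = sd_deg), rule)
}

# Elevation sensory sd as a function of target azimuth: logistic binaural
# weighting of the spectral cues under plugged hearing, constant otherwise.
elevation_sensory_sd <- function(model, target_az_deg) {
  lo <- model$elevation_sensory_sd_hearing_deg
  if (!is_plugged(model)) return(rep(lo, length(target_az_deg)))
  hi <- model$elevation_sensory_sd_plugged_deg
  lo + (hi - lo) * plogis(model$binaural_weight_slope * target_az_deg)
}

azimuth_sensory_sd <- function(model, stimulus_type) {
  sds <- model$azimuth_sensory_sd_deg
  if (length(sds) == 1L && is.null(names(sds))) return(unname(sds))
  if (!stimulus_type %in% names(sds))
    stop("no azimuth sensory sd for stimulus type '", stimulus_type, "'")
  unname(sds[[stimulus_type]])
}

# Mean of the azimuth sensory encoding: veridical under binaural hearing,
# pulled toward the free ear by the perceived (plug-induced) ILD, with a
# level-dependent component so that louder sounds are heard further leftward.
azimuth_sensory_mean <- function(model, target_az_deg, level_dBA) {
  if (!is_plugged(model)) return(target_az_deg)
  iprox <- proximal_level(target_az_deg, level_dBA, model$hse_db)
  target_az_deg + model$perceived_ild_bias_deg +
    model$ild_level_slope_deg_per_db * (iprox - model$level_reference_dBA)
}

#' Simulate a single localization trial
#'
#' Draws one stimulus-response trial from a [listener_model()]: the azimuth
#' and elevation response components are sampled from the channel-wise
#' [posterior_response()] distributions, independent Gaussian motor noise is
#' added to both, and a reaction time is drawn as an affine-increasing
#' function of the azimuth sensory sd with multiplicative lognormal noise
#' (faster responses when the sensory evidence is more reliable).
#'
#' @param model a [listener_model()].
#' @param target a direction, e.g. `double_polar(30, 20)` or any list with
#'   `azimuth_deg`/`elevation_deg`.
#' @param stimulus_type `"BB"`, `"LP"` or `"HP"`.
#' @param level_dBA free-field level in dBA.
#' @param trial_index ordinal index stored in the record.
#' @param phase phase label stored in the record.
#' @return A one-row trial-table data.frame.
#' @examples
#' set.seed(1)
#' simulate_trial(listener_model("plugged_pre"), double_polar(30, 20), "HP", 60)
#' @export
simulate_trial <- function(model, target, stimulus_type = "HP", level_dBA = 60,
                           trial_index = 1L, phase = "pre") {
  stopifnot(inherits(model, "listener_model"))
  az <- target$azimuth_deg[1]; el <- target$elevation_deg[1]
  if (!is_valid_direction(az, el))
    stop("target outside the frontal hemifield diamond")
  if (!stimulus_type %in% .stimulus_types)
    stop("unknown stimulus type '", stimulus_type, "'")

  sd_az <- azimuth_sensory_sd(model, stimulus_type)
  mu_az <- azimuth_sensory_mean(model, az, level_dBA)
  az_dist <- channel_response(model$azimuth_prior, mu_az, sd_az,
                              model$decision_rule)

  sd_el <- elevation_sensory_sd(model, az)
  el_dist <- channel_response(model$elevation_prior, el, sd_el,
                              model$decision_rule)

  resp_az <- rnorm(1, az_dist$mean_deg, az_dist$sd_deg) +
    rnorm(1, 0, model$motor_noise_sd_deg)
  resp_el <- rnorm(1, el_dist$mean_deg, el_dist$sd_deg) +
    rnorm(1, 0, model$motor_noise_sd_deg)
  rt <- (model$rt_base_ms + model$rt_ms_per_deg * sd_az) *
    rlnorm(1, 0, model$rt_lognorm_sdlog)

  data.frame(
    trial_index = as.integer(trial_index),
    phase = phase,
    condition = if (is_plugged(model)) "plugged" else "binaural",
    stimulus_type = stimulus_type,
    level_dBA = level_dBA,
    target_az_deg = az,
    target_el_deg = el,
    resp_az_deg = resp_az,
    resp_el_deg = resp_el,
    rt_ms = rt
  )
}

#' Training schedule of gradual prior updating
#'
#' During feedback training the listener's spatial priors and azimuth sensory
#' reliability relax exponentially from their pre-training values toward
#' post-training values: parameter \eqn{\theta(t) = \theta_{end} +
#' (\theta_{start} - \theta_{end}) e^{-(t-1)/\tau}} for trial \eqn{t}. The
#' azimuth prior widens and recentres (responses escape the prior's capture),
#' the elevation prior narrows onto the horizon, and the azimuth sensory sd
#' shrinks as the head-shadow and remapped binaural cues become informative.
#'
#' @param n_trials number of training trials (default 500: ten azimuths, 50
#'   repeats each).
#' @param azimuth_prior_start,azimuth_prior_end,elevation_prior_start,elevation_prior_end
#'   [gaussian_prior()] endpoints.
#' @param azimuth_sensory_sd_start_deg,azimuth_sensory_sd_end_deg sensory-sd
#'   endpoints for the trained (HP) stimulus, degrees.
#' @param time_constant_trials exponential time constant \eqn{\tau}, trials.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(n_trials = 500,
                              azimuth_prior_start = gaussian_prior(-40, 15),
                              azimuth_prior_end = gaussian_prior(-10, 60),
                              elevation_prior_start = gaussian_prior(3, 12),
                              elevation_prior_end = gaussian_prior(0, 5),
                              azimuth_sensory_sd_start_deg = 30,
                              azimuth_sensory_sd_end_deg = 15,
                              time_constant_trials = 150) {
  stopifnot(n_trials >= 1, time_constant_trials > 0,
            azimuth_sensory_sd_start_deg > 0, azimuth_sensory_sd_end_deg > 0)
  structure(list(
    n_trials = as.integer(n_trials),
    azimuth_prior_start = azimuth_prior_start,
    azimuth_prior_end = azimuth_prior_end,
    elevation_prior_start = elevation_prior_start,
    elevation_prior_end = elevation_prior_end,
    azimuth_sensory_sd_start_deg = azimuth_sensory_sd_start_deg,
    azimuth_sensory_sd_end_deg = azimuth_sensory_sd_end_deg,
    time_constant_trials = time_constant_trials
  ), class = "training_schedule")
}

#' @export
print.training_schedule <- function(x, ...) {
  cat(sprintf(
    "Training schedule: %d trials, exponential time constant %.3g trials\n",
    x$n_trials, x$time_constant_trials))
  cat(sprintf("  azimuth prior: (%g, %g) -> (%g, %g) deg\n",
              x$azimuth_prior_start$mean_deg, x$azimuth_prior_start$sd_deg,
              x$azimuth_prior_end$mean_deg, x$azimuth_prior_end$sd_deg))
  cat(sprintf("  elevation prior: (%g, %g) -> (%g, %g) deg\n",
              x$elevation_prior_start$mean_deg, x$elevation_prior_start$sd_deg,
              x$elevation_prior_end$mean_deg, x$elevation_prior_end$sd_deg))
  cat(sprintf("  azimuth sensory sd: %g -> %g deg\n",
              x$azimuth_sensory_sd_start_deg, x$azimuth_sensory_sd_end_deg))
  invisible(x)
}

# Listener state at training trial t under exponential relaxation.
schedule_model_at <- function(model, schedule, t) {
  f <- exp(-(t - 1) / schedule$time_constant_trials)
  mix <- function(start, end) end + (start - end) * f
  model$azimuth_prior <- gaussian_prior(
    mix(schedule$azimuth_prior_start$mean_deg, schedule$azimuth_prior_end$mean_deg),
    mix(schedule$azimuth_prior_start$sd_deg, schedule$azimuth_prior_end$sd_deg)
  )
  model$elevation_prior <- gaussian_prior(
    mix(schedule$elevation_prior_start$mean_deg, schedule$elevation_prior_end$mean_deg),
    mix(schedule$elevation_prior_start$sd_deg, schedule$elevation_prior_end$sd_deg)
  )
  sd_t <- mix(schedule$azimuth_sensory_sd_start_deg, schedule$azimuth_sensory_sd_end_deg)
  model$azimuth_sensory_sd_deg[] <- sd_t
  model
}

# Deterministic per-trial RNG substream: the draw for trial i depends only on
# (session seed, i), so reordering the design never reshuffles trial noise.
with_trial_seed <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647))
  expr
}

# Uniform draw of a test/control target inside the frontal-hemifield diamond
# with elevation clipped to the speaker range.
draw_target <- function(az_range, el_range) {
  repeat {
    az <- runif(1, az_range[1], az_range[2])
    lo <- max(el_range[1], -(90 - abs(az)))
    hi <- min(el_range[2], 90 - abs(az))
    if (hi > lo) return(c(az, runif(1, lo, hi)))
  }
}

#' Simulate a full experimental session
#'
#' Generates a trial table for one of the canonical session designs:
#' \describe{
#'   \item{`training`}{500 feedback trials (or `schedule$n_trials`) of the
#'     HP stimulus at 60 dBA from the ten fixed azimuths on the horizon, each
#'     presented equally often in pseudo-random order; the listener's priors
#'     and azimuth sensory sd follow the [training_schedule()] trial by
#'     trial.}
#'   \item{`pre_test` / `post_test`}{180 trials of HP sounds at 50, 60 and 70
#'     dBA (60 each), at pseudo-random locations with azimuth in \[-60, 60\]°
#'     and elevation in \[-40, 50\]° inside the diamond, excluding the
#'     training locations.}
#'   \item{`control_binaural` / `control_plugged`}{300 trials: HP at six
#'     levels (45-70 dBA in 5-dB steps, 30 locations each) plus BB and LP at
#'     50 and 65 dBA (30 locations each), azimuth in \[-80, 80\]°, elevation
#'     in \[-40, 50\]°.}
#' }
#' The same seed always yields a byte-identical table; per-trial noise uses
#' deterministic substreams derived from `(seed, trial_index)`.
#'
#' @param model a [listener_model()]; for `training` designs its condition
#'   should be a plugged preset.
#' @param design one of `"training"`, `"pre_test"`, `"post_test"`,
#'   `"control_binaural"`, `"control_plugged"`.
#' @param seed integer session seed.
#' @param n_trials optional override of the design's trial count (scaled
#'   proportionally across the stimulus menu).
#' @param schedule a [training_schedule()]; only used (and defaulted) for the
#'   `training` design.
#' @return A trial-table data.frame.
#' @examples
#' tr <- simulate_session(listener_model("plugged_pre"), "pre_test", seed = 1)
#' table(tr$level_dBA)
#' @export
simulate_session <- function(model,
                             design = c("training", "pre_test", "post_test",
                                        "control_binaural", "control_plugged"),
                             seed = 1L, n_trials = NULL, schedule = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(model, "listener_model"))
  seed <- as.integer(seed)

  plan <- with_trial_seed(seed, 0L, session_plan(design, n_trials, schedule))
  phase <- switch(design,
    training = "training",
    pre_test = "pre",
    post_test = "post",
    control_binaural = "control",
    control_plugged = "control"
  )

  rows <- vector("list", nrow(plan$targets))
  for (i in seq_len(nrow(plan$targets))) {
    m_i <- if (!is.null(plan$schedule))
      schedule_model_at(model, plan$schedule, i) else model
    rows[[i]] <- with_trial_seed(seed, i, simulate_trial(
      m_i,
      list(azimuth_deg = plan$targets$az[i], elevation_deg = plan$targets$el[i]),
      stimulus_type = plan$targets$type[i],
      level_dBA = plan$targets$level[i],
      trial_index = i, phase = phase
    ))
  }
  do.call(rbind, rows)
}

# Build the randomized stimulus menu for a session design (runs inside the
# seed-0 substream of the session).
session_plan <- function(design, n_trials, schedule) {
  if (design == "training") {
    if (is.null(schedule)) schedule <- training_schedule(
      n_trials = if (is.null(n_trials)) 500 else n_trials)
    n <- schedule$n_trials
    reps <- ceiling(n / length(.training_azimuths))
    az <- sample(rep(.training_azimuths, reps))[seq_len(n)]
    targets <- data.frame(az = az, el = 0, type = "HP", level = 60)
    return(list(targets = targets, schedule = schedule))
  }

  if (design %in% c("pre_test", "post_test")) {
    n <- if (is.null(n_trials)) 180 else n_trials
    levels <- sample(rep(c(50, 60, 70), length.out = n))
    tt <- t(vapply(seq_len(n), function(i) {
      repeat {
        d <- draw_target(c(-60, 60), c(-40, 50))
        # test targets never coincide with the ten trained locations
        if (!(d[2] == 0 && d[1] %in% .training_azimuths)) return(d)
      }
    }, numeric(2)))
    targets <- data.frame(az = tt[, 1], el = tt[, 2], type = "HP", level = levels)
    return(list(targets = targets, schedule = NULL))
  }

  # control sessions: 180 HP (six levels) + 60 BB + 60 LP (two levels each)
  n <- if (is.null(n_trials)) 300 else n_trials
  menu <- c(
    lapply(seq(45, 70, by = 5), function(l) c(type = "HP", level = l)),
    lapply(c(50, 65), function(l) c(type = "BB", level = l)),
    lapply(c(50, 65), function(l) c(type = "LP", level = l))
  )
  weights <- c(rep(30, 6), rep(30, 4)) / 300
  counts <- round(weights * n)
  counts[1] <- counts[1] + (n - sum(counts))  # absorb rounding in HP45
  type <- unlist(mapply(function(m, k) rep(m[["type"]], k), menu, counts))
  level <- as.numeric(unlist(mapply(function(m, k) rep(m[["level"]], k), menu, counts)))
  ord <- sample(length(type))
  tt <- t(vapply(seq_along(type), function(i) draw_target(c(-80, 80), c(-40, 50)),
                 numeric(2)))
  targets <- data.frame(az = tt[, 1], el = tt[, 2],
                        type = type[ord], level = level[ord])
  list(targets = targets, schedule = NULL)
}

#' Simulate method for listener models
#'
#' Thin wrapper around [simulate_session()] following the base-R `simulate`
#' generic: returns a list of `nsim` trial tables (or a single table when
#' `nsim = 1`), with session seeds derived from `seed`.
#'
#' @param object a [listener_model()].
#' @param nsim number of sessions.
#' @param seed integer seed.
#' @param design,n_trials,schedule passed to [simulate_session()].
#' @param ... ignored.
#' @export
simulate.listener_model <- function(object, nsim = 1, seed = 1L,
                                    design = "pre_test", n_trials = NULL,
                                    schedule = NULL, ...) {
  out <- lapply(seq_len(nsim), function(k)
    simulate_session(object, design, seed = as.integer(seed) + k - 1L,
                     n_trials = n_trials, schedule = schedule))
  if (nsim == 1) out[[1]] else out
}
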