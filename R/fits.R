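#' Standardize to z-scores
#'
#' Centers and scales a numeric vector to mean 0 and sample standard
#' deviation 1 (denominator n - 1). Used to put response, proximal level and
#' target coordinates on a common dimensionless scale before multiple
#' regression, so that the fitted coefficients are directly comparable
#' standardized weights.
#'
#' @param values numeric vector, length >= 2, nonzero sample SD.
#' @return The standardized vector.
#' @examples
#' zscore(c(1, 2, 3))  # -1 0 1
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to z-score")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance predictor")
  (values - mean(values)) / s
}

#' Linear stimulus-response fit
#'
#' Ordinary least-squares fit of localization responses against target
#' angles, one spatial component at a time:
#' \deqn{R = a + b T}
#' with bias \eqn{a} (degrees) and gain \eqn{b} (dimensionless slope). An
#' ideal localizer has gain 1 and bias 0. Alongside the fit the summary
#' statistics of localization performance are computed: Pearson's r, the
#' coefficient of determination r^2, the SD of the residuals around the
#' fitted line, and the mean absolute localization error
#' MAE = mean |response - target| (on the raw stimulus-response differences,
#' not the fit residuals).
#'
#' @param targets_deg,responses_deg numeric vectors of equal length (n >= 3),
#'   degrees; targets must vary.
#' @return An object of class `loc_fit` with fields `gain`, `bias_deg`, `r`,
#'   `r2`, `residual_sd_deg`, `mae_deg`, `n`, and the underlying data.
#' @examples
#' f <- fit_stimulus_response(c(-60, -30, 0, 30, 60), c(-50, -40, -30, -20, -10))
#' coef(f)  # bias -30, gain 1/3
#' @export
fit_stimulus_response <- function(targets_deg, responses_deg) {
  if (length(targets_deg) != length(responses_deg))
    stop("targets and responses must have equal length")
  n <- length(targets_deg)
  if (n < 3) stop("need at least 3 trials for a stimulus-response fit")
  if (!all(is.finite(targets_deg)) || !all(is.finite(responses_deg)))
    stop("non-finite angle in stimulus-response data")
  if (var(targets_deg) == 0) stop("degenerate fit: targets do not vary")

  fit <- lm(responses_deg ~ targets_deg)
  res <- residuals(fit)
  # r undefined for constant responses (e.g. a fully prior-captured listener)
  r <- if (sd(responses_deg) == 0) NA_real_ else cor(targets_deg, responses_deg)
  structure(list(
    gain = unname(coef(fit)[2]),
    bias_deg = unname(coef(fit)[1]),
    r = r,
    r2 = r^2,
    residual_sd_deg = sd(res),
    mae_deg = mean(abs(responses_deg - targets_deg)),
    n = n,
    targets_deg = targets_deg,
    responses_deg = responses_deg,
    lm = fit
  ), class = "loc_fit")
}

#' @export
print.loc_fit <- function(x, digits = 3, ...) {
  cat("Stimulus-response fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  gain %.*g, bias %.*g deg, r^2 %.*g\n",
              digits, x$gain, digits, x$bias_deg, digits, x$r2))
  cat(sprintf("  residual SD %.*g deg, MAE %.*g deg\n",
              digits, x$residual_sd_deg, digits, x$mae_deg))
  invisible(x)
}

#' @export
summary.loc_fit <- function(object, ...) {
  out <- unclass(object)[c("gain", "bias_deg", "r", "r2",
                           "residual_sd_deg", "mae_deg", "n")]
  structure(out, class = "summary.loc_fit")
}

#' @export
print.summary.loc_fit <- function(x, ...) {
  print(unlist(x))
  invisible(x)
}

#' @export
coef.loc_fit <- function(object, ...) {
  c(bias_deg = object$bias_deg, gain = object$gain)
}

#' @export
predict.loc_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$targets_deg else newdata
  object$bias_deg + object$gain * t
}

#' @export
residuals.loc_fit <- function(object, ...) {
  object$responses_deg - predict(object)
}

#' @export
fitted.loc_fit <- function(object, ...) predict(object)

#' @export
plot.loc_fit <- function(x, xlab = "target (deg)", ylab = "response (deg)", ...) {
  plot(x$targets_deg, x$responses_deg, xlab = xlab, ylab = ylab, ...)
  abline(0, 1, lty = 2, col = "grey60")
  abline(x$bias_deg, x$gain)
  invisible(x)
}

# Shared machinery of the standardized multiple regressions: z-score the
# response and predictors and fit least squares without an intercept (the
# z-scored variables are already centered).
standardized_fit <- function(response, predictors, model_label, n_min = 10) {
  n <- length(response)
  if (n < n_min)
    stop("need at least ", n_min, " trials for the ", model_label, " cue regression")
  z_y <- zscore(response)
  Z <- vapply(predictors, zscore, numeric(n))
  kappa_z <- kappa(Z, exact = TRUE)
  collinearity_warning <- NULL
  if (kappa_z > 1e3) {
    collinearity_warning <- sprintf(
      "near-collinear standardized predictors (condition number %.3g)", kappa_z)
    warning(collinearity_warning, call. = FALSE)
  }
  fit <- lm(z_y ~ 0 + Z)
  coefs <- setNames(unname(coef(fit)), names(predictors))
  # statistics computed directly so an exact (zero-residual) fit stays silent
  rss <- sum(residuals(fit)^2)
  r2 <- 1 - rss / sum(z_y^2)
  sigma2 <- rss / (n - ncol(Z))
  ses <- setNames(sqrt(diag(sigma2 * solve(crossprod(Z)))), names(predictors))
  list(coefs = coefs, se = ses, r2 = r2, n = n,
       condition_number = kappa_z, warning = collinearity_warning, lm = fit)
}

#' Standardized cue-weight regressions
#'
#' Quantify the relative contributions of the acoustic cues to the
#' localization response through multiple linear regression on z-scored
#' variables (see [zscore()]), fit without an intercept.
#'
#' `fit_azimuth_cues()` regresses the standardized azimuth response on the
#' standardized proximal sound level at the free ear (computed per trial from
#' the sinusoidal head-shadow model, [proximal_level()]) and the standardized
#' target azimuth:
#' \deqn{\hat R_\alpha = p \hat I_{prox} + q \hat T_\alpha.}
#' A perfect localizer yields p = 0, q = 1; responses fully driven by the
#' ambiguous head-shadow level cue yield p = 1, q = 0. Negative p means
#' louder sounds push responses toward the free (left) ear.
#'
#' `fit_elevation_cues()` extends the regression to the elevation response:
#' \deqn{\hat R_\epsilon = p \hat I_{prox} + q \hat T_\alpha + s \hat T_\epsilon,}
#' optionally restricted to targets in the left (azimuth < 0) or right
#' (azimuth > 0) hemifield; targets exactly on the midline belong to neither.
#' An ideal localizer yields \[p, q, s\] = \[0, 0, 1\].
#'
#' The trials must span at least two distinct sound levels: with a single
#' level the proximal level is a deterministic monotone function of target
#' azimuth and the weights are unidentifiable, so the fit is refused.
#'
#' @param trials trial-table data.frame.
#' @param hse_db head-shadow magnitude used to build the proximal-level
#'   regressor (default 10 dB).
#' @param hemifield `"all"`, `"left"` or `"right"` (elevation model only).
#' @return An object of class `cue_fit`: standardized weights (`p`, `q` and,
#'   for the elevation model, `s`), their standard errors `se`, the multiple
#'   `r2`, the trial count `n`, the `condition_number` of the standardized
#'   design, and `hemifield`/`model` metadata.
#' @examples
#' tr <- simulate_session(listener_model("plugged_pre"), "pre_test", seed = 2)
#' fit_azimuth_cues(tr)
#' fit_elevation_cues(tr, hemifield = "left")
#' @export
fit_azimuth_cues <- function(trials, hse_db = 10) {
  trials <- as.data.frame(trials)
  if (length(unique(trials$level_dBA)) < 2)
    stop("collinear design: azimuth cue weights are unidentifiable with a ",
         "single sound level (proximal level is then a monotone function of ",
         "target azimuth)")
  iprox <- proximal_level(trials$target_az_deg, trials$level_dBA, hse_db)
  f <- standardized_fit(
    trials$resp_az_deg,
    list(p = iprox, q = trials$target_az_deg),
    model_label = "azimuth"
  )
  structure(c(list(model = "azimuth", hemifield = "all", hse_db = hse_db), f),
            class = "cue_fit")
}

#' @rdname fit_azimuth_cues
#' @export
fit_elevation_cues <- function(trials, hse_db = 10,
                               hemifield = c("all", "left", "right")) {
  hemifield <- match.arg(hemifield)
  trials <- as.data.frame(trials)
  keep <- switch(hemifield,
    all = rep(TRUE, nrow(trials)),
    left = trials$target_az_deg < 0,
    right = trials$target_az_deg > 0
  )
  trials <- trials[keep, , drop = FALSE]
  if (nrow(trials) < 10)
    stop("fewer than 10 trials in the '", hemifield,
         "' hemifield for the elevation cue regression")
  if (length(unique(trials$level_dBA)) < 2)
    stop("collinear design: elevation cue weights require at least two ",
         "distinct sound levels")
  iprox <- proximal_level(trials$target_az_deg, trials$level_dBA, hse_db)
  f <- standardized_fit(
    trials$resp_el_deg,
    list(p = iprox, q = trials$target_az_deg, s = trials$target_el_deg),
    model_label = "elevation"
  )
  structure(c(list(model = "elevation", hemifield = hemifield, hse_db = hse_db), f),
            class = "cue_fit")
}

#' @export
print.cue_fit <- function(x, digits = 3, ...) {
  cat("Standardized cue weights (", x$model, " response, hemifield ",
      x$hemifield, ", n = ", x$n, ")\n", sep = "")
  w <- x$coefs
  for (nm in names(w))
    cat(sprintf("  %s = %+.*f (SE %.3g)\n", nm, digits, w[[nm]], x$se[[nm]]))
  cat(sprintf("  multiple r^2 = %.*g\n", digits, x$r2))
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' @export
coef.cue_fit <- function(object, ...) object$coefs

#' @export
summary.cue_fit <- function(object, ...) {
  data.frame(weight = names(object$coefs),
             estimate = unname(object$coefs),
             se = unname(object$se),
             row.names = NULL)
}
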