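new_window_series <- function(df, kind, window_size, step, min_count) {
  structure(df, class = c("window_series", "data.frame"),
            kind = kind, window_size = window_size, step = step,
            min_count = min_count)
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("Window series (%s): %d centers, window %g, step %g\n",
              attr(x, "kind"), nrow(x), attr(x, "window_size"), attr(x, "step")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' @export
plot.window_series <- function(x, metric = "gain", ...) {
  plot(x$center, x[[metric]], type = "b",
       xlab = if (attr(x, "kind") == "trial_window") "trial (window center)"
              else "target azimuth (bin center, deg)",
       ylab = metric, ...)
  invisible(x)
}

#' Windowed training-dynamics analysis
#'
#' Slides a running window over the training trials (default 50 trials wide,
#' advancing in 5-trial steps; only fully contained windows are used, so 500
#' trials yield (500 - 50)/5 + 1 = 91 windows) and refits the azimuth
#' stimulus-response regression in each window. The resulting series of gain,
#' r^2, mean absolute error and mean reaction time tracks how localization
#' performance evolves with feedback training.
#'
#' @param trials training-phase trial table (sorted internally by
#'   `trial_index`); must contain at least `window` trials.
#' @param window window width, trials.
#' @param step shift between consecutive windows, trials.
#' @return A `window_series` data.frame with columns `center` (window
#'   midpoint in trial index), `gain`, `r2`, `mae_deg`, `rt_ms`, `n`.
#' @examples
#' tr <- simulate_session(listener_model("plugged_training"), "training", seed = 3)
#' ws <- windowed_training_metrics(tr)
#' nrow(ws)  # 91
#' @export
windowed_training_metrics <- function(trials, window = 50, step = 5) {
  trials <- as.data.frame(trials)
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  n <- nrow(trials)
  if (n < window)
    stop("need at least ", window, " trials for a ", window, "-trial window")
  starts <- seq(1L, n - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    w <- trials[s:(s + window - 1L), ]
    f <- fit_stimulus_response(w$target_az_deg, w$resp_az_deg)
    data.frame(center = s + (window - 1) / 2,
               gain = f$gain, r2 = f$r2, mae_deg = f$mae_deg,
               rt_ms = mean(w$rt_ms, na.rm = TRUE), n = window)
  })
  new_window_series(do.call(rbind, rows), "trial_window", window, step,
                    min_count = window)
}

#' Local elevation gain versus target azimuth
#'
#' Measures the elevation response gain locally, in azimuth bins of width
#' `bin_width_deg` shifted in `step_deg` steps across `range_deg` (defaults:
#' 20° bins, 5° steps, centers from -80° to +60°, i.e. 29 bins). Each bin
#' collects the trials whose target azimuth lies in \[center - w/2,
#' center + w/2) and refits the elevation stimulus-response regression.
#' Under monaural plugging this exposes the azimuth-dependent binaural
#' weighting of the spectral elevation cues: near-normal gain on the free
#' side falling toward zero on the plugged side. Bins holding fewer than
#' `min_count` trials (or without elevation variation) are reported as
#' missing (`NA`), never fit.
#'
#' @param trials trial table with elevation-varying targets.
#' @param bin_width_deg bin width, degrees.
#' @param step_deg shift between bin centers, degrees.
#' @param range_deg numeric length-2: first and last bin center, degrees.
#' @param min_count minimum trials per bin.
#' @return A `window_series` data.frame with columns `center` (bin-center
#'   azimuth), `gain`, `r2`, `mae_deg`, `n`.
#' @examples
#' tr <- simulate_session(listener_model("plugged_pre"), "control_plugged", seed = 4)
#' local_elevation_gain(tr)
#' @export
local_elevation_gain <- function(trials, bin_width_deg = 20, step_deg = 5,
                                 range_deg = c(-80, 60), min_count = 5) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L) stop("empty trial table")
  centers <- seq(range_deg[1], range_deg[2], by = step_deg)
  half <- bin_width_deg / 2
  rows <- lapply(centers, function(cc) {
    # inclusive left edge, exclusive right edge
    b <- trials[trials$target_az_deg >= cc - half &
                  trials$target_az_deg < cc + half, ]
    if (nrow(b) < min_count || length(unique(b$target_el_deg)) < 2 ||
        var(b$target_el_deg) == 0)
      return(data.frame(center = cc, gain = NA_real_, r2 = NA_real_,
                        mae_deg = NA_real_, n = nrow(b)))
    f <- fit_stimulus_response(b$target_el_deg, b$resp_el_deg)
    data.frame(center = cc, gain = f$gain, r2 = f$r2, mae_deg = f$mae_deg,
               n = nrow(b))
  })
  new_window_series(do.call(rbind, rows), "azimuth_bin", bin_width_deg,
                    step_deg, min_count)
}

#' Average window series across sessions
#'
#' Aligns several `window_series` objects (e.g. one per listener) on their
#' centers and returns the across-session mean and SD per center. Sessions
#' missing a value at a center are excluded from that center's average.
#'
#' @param series_list list of `window_series` objects with identical centers
#'   and metrics.
#' @param metrics metric columns to aggregate.
#' @return A data.frame with columns `center`, then `<metric>_mean`,
#'   `<metric>_sd` and `<metric>_n` for each metric.
#' @export
aggregate_window_series <- function(series_list,
                                    metrics = c("gain", "r2", "mae_deg")) {
  stopifnot(length(series_list) >= 1)
  centers <- series_list[[1]]$center
  for (s in series_list)
    if (!isTRUE(all.equal(s$center, centers)))
      stop("window series are not aligned on the same centers")
  metrics <- intersect(metrics, names(series_list[[1]]))
  out <- data.frame(center = centers)
  for (m in metrics) {
    vals <- vapply(series_list, function(s) as.numeric(s[[m]]),
                   numeric(length(centers)))
    vals <- matrix(vals, nrow = length(centers))
    out[[paste0(m, "_mean")]] <- rowMeans(vals, na.rm = TRUE)
    out[[paste0(m, "_sd")]] <- apply(vals, 1, sd, na.rm = TRUE)
    out[[paste0(m, "_n")]] <- rowSums(!is.na(vals))
  }
  for (col in grep("_(mean|sd)$", names(out), value = TRUE))
    out[[col]][is.nan(out[[col]])] <- NA
  out
}
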