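#' Double-polar directions
#'
#' In the double-polar coordinate system the azimuth angle is measured from
#' the midsagittal plane (positive rightward) and the elevation angle from the
#' horizontal plane (positive upward). Any physical direction in the frontal
#' hemifield satisfies \eqn{|\alpha| + |\epsilon| \le 90}°, the diamond-shaped
#' boundary of the frontal field.
#'
#' @param azimuth_deg,elevation_deg angles in degrees.
#' @return A data.frame with columns `azimuth_deg` and `elevation_deg`
#'   (vectorized).
#' @examples
#' double_polar(30, 20)
#' @export
double_polar <- function(azimuth_deg, elevation_deg) {
  stopifnot(length(azimuth_deg) == length(elevation_deg))
  if (!all(is.finite(azimuth_deg)) || !all(is.finite(elevation_deg)))
    stop("double-polar angles must be finite")
  bad <- !is_valid_direction(azimuth_deg, elevation_deg)
  if (any(bad))
    stop(sprintf(
      "direction outside the frontal hemifield: |azimuth| + |elevation| = %g > 90",
      abs(azimuth_deg[bad][1]) + abs(elevation_deg[bad][1])
    ))
  data.frame(azimuth_deg = azimuth_deg, elevation_deg = elevation_deg)
}

# Diamond-boundary test with rounding at 1e-9 so that directions on the 90
# degree rim are accepted regardless of float jitter.
is_valid_direction <- function(azimuth_deg, elevation_deg) {
  is.finite(azimuth_deg) & is.finite(elevation_deg) &
    round(abs(azimuth_deg) + abs(elevation_deg), 9) <= 90
}

#' Validate a trial table
#'
#' Checks every trial against the invariants of the trial-table contract:
#' known phase/condition/stimulus tokens, free-field level within a 30-90 dBA
#' sanity band, finite angles, targets inside the frontal-hemifield diamond
#' (|azimuth| + |elevation| <= 90°), training-phase targets on the horizon at
#' one of the ten fixed training azimuths, and nonnegative (or missing)
#' reaction times. Responses are head-pointing directions and are not
#' constrained to the diamond.
#'
#' @param trials a trial-table data.frame (see [read_trial_table()]).
#' @return A data.frame of violations with columns `trial_index`, `field` and
#'   `message`; zero rows means every trial is valid.
#' @examples
#' tr <- simulate_session(listener_model("binaural"), "pre_test", seed = 1)
#' nrow(validate_trials(tr))  # 0
#' @export
validate_trials <- function(trials) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L)
    stop("empty trial table: nothing to validate")
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ", paste(missing_cols, collapse = ", "))

  v <- list()
  flag <- function(idx, field, message) {
    if (length(idx))
      v[[length(v) + 1L]] <<- data.frame(
        trial_index = trials$trial_index[idx], field = field, message = message[idx]
      )
  }
  n <- nrow(trials)

  bad <- !(trials$phase %in% .phases)
  flag(which(bad), "phase", sprintf("unknown phase token '%s'", trials$phase))
  bad <- !(trials$condition %in% .conditions)
  flag(which(bad), "condition", sprintf("unknown condition token '%s'", trials$condition))
  bad <- !(trials$stimulus_type %in% .stimulus_types)
  flag(which(bad), "stimulus_type",
       sprintf("unknown stimulus_type token '%s'", trials$stimulus_type))

  bad <- !is.finite(trials$trial_index) | trials$trial_index < 1
  flag(which(bad), "trial_index", rep("trial_index must be >= 1", n))

  bad <- !is.finite(trials$level_dBA) | trials$level_dBA < 30 | trials$level_dBA > 90
  flag(which(bad), "level_dBA",
       sprintf("level %.6g dBA outside [30, 90]", trials$level_dBA))

  bad <- !is.finite(trials$target_az_deg) | !is.finite(trials$target_el_deg)
  flag(which(bad), "target", rep("non-finite target angle", n))

  s <- round(abs(trials$target_az_deg) + abs(trials$target_el_deg), 9)
  bad <- is.finite(s) & s > 90
  flag(which(bad), "target",
       sprintf("|alpha|+|epsilon| = %.6g > 90", s))

  bad <- !is.finite(trials$resp_az_deg) | !is.finite(trials$resp_el_deg)
  flag(which(bad), "response", rep("non-finite response angle", n))

  is_training <- trials$phase == "training"
  bad <- is_training & (trials$target_el_deg != 0 |
                          !(trials$target_az_deg %in% .training_azimuths))
  flag(which(bad), "target",
       rep("training target must be at elevation 0 and a fixed training azimuth", n))

  bad <- !is.na(trials$rt_ms) & trials$rt_ms < 0
  flag(which(bad), "rt_ms", rep("reaction time must be nonnegative or missing", n))

  if (length(v)) {
    out <- do.call(rbind, v)
    out <- out[order(out$trial_index), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(trial_index = integer(), field = character(), message = character())
  }
}

#' Read and write trial tables
#'
#' Trial tables are comma-separated UTF-8 files with the exact header
#' `trial_index,phase,condition,stimulus_type,level_dBA,target_az_deg,target_el_deg,resp_az_deg,resp_el_deg,rt_ms`.
#' Angles are decimal degrees; `rt_ms` may be empty for missing reaction
#' times (never 0). Writing and re-reading reproduces numeric fields to at
#' least 1e-6 and enum fields exactly.
#'
#' @param path file path.
#' @param trials a trial-table data.frame.
#' @return `read_trial_table()` returns the trial-table data.frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (!identical(names(raw), .trial_columns)) {
    missing_cols <- setdiff(.trial_columns, names(raw))
    if (length(missing_cols))
      stop("missing column(s) in trial table: ", paste(missing_cols, collapse = ", "))
    stop("trial-table header must be exactly: ", paste(.trial_columns, collapse = ","))
  }
  if (nrow(raw) == 0L) return(empty_trial_table())

  check_enum <- function(col, allowed) {
    bad <- which(!(raw[[col]] %in% allowed))
    if (length(bad))
      stop(sprintf("row %d, column '%s': unknown token '%s'",
                   bad[1], col, raw[[col]][bad[1]]))
  }
  check_enum("phase", .phases)
  check_enum("condition", .conditions)
  check_enum("stimulus_type", .stimulus_types)

  num <- function(col, allow_empty = FALSE) {
    x <- raw[[col]]
    empty <- !nzchar(trimws(x))
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !empty)
    if (length(bad))
      stop(sprintf("row %d, column '%s': non-numeric value '%s'",
                   bad[1], col, x[bad[1]]))
    if (!allow_empty && any(empty))
      stop(sprintf("row %d, column '%s': empty value", which(empty)[1], col))
    out
  }

  data.frame(
    trial_index = as.integer(num("trial_index")),
    phase = raw$phase,
    condition = raw$condition,
    stimulus_type = raw$stimulus_type,
    level_dBA = num("level_dBA"),
    target_az_deg = num("target_az_deg"),
    target_el_deg = num("target_el_deg"),
    resp_az_deg = num("resp_az_deg"),
    resp_el_deg = num("resp_el_deg"),
    rt_ms = num("rt_ms", allow_empty = TRUE)
  )
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  trials <- as.data.frame(trials)[, .trial_columns]
  write.csv(trials, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

empty_trial_table <- function() {
  data.frame(
    trial_index = integer(), phase = character(), condition = character(),
    stimulus_type = character(), level_dBA = numeric(),
    target_az_deg = numeric(), target_el_deg = numeric(),
    resp_az_deg = numeric(), resp_el_deg = numeric(), rt_ms = numeric()
  )
}
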