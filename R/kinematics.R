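SAMPLE_DT_MS <- 5 # 200 Hz tablet sampling
STATIONARY_TOL_CM <- 0.01 # "no further change" tolerance, tablet quantization scale
MIN_STATIONARY_MS <- 100 / 3 # two vertical monitor refreshes
SLOW_SPEED_CM_S <- 20
SG_ORDER <- 2
SG_WINDOW <- 31 # samples; 155 ms at 200 Hz

#' Detect movement onset and offset
#'
#' Onset is the first sample beyond `home_radius_cm` of the home position.
#' Offset is the first sample at or after onset that is followed by at least
#' 33.3 ms with no detectable change in stylus coordinates; at 5 ms sampling
#' this requires 7 consecutive stationary inter-sample steps (35 ms, the first
#' duration meeting the minimum). A step is stationary when the displacement
#' between consecutive samples is below `tol_cm`. If no such run exists the
#' offset falls back to the last sample and `no_offset` is flagged so the
#' trial can be excluded downstream.
#'
#' @param traj A trajectory tibble with columns `t_ms`, `x_cm`, `y_cm`.
#' @param home_radius_cm Radius of the home region, cm.
#' @param tol_cm Stationarity tolerance on consecutive-sample displacement.
#' @param min_stationary_ms Minimum stationary duration, ms.
#' @return A list with `onset_ms`, `offset_ms`, `no_offset`.
#' @export
detect_movement_offset <- function(traj, home_radius_cm = 0.5,
                                   tol_cm = STATIONARY_TOL_CM,
                                   min_stationary_ms = MIN_STATIONARY_MS) {
  stopifnot(all(diff(traj$t_ms) > 0))
  r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  onset_idx <- which(r > home_radius_cm)[1]
  if (is.na(onset_idx)) stop("trajectory never leaves the home region")
  n <- nrow(traj)
  dt <- median(diff(traj$t_ms))
  need <- ceiling(min_stationary_ms / dt) # 7 intervals at 5 ms
  step <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  stationary <- step < tol_cm # step i: sample i -> i + 1
  offset_idx <- NA_integer_
  i <- onset_idx + 1L # offset is sought strictly after movement initiation
  while (i + need <= n) {
    if (all(stationary[i:(i + need - 1L)])) {
      offset_idx <- i
      break
    }
    # jump past the first moving step in the window
    i <- i + which(!stationary[i:(i + need - 1L)])[1]
  }
  if (is.na(offset_idx)) {
    list(onset_ms = traj$t_ms[onset_idx], offset_ms = traj$t_ms[n], no_offset = TRUE)
  } else {
    list(onset_ms = traj$t_ms[onset_idx], offset_ms = traj$t_ms[offset_idx], no_offset = FALSE)
  }
}

#' Mean movement speed between onset and offset
#'
#' Path length (summed consecutive-sample displacements) divided by duration.
#' Movements slower than 20 cm/s (strictly) are flagged slow.
#'
#' @param traj Trajectory tibble (`t_ms`, `x_cm`, `y_cm`).
#' @param onset_ms,offset_ms Movement window from [detect_movement_offset()].
#' @param threshold_cm_s Slow-movement threshold.
#' @return A list with `mean_speed_cm_s` and `slow_flag`.
#' @export
mean_speed <- function(traj, onset_ms, offset_ms, threshold_cm_s = SLOW_SPEED_CM_S) {
  if (offset_ms <= onset_ms) stop("offset must follow onset")
  keep <- traj$t_ms >= onset_ms & traj$t_ms <= offset_ms
  x <- traj$x_cm[keep]
  y <- traj$y_cm[keep]
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  speed <- path / ((offset_ms - onset_ms) / 1000)
  list(mean_speed_cm_s = speed, slow_flag = speed < threshold_cm_s)
}

#' Endpoint direction and extent relative to a target
#'
#' Direction is the signed angular difference (degrees, clockwise positive,
#' wrapped to (-180, 180]) between the endpoint bearing about the home
#' position and the target-center bearing; extent is the Euclidean distance
#' from home to the endpoint.
#'
#' @param x,y Endpoint coordinates, cm (vectorized).
#' @param target_location_deg Target-center bearing(s), degrees.
#' @return A tibble with `direction_deg` and `extent_cm`.
#' @export
endpoint_metrics <- function(x, y, target_location_deg) {
  extent <- sqrt(x^2 + y^2)
  if (any(extent == 0)) stop("endpoint at the home position has no defined direction")
  fast_tibble(
    direction_deg = wrap_angle_deg(bearing_deg(x, y) - target_location_deg),
    extent_cm = extent
  )
}

#' Maximum path deviation from the straight home-endpoint line
#'
#' The maximum distance of any sample in the movement window from the straight
#' segment connecting the home position to the movement endpoint (the sample
#' at offset).
#'
#' @param traj Trajectory tibble.
#' @param onset_ms,offset_ms Movement window.
#' @return Maximum deviation in cm.
#' @export
max_path_deviation <- function(traj, onset_ms, offset_ms) {
  keep <- traj$t_ms >= onset_ms & traj$t_ms <= offset_ms
  x <- traj$x_cm[keep]
  y <- traj$y_cm[keep]
  ex <- x[length(x)]
  ey <- y[length(y)]
  len2 <- ex^2 + ey^2
  if (len2 == 0) stop("endpoint coincides with the home position")
  # projection of each sample on the segment, clamped to [0, 1]
  tproj <- pmin(pmax((x * ex + y * ey) / len2, 0), 1)
  max(sqrt((x - tproj * ex)^2 + (y - tproj * ey)^2))
}

# Savitzky-Golay first-derivative speed; NA where the full window does not fit
sg_speed <- function(traj, window = SG_WINDOW, order = SG_ORDER) {
  n <- nrow(traj)
  dt_s <- median(diff(traj$t_ms)) / 1000
  if (n < window) {
    return(rep(NA_real_, n))
  }
  fc <- signal::sgolay(p = order, n = window, m = 1, ts = dt_s)
  ctr <- (window + 1) / 2
  cvec <- fc[ctr, ]
  half <- (window - 1) / 2
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    vx[i] <- sum(cvec * traj$x_cm[idx])
    vy[i] <- sum(cvec * traj$y_cm[idx])
  }
  sqrt(vx^2 + vy^2)
}

#' Movement direction at the time of peak velocity
#'
#' Speed is the magnitude of the Savitzky-Golay first derivative (order 2,
#' 31-sample window = 155 ms at 200 Hz) of the x and y stylus coordinates.
#' The peak is located within the movement window, restricted to samples where
#' the full filter window fits; direction is, by default, the bearing of the
#' stylus *position* at the peak sample relative to the target bearing
#' (consistent with the endpoint definition), or the bearing of the velocity
#' vector with `method = "velocity"`.
#'
#' @param traj Trajectory tibble.
#' @param target_location_deg Target-center bearing, degrees.
#' @param onset_ms,offset_ms Movement window.
#' @param method `"position"` (default) or `"velocity"`.
#' @param window,order Savitzky-Golay filter settings.
#' @param fallback If `TRUE` (default) and fewer samples than `window` are
#'   available, the largest odd window `>= 5` that fits is used; if `FALSE`,
#'   `NA` is returned for such trials.
#' @return A list with `peakvel_direction_deg`, `peak_speed_cm_s`,
#'   `peak_time_ms`.
#' @export
direction_at_peak_velocity <- function(traj, target_location_deg,
                                       onset_ms, offset_ms,
                                       method = c("position", "velocity"),
                                       window = SG_WINDOW, order = SG_ORDER,
                                       fallback = TRUE) {
  method <- match.arg(method)
  n <- nrow(traj)
  if (n < window) {
    if (!fallback || n < 5) {
      return(list(
        peakvel_direction_deg = NA_real_, peak_speed_cm_s = NA_real_,
        peak_time_ms = NA_real_
      ))
    }
    window <- max(5L, n - (1 - n %% 2)) # largest odd window that fits
  }
  dt_s <- median(diff(traj$t_ms)) / 1000
  fc <- signal::sgolay(p = order, n = window, m = 1, ts = dt_s)
  ctr <- (window + 1) / 2
  cvec <- fc[ctr, ]
  half <- (window - 1) / 2
  valid <- (half + 1):(n - half)
  in_window <- traj$t_ms[valid] >= onset_ms & traj$t_ms[valid] <= offset_ms
  valid <- valid[in_window]
  if (length(valid) == 0) {
    return(list(
      peakvel_direction_deg = NA_real_, peak_speed_cm_s = NA_real_,
      peak_time_ms = NA_real_
    ))
  }
  vx <- vapply(valid, function(i) sum(cvec * traj$x_cm[(i - half):(i + half)]), 0)
  vy <- vapply(valid, function(i) sum(cvec * traj$y_cm[(i - half):(i + half)]), 0)
  speed <- sqrt(vx^2 + vy^2)
  k <- which.max(speed)
  i_pk <- valid[k]
  brg <- if (method == "position") {
    bearing_deg(traj$x_cm[i_pk], traj$y_cm[i_pk])
  } else {
    bearing_deg(vx[k], vy[k])
  }
  list(
    peakvel_direction_deg = wrap_angle_deg(brg - target_location_deg),
    peak_speed_cm_s = speed[k],
    peak_time_ms = traj$t_ms[i_pk]
  )
}

#' Summarize one trajectory into per-trial kinematic measures
#'
#' @param traj Trajectory tibble for a single trial.
#' @param target_location_deg Target-center bearing, degrees.
#' @param ... Passed to [direction_at_peak_velocity()].
#' @return A one-row tibble: onset/offset times, endpoint coordinates and
#'   metrics, mean speed and slow flag, maximum path deviation, peak-velocity
#'   direction and speed, and a `no_offset` flag.
#' @export
summarize_trajectory <- function(traj, target_location_deg, ...) {
  off <- detect_movement_offset(traj)
  sp <- mean_speed(traj, off$onset_ms, off$offset_ms)
  i_off <- which(traj$t_ms == off$offset_ms)[1]
  ep <- endpoint_metrics(traj$x_cm[i_off], traj$y_cm[i_off], target_location_deg)
  dev <- max_path_deviation(traj, off$onset_ms, off$offset_ms)
  pk <- direction_at_peak_velocity(traj, target_location_deg,
                                   off$onset_ms, off$offset_ms, ...)
  tibble::tibble(
    onset_ms = off$onset_ms, offset_ms = off$offset_ms, no_offset = off$no_offset,
    endpoint_x_cm = traj$x_cm[i_off], endpoint_y_cm = traj$y_cm[i_off],
    direction_deg = ep$direction_deg, extent_cm = ep$extent_cm,
    mean_speed_cm_s = sp$mean_speed_cm_s, slow_flag = sp$slow_flag,
    max_dev_cm = dev,
    peakvel_direction_deg = pk$peakvel_direction_deg,
    peak_speed_cm_s = pk$peak_speed_cm_s,
    peak_time_ms = pk$peak_time_ms
  )
}

#' Compute kinematic summaries for a set of trials
#'
#' @param trajectories Long trajectory tibble (`trial_id`, `t_ms`, `x_cm`,
#'   `y_cm`).
#' @param trials Trial tibble with `trial_id` and `location_deg`.
#' @param ... Passed to [summarize_trajectory()].
#' @return A tibble with one row per trial (keyed by `trial_id`).
#' @export
compute_kinematics <- function(trajectories, trials, ...) {
  loc <- setNames(trials$location_deg, trials$trial_id)
  parts <- lapply(split(trajectories, trajectories$trial_id), function(tr) {
    res <- summarize_trajectory(tr, loc[[tr$trial_id[1]]], ...)
    res$trial_id <- tr$trial_id[1]
    res
  })
  out <- dplyr::bind_rows(parts)
  out[match(trials$trial_id[trials$trial_id %in% out$trial_id], out$trial_id), ]
}
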