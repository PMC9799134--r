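EXPLORED_DENOMINATOR <- c(direction = ARC_CENTRAL_ANGLE_DEG, extent = TARGET_EXTENT_CM)

#' Per-target-location IQR and its mean
#'
#' Endpoint variability is quantified as the interquartile range
#' (linear-interpolation quantiles), computed separately for each target
#' location and then averaged (unweighted) across the three locations, so that
#' target-specific spatial biases do not inflate the spread.
#'
#' @param values Numeric values (e.g., per-trial direction in degrees or
#'   extent in cm).
#' @param location Target location of each value, degrees.
#' @param locations The required set of locations.
#' @return A list with `per_location` (tibble `location_deg`, `iqr`) and
#'   `mean_iqr`.
#' @export
iqr_by_target <- function(values, location, locations = TARGET_LOCATIONS_DEG) {
  missing_loc <- setdiff(locations, unique(location))
  if (length(missing_loc) > 0) {
    stop("no trials for target location(s): ", paste(missing_loc, collapse = ", "))
  }
  iqrs <- vapply(locations, function(l) iqr_linear(values[location == l]), 0)
  list(
    per_location = tibble::tibble(location_deg = locations, iqr = iqrs),
    mean_iqr = mean(iqrs)
  )
}

#' Explored variability: IQR as a percentage of the redundant span
#'
#' Direction IQRs (degrees) are divided by 30.56 degrees (the central angle of
#' the 8 cm arc targets at 15 cm radius) and extent IQRs (cm) by 8 cm (the
#' length of the radial line targets), then multiplied by 100. 100% means the
#' endpoint spread covered the full length of the redundant target.
#'
#' @param iqr_native IQR in native units (degrees or cm); vectorized.
#' @param dimension `"direction"` or `"extent"` (recycled).
#' @return Explored variability in percent.
#' @export
explored_variability <- function(iqr_native, dimension) {
  stopifnot(all(dimension %in% names(EXPLORED_DENOMINATOR)), all(iqr_native >= 0))
  100 * iqr_native / EXPLORED_DENOMINATOR[dimension]
}

#' Invert the explored-variability conversion
#'
#' @param pct Explored variability in percent.
#' @param dimension `"direction"` or `"extent"`.
#' @return IQR in native units (degrees or cm).
#' @export
iqr_from_explored <- function(pct, dimension) {
  stopifnot(all(dimension %in% names(EXPLORED_DENOMINATOR)), all(pct >= 0))
  pct / 100 * EXPLORED_DENOMINATOR[dimension]
}

#' Per-subject explored-variability table
#'
#' Computes direction and extent IQRs (per target location, then averaged) and
#' their explored-variability percentages, per subject x priming condition x
#' phase. Excluded trials are dropped when an `excluded` column is present.
#' In the test phase each mini-block's final (test) trial is dropped, because
#' it reflects the correction to the preceding feedback rather than baseline
#' variability. If a `peakvel_direction_deg` column is present, direction
#' variability is additionally computed at the time of peak velocity
#' (`stage = "peak_velocity"`).
#'
#' @param trials Trial tibble with endpoints (and optionally exclusion flags
#'   and peak-velocity directions).
#' @param keep_locations If `TRUE`, per-location rows are returned alongside
#'   the across-location average (`location = "avg"`).
#' @return A tidy tibble: `subject_id`, `priming_condition`, `phase`,
#'   `dimension`, `stage`, `location`, `iqr_native`, `explored_pct`.
#' @export
phase_variability_table <- function(trials, keep_locations = FALSE) {
  if ("excluded" %in% names(trials)) {
    trials <- trials[!trials$excluded, , drop = FALSE]
  }
  trials <- trials[!(trials$phase == "test" & trials$role == "test"), , drop = FALSE]

  ep <- endpoint_metrics(trials$endpoint_x_cm, trials$endpoint_y_cm, trials$location_deg)
  trials$.dir <- ep$direction_deg
  trials$.ext <- ep$extent_cm

  measures <- list(
    list(col = ".dir", dimension = "direction", stage = "endpoint"),
    list(col = ".ext", dimension = "extent", stage = "endpoint")
  )
  if ("peakvel_direction_deg" %in% names(trials)) {
    measures <- c(measures, list(
      list(col = "peakvel_direction_deg", dimension = "direction", stage = "peak_velocity")
    ))
  }

  key <- interaction(trials$subject_id, trials$priming_condition, trials$phase,
                     drop = TRUE)
  parts <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    sub <- trials[idx, , drop = FALSE]
    dplyr::bind_rows(lapply(measures, function(m) {
      v <- sub[[m$col]]
      ok <- !is.na(v)
      res <- iqr_by_target(v[ok], sub$location_deg[ok])
      rows <- tibble::tibble(
        subject_id = sub$subject_id[1],
        priming_condition = sub$priming_condition[1],
        phase = sub$phase[1],
        dimension = m$dimension, stage = m$stage,
        location = "avg", iqr_native = res$mean_iqr
      )
      if (keep_locations) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          subject_id = sub$subject_id[1],
          priming_condition = sub$priming_condition[1],
          phase = sub$phase[1],
          dimension = m$dimension, stage = m$stage,
          location = as.character(res$per_location$location_deg),
          iqr_native = res$per_location$iqr
        ))
      }
      rows
    }))
  })
  out <- dplyr::bind_rows(parts)
  out$explored_pct <- explored_variability(out$iqr_native, out$dimension)
  dplyr::arrange(out, .data$subject_id, .data$priming_condition, .data$phase,
                 .data$dimension, .data$stage, .data$location)
}
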